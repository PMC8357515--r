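test_that("discrete_conv2d matches the four-nested-loop oracle", {
  set.seed(1)
  # the worked 6x6 / 4x4 case: valid output is 3x3
  P <- matrix(rnorm(36), 6, 6); Q <- matrix(rnorm(16), 4, 4)
  out <- discrete_conv2d(P, Q)
  expect_equal(dim(out), c(3L, 3L))
  expect_equal(out, conv_oracle(P, Q), tolerance = 1e-12)

  # random sizes and kernels
  for (rep in 1:20) {
    n <- sample(4:8, 1); q <- sample(1:min(4, n), 1)
    P <- matrix(rnorm(n * n), n, n); Q <- matrix(rnorm(q * q), q, q)
    expect_equal(discrete_conv2d(P, Q), conv_oracle(P, Q), tolerance = 1e-12)
  }

  # trivial contracts: 1x1 scaling kernel, zero input yields the bias
  P <- matrix(rnorm(25), 5, 5)
  expect_equal(discrete_conv2d(P, matrix(2, 1, 1)), 2 * P)
  expect_true(all(discrete_conv2d(matrix(0, 5, 5), Q, bias = 3) == 3))

  # stride and dilation against a direct reindexing oracle
  X <- matrix(rnorm(100), 10, 10); K <- matrix(rnorm(9), 3, 3)
  d2 <- discrete_conv2d(X, K, dilation = 2)
  or2 <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    s <- 0
    for (a in 1:3) for (b in 1:3) s <- s + X[i + (a - 1) * 2, j + (b - 1) * 2] * K[a, b]
    or2[i, j] <- s
  }
  expect_equal(d2, or2, tolerance = 1e-12)
  s2 <- discrete_conv2d(X, K, stride = 2)
  full <- conv_oracle(X, K)
  expect_equal(s2, full[seq(1, 8, by = 2), seq(1, 8, by = 2)], tolerance = 1e-12)
  expect_error(discrete_conv2d(matrix(0, 3, 3), matrix(rnorm(16), 4, 4)), "larger")
})

test_that("output_size implements the floored size formula", {
  expect_equal(output_size(6, 4, 0, 1), 3L)
  expect_equal(output_size(6, 4, 1, 1), 5L)
  expect_equal(output_size(128, 5, 2, 1), 128L)
  expect_equal(output_size(7, 2, 0, 2), 3L)   # floored division
  expect_error(output_size(3, 5, 0, 1), "larger")
})

test_that("hdc_max_gap runs the backward recursion", {
  expect_equal(hdc_max_gap(c(2, 4, 5))$max_gaps, c(2L, 4L, 5L))
  expect_equal(hdc_max_gap(7)$max_gaps, 7L)
  expect_equal(hdc_max_gap(c(1, 1, 1))$max_gaps, c(1L, 1L, 1L))
  expect_error(hdc_max_gap(integer(0)), "empty")
  # property over random schedules
  set.seed(5)
  for (rep in 1:100) {
    lam <- sample(1:6, sample(1:5, 1), replace = TRUE)
    N <- hdc_max_gap(lam)$max_gaps
    expect_equal(N[length(N)], lam[length(lam)])
    expect_true(all(N >= lam))
  }
})

test_that("check_no_gridding agrees with brute-force footprint composition", {
  expect_true(check_no_gridding(c(1, 2, 5), 3)$ok)
  expect_false(check_no_gridding(c(2, 2, 2), 3)$ok)
  expect_gt(check_no_gridding(c(2, 2, 2), 3)$n_gaps, 0)
  expect_true(check_no_gridding(1, 4)$ok)
  set.seed(6)
  for (rep in 1:30) {
    lam <- sample(1:5, sample(1:4, 1), replace = TRUE)
    q <- sample(2:4, 1)
    expect_equal(check_no_gridding(lam, q)$ok, footprint_oracle(lam, q))
  }
})

test_that("activation functions satisfy their identities", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid_deriv(0), 0.25)
  expect_lt(abs(sigmoid(30) - 1), 1e-12)
  expect_lt(sigmoid(-30), 1e-12)
  cg <- seq(-20, 20, length.out = 1e4)
  expect_lt(max(abs(exp(-cg) / (1 + exp(-cg))^2 - sigmoid_deriv(cg))), 1e-12)

  expect_equal(relu(-3), 0); expect_equal(relu_deriv(-3), 0)
  expect_equal(relu(5), 5);  expect_equal(relu_deriv(5), 1)
  expect_equal(relu(0), 0);  expect_equal(relu_deriv(0), 0)
  m <- matrix(c(-1, 0, 2, 3), 2)
  expect_equal(relu_deriv(m), matrix(c(0, 0, 1, 1), 2))
})

test_that("mse_loss matches the elementwise sum", {
  expect_equal(mse_loss(c(1, 1), c(1, 1)), 0)
  expect_equal(mse_loss(c(1, 0), c(0, 1), m = 2), 0.5)
  set.seed(7)
  K <- matrix(rnorm(20), 4, 5); G <- matrix(rnorm(20), 4, 5)
  s <- 0
  for (i in 1:4) for (j in 1:5) s <- s + (K[i, j] - G[i, j])^2
  expect_equal(mse_loss(K, G), s / 40)
  expect_error(mse_loss(1:3, 1:4), "shape")
})

test_that("build_dlfcnn reproduces the layer table and is size-agnostic", {
  spec <- build_dlfcnn()
  maps <- vapply(spec$layers, `[[`, 0L, "n_maps")
  expect_equal(maps, c(14L, 14L, 14L, 14L, 28L, 28L, 28L, 28L, 52L))
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_equal(kinds[c(2, 4, 6, 8)], rep("downsample", 4))
  expect_equal(spec$layers[[9]]$kind, "conv_as_fc")
  dils <- vapply(spec$layers, `[[`, 0L, "dilation")
  expect_equal(dils[c(3, 5, 7)], c(2L, 4L, 5L))

  wts <- init_network_weights(spec, seed = 1)
  for (n in c(32L, 64L, 128L)) {
    px <- matrix(rnorm(n * n, -400, 300), n, n)
    fw <- periseg:::fcn_forward(spec, wts, px)
    expect_equal(dim(fw$prob), c(n, n))
    expect_true(all(fw$prob > 0 & fw$prob < 1))
  }
  expect_error(periseg:::fcn_forward(spec, wts, matrix(0, 16, 16)), "minimum")
})

test_that("realized layer sizes follow the output-size formula", {
  spec <- build_dlfcnn()
  wts <- init_network_weights(spec, seed = 2)
  in_maps <- periseg:::layer_in_maps(spec)
  for (n in c(32L, 64L, 128L)) {
    X <- periseg:::as_feature_cube(matrix(rnorm(n * n), n, n))
    size <- n
    for (k in seq_along(spec$layers)) {
      l <- spec$layers[[k]]
      if (l$kind == "downsample") {
        p <- periseg:::cpp_maxpool2(X)
        X <- p$Y
        if (!p$identity) size <- output_size(size, 2, 0, 2)
      } else {
        X <- periseg:::cpp_conv2d(X, wts[[l$name]]$Wm, wts[[l$name]]$b,
                                  l$kernel_size, l$stride, l$padding, l$dilation)
        size <- output_size(size, l$kernel_size, l$padding, l$stride, l$dilation)
      }
      expect_equal(dim(X)[1], size, info = sprintf("n=%d layer=%s", n, l$name))
    }
  }
})

test_that("network weights initialize reproducibly with correct shapes", {
  spec <- build_dlfcnn()
  w1 <- init_network_weights(spec, seed = 9)
  w2 <- init_network_weights(spec, seed = 9)
  expect_identical(w1, w2)
  expect_equal(dim(w1$C1$Wm), c(14L, 4L))       # 1 in-map, 2x2
  expect_equal(dim(w1$C5$Wm), c(28L, 14L * 25L))
  expect_equal(dim(w1$F9$Wm), c(52L, 28L))
  expect_equal(dim(w1$head$Wm), c(1L, 52L))
})

test_that("layer backward passes match central finite differences", {
  set.seed(11)
  spec <- build_dlfcnn()
  wts <- init_network_weights(spec, seed = 12)
  px <- matrix(rnorm(32 * 32, -400, 300), 32, 32)
  K <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
  loss_fn <- function(w) mse_loss(K, periseg:::fcn_forward(spec, w, px)$prob)
  fw <- periseg:::fcn_forward(spec, wts, px, keep = TRUE)
  grads <- periseg:::zero_grads(wts)
  grads <- periseg:::fcn_backward(spec, wts, fw,
                                  periseg:::mse_loss_grad(K, fw$prob), grads)
  eps <- 1e-5
  for (nm in names(wts)) {
    for (k in sample(length(wts[[nm]]$Wm), min(2, length(wts[[nm]]$Wm)))) {
      wp <- wts; wp[[nm]]$Wm[k] <- wp[[nm]]$Wm[k] + eps
      wm <- wts; wm[[nm]]$Wm[k] <- wm[[nm]]$Wm[k] - eps
      num <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
      ana <- grads[[nm]]$Wm[k]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-4,
                label = sprintf("gradient of %s[%d]", nm, k))
    }
    bp <- wts; bp[[nm]]$b[1] <- bp[[nm]]$b[1] + eps
    bm <- wts; bm[[nm]]$b[1] <- bm[[nm]]$b[1] - eps
    num <- (loss_fn(bp) - loss_fn(bm)) / (2 * eps)
    expect_lt(abs(num - grads[[nm]]$b[1]) / max(abs(num), abs(grads[[nm]]$b[1]), 1e-8),
              1e-4, label = sprintf("bias gradient of %s", nm))
  }
})

test_that("baseline patch network classifies patches and slides over slices", {
  spec <- build_baseline_cnn(32L)
  maps <- vapply(spec$layers, `[[`, 0L, "n_maps")
  expect_equal(maps, c(14L, 14L, 14L, 14L, 28L, 28L, 28L, 28L, 52L))
  expect_error(build_baseline_cnn(8L))
  wts <- init_network_weights(spec, seed = 3)
  p <- periseg:::patch_forward(spec, wts, matrix(rnorm(32 * 32), 32, 32))
  expect_length(p$prob, 1)
  expect_true(p$prob > 0 && p$prob < 1)

  trained <- structure(list(spec = spec, weights = wts,
                            config = training_config(seed = 1)),
                       class = "trained_network")
  pm <- predict_prob(trained, matrix(rnorm(40 * 40, -300, 200), 40, 40), stride = 8L)
  expect_equal(dim(pm), c(40L, 40L))
})

test_that("training reduces the loss and is seed-reproducible", {
  co <- generate_cohort(8, 0, small_lesion_config(), seed = 21)
  data <- lapply(co, function(s) list(slice = s$slice, mask = s$truth$lesion_mask))
  cfg <- training_config(epochs = 3L, batch_size = 4L, seed = 31L)
  tr1 <- train_network(build_dlfcnn(), data, cfg)
  expect_true(all(is.finite(tr1$history$R)))
  expect_lt(tr1$history$R[3], tr1$history$R[1])
  tr2 <- train_network(build_dlfcnn(), data, cfg)
  expect_identical(tr1$weights, tr2$weights)

  trb <- train_network(build_baseline_cnn(32L), data,
                       training_config(epochs = 2L, batch_size = 8L, seed = 31L))
  expect_true(all(is.finite(trb$history$R)))
})

test_that("predict_mask thresholds the probability map elementwise", {
  co <- generate_cohort(2, 0, small_lesion_config(), seed = 22)
  data <- lapply(co, function(s) list(slice = s$slice, mask = s$truth$lesion_mask))
  tr <- train_network(build_dlfcnn(), data, training_config(epochs = 1L, seed = 5L))
  pr <- predict_prob(tr, co[[1]]$slice)
  expect_identical(predict_mask(tr, co[[1]]$slice, 0.5), pr > 0.5)
  expect_identical(predict_mask(tr, co[[1]]$slice, 0.001), pr > 0.001)
  fake <- tr; fake$weights <- NULL
  expect_error(predict_mask(fake, co[[1]]$slice), "weights")
})
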