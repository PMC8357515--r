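#' Layer specification
#'
#' One layer of a network stack: a convolution (`conv`), a 2x2 max-pooling
#' downsampler (`downsample`), or a 1x1 convolution standing in for a fully
#' connected layer (`conv_as_fc`).
#'
#' @param name layer label (e.g. "C1").
#' @param kind one of "conv", "downsample", "conv_as_fc".
#' @param n_maps feature-map count output by the layer.
#' @param kernel_size kernel side q (window side for downsample).
#' @param stride stride t.
#' @param padding zero padding o per side.
#' @param dilation dilation interval lambda.
#' @param activation one of "relu", "sigmoid", "none".
#' @return A list of class `layer_spec`.
#' @export
layer_spec <- function(name, kind, n_maps, kernel_size = 1L, stride = 1L,
                       padding = 0L, dilation = 1L, activation = "none") {
  kind <- match.arg(kind, c("conv", "downsample", "conv_as_fc"))
  activation <- match.arg(activation, c("relu", "sigmoid", "none"))
  stopifnot(stride >= 1, padding >= 0, dilation >= 1, n_maps >= 1)
  structure(list(name = name, kind = kind, n_maps = as.integer(n_maps),
                 kernel_size = as.integer(kernel_size), stride = as.integer(stride),
                 padding = as.integer(padding), dilation = as.integer(dilation),
                 activation = activation),
            class = "layer_spec")
}

#' Build the DLFCNN segmentation network specification
#'
#' The nine-layer fully convolutional stack: C1 (14 maps, 2x2) through F9
#' (52 maps, 1x1 convolution standing in for the fully connected layer),
#' with 2x2 max-pooling downsamplers S2/S4/S6/S8 and hybrid dilations
#' (2, 4, 5) on C3/C5/C7. A 1x1 sigmoid head produces one probability map,
#' upsampled back to the input resolution. Because every layer is
#' convolutional, any input side length >= 32 is accepted and the output map
#' is spatially aligned with the input.
#'
#' Upsampling modes: `"bilinear_skip"` (default) bilinearly upsamples the
#' deep logit map and fuses it with 1x1-convolution logit maps taken from
#' the dilated-convolution stages C3 (stride 2) and C5 (stride 4) — classic
#' fully-convolutional skip refinement; `"bilinear"` uses the single coarse
#' logit map alone. Upsampling interpolates at the true receptive-field
#' centers of each coarse grid (the floor-pooled encoder's grids are offset
#' and truncated, not uniformly spread). The sigmoid is applied after
#' upsampling/fusion.
#'
#' @param dilations dilation intervals for C3/C5/C7 (default `c(2, 4, 5)`).
#' @param upsample `"bilinear_skip"` or `"bilinear"`.
#' @return A list of class `network_spec`.
#' @export
build_dlfcnn <- function(dilations = c(2L, 4L, 5L), upsample = "bilinear_skip") {
  upsample <- match.arg(upsample, c("bilinear_skip", "bilinear"))
  stopifnot(length(dilations) == 3, all(dilations >= 1))
  same_pad <- function(q, d) as.integer(((q - 1) * d) / 2)
  layers <- list(
    layer_spec("C1", "conv", 14, 2, padding = 0, activation = "relu"),
    layer_spec("S2", "downsample", 14, 2, stride = 2),
    layer_spec("C3", "conv", 14, 5, padding = same_pad(5, dilations[1]),
               dilation = dilations[1], activation = "relu"),
    layer_spec("S4", "downsample", 14, 2, stride = 2),
    layer_spec("C5", "conv", 28, 5, padding = same_pad(5, dilations[2]),
               dilation = dilations[2], activation = "relu"),
    layer_spec("S6", "downsample", 28, 2, stride = 2),
    layer_spec("C7", "conv", 28, 5, padding = same_pad(5, dilations[3]),
               dilation = dilations[3], activation = "relu"),
    layer_spec("S8", "downsample", 28, 2, stride = 2),
    layer_spec("F9", "conv_as_fc", 52, 1, activation = "relu")
  )
  structure(list(type = "fcn", layers = layers, upsample = upsample,
                 out_activation = "sigmoid",
                 skip_after = if (upsample == "bilinear_skip") c("C3", "C5") else character(0),
                 dilations = as.integer(dilations),
                 min_input = 32L,
                 hu_window_level = 40, hu_window_width = 400),
            class = "network_spec")
}

#' Build the patch-classifier CNN baseline
#'
#' The comparison network: the same convolutional trunk as the fully
#' convolutional model, but terminating in a true fully connected
#' classification (realized as 1x1 convolutions on the 1x1 trunk output) of
#' the center pixel of a fixed-size patch. Whole-slice segmentation is done
#' by sliding the patch window over the (reflect-padded) slice.
#'
#' @param patch_size patch side length in pixels (>= 16).
#' @return A list of class `network_spec` with `type = "patch"`.
#' @export
build_baseline_cnn <- function(patch_size = 32L) {
  stopifnot(patch_size >= 16)
  base <- build_dlfcnn(upsample = "bilinear")
  structure(list(type = "patch", layers = base$layers, upsample = "none",
                 out_activation = "sigmoid", skip_after = character(0),
                 dilations = base$dilations,
                 patch_size = as.integer(patch_size),
                 hu_window_level = base$hu_window_level,
                 hu_window_width = base$hu_window_width),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> type=%s, %d layers, upsample=%s\n",
              x$type, length(x$layers), x$upsample))
  for (l in x$layers)
    cat(sprintf("  %-3s %-11s maps=%-3d q=%d s=%d o=%d lambda=%d act=%s\n",
                l$name, l$kind, l$n_maps, l$kernel_size, l$stride, l$padding,
                l$dilation, l$activation))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size minibatch size for stochastic gradient descent.
#' @param learning_rate positive SGD step size; `NULL` (default) selects a
#'   per-model default (4 for fully convolutional models, whose per-pixel
#'   loss normalization shrinks and partially cancels the summed gradients;
#'   0.5 for patch classifiers, whose single-output gradients are much
#'   larger).
#' @param seed integer seed controlling initialization, shuffling and patch
#'   sampling; identical seeds give bit-identical training runs.
#' @param m output count normalizing the loss; `NULL` (default) uses the
#'   number of output elements in each minibatch.
#' @param binarize_threshold probability cut used by [predict_mask()].
#' @param patches_per_slice patches sampled per slice per epoch when training
#'   a patch-classifier model (balanced between lesion and background
#'   centers where possible).
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 30L, batch_size = 8L, learning_rate = NULL,
                            seed = 1L, m = NULL, binarize_threshold = 0.5,
                            patches_per_slice = 8L) {
  stopifnot(epochs >= 1, batch_size >= 1,
            is.null(learning_rate) || learning_rate > 0,
            binarize_threshold > 0, binarize_threshold < 1, patches_per_slice >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed), m = m,
                 binarize_threshold = binarize_threshold,
                 patches_per_slice = as.integer(patches_per_slice)),
            class = "training_config")
}

#' Initialize network weights
#'
#' Uniform initialization scaled by fan-in: each convolution's weights are
#' drawn from U(-s, s) with \eqn{s = 1/\sqrt{C_{in} q^2}}; biases start at 0.
#' Skip-fusion logit heads are included when the spec requests them.
#'
#' @param spec a `network_spec`.
#' @param seed integer RNG seed.
#' @return A list of per-layer weight lists (`Wm`, `b`) keyed by layer name,
#'   plus logit heads (`head`, and `head_S2`/`head_S4` under skip fusion).
#' @export
init_network_weights <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  wts <- list()
  c_in <- 1L
  for (l in spec$layers) {
    if (l$kind == "downsample") next
    fan_in <- c_in * l$kernel_size^2
    s <- 1 / sqrt(fan_in)
    wts[[l$name]] <- list(
      Wm = matrix(runif(l$n_maps * fan_in, -s, s), nrow = l$n_maps),
      b = rep(0, l$n_maps))
    c_in <- l$n_maps
  }
  head_init <- function(c_in) {
    s <- 1 / sqrt(c_in)
    list(Wm = matrix(runif(c_in, -s, s), nrow = 1), b = 0)
  }
  wts[["head"]] <- head_init(c_in)
  for (nm in spec$skip_after) {
    maps_at <- spec$layers[[which(vapply(spec$layers, `[[`, "", "name") == nm)]]$n_maps
    wts[[paste0("head_", nm)]] <- head_init(maps_at)
  }
  wts
}

# Coordinate mapping (a, b) of each head's source grid: cell k of the grid
# sits at original-image coordinate a*k + b. Same-padded convolutions are
# identity; C1 (2x2, unpadded) shifts by +0.5; each 2x2/2 pool maps
# k -> 2k - 0.5 in its input grid.
head_grid_maps <- function(spec) {
  a <- 1; b <- 0
  maps <- list()
  for (l in spec$layers) {
    if (l$kind == "downsample") {
      b <- b - 0.5 * a
      a <- 2 * a
    } else if (l$padding == 0L && l$kernel_size > 1L) {
      b <- b + a * (l$kernel_size - 1) / 2 * l$dilation
    }
    if (l$name %in% spec$skip_after)
      maps[[paste0("head_", l$name)]] <- c(a = a, b = b)
  }
  maps[["head"]] <- c(a = a, b = b)
  maps
}

# channel count entering each layer (input is single-channel HU)
layer_in_maps <- function(spec) {
  c_in <- 1L
  out <- integer(length(spec$layers))
  for (k in seq_along(spec$layers)) {
    out[k] <- c_in
    c_in <- spec$layers[[k]]$n_maps
  }
  out
}

# CT display-window normalization (soft-tissue window by default): maps the
# clinically relevant HU band to [-1, 1] so that tissue-level contrast, not
# the dominant air-body step, drives the early features.
normalize_hu <- function(spec, pixels)
  pmin(pmax((pixels - spec$hu_window_level) / (spec$hu_window_width / 2), -1), 1)

# Forward pass through the trunk layers; returns activations and pooling
# caches for backprop plus outputs at requested skip points.
trunk_forward <- function(spec, wts, X, keep = FALSE) {
  cache <- if (keep) vector("list", length(spec$layers)) else NULL
  skips <- list()
  for (k in seq_along(spec$layers)) {
    l <- spec$layers[[k]]
    if (l$kind == "downsample") {
      p <- cpp_maxpool2(X)
      if (keep) cache[[k]] <- list(kind = "pool", in_dim = dim(X), argmax = p$argmax)
      X <- p$Y
    } else {
      pre <- cpp_conv2d(X, wts[[l$name]]$Wm, wts[[l$name]]$b,
                        l$kernel_size, l$stride, l$padding, l$dilation)
      out <- if (l$activation == "relu") relu(pre) else
             if (l$activation == "sigmoid") sigmoid(pre) else pre
      if (keep) cache[[k]] <- list(kind = "conv", input = X, pre = pre)
      X <- out
    }
    if (l$name %in% spec$skip_after) skips[[l$name]] <- X
  }
  list(out = X, cache = cache, skips = skips)
}

# Full forward pass of an FCN spec on one slice (matrix of HU values).
# Returns the probability map and, when keep = TRUE, everything needed for
# the backward pass.
fcn_forward <- function(spec, wts, pixels, keep = FALSE) {
  H <- nrow(pixels); W <- ncol(pixels)
  if (min(H, W) < spec$min_input)
    stop(sprintf("input %dx%d below the minimum supported size %d", H, W, spec$min_input))
  X <- as_feature_cube(normalize_hu(spec, pixels))
  tr <- trunk_forward(spec, wts, X, keep = keep)
  heads <- list(head = cpp_conv2d(tr$out, wts$head$Wm, wts$head$b, 1L, 1L, 0L, 1L))
  for (nm in spec$skip_after)
    heads[[paste0("head_", nm)]] <-
      cpp_conv2d(tr$skips[[nm]], wts[[paste0("head_", nm)]]$Wm,
                 wts[[paste0("head_", nm)]]$b, 1L, 1L, 0L, 1L)
  logit <- matrix(0, H, W)
  ups <- list()
  grid_maps <- head_grid_maps(spec)
  for (nm in names(heads)) {
    hd <- dim(heads[[nm]])
    hm <- matrix(heads[[nm]][, , 1L], hd[1], hd[2])
    gm <- grid_maps[[nm]]
    Br <- center_interp_matrix(H, nrow(hm), gm["a"], gm["b"])
    Bc <- center_interp_matrix(W, ncol(hm), gm["a"], gm["b"])
    ups[[nm]] <- list(Br = Br, Bc = Bc, dim = dim(hm))
    logit <- logit + Br %*% hm %*% t(Bc)
  }
  prob <- sigmoid(logit)
  out <- list(prob = prob, logit = logit)
  if (keep) {
    out$trunk <- tr
    out$ups <- ups
  }
  out
}

# Backward through the trunk given gradient at its output plus gradients
# injected at skip points; accumulates weight gradients into `grads`.
trunk_backward <- function(spec, wts, cache, d_out, d_skips, grads) {
  dX <- d_out
  for (k in rev(seq_along(spec$layers))) {
    l <- spec$layers[[k]]
    if (l$name %in% names(d_skips))
      dX <- dX + d_skips[[l$name]]
    cc <- cache[[k]]
    if (cc$kind == "pool") {
      dX <- cpp_maxpool2_backward(dX, cc$argmax, cc$in_dim[1], cc$in_dim[2])
    } else {
      dpre <- if (l$activation == "relu") dX * relu_deriv(cc$pre) else
              if (l$activation == "sigmoid") dX * sigmoid_deriv(cc$pre) else dX
      bw <- cpp_conv2d_backward(cc$input, wts[[l$name]]$Wm, dpre,
                                l$kernel_size, l$stride, l$padding, l$dilation)
      grads[[l$name]]$Wm <- grads[[l$name]]$Wm + bw$dW
      grads[[l$name]]$b <- grads[[l$name]]$b + as.numeric(bw$db)
      dX <- bw$dX
    }
  }
  grads
}

zero_grads <- function(wts) lapply(wts, function(w) list(Wm = w$Wm * 0, b = w$b * 0))

# Backward pass for one FCN sample. fw is fcn_forward(..., keep = TRUE);
# dprob is dLoss/dprob. Returns accumulated grads.
fcn_backward <- function(spec, wts, fw, dprob, grads) {
  dlogit <- dprob * fw$prob * (1 - fw$prob)
  d_skips <- list()
  d_trunk_out <- NULL
  for (nm in names(fw$ups)) {
    u <- fw$ups[[nm]]
    dhm <- t(u$Br) %*% dlogit %*% u$Bc              # back through bilinear basis
    dhead <- array(dhm, c(u$dim, 1L))
    src <- if (nm == "head") fw$trunk$out else fw$trunk$skips[[sub("head_", "", nm)]]
    bw <- cpp_conv2d_backward(src, wts[[nm]]$Wm, dhead, 1L, 1L, 0L, 1L)
    grads[[nm]]$Wm <- grads[[nm]]$Wm + bw$dW
    grads[[nm]]$b <- grads[[nm]]$b + as.numeric(bw$db)
    if (nm == "head") d_trunk_out <- bw$dX
    else d_skips[[sub("head_", "", nm)]] <- bw$dX
  }
  trunk_backward(spec, wts, fw$trunk$cache, d_trunk_out, d_skips, grads)
}

# Patch model: forward to a single probability for the patch center pixel.
patch_forward <- function(spec, wts, patch_pixels, keep = FALSE) {
  X <- as_feature_cube(normalize_hu(spec, patch_pixels))
  tr <- trunk_forward(spec, wts, X, keep = keep)
  logit_map <- cpp_conv2d(tr$out, wts$head$Wm, wts$head$b, 1L, 1L, 0L, 1L)
  logit <- mean(logit_map)     # trunk output is 1x1 for supported patch sizes
  out <- list(prob = sigmoid(logit), logit = logit)
  if (keep) { out$trunk <- tr; out$logit_dim <- dim(logit_map) }
  out
}

patch_backward <- function(spec, wts, fw, dprob, grads) {
  dlogit <- dprob * fw$prob * (1 - fw$prob)
  dmap <- array(dlogit / prod(fw$logit_dim[1:2]), fw$logit_dim)
  bw <- cpp_conv2d_backward(fw$trunk$out, wts$head$Wm, dmap, 1L, 1L, 0L, 1L)
  grads$head$Wm <- grads$head$Wm + bw$dW
  grads$head$b <- grads$head$b + as.numeric(bw$db)
  trunk_backward(spec, wts, fw$trunk$cache, bw$dX, list(), grads)
}

slice_pixels <- function(x) if (is_ct_slice(x)) x$pixels else x

#' Train a segmentation network
#'
#' Minimizes the mean-squared-error loss \eqn{R = (1/2m)\sum(K - g(P))^2} by
#' minibatch stochastic gradient descent. Fully convolutional models train on
#' whole slices against aligned binary masks; patch models train on patches
#' sampled (balanced lesion/background, reflect-padded borders) around mask
#' pixels. Training is bit-reproducible from `config$seed`.
#'
#' @param model a `network_spec` from [build_dlfcnn()] or
#'   [build_baseline_cnn()].
#' @param data list of samples, each a list with elements `slice` (a
#'   [ct_slice()] or HU matrix) and `mask` (logical matrix, the gold label).
#' @param config a [training_config()].
#' @param verbose print the per-epoch loss.
#' @param init_weights optional warm-start weights (e.g. a previous fit's
#'   `$weights`); when `NULL`, weights are initialized from `config$seed`.
#' @return A list of class `trained_network`: `spec`, `weights`, `history`
#'   (data.frame with `epoch` and `R`), `config`.
#' @export
train_network <- function(model, data, config = training_config(), verbose = FALSE,
                          init_weights = NULL) {
  stopifnot(inherits(model, "network_spec"), length(data) >= 1)
  data <- lapply(data, function(s) {
    px <- slice_pixels(s$slice)
    mk <- as_binary_mask(s$mask)
    check_same_shape(px, mk, "slice and mask")
    list(pixels = px, mask = mk)
  })
  set.seed(config$seed)
  wts <- if (is.null(init_weights)) init_network_weights(model, seed = config$seed)
         else init_weights
  lr <- config$learning_rate
  if (is.null(lr)) lr <- if (model$type == "fcn") 4 else 0.5
  history <- data.frame(epoch = integer(0), R = numeric(0))
  pad_half <- if (model$type == "patch") model$patch_size %/% 2L else 0L

  for (ep in seq_len(config$epochs)) {
    if (model$type == "fcn") {
      order <- sample.int(length(data))
      units <- lapply(order, function(i) data[[i]])
    } else {
      units <- sample_patches(data, model$patch_size, config$patches_per_slice)
    }
    batch_starts <- seq(1, length(units), by = config$batch_size)
    ep_loss <- 0
    for (bs in batch_starts) {
      idx <- bs:min(bs + config$batch_size - 1, length(units))
      grads <- zero_grads(wts)
      bloss <- 0
      for (u in units[idx]) {
        if (model$type == "fcn") {
          fw <- fcn_forward(model, wts, u$pixels, keep = TRUE)
          K <- u$mask * 1
          m <- if (is.null(config$m)) length(K) else config$m
          bloss <- bloss + mse_loss(K, fw$prob, m)
          dprob <- mse_loss_grad(K, fw$prob, m) / length(idx)
          grads <- fcn_backward(model, wts, fw, dprob, grads)
        } else {
          fw <- patch_forward(model, wts, u$pixels, keep = TRUE)
          m <- if (is.null(config$m)) 1 else config$m
          bloss <- bloss + mse_loss(u$target, fw$prob, m)
          dprob <- mse_loss_grad(u$target, fw$prob, m) / length(idx)
          grads <- patch_backward(model, wts, fw, dprob, grads)
        }
      }
      bloss <- bloss / length(idx)
      if (!is.finite(bloss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      ep_loss <- ep_loss + bloss
      for (nm in names(wts)) {
        wts[[nm]]$Wm <- wts[[nm]]$Wm - lr * grads[[nm]]$Wm
        wts[[nm]]$b <- wts[[nm]]$b - lr * grads[[nm]]$b
      }
    }
    R_ep <- ep_loss / length(batch_starts)
    history <- rbind(history, data.frame(epoch = ep, R = R_ep))
    if (verbose) message(sprintf("epoch %3d  R = %.6f", ep, R_ep))
  }
  structure(list(spec = model, weights = wts, history = history, config = config),
            class = "trained_network")
}

# Reflect-pad a matrix by `p` pixels on each side.
reflect_pad <- function(x, p) {
  if (p == 0) return(x)
  n <- nrow(x); m <- ncol(x)
  if (p >= n || p >= m) stop("reflection pad wider than the image")
  ri <- c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(m), m - seq_len(p))
  x[ri, ci]
}

# Balanced patch sampling for baseline training. Returns units with `pixels`
# (patch) and `target` (center-pixel label).
sample_patches <- function(data, patch_size, per_slice) {
  half <- patch_size %/% 2L
  units <- list()
  for (s in data) {
    padded <- reflect_pad(s$pixels, half)
    pos <- which(s$mask)
    neg <- which(!s$mask)
    n_pos <- min(length(pos), per_slice %/% 2L)
    n_neg <- per_slice - n_pos
    pick <- c(if (n_pos > 0) pos[sample.int(length(pos), n_pos)] else integer(0),
              neg[sample.int(length(neg), min(n_neg, length(neg)))])
    for (lin in pick) {
      i <- (lin - 1L) %% nrow(s$mask) + 1L
      j <- (lin - 1L) %/% nrow(s$mask) + 1L
      units[[length(units) + 1L]] <- list(
        pixels = padded[i:(i + patch_size - 1L), j:(j + patch_size - 1L)],
        target = s$mask[i, j] * 1)
    }
  }
  units[sample.int(length(units))]
}

#' Predict a probability map for one slice
#'
#' @param trained a `trained_network` from [train_network()].
#' @param slice a [ct_slice()] or HU matrix.
#' @param stride for patch models, the sliding-window evaluation stride;
#'   positions between strides take the nearest evaluated probability.
#' @return Numeric matrix of probabilities aligned with the slice.
#' @export
predict_prob <- function(trained, slice, stride = 1L) {
  stopifnot(inherits(trained, "trained_network"))
  px <- slice_pixels(slice)
  spec <- trained$spec
  if (spec$type == "fcn")
    return(fcn_forward(spec, trained$weights, px)$prob)
  half <- spec$patch_size %/% 2L
  padded <- reflect_pad(px, half)
  H <- nrow(px); W <- ncol(px)
  ri <- unique(c(seq(1L, H, by = stride), H))
  ci <- unique(c(seq(1L, W, by = stride), W))
  coarse <- matrix(0, length(ri), length(ci))
  for (a in seq_along(ri)) {
    for (b in seq_along(ci)) {
      patch <- padded[ri[a]:(ri[a] + spec$patch_size - 1L),
                      ci[b]:(ci[b] + spec$patch_size - 1L)]
      coarse[a, b] <- patch_forward(spec, trained$weights, patch)$prob
    }
  }
  # nearest-evaluated-position fill back to full resolution
  rmap <- vapply(seq_len(H), function(i) which.min(abs(ri - i)), 1L)
  cmap <- vapply(seq_len(W), function(j) which.min(abs(ci - j)), 1L)
  coarse[rmap, cmap, drop = FALSE]
}

#' Predict a binary mask for one slice
#'
#' Thresholds the network probability map at `binarize_threshold`
#' (probability strictly greater than the cut is foreground... pixels equal
#' to the cut are background).
#'
#' @inheritParams predict_prob
#' @param binarize_threshold probability cut in (0, 1); defaults to the
#'   training configuration's value.
#' @return Logical matrix.
#' @export
predict_mask <- function(trained, slice, binarize_threshold = NULL, stride = 1L) {
  if (!inherits(trained, "trained_network") || is.null(trained$weights))
    stop("model has no trained weights")
  thr <- if (is.null(binarize_threshold)) trained$config$binarize_threshold else binarize_threshold
  stopifnot(thr > 0, thr < 1)
  predict_prob(trained, slice, stride = stride) > thr
}
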