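test_that("confusion counts match a pixel-loop oracle", {
  set.seed(13)
  for (rep in 1:5) {
    C <- random_mask(16); D <- random_mask(16)
    cc <- confusion_counts(C, D)
    tp <- fp <- fn <- tn <- 0
    for (i in 1:16) for (j in 1:16) {
      if (C[i, j] && D[i, j]) tp <- tp + 1
      else if (!C[i, j] && D[i, j]) fp <- fp + 1
      else if (C[i, j] && !D[i, j]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]),
                 c(TP = tp, FP = fp, FN = fn, TN = tn))
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 256)
  }
  C <- random_mask(8)
  cc <- confusion_counts(C, C)
  expect_equal(cc$TP, sum(C)); expect_equal(cc$FP, 0); expect_equal(cc$FN, 0)
  expect_error(confusion_counts(random_mask(4), random_mask(5)), "shape")
})

test_that("jaccard and dice handle the canonical cases", {
  A <- disk_mask(20, 10, 10, 5)
  expect_equal(jaccard(A, A), 1)
  expect_equal(dice(A, A), 1)
  B <- matrix(FALSE, 20, 20); B[1:2, 1:2] <- TRUE    # disjoint from A
  expect_equal(jaccard(A, B), 0)
  expect_equal(dice(A, B), 0)
  # |C|=4, |D|=4, overlap 2
  C <- matrix(FALSE, 4, 4); C[1, 1:4] <- TRUE
  D <- matrix(FALSE, 4, 4); D[1, 3:4] <- TRUE; D[2, 1:2] <- TRUE
  expect_equal(jaccard(C, D), 2 / 6)
  expect_equal(dice(C, D), 0.5)
  # empty-vs-empty convention
  E <- matrix(FALSE, 5, 5)
  expect_equal(jaccard(E, E), 1)
  expect_equal(dice(E, E), 1)
})

test_that("precision and recall follow the TP ratios with the zero convention", {
  expect_equal(round(100 * precision(list(TP = 58, FP = 2)), 2), 96.67)
  expect_equal(recall(list(TP = 9, FN = 1)), 0.9)
  p0 <- precision(list(TP = 0, FP = 0))
  expect_equal(as.numeric(p0), 0)
  expect_true(attr(p0, "undefined"))
})

test_that("the dice-jaccard identity holds on random mask pairs", {
  set.seed(14)
  for (rep in 1:100) {
    C <- random_mask(12, runif(1, 0.1, 0.6))
    D <- random_mask(12, runif(1, 0.1, 0.6))
    m <- evaluate_masks(C, D)
    expect_lt(abs(m$dice - 2 * m$jaccard / (1 + m$jaccard)), 1e-12)
    expect_true(all(unlist(m[c("jaccard", "dice")]) >= 0 &
                    unlist(m[c("jaccard", "dice")]) <= 1))
  }
})

test_that("metrics are symmetric, monotone in overlap, translation invariant", {
  set.seed(15)
  C <- random_mask(14, 0.4); D <- random_mask(14, 0.4)
  expect_equal(jaccard(C, D), jaccard(D, C))
  expect_equal(dice(C, D), dice(D, C))
  # precision/recall swap under exchange of the masks
  cc <- confusion_counts(C, D); cr <- confusion_counts(D, C)
  expect_equal(as.numeric(precision(cc)), as.numeric(recall(cr)))

  # monotonicity: move one predicted-positive pixel onto the gold mask
  C <- disk_mask(20, 10, 10, 6)
  D <- disk_mask(20, 12, 12, 6)
  base <- evaluate_masks(C, D)
  D2 <- D
  flip_off <- which(D & !C)[1]; flip_on <- which(C & !D)[1]
  D2[flip_off] <- FALSE; D2[flip_on] <- TRUE
  grown <- evaluate_masks(C, D2)
  expect_gte(grown$jaccard, base$jaccard)
  expect_gte(grown$dice, base$dice)

  # simultaneous translation of both masks (shift stays inside the grid)
  Cb <- matrix(FALSE, 30, 30); Cb[4:23, 4:23] <- C
  Db <- matrix(FALSE, 30, 30); Db[4:23, 4:23] <- D
  shift <- function(m, k) rbind(matrix(FALSE, k, ncol(m)), m[1:(nrow(m) - k), ])
  expect_equal(jaccard(shift(Cb, 3), shift(Db, 3)), jaccard(Cb, Db))

  # evaluate bundles: empty prediction
  E <- matrix(FALSE, 20, 20)
  m <- evaluate_masks(C, E)
  expect_equal(m$dice, 0); expect_equal(as.numeric(m$recall), 0)
})

test_that("evaluate_cohort reports per-slice rows plus a macro mean", {
  C1 <- disk_mask(16, 8, 8, 4); D1 <- disk_mask(16, 8, 8, 4)
  C2 <- disk_mask(16, 8, 8, 4); D2 <- matrix(FALSE, 16, 16)
  df <- evaluate_cohort(list(C1, C2), list(D1, D2))
  expect_equal(nrow(df), 3)
  expect_equal(df$dice[df$slice == "mean"], mean(df$dice[df$slice != "mean"]))
  expect_equal(df$dice[1], 1)
})
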