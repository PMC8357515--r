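#' Pixel confusion counts between a gold mask and a prediction
#'
#' @param C gold-standard binary mask (expert label).
#' @param D predicted binary mask, same shape.
#' @return A list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(C, D) {
  C <- as_binary_mask(C); D <- as_binary_mask(D)
  check_same_shape(C, D, "masks")
  TP <- sum(C & D)
  structure(list(TP = TP, FP = sum(D) - TP, FN = sum(C) - TP,
                 TN = sum(!C & !D)),
            class = "confusion_counts")
}

#' Jaccard overlap of two masks
#'
#' \eqn{|C \cap D| / |C \cup D|}. Jaccard = 1 means the segmentation
#' completely overlaps the gold standard. Two empty masks agree perfectly on
#' "nothing present" and score 1.
#'
#' @inheritParams confusion_counts
#' @return Value in [0, 1].
#' @export
jaccard <- function(C, D) {
  cc <- confusion_counts(C, D)
  un <- cc$TP + cc$FP + cc$FN
  if (un == 0) 1 else cc$TP / un
}

#' Dice coefficient of two masks
#'
#' \eqn{2|C \cap D| / (|C| + |D|)}; related to Jaccard by
#' Dice = 2J / (1 + J). Two empty masks score 1.
#'
#' @inheritParams confusion_counts
#' @return Value in [0, 1].
#' @export
dice <- function(C, D) {
  cc <- confusion_counts(C, D)
  den <- 2 * cc$TP + cc$FP + cc$FN
  if (den == 0) 1 else 2 * cc$TP / den
}

#' Precision (accuracy rate) and recall from confusion counts
#'
#' Precision = TP / (TP + FP); recall = TP / (TP + FN). A zero denominator
#' returns 0 with the attribute `undefined = TRUE`.
#'
#' @param counts a `confusion_counts` (or a list with TP/FP/FN fields).
#' @return Value in [0, 1], possibly with attribute `undefined`.
#' @export
precision <- function(counts) ratio_or_zero(counts$TP, counts$TP + counts$FP)

#' @rdname precision
#' @export
recall <- function(counts) ratio_or_zero(counts$TP, counts$TP + counts$FN)

ratio_or_zero <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' Evaluate a segmentation against the gold standard
#'
#' Bundles Jaccard, Dice, precision and recall with the underlying pixel
#' confusion counts for one (gold, prediction) mask pair.
#'
#' @inheritParams confusion_counts
#' @return A list of class `segmentation_metrics` with fields `jaccard`,
#'   `dice`, `precision`, `recall`, `counts`.
#' @export
evaluate_masks <- function(C, D) {
  cc <- confusion_counts(C, D)
  un <- cc$TP + cc$FP + cc$FN
  structure(list(jaccard = if (un == 0) 1 else cc$TP / un,
                 dice = if (un == 0) 1 else 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN),
                 precision = precision(cc), recall = recall(cc),
                 counts = cc),
            class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf("<segmentation_metrics> J=%.4f Dice=%.4f P=%.4f R=%.4f (TP=%d FP=%d FN=%d TN=%d)\n",
              x$jaccard, x$dice, x$precision, x$recall,
              x$counts$TP, x$counts$FP, x$counts$FN, x$counts$TN))
  invisible(x)
}

#' Evaluate a cohort of mask pairs
#'
#' Computes per-slice metrics and their macro average (unweighted mean over
#' slices).
#'
#' @param gold list of gold masks.
#' @param pred list of predicted masks, same length and shapes.
#' @return A data.frame with one row per slice plus a final `"mean"` row;
#'   columns `slice`, `jaccard`, `dice`, `precision`, `recall`, `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
evaluate_cohort <- function(gold, pred) {
  stopifnot(length(gold) == length(pred), length(gold) >= 1)
  rows <- lapply(seq_along(gold), function(i) {
    m <- evaluate_masks(gold[[i]], pred[[i]])
    data.frame(slice = as.character(i), jaccard = m$jaccard, dice = m$dice,
               precision = as.numeric(m$precision), recall = as.numeric(m$recall),
               tp = m$counts$TP, fp = m$counts$FP, fn = m$counts$FN,
               tn = m$counts$TN)
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(slice = "mean", jaccard = mean(df$jaccard),
                         dice = mean(df$dice), precision = mean(df$precision),
                         recall = mean(df$recall), tp = mean(df$tp),
                         fp = mean(df$fp), fn = mean(df$fn), tn = mean(df$tn))
  rbind(df, mean_row)
}
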