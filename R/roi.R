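#' Iterative (two-class-mean) threshold
#'
#' Global binarization threshold by the classic two-class-mean fixed point:
#' start from the image mean, then repeat
#' \eqn{T_{k+1} = (\mu_{\le T_k} + \mu_{> T_k})/2}
#' until successive thresholds differ by less than `tolerance` or `max_iter`
#' is reached. If one side of the split is empty its class mean is taken to
#' be \eqn{T_k} itself, which forces convergence on skewed images. A constant
#' image returns that constant immediately, flagged as degenerate.
#'
#' @param slice a [ct_slice()] or numeric matrix (HU).
#' @param tolerance convergence tolerance in HU (> 0).
#' @param max_iter iteration cap.
#' @return A list of class `threshold_result`: `threshold_hu`,
#'   `n_iterations`, `history` (thresholds after each update, starting with
#'   the initial mean), `converged`, `degenerate`.
#' @export
iterative_threshold <- function(slice, tolerance = 0.5, max_iter = 100L) {
  px <- slice_pixels(slice)
  if (length(px) == 0) stop("empty image")
  stopifnot(tolerance > 0, max_iter >= 1)
  if (diff(range(px)) == 0) {
    v <- px[1]
    return(structure(list(threshold_hu = v, n_iterations = 1L, history = v,
                          converged = TRUE, degenerate = TRUE),
                     class = "threshold_result"))
  }
  T_cur <- mean(px)
  history <- T_cur
  converged <- FALSE
  n <- 0L
  while (n < max_iter) {
    n <- n + 1L
    lo <- px[px <= T_cur]
    hi <- px[px > T_cur]
    m_lo <- if (length(lo)) mean(lo) else T_cur
    m_hi <- if (length(hi)) mean(hi) else T_cur
    T_new <- (m_lo + m_hi) / 2
    history <- c(history, T_new)
    if (abs(T_new - T_cur) < tolerance) {
      T_cur <- T_new
      converged <- TRUE
      break
    }
    T_cur <- T_new
  }
  structure(list(threshold_hu = T_cur, n_iterations = n, history = history,
                 converged = converged, degenerate = FALSE),
            class = "threshold_result")
}

#' Morphology chain for ROI cleanup
#'
#' Applies, in order: dilation, erosion, cavity filling, opening, closing -
#' all with a disk structuring element of radius `se_radius_px`. (The sixth
#' listed operation, masking, is [apply_mask()].) An empty mask passes
#' through empty.
#'
#' @param mask logical matrix.
#' @param se_radius_px structuring-element disk radius (default 2).
#' @return Logical matrix.
#' @export
morphology_chain <- function(mask, se_radius_px = 2L) {
  m <- as_binary_mask(mask)
  m <- binary_dilate(m, se_radius_px)
  m <- binary_erode(m, se_radius_px)
  m <- fill_holes(m)
  m <- binary_open(m, se_radius_px)
  binary_close(m, se_radius_px)
}

#' Mask a CT slice
#'
#' Keeps the original HU value wherever `mask` is true and writes `fill_hu`
#' elsewhere.
#'
#' @param slice a [ct_slice()] or numeric matrix.
#' @param mask logical matrix of the same shape.
#' @param fill_hu value written outside the mask (default -1024, the air
#'   floor).
#' @return Same type as `slice` (a `ct_slice` stays a `ct_slice`).
#' @export
apply_mask <- function(slice, mask, fill_hu = -1024) {
  px <- slice_pixels(slice)
  mask <- as_binary_mask(mask)
  check_same_shape(px, mask, "slice and mask")
  out <- px
  out[!mask] <- fill_hu
  if (is_ct_slice(slice)) ct_slice(out, slice$spacing_mm) else out
}

#' Extract the region of interest from a CT slice
#'
#' The full preprocessing pipeline: iterative threshold, binarize (pixels
#' strictly above the threshold are foreground; ties go to background),
#' morphology chain, largest connected component (8-connectivity), then the
#' mask operation. The result is a single connected, hole-free region; this
#' reduces the data volume and noise interference and completes the outline
#' of the lesion area.
#'
#' @param slice a [ct_slice()] or numeric matrix.
#' @param tolerance,max_iter passed to [iterative_threshold()].
#' @param se_radius_px passed to [morphology_chain()].
#' @param fill_hu fill value for masked-out pixels.
#' @return A list of class `roi_result`: `roi_mask` (logical),
#'   `masked_slice`, `threshold` (a `threshold_result`). When nothing
#'   survives thresholding the ROI is empty and a warning is raised.
#' @export
extract_roi <- function(slice, tolerance = 0.5, max_iter = 100L,
                        se_radius_px = 2L, fill_hu = -1024) {
  px <- slice_pixels(slice)
  th <- iterative_threshold(px, tolerance = tolerance, max_iter = max_iter)
  fg <- px > th$threshold_hu
  if (!any(fg)) {
    warning("no foreground above the threshold; returning an empty ROI")
    roi <- fg
  } else {
    roi <- largest_component(morphology_chain(fg, se_radius_px), 8L)
  }
  structure(list(roi_mask = roi,
                 masked_slice = apply_mask(slice, roi, fill_hu),
                 threshold = th),
            class = "roi_result")
}
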