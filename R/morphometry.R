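#' Skin-band thickness by centroid ray casting
#'
#' Measures the thickness of an annular band (the epidermis/dermis layer on
#' a CT slice) by casting `n_rays` evenly spaced rays from the band's
#' centroid and recording, per ray, the chord length through the band. The
#' band should be a closed annulus around its centroid; rays that never
#' cross the band are dropped and flagged (`open_band`).
#'
#' @param band logical matrix marking the skin band, or a `phantom_truth`
#'   (its epidermis/dermis class is used).
#' @param spacing_mm pixel spacing in mm (scalar or (row, col); rays use the
#'   geometric mean for oblique directions). Taken from the truth's config
#'   when a `phantom_truth` is given.
#' @param n_rays number of rays (default 64).
#' @param step_px ray sampling step in pixels (default 0.25).
#' @return A list of class `thickness_measurement`: `mean_mm`, `min_mm`,
#'   `max_mm`, `n_samples` (rays that crossed the band), `open_band`.
#' @export
skin_thickness <- function(band, spacing_mm = NULL, n_rays = 64L,
                           step_px = 0.25) {
  if (inherits(band, "phantom_truth")) {
    if (is.null(spacing_mm)) spacing_mm <- band$config$pixel_spacing_mm
    band <- tissue_mask(band, "epidermis_dermis")
  }
  band <- as_binary_mask(band)
  if (!any(band)) stop("empty skin band")
  if (is.null(spacing_mm)) stop("spacing_mm is required for a plain mask")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  n <- nrow(band); m <- ncol(band)
  idx <- which(band)
  ci <- mean((idx - 1) %% n + 1)        # centroid row
  cj <- mean((idx - 1) %/% n + 1)       # centroid col
  max_r <- sqrt(n^2 + m^2)
  ts <- seq(0, max_r, by = step_px)
  widths <- rep(NA_real_, n_rays)
  for (k in seq_len(n_rays)) {
    th <- 2 * pi * (k - 1) / n_rays
    dy <- sin(th); dx <- cos(th)
    ri <- round(ci + ts * dy)
    rj <- round(cj + ts * dx)
    keep <- ri >= 1 & ri <= n & rj >= 1 & rj <= m
    hit <- band[cbind(ri[keep], rj[keep])]
    if (!any(hit)) next
    # chord = extent of the (first) contiguous run of band samples
    runs <- rle(hit)
    first_on <- which(runs$values)[1]
    n_on <- runs$lengths[first_on]
    step_mm <- step_px * sqrt((dy * spacing_mm[1])^2 + (dx * spacing_mm[2])^2)
    widths[k] <- n_on * step_mm
  }
  ok <- !is.na(widths)
  if (!any(ok)) stop("no ray crossed the band")
  structure(list(mean_mm = mean(widths[ok]), min_mm = min(widths[ok]),
                 max_mm = max(widths[ok]), n_samples = sum(ok),
                 open_band = any(!ok)),
            class = "thickness_measurement")
}

#' HU statistics over a region
#'
#' Mean and (n-1)-denominator standard deviation of the HU values inside a
#' region mask.
#'
#' @param slice a [ct_slice()] or HU matrix.
#' @param region logical matrix, same shape, non-empty.
#' @return A list of class `hu_stats`: `mean_hu`, `sd_hu`, `n_pixels`.
#' @export
region_hu_stats <- function(slice, region) {
  px <- slice_pixels(slice)
  region <- as_binary_mask(region)
  check_same_shape(px, region, "slice and region")
  if (!any(region)) stop("empty region")
  v <- px[region]
  structure(list(mean_hu = mean(v),
                 sd_hu = if (length(v) > 1) sd(v) else 0,
                 n_pixels = length(v)),
            class = "hu_stats")
}

#' Fascia HU statistics from a phantom with partial-volume avoidance
#'
#' Convenience wrapper measuring the subcutaneous-fascia class of a phantom
#' after eroding the class mask by `erode_px` pixels, keeping the
#' measurement away from blurred class interfaces (the same reason HU
#' regions of interest are placed away from tissue boundaries on real CT).
#'
#' @param sample a list with `slice` and `truth` as returned by
#'   [generate_phantom()].
#' @param erode_px interface margin in pixels (default 3).
#' @return An `hu_stats` list.
#' @export
fascia_hu_stats <- function(sample, erode_px = 3L) {
  region <- tissue_mask(sample$truth, "subcutaneous_fascia", erode_px = erode_px)
  region_hu_stats(sample$slice, region)
}

#' Two-group comparison of a continuous measurement
#'
#' Group means, standard deviations and a Welch (unequal-variance) two-sided
#' t-test. Purely descriptive: no decision logic.
#'
#' @param values numeric vector of per-sample measurements.
#' @param groups factor/character vector of group labels (exactly two
#'   levels, each with >= 2 samples).
#' @return A list of class `group_comparison`: `summary` (data.frame with
#'   group, n, mean, sd), `t`, `df`, `p_value`.
#' @export
group_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  ns <- table(groups)
  if (any(ns < 2)) stop("each group needs at least 2 samples")
  smry <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v))
  }))
  tt <- t.test(values ~ groups, var.equal = FALSE)
  structure(list(summary = smry, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("Welch t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p_value))
  invisible(x)
}
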