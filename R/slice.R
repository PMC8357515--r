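#' CT slice container
#'
#' A `ct_slice` is the unit of processing throughout periseg: a 2-D matrix of
#' Hounsfield-unit (HU) values plus the physical pixel spacing. HU values are
#' expected to lie within the CT scale (air -1024 ... dense bone ~3071),
#' but only finiteness is enforced strictly; plausibility is a warning.
#'
#' @param pixels numeric matrix of HU values.
#' @param spacing_mm numeric length-2 (row, col) spacing in mm/pixel, or a
#'   single number used for both axes.
#' @return An object of class `ct_slice` with elements `pixels` and
#'   `spacing_mm`.
#' @export
ct_slice <- function(pixels, spacing_mm = c(0.5, 0.5)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop("ct_slice pixels must be finite")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be two positive finite numbers")
  if (min(pixels) < -1024 || max(pixels) > 3071)
    warning("HU values outside the plausible CT range [-1024, 3071]")
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm)),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.3g x %.3g mm, HU range [%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ct_slice <- function(x) dim(x$pixels)

is_ct_slice <- function(x) inherits(x, "ct_slice")

# Coerce and validate a binary mask aligned to some image: accepts a logical
# matrix or anything coercible (0/1, 0/255); returns a logical matrix.
as_binary_mask <- function(mask) {
  if (is.list(mask) && !is.null(mask$pixels)) mask <- mask$pixels
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) {
    if (!is.numeric(mask)) stop("mask must be logical or numeric")
    mask <- mask != 0
  }
  if (anyNA(mask)) stop("mask must not contain NA")
  mask
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have mismatched shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
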