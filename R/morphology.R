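#' Binary morphology with a disk structuring element
#'
#' Dilation, erosion, opening and closing of logical masks using a disk of
#' radius `r` pixels (the set of integer offsets with dx^2 + dy^2 <= r^2).
#' Pixels beyond the image border are treated as background, the usual
#' zero-boundary convention.
#'
#' @param mask logical matrix (anything coercible via nonzero-is-true).
#' @param r disk radius in pixels (>= 0; radius 0 is the identity).
#' @return Logical matrix of the same shape.
#' @export
binary_dilate <- function(mask, r = 2L) {
  mask <- as_binary_mask(mask)
  morph_shift_reduce(mask, r, any_op = TRUE)
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, r = 2L) {
  mask <- as_binary_mask(mask)
  morph_shift_reduce(mask, r, any_op = FALSE)
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, r = 2L) binary_dilate(binary_erode(mask, r), r)

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, r = 2L) binary_erode(binary_dilate(mask, r), r)

disk_offsets <- function(r) {
  ix <- seq(-r, r)
  off <- expand.grid(dy = ix, dx = ix)
  off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
}

# Shifted-copy OR (dilate) / AND (erode) over the disk offsets.
morph_shift_reduce <- function(mask, r, any_op) {
  if (r == 0) return(mask)
  off <- disk_offsets(r)
  n <- nrow(mask); m <- ncol(mask)
  acc <- NULL
  for (k in seq_len(nrow(off))) {
    dy <- off$dy[k]; dx <- off$dx[k]
    sh <- matrix(!any_op, n, m)       # out-of-border: FALSE for both ops
    sr <- max(1, 1 + dy):min(n, n + dy)
    sc <- max(1, 1 + dx):min(m, m + dx)
    sh[sr, sc] <- mask[sr - dy, sc - dx]
    acc <- if (is.null(acc)) sh else if (any_op) acc | sh else acc & sh
  }
  acc
}

#' Fill interior cavities of a binary mask
#'
#' Background regions (4-connected) not reachable from the image border are
#' holes; they are converted to foreground. Foreground pixels are never
#' removed.
#'
#' @param mask logical matrix.
#' @return Logical matrix with all interior holes filled.
#' @export
fill_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  bg <- cpp_label_components(!mask, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels != 0L]
  holes <- bg != 0L & !(bg %in% border_labels)
  mask | holes
}

#' Label connected components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (background 0).
#' @export
label_components <- function(mask, connectivity = 8L) {
  cpp_label_components(as_binary_mask(mask), as.integer(connectivity))
}

#' Keep only the largest connected component
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Logical matrix; empty input passes through empty. Ties are broken
#'   in favour of the first-labelled (scan-order) component.
#' @export
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(lab > 0L)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# number of interior holes of a mask (4-connected background regions not
# touching the border); used by tests and the ROI contract
count_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  bg <- cpp_label_components(!mask, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  length(setdiff(unique(bg[bg != 0L]), border_labels))
}
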