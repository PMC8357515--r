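#' Spatial output size of a convolution
#'
#' Computes the output side length of a convolution with input side `i`,
#' kernel side `q`, symmetric zero padding `o` and stride `t`:
#' \eqn{\lfloor (i - q + 2o)/t \rfloor + 1}. Non-exact division is floored.
#' With `dilation` > 1 the kernel side is replaced by its effective extent
#' \eqn{q + (q-1)(\lambda-1)}.
#'
#' @param i input side length (pixels).
#' @param q kernel side length.
#' @param o zero padding per side (default 0).
#' @param t stride (default 1).
#' @param dilation kernel tap spacing \eqn{\lambda} (default 1, dense).
#' @return Integer output side length.
#' @examples
#' output_size(6, 4)          # 3
#' output_size(6, 4, o = 1)   # 5
#' output_size(128, 5, o = 2) # 128 ("same" padding)
#' @export
output_size <- function(i, q, o = 0, t = 1, dilation = 1) {
  stopifnot(t >= 1, o >= 0, q >= 1, dilation >= 1)
  q_eff <- q + (q - 1L) * (dilation - 1L)
  if (i + 2 * o < q_eff)
    stop(sprintf("kernel (effective extent %d) larger than padded input (%d)",
                 q_eff, i + 2 * o))
  as.integer(floor((i - q_eff + 2 * o) / t) + 1)
}

#' Discrete 2-D convolution (cross-correlation)
#'
#' Direct discrete convolution in the cross-correlation orientation
#' \eqn{L(i,j) = \sum_a \sum_b P(a+i, b+j) Q(a,b)}, generalized with stride,
#' zero padding and dilation. Multi-channel inputs are contracted over the
#' input-channel axis, one output map per output channel, plus a per-map bias.
#'
#' @param input numeric matrix (single map) or 3-D array `(H, W, C_in)`.
#' @param weights numeric matrix (single-in single-out kernel) or 4-D array
#'   `(q, q, C_in, C_out)`.
#' @param bias per-output-map offset (default 0).
#' @param stride,padding,dilation convolution hyperparameters.
#' @return A matrix if `C_out == 1`, else a 3-D array `(H_out, W_out, C_out)`.
#' @export
discrete_conv2d <- function(input, weights, bias = NULL, stride = 1,
                            padding = 0, dilation = 1) {
  X <- as_feature_cube(input)
  if (is.matrix(weights)) weights <- array(weights, c(dim(weights), 1L, 1L))
  if (length(dim(weights)) != 4L) stop("weights must be a matrix or 4-D array")
  dw <- dim(weights)
  if (dw[1] != dw[2]) stop("only square kernels are supported")
  q <- dw[1]; c_in <- dw[3]; c_out <- dw[4]
  if (c_in != dim(X)[3])
    stop(sprintf("kernel expects %d input maps, input has %d", c_in, dim(X)[3]))
  if (is.null(bias)) bias <- rep(0, c_out)
  if (length(bias) == 1L) bias <- rep(bias, c_out)
  Y <- cpp_conv2d(X, kernel_to_wmat(weights), bias, q, stride, padding, dilation)
  drop_feature_cube(Y)
}

# (H, W, C) cube from matrix or 3-D array
as_feature_cube <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("feature map must be a matrix or 3-D array")
  storage.mode(x) <- "double"
  x
}

drop_feature_cube <- function(x) {
  if (dim(x)[3] == 1L) matrix(x[, , 1L], dim(x)[1], dim(x)[2]) else x
}

# Flatten a (q, q, C_in, C_out) kernel to the (C_out x C_in*q*q) matrix layout
# used by the C++ im2col path: columns run fastest over kernel column b, then
# kernel row a, then input channel.
kernel_to_wmat <- function(W) {
  d <- dim(W); q <- d[1]
  Wm <- matrix(0, nrow = d[4], ncol = d[3] * q * q)
  for (ci in seq_len(d[3])) {
    for (a in seq_len(q)) {
      for (b in seq_len(q)) {
        Wm[, (ci - 1L) * q * q + (a - 1L) * q + b] <- W[a, b, ci, ]
      }
    }
  }
  Wm
}

#' Maximum permissible dilation gaps of a stacked dilated-convolution schedule
#'
#' For per-layer dilation intervals \eqn{\lambda_1, \dots, \lambda_n}, runs the
#' backward "zigzag" recursion
#' \eqn{N_n = \lambda_n}, \eqn{N_i = \max(N_{i+1} - 2\lambda_i,\;
#' N_{i+1} - 2(N_{i+1} - \lambda_i),\; \lambda_i)},
#' which bounds the largest uncovered gap the stack may leave. A schedule is
#' free of gridding when the gap bound stays controlled through the first
#' layer; use [check_no_gridding()] for an explicit footprint audit.
#'
#' @param lambdas integer vector of per-layer dilation intervals, first layer
#'   first. All must be >= 1.
#' @return A list of class `dilation_schedule` with `lambdas` and `max_gaps`.
#' @examples
#' hdc_max_gap(c(2, 4, 5))$max_gaps   # 2 4 5
#' @export
hdc_max_gap <- function(lambdas) {
  if (length(lambdas) == 0) stop("empty dilation schedule")
  lambdas <- as.integer(lambdas)
  if (any(lambdas < 1)) stop("all dilation intervals must be >= 1")
  n <- length(lambdas)
  N <- integer(n)
  N[n] <- lambdas[n]
  if (n > 1) {
    for (i in seq(n - 1, 1)) {
      N[i] <- max(N[i + 1] - 2L * lambdas[i],
                  N[i + 1] - 2L * (N[i + 1] - lambdas[i]),
                  lambdas[i])
    }
  }
  structure(list(lambdas = lambdas, max_gaps = N), class = "dilation_schedule")
}

#' Audit a dilation schedule for gridding by explicit footprint composition
#'
#' Composes the 1-D receptive-field footprints of a stack of dilated kernels
#' of side `kernel_size` by brute force: layer by layer, every covered offset
#' spawns the taps of the next dilated kernel. The stack exhibits "gridding"
#' when the final footprint has uncovered positions strictly inside its span.
#'
#' @param lambdas per-layer dilation intervals, first layer first.
#' @param kernel_size kernel side length q (same for all layers).
#' @return List with `ok` (TRUE iff no interior gaps), `coverage` (logical
#'   vector over the footprint span), `offsets` (integer positions covered,
#'   centered at 0), and `n_gaps`.
#' @examples
#' check_no_gridding(c(1, 2, 5), 3)$ok  # TRUE
#' check_no_gridding(c(2, 2, 2), 3)$ok  # FALSE: classic gridding
#' @export
check_no_gridding <- function(lambdas, kernel_size) {
  stopifnot(length(lambdas) >= 1, all(lambdas >= 1), kernel_size >= 1)
  half <- (kernel_size - 1) %/% 2
  taps <- function(lam) (-half:(kernel_size - 1 - half)) * lam
  covered <- 0L
  for (lam in lambdas) {
    covered <- unique(as.integer(outer(covered, taps(lam), `+`)))
  }
  covered <- sort(covered)
  span <- seq(min(covered), max(covered))
  cov <- span %in% covered
  list(ok = all(cov), coverage = cov, offsets = covered,
       n_gaps = sum(!cov))
}

#' Sigmoid activation and its derivative
#'
#' \eqn{\mathrm{Sig}(c) = 1/(1+e^{-c})}; the derivative is computed in the
#' numerically safe product form \eqn{\mathrm{Sig}(c)(1-\mathrm{Sig}(c))},
#' which is algebraically identical to \eqn{e^{-c}/(1+e^{-c})^2}.
#' Both saturate without overflow for any finite input.
#'
#' @param c numeric vector, matrix or array.
#' @return Values in (0, 1) (`sigmoid`) or (0, 0.25] (`sigmoid_deriv`), same
#'   shape as the input.
#' @export
sigmoid <- function(c) {
  out <- c
  pos <- !is.na(c) & c >= 0
  out[pos] <- 1 / (1 + exp(-c[pos]))
  ez <- exp(c[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' @rdname sigmoid
#' @export
sigmoid_deriv <- function(c) {
  s <- sigmoid(c)
  s * (1 - s)
}

#' Rectified linear unit and its derivative
#'
#' \eqn{\mathrm{ReLU}(c) = \max(0, c)}. The derivative is 0 for c < 0 and 1
#' for c > 0; at exactly c = 0 (where it is undefined) the convention 0 is
#' used.
#'
#' @param c numeric vector, matrix or array.
#' @export
relu <- function(c) pmax(c, 0)

#' @rdname relu
#' @export
relu_deriv <- function(c) {
  d <- c
  d[] <- as.numeric(c > 0)
  d
}

#' Mean-squared-error training loss
#'
#' \eqn{R = \frac{1}{2m} \sum (K - g(P))^2} over aligned target and output
#' arrays, where `m` is the number of outputs entering the sum (defaults to
#' the element count).
#'
#' @param K targets (actual values).
#' @param gP model outputs, same shape as `K`.
#' @param m normalizing output count.
#' @return Non-negative scalar loss.
#' @export
mse_loss <- function(K, gP, m = length(K)) {
  if (!identical(dim(K), dim(gP)) || length(K) != length(gP))
    stop("targets and outputs have mismatched shapes")
  stopifnot(m >= 1)
  sum((K - gP)^2) / (2 * m)
}

# Gradient of mse_loss with respect to the outputs gP.
mse_loss_grad <- function(K, gP, m = length(K)) (gP - K) / m

# Row-interpolation matrix taking an m-sample axis to an n-sample axis with
# align-to-pixel-centers bilinear weights (the resize convention: source
# coordinate of output pixel i is (i + 0.5) * m/n - 0.5, clamped at the ends).
bilinear_matrix <- function(n_out, n_in) {
  B <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  s0 <- floor(src)
  f <- src - s0
  s0c <- pmin(pmax(s0, 0), n_in - 1)
  s1c <- pmin(s0 + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    B[i, s0c[i] + 1] <- B[i, s0c[i] + 1] + (1 - f[i])
    B[i, s1c[i] + 1] <- B[i, s1c[i] + 1] + f[i]
  }
  B
}

# Bilinear 2-D upsample of a matrix to (h, w) via the separable basis.
bilinear_upsample <- function(x, h, w) {
  Br <- bilinear_matrix(h, nrow(x))
  Bc <- bilinear_matrix(w, ncol(x))
  Br %*% x %*% t(Bc)
}

# Interpolation matrix from a coarse feature grid whose cell k sits at
# original-image coordinate a*k + b (receptive-field center), to the full
# image axis 1..n_out. Positions outside the covered span clamp to the edge
# cells. This respects the true geometry of the floor-pooled encoder, where
# coarse grids are offset and truncated rather than uniformly spread.
center_interp_matrix <- function(n_out, n_src, a, b) {
  B <- matrix(0, n_out, n_src)
  src <- (seq_len(n_out) - b) / a        # fractional source index
  s0 <- floor(src)
  f <- src - s0
  s0c <- pmin(pmax(s0, 1), n_src)
  s1c <- pmin(pmax(s0 + 1, 1), n_src)
  f[s0 < 1] <- 1; f[s0 >= n_src] <- 0
  for (i in seq_len(n_out)) {
    B[i, s0c[i]] <- B[i, s0c[i]] + (1 - f[i])
    B[i, s1c[i]] <- B[i, s1c[i]] + f[i]
  }
  B
}
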