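# Shared fixtures: small phantom configurations and brute-force oracles used
# across test files. Everything is generated in code; no stored data.

small_lesion_config <- function(seed = 7L, ...) {
  phantom_config(image_size = 64L, pixel_spacing_mm = 1.0, group = "lesion",
                 seed = seed, ...)
}

small_control_config <- function(seed = 7L, ...) {
  phantom_config(image_size = 64L, pixel_spacing_mm = 1.0, group = "control",
                 seed = seed, ...)
}

# noiseless variant: per-class sd 0, no global noise (blur kept unless asked)
noiseless_config <- function(group = "lesion", seed = 7L, blur = 0, ...) {
  hu <- lapply(periseg:::default_tissue_hu(group), function(p) c(p[1], 0))
  phantom_config(image_size = 64L, pixel_spacing_mm = 1.0, group = group,
                 tissue_hu = hu, noise_sd_hu = 0, blur_sigma_px = blur,
                 seed = seed, ...)
}

# four-nested-loop cross-correlation oracle (valid region, single channel)
conv_oracle <- function(P, Q) {
  hq <- nrow(Q)
  Ho <- nrow(P) - hq + 1L
  Wo <- ncol(P) - hq + 1L
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- 0
    for (a in seq_len(hq)) for (b in seq_len(hq))
      s <- s + P[i + a - 1L, j + b - 1L] * Q[a, b]
    out[i, j] <- s
  }
  out
}

# 1-D footprint composition oracle for gridding detection
footprint_oracle <- function(lambdas, q) {
  half <- (q - 1) %/% 2
  taps <- function(lam) (-half:(q - 1 - half)) * lam
  cov <- 0L
  for (lam in lambdas) cov <- unique(as.integer(outer(cov, taps(lam), `+`)))
  cov <- sort(cov)
  span <- seq(min(cov), max(cov))
  all(span %in% cov)
}

# disk mask helper
disk_mask <- function(n, ci, cj, r) {
  (row(matrix(0, n, n)) - ci)^2 + (col(matrix(0, n, n)) - cj)^2 <= r^2
}

random_mask <- function(n, p = 0.3) matrix(runif(n * n) < p, n, n)
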