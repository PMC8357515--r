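#' Tissue classes used by the phantom generator
#' @export
PHANTOM_TISSUES <- c("background", "epidermis_dermis", "subcutaneous_fascia",
                     "soft_tissue", "abscess_wall", "abscess_core", "anal_canal")

# Default per-tissue (mean, sd) HU. Fascia depends on the study group:
# lesion -95.45 +/- 8.26 vs control -76.34 +/- 7.69. Classes the study does
# not quantify carry idealized defaults recorded here, never in analysis code.
default_tissue_hu <- function(group) {
  fascia <- if (group == "lesion") c(-95.45, 8.26) else c(-76.34, 7.69)
  list(background         = c(-1000, 0),
       epidermis_dermis   = c(60, 15),
       subcutaneous_fascia = fascia,
       soft_tissue        = c(30, 10),
       abscess_wall       = c(40, 10),
       abscess_core       = c(15, 8),
       anal_canal         = c(-800, 50))
}

group_thickness_range <- function(group)
  if (group == "lesion") c(4.1, 4.9) else c(1.8, 3.6)

#' Phantom configuration
#'
#' Parameters of one synthetic perianal CT slice. The phantom is a cropped
#' perianal field of view: an elliptical body cross-section with an
#' epidermis/dermis band at the surface, a subcutaneous fascia band beneath
#' it, interior soft tissue, a central air-containing anal canal, and - for
#' the lesion group - a U-shaped high-attenuation abscess wall around a
#' low-attenuation core, opening toward and abutting the canal.
#'
#' All linear dimensions are in millimetres; the defaults give a 64 mm field
#' of view (128 px at 0.5 mm/px). Skin-band thickness defaults to the middle
#' of the group's range (lesion 4.1-4.9 mm, control 1.8-3.6 mm).
#'
#' @param image_size pixels per side (>= 32).
#' @param pixel_spacing_mm mm per pixel.
#' @param group "lesion" or "control".
#' @param skin_thickness_mm epidermis+dermis band thickness; `NULL` uses the
#'   group-range midpoint.
#' @param tissue_hu named list mapping tissue class to `c(mean, sd)` HU;
#'   `NULL` uses the defaults for the group.
#' @param lesion_geometry list with `outer_radius_mm`, `core_radius_mm`,
#'   `gap_angle_deg` (angular opening of the U), `angle_deg` (direction of
#'   the lesion center from the canal; 90 = posterior), and optionally
#'   `center_offset_mm` (distance canal-center to lesion-center; `NULL`
#'   abuts the canal).
#' @param noise_sd_hu additive Gaussian noise (HU) on top of per-tissue
#'   heterogeneity.
#' @param blur_sigma_px Gaussian edge-blur width in pixels (blurred lesion
#'   margins).
#' @param fascia_thickness_mm thickness of the subcutaneous fascia band.
#' @param canal_radius_mm anal-canal radius.
#' @param body_axes_frac semi-axes of the body ellipse as fractions of the
#'   field of view (col, row).
#' @param seed integer RNG seed; identical configurations are bit-identical.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L, pixel_spacing_mm = 0.5,
                           group = c("lesion", "control"),
                           skin_thickness_mm = NULL, tissue_hu = NULL,
                           lesion_geometry = list(), noise_sd_hu = 5,
                           blur_sigma_px = 1, fascia_thickness_mm = 6,
                           canal_radius_mm = 3,
                           body_axes_frac = c(0.45, 0.42), seed = 1L) {
  group <- match.arg(group)
  if (image_size < 32) stop("geometry error: image_size must be >= 32")
  if (is.null(skin_thickness_mm))
    skin_thickness_mm <- mean(group_thickness_range(group))
  if (skin_thickness_mm <= 0) stop("skin_thickness_mm must be positive")
  if (is.null(tissue_hu)) tissue_hu <- default_tissue_hu(group)
  if (!all(PHANTOM_TISSUES %in% names(tissue_hu)))
    stop("tissue_hu must name all tissue classes")
  geom <- modifyList(list(outer_radius_mm = 5.5, core_radius_mm = 3,
                          gap_angle_deg = 80, angle_deg = 90,
                          center_offset_mm = NULL), lesion_geometry)
  if (geom$core_radius_mm >= geom$outer_radius_mm)
    stop("geometry error: core radius must be smaller than outer radius")
  stopifnot(noise_sd_hu >= 0, blur_sigma_px >= 0, pixel_spacing_mm > 0,
            fascia_thickness_mm > 0, canal_radius_mm > 0)
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing_mm = pixel_spacing_mm, group = group,
                 skin_thickness_mm = skin_thickness_mm, tissue_hu = tissue_hu,
                 lesion_geometry = geom, noise_sd_hu = noise_sd_hu,
                 blur_sigma_px = blur_sigma_px,
                 fascia_thickness_mm = fascia_thickness_mm,
                 canal_radius_mm = canal_radius_mm,
                 body_axes_frac = body_axes_frac, seed = as.integer(seed)),
            class = "phantom_config")
}

# Gaussian blur as separable band-matrix products with renormalized edge
# rows (avoids darkening toward the air border that zero padding would cause).
gaussian_blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    G[i, j] <- w / sum(w)
  }
  G
}

#' Generate one synthetic perianal CT phantom
#'
#' Builds the tissue-class map from the configured geometry, draws per-pixel
#' HU from each class's (mean, sd), adds global Gaussian noise, then applies
#' a Gaussian edge blur, emulating the blurred lesion margins and uneven
#' density of perianal abscesses on CT. Control-group phantoms contain no
#' lesion. Identical configurations (including the seed) produce
#' bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return A list with `slice` (a [ct_slice()]) and `truth`, a
#'   `phantom_truth` list carrying `tissue_map` (integer matrix, levels in
#'   `attr(,"tissues")`), `lesion_mask` (logical), `skin_thickness_mm`,
#'   `hu_params`, and `group`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  n <- config$image_size
  sp <- config$pixel_spacing_mm
  ctr <- (n + 1) / 2
  fov <- n * sp

  # mm coordinates relative to the image center (x = cols, y = rows)
  xs <- (col(matrix(0, n, n)) - ctr) * sp
  ys <- (row(matrix(0, n, n)) - ctr) * sp
  r <- sqrt(xs^2 + ys^2)
  a <- config$body_axes_frac[1] * fov   # semi-axis along x
  b <- config$body_axes_frac[2] * fov   # semi-axis along y
  # boundary radius of the body ellipse along each pixel's direction
  rb <- a * b / sqrt((b * xs / pmax(r, 1e-9))^2 + (a * ys / pmax(r, 1e-9))^2)
  rb[r < 1e-9] <- b

  t_skin <- config$skin_thickness_mm
  t_fascia <- config$fascia_thickness_mm
  tmap <- matrix(1L, n, n)                              # background
  body <- r <= rb
  depth <- rb - r                                       # radial depth below surface
  tmap[body & depth < t_skin] <- 2L                     # epidermis_dermis
  tmap[body & depth >= t_skin & depth < t_skin + t_fascia] <- 3L
  tmap[body & depth >= t_skin + t_fascia] <- 4L         # soft_tissue
  tmap[r <= config$canal_radius_mm] <- 7L               # anal_canal

  lesion_mask <- matrix(FALSE, n, n)
  if (config$group == "lesion") {
    g <- config$lesion_geometry
    d <- g$center_offset_mm
    if (is.null(d)) d <- config$canal_radius_mm + g$outer_radius_mm - 1.5
    phi <- g$angle_deg * pi / 180
    lx <- d * cos(phi); ly <- d * sin(phi)
    soft_reach <- b - t_skin - t_fascia                 # usable radius near angle 90
    if (d + g$outer_radius_mm > soft_reach - 0.5 ||
        2 * g$outer_radius_mm > fov / 2)
      stop(sprintf(
        "geometry error: lesion (offset %.1f + radius %.1f mm) does not fit inside the soft tissue (reach %.1f mm)",
        d, g$outer_radius_mm, soft_reach))
    rho <- sqrt((xs - lx)^2 + (ys - ly)^2)
    ang <- atan2(ys - ly, xs - lx) * 180 / pi
    open_dir <- (g$angle_deg + 180) %% 360              # the U opens toward the canal
    dang <- abs(((ang - open_dir + 180) %% 360) - 180)
    core <- rho <= g$core_radius_mm
    wall <- rho <= g$outer_radius_mm & !core & dang > g$gap_angle_deg / 2
    soft <- tmap == 4L
    tmap[core & soft] <- 6L                             # abscess_core
    tmap[wall & soft] <- 5L                             # abscess_wall
    lesion_mask <- tmap == 5L | tmap == 6L
  }

  mu <- vapply(config$tissue_hu[PHANTOM_TISSUES], `[`, 0, 1)
  sdv <- vapply(config$tissue_hu[PHANTOM_TISSUES], `[`, 0, 2)
  hu <- mu[tmap] + rnorm(n * n) * sdv[tmap] + rnorm(n * n) * config$noise_sd_hu
  hu <- matrix(hu, n, n)
  if (config$blur_sigma_px > 0) {
    G <- gaussian_blur_matrix(n, config$blur_sigma_px)
    hu <- G %*% hu %*% t(G)
  }
  hu <- pmin(pmax(hu, -1024), 3071)

  attr(tmap, "tissues") <- PHANTOM_TISSUES
  truth <- structure(list(tissue_map = tmap, lesion_mask = lesion_mask,
                          skin_thickness_mm = t_skin,
                          hu_params = config$tissue_hu, group = config$group,
                          config = config),
                     class = "phantom_truth")
  list(slice = ct_slice(hu, c(sp, sp)), truth = truth)
}

#' Generate a two-group phantom cohort
#'
#' Draws per-sample skin thickness uniformly within the group's range
#' (lesion 4.1-4.9 mm, control 1.8-3.6 mm) and jitters the lesion geometry
#' (outer radius, core radius, U opening and orientation) uniformly within
#' realistic bands; everything is reproducible from `seed`.
#'
#' @param n_lesion,n_control sample counts (>= 0).
#' @param base_config a [phantom_config()] providing image size, spacing,
#'   noise and blur; per-sample fields are overridden per draw.
#' @param seed integer cohort seed.
#' @return A list of samples as returned by [generate_phantom()]; each
#'   `truth$group` carries the group label. Lesion samples come first.
#' @export
generate_cohort <- function(n_lesion, n_control,
                            base_config = phantom_config(), seed = 1L) {
  stopifnot(n_lesion >= 0, n_control >= 0)
  n <- n_lesion + n_control
  if (n == 0) return(list())
  set.seed(as.integer(seed))
  groups <- rep(c("lesion", "control"), c(n_lesion, n_control))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    rng <- group_thickness_range(g)
    outer <- runif(1, 4.5, 6.5)
    geom <- list(outer_radius_mm = outer,
                 core_radius_mm = outer * runif(1, 0.45, 0.65),
                 gap_angle_deg = runif(1, 60, 100),
                 angle_deg = 90 + runif(1, -30, 30))
    cfg <- phantom_config(
      image_size = base_config$image_size,
      pixel_spacing_mm = base_config$pixel_spacing_mm,
      group = g,
      skin_thickness_mm = runif(1, rng[1], rng[2]),
      lesion_geometry = geom,
      noise_sd_hu = base_config$noise_sd_hu,
      blur_sigma_px = base_config$blur_sigma_px,
      fascia_thickness_mm = base_config$fascia_thickness_mm,
      canal_radius_mm = base_config$canal_radius_mm,
      body_axes_frac = base_config$body_axes_frac,
      seed = seeds[i])
    out[[i]] <- generate_phantom(cfg)
  }
  out
}

#' Tissue-class mask from a phantom ground truth
#'
#' @param truth a `phantom_truth`.
#' @param tissue tissue-class name (see `PHANTOM_TISSUES`).
#' @param erode_px erode the class mask by this many pixels before returning
#'   (partial-volume avoidance for HU measurements near class interfaces).
#' @return Logical matrix.
#' @export
tissue_mask <- function(truth, tissue, erode_px = 0L) {
  k <- match(tissue, PHANTOM_TISSUES)
  if (is.na(k)) stop("unknown tissue class: ", tissue)
  m <- truth$tissue_map == k
  if (erode_px > 0) m <- binary_erode(m, erode_px)
  m
}
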