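# File I/O. No image codec package exists in the target environment, so two
# simple open formats are implemented natively:
#  * NIfTI-1 (.nii / .nii.gz), float64 data for slices, uint8 for masks,
#    spacing in pixdim. Only single-slice 2-D volumes are written; readers
#    accept the common scalar datatypes.
#  * Uncompressed little-endian grayscale TIFF (.tif/.tiff), 16-bit for
#    slices (HU stored with a +1024 offset as unsigned values, so integer HU
#    round-trips losslessly) and 8-bit {0,255} for masks. Pixel spacing
#    travels in a JSON sidecar `<path>.json`.
# PNG is rejected: base R has no zlib/CRC32 codec to build one honestly.

u16_to_raw <- function(v) as.raw(c(rbind(v %% 256L, v %/% 256L)))
u32_to_raw <- function(v) {
  as.raw(c(rbind(v %% 256L, (v %/% 256L) %% 256L,
                 (v %/% 65536L) %% 256L, (v %/% 16777216L) %% 256L)))
}
raw_to_u16 <- function(r) readBin(r, "integer", n = length(r) / 2, size = 2,
                                  signed = FALSE, endian = "little")

file_ext <- function(path) tolower(sub(".*\\.", "", sub("\\.gz$", ".gz", path)))

is_nii <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_tiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

# ---- TIFF ------------------------------------------------------------------

tiff_write <- function(pixels_u, path, bits) {
  H <- nrow(pixels_u); W <- ncol(pixels_u)
  vals <- as.integer(round(t(pixels_u)))          # row-major raster order
  maxv <- 2^bits - 1
  if (any(vals < 0 | vals > maxv)) stop("pixel values out of range for ", bits, "-bit TIFF")
  data <- if (bits == 16) u16_to_raw(vals) else as.raw(vals)
  entries <- list(
    c(256L, 4L, 1L, W), c(257L, 4L, 1L, H), c(258L, 3L, 1L, bits),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, 0L),
    c(277L, 3L, 1L, 1L), c(278L, 4L, 1L, H), c(279L, 4L, 1L, length(data)),
    c(339L, 3L, 1L, 1L))
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + 12L * length(entries) + 4L
  entries[[6]][4] <- data_offset                  # StripOffsets
  out <- c(charToRaw("II"), u16_to_raw(42L), u32_to_raw(ifd_offset),
           u16_to_raw(length(entries)))
  for (e in entries) {
    val_field <- if (e[2] == 3L) c(u16_to_raw(e[4]), as.raw(c(0, 0))) else u32_to_raw(e[4])
    out <- c(out, u16_to_raw(e[1]), u16_to_raw(e[2]), u32_to_raw(e[3]), val_field)
  }
  out <- c(out, u32_to_raw(0L), data)
  writeBin(out, path)
  invisible(path)
}

tiff_read <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(r[1:2]), "II") || raw_to_u16(r[3:4]) != 42L)
    stop("not a little-endian TIFF file: ", path)
  u32 <- function(off) sum(as.integer(r[off + 1:4]) * c(1, 256, 65536, 16777216))
  ifd <- u32(4L)
  n_entries <- raw_to_u16(r[ifd + 1:2])
  tags <- list()
  for (k in seq_len(n_entries)) {
    base <- ifd + 2L + 12L * (k - 1L)
    tag <- raw_to_u16(r[base + 1:2]); type <- raw_to_u16(r[base + 3:4])
    count <- u32(base + 4L)
    vals <- if (type == 3L && count <= 2L) {
      raw_to_u16(r[base + 8L + seq_len(2L * count)])
    } else if (type == 4L && count == 1L) {
      u32(base + 8L)
    } else {                                       # stored out of line
      off <- u32(base + 8L)
      if (type == 3L) raw_to_u16(r[off + seq_len(2L * count)])
      else vapply(seq_len(count), function(i) u32(off + 4L * (i - 1L)), 0)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("TIFF tag ", tag, " missing in ", path)
    v
  }
  W <- need(256L); H <- need(257L); bits <- need(258L)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stop("only uncompressed TIFF is supported")
  offsets <- need(273L); counts <- need(279L)
  data <- unlist(lapply(seq_along(offsets),
                        function(i) r[offsets[i] + seq_len(counts[i])]),
                 use.names = FALSE)
  vals <- if (bits == 16L) raw_to_u16(as.raw(data)) else as.integer(as.raw(data))
  matrix(vals, nrow = H, ncol = W, byrow = TRUE)
}

sidecar_path <- function(path) paste0(path, ".json")

# ---- NIfTI-1 ---------------------------------------------------------------

nifti_write <- function(pixels, path, spacing_mm, datatype = 64L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  H <- nrow(pixels); W <- ncol(pixels)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                       # sizeof_hdr
  wc(36)                            # data_type..dim_info
  # dim[1] is the fastest-varying axis = R matrix rows (column-major layout)
  wi(c(2L, H, W, 1L, 1L, 1L, 1L, 1L), 2)
  wf(c(0, 0, 0)); wi(0L, 2)         # intent_p1..3, intent_code
  bitpix <- c(`2` = 8L, `4` = 16L, `64` = 64L)[as.character(datatype)]
  wi(datatype, 2); wi(bitpix, 2); wi(0L, 2)
  wf(c(1, spacing_mm[1], spacing_mm[2], 1, 1, 1, 1, 1))   # pixdim
  wf(352); wf(1); wf(0)             # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc(1)                  # slice_end, slice_code
  writeBin(as.raw(2L), con)         # xyzt_units: mm
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)   # cal_max..toffset, glmax, glmin
  desc <- charToRaw("periseg 2-D CT slice")
  writeBin(c(desc, raw(80 - length(desc))), con)
  wc(24)                            # aux_file
  wi(c(0L, 0L), 2)                  # qform_code, sform_code
  wf(rep(0, 6)); wf(rep(0, 12))     # quaternions, srow
  wc(16)                            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  wc(4)                             # extension flag
  if (datatype == 64L) {
    writeBin(as.numeric(pixels), con, size = 8, endian = "little")
  } else if (datatype == 4L) {
    writeBin(as.integer(pixels), con, size = 2, endian = "little")
  } else {
    writeBin(as.raw(as.integer(pixels)), con)
  }
  invisible(path)
}

nifti_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("not a NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  dims <- ri(40, 2, 8)
  if (dims[1] < 2 || any(dims[4:8] > 1))
    stop("only single-slice 2-D NIfTI volumes are supported")
  H <- dims[2]; W <- dims[3]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  if (scl_slope == 0) scl_slope <- 1
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- H * W
  vals <- switch(as.character(datatype),
    `2`  = as.integer(readBin(con, "raw", n)),
    `4`  = readBin(con, "integer", n, size = 2, endian = "little"),
    `8`  = readBin(con, "integer", n, size = 4, endian = "little"),
    `16` = readBin(con, "double", n, size = 4, endian = "little"),
    `64` = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype))
  list(pixels = matrix(vals * scl_slope + scl_inter, H, W),
       spacing_mm = pixdim[2:3])
}

# ---- public slice / mask I/O ----------------------------------------------

#' Read and write CT slices
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`; float64 data, per-axis
#' spacing in the header) and uncompressed 16-bit grayscale little-endian
#' TIFF (`.tif`/`.tiff`; integer HU stored with a +1024 offset, spacing in a
#' JSON sidecar `<path>.json`). TIFF quantizes to integer HU; NIfTI is fully
#' lossless. `.png` and other extensions raise an explicit error.
#'
#' @param path file path with a supported extension.
#' @param slice a [ct_slice()] (or HU matrix plus `spacing_mm`).
#' @param spacing_mm spacing override when `slice` is a plain matrix.
#' @return `read_slice` returns a [ct_slice()]; `write_slice` returns the
#'   path invisibly.
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is_nii(path)) {
    v <- nifti_read(path)
    return(ct_slice(v$pixels, v$spacing_mm))
  }
  if (is_tiff(path)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop("missing spacing: TIFF slices need a JSON sidecar at ", sc,
           " with field spacing_mm")
    meta <- jsonlite::fromJSON(sc)
    if (is.null(meta$spacing_mm)) stop("sidecar ", sc, " lacks spacing_mm")
    return(ct_slice(tiff_read(path) - 1024L, meta$spacing_mm))
  }
  stop("unsupported slice format: ", path, " (use .nii, .nii.gz, .tif or .tiff)")
}

#' @rdname read_slice
#' @export
write_slice <- function(slice, path, spacing_mm = NULL) {
  if (is_ct_slice(slice)) {
    px <- slice$pixels
    if (is.null(spacing_mm)) spacing_mm <- slice$spacing_mm
  } else px <- slice
  if (is.null(spacing_mm)) stop("spacing_mm required")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (is_nii(path)) {
    nifti_write(px, path, spacing_mm, datatype = 64L)
  } else if (is_tiff(path)) {
    tiff_write(round(px) + 1024, path, bits = 16L)
    jsonlite::write_json(list(spacing_mm = spacing_mm), sidecar_path(path),
                         auto_unbox = FALSE, digits = NA)
  } else stop("unsupported slice format: ", path)
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are stored as 8-bit images with values {0, 255} (TIFF) or a uint8
#' NIfTI volume; on reading, any nonzero pixel is foreground.
#'
#' @param mask logical matrix.
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return `read_mask` returns a logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- if (is_nii(path)) nifti_read(path)$pixels
        else if (is_tiff(path)) tiff_read(path)
        else stop("unsupported mask format: ", path)
  if (length(px) == 0) stop("empty mask file: ", path)
  px != 0
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  m <- as_binary_mask(mask) * 255L
  if (is_nii(path)) nifti_write(m, path, c(1, 1), datatype = 2L)
  else if (is_tiff(path)) tiff_write(m, path, bits = 8L)
  else stop("unsupported mask format: ", path)
  invisible(path)
}

# ---- weights archive -------------------------------------------------------

#' Save and load trained network weights
#'
#' The archive is a raw little-endian float64 stream (`<path>`) plus a JSON
#' manifest (`<path>.json`) recording the network spec, per-array shapes and
#' offsets, the training configuration and the loss history.
#'
#' @param trained a `trained_network`.
#' @param path path for the binary weight stream (e.g. `weights.bin`).
#' @return `read_weights` returns a `trained_network`.
#' @export
write_weights <- function(trained, path) {
  stopifnot(inherits(trained, "trained_network"))
  arrays <- list()
  values <- numeric(0)
  for (nm in names(trained$weights)) {
    w <- trained$weights[[nm]]
    arrays[[nm]] <- list(w_dim = dim(w$Wm), b_len = length(w$b),
                         offset = length(values))
    values <- c(values, as.numeric(w$Wm), as.numeric(w$b))
  }
  con <- file(path, "wb")
  writeBin(values, con, size = 8, endian = "little")
  close(con)
  manifest <- list(format = "periseg-weights-v1",
                   spec = unclass_spec(trained$spec),
                   config = unclass(trained$config),
                   history = trained$history,
                   arrays = arrays, n_values = length(values))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_spec <- function(spec) {
  s <- unclass(spec)
  s$layers <- lapply(s$layers, unclass)
  s
}

respec <- function(s) {
  s$layers <- lapply(s$layers, function(l) structure(l, class = "layer_spec"))
  structure(s, class = "network_spec")
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  manifest <- jsonlite::fromJSON(paste0(path, ".json"), simplifyDataFrame = FALSE,
                                 simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(manifest$format, "periseg-weights-v1"))
    stop("not a periseg weights archive: ", path)
  con <- file(path, "rb")
  values <- readBin(con, "double", manifest$n_values, size = 8, endian = "little")
  close(con)
  wts <- list()
  for (nm in names(manifest$arrays)) {
    a <- manifest$arrays[[nm]]
    wd <- unlist(a$w_dim)
    nw <- prod(wd)
    wts[[nm]] <- list(Wm = matrix(values[a$offset + seq_len(nw)], wd[1], wd[2]),
                      b = values[a$offset + nw + seq_len(a$b_len)])
  }
  spec <- manifest$spec
  spec$layers <- lapply(spec$layers, function(l) do.call(layer_spec, l))
  spec$skip_after <- as.character(unlist(spec$skip_after))
  spec <- structure(spec, class = "network_spec")
  cfgf <- manifest$config
  cfg <- training_config(epochs = cfgf$epochs, batch_size = cfgf$batch_size,
                         learning_rate = cfgf$learning_rate, seed = cfgf$seed,
                         m = cfgf$m, binarize_threshold = cfgf$binarize_threshold,
                         patches_per_slice = cfgf$patches_per_slice)
  history <- do.call(rbind, lapply(manifest$history, as.data.frame))
  structure(list(spec = spec, weights = wts, history = history, config = cfg),
            class = "trained_network")
}
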