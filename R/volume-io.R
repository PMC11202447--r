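#' Construct a volumetric image
#'
#' A `volume` is a single-channel 3D scalar field with per-axis voxel spacing
#' (mm), a 4x4 voxel-to-world affine, and free-form provenance metadata. It is
#' the unit every other function in the package consumes: raw CT-like
#' intensities before [window_intensity()], values in `[0, 1]` after.
#'
#' @param data numeric 3D array (trailing singleton axes are squeezed).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(c(spacing, 1))`.
#' @param meta named list of provenance entries.
#' @return An object of class `volume`.
#' @seealso [binary_mask()], [read_nifti()], [window_intensity()]
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL, meta = list()) {
  data <- squeeze_3d(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive finite numbers (mm).")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) abort("`affine` must be a 4x4 matrix.")
  structure(
    list(data = data, spacing = spacing, affine = affine, meta = meta),
    class = "volume"
  )
}

#' Construct a binary segmentation mask
#'
#' A `binary_mask` shares the geometry of a [volume()] but its voxels are
#' exactly 0 (background) or 1 (foreground) — ground truth or prediction.
#'
#' @inheritParams volume
#' @return An object of class `binary_mask` (also a `volume`).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL, meta = list()) {
  v <- volume(data, spacing, affine, meta)
  check_binary(v$data)
  class(v) <- c("binary_mask", "volume")
  v
}

#' @export
is_volume <- function(x) inherits(x, "volume")

#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @export
print.volume <- function(x, ...) {
  kind <- if (is_binary_mask(x)) "binary_mask" else "volume"
  cat(sprintf(
    "<%s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
    kind, paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, digits = 4), collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

squeeze_3d <- function(data) {
  if (!is.numeric(data) && !is.logical(data)) abort("volume data must be numeric.")
  d <- dim(data)
  if (is.null(d)) abort("volume data must be an array with 3 spatial axes.")
  if (length(d) > 3) {
    keep <- d > 1
    # allow e.g. 4D NIfTI with a singleton time axis
    if (sum(keep) > 3) {
      abort(sprintf(
        "volume has %d non-singleton axes; exactly 3 spatial axes are supported.",
        sum(keep)
      ))
    }
    d2 <- d[keep]
    d2 <- c(d2, rep(1L, 3 - length(d2)))
    data <- array(as.numeric(data), dim = d2)
  } else if (length(d) < 3) {
    abort("volume data must have 3 spatial axes.")
  } else {
    data <- array(as.numeric(data), dim = d)
  }
  data
}

check_binary <- function(x, where = "mask") {
  if (!all(x == 0 | x == 1)) {
    abort(sprintf("%s contains values other than 0/1.", where))
  }
  invisible(TRUE)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol
}

# ---------------------------------------------------------------------------
# NIfTI-1 read/write. No R NIfTI package is available in this stack, so the
# single-file (.nii / .nii.gz) NIfTI-1 codec is implemented directly; it is
# cross-checked against nibabel in the test suite.
# ---------------------------------------------------------------------------

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 (`.nii`, optionally gzip-compressed `.nii.gz`).
#' Voxel spacing comes from the header `pixdim`; the affine from the sform
#' when present, else the qform quaternion, else a diagonal spacing matrix.
#' 4D files with a singleton trailing axis are squeezed to 3D.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()]; header scaling (`scl_slope`/`scl_inter`) is applied.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) abort(sprintf("NIfTI file does not exist: %s", path))
  con <- gzfile(path, "rb")  # reads plain files transparently too
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) abort(sprintf("corrupt NIfTI file (truncated header): %s", path))
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) abort(sprintf("not a NIfTI-1 file (bad sizeof_hdr): %s", path))
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) abort(sprintf("not a NIfTI-1 file (bad magic): %s", path))
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3 || ndim > 7) abort(sprintf("unsupported NIfTI dimensionality %d: %s", ndim, path))
  shape <- dims[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  qform_code <- rd(252, "integer", 1, 2)
  sform_code <- rd(254, "integer", 1, 2)
  quat <- rd(256, "double", 6, 4)  # b, c, d, qoffset x/y/z
  srow <- rbind(rd(280, "double", 4, 4), rd(296, "double", 4, 4), rd(312, "double", 4, 4))

  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) abort(sprintf("unsupported NIfTI datatype code %d: %s", datatype, path))
  n_vox <- prod(shape)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox) abort(sprintf("corrupt NIfTI file (truncated data): %s", path))
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1

  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    affine <- quaternion_affine(quat[1], quat[2], quat[3], quat[4:6],
                                spacing, qfac = ifelse(pixdim[1] < 0, -1, 1))
  }
  v <- volume(data, spacing = spacing, affine = affine,
              meta = list(path = path, datatype = datatype))
  v
}

quaternion_affine <- function(b, c, d, offset, spacing, qfac = 1) {
  a2 <- 1 - b^2 - c^2 - d^2
  a <- sqrt(max(a2, 0))
  R <- rbind(
    c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),     2 * (b * d + a * c)),
    c(2 * (b * c + a * d),   a^2 + c^2 - b^2 - d^2,   2 * (c * d - a * b)),
    c(2 * (b * d - a * c),   2 * (c * d + a * b),     a^2 + d^2 - b^2 - c^2)
  )
  S <- diag(c(spacing[1], spacing[2], spacing[3] * qfac))
  rbind(cbind(R %*% S, offset), c(0, 0, 0, 1))
}

#' Write a volume or mask as NIfTI-1
#'
#' Writes single-file NIfTI-1, gzip-compressed when `path` ends in `.gz`.
#' Masks are stored as `uint8`, images as `float64` by default, so
#' `read_nifti(write_nifti(v))` round-trips exactly.
#'
#' @param v a [volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype one of `"float64"`, `"float32"`, `"uint8"`; default picks
#'   `uint8` for masks and `float64` otherwise.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(v, path, datatype = NULL) {
  stopifnot(is_volume(v))
  if (is.null(datatype)) datatype <- if (is_binary_mask(v)) "uint8" else "float64"
  dt_code <- switch(datatype,
    float64 = 64L, float32 = 16L, uint8 = 2L,
    abort(sprintf("unsupported write datatype '%s'", datatype))
  )
  dt_size <- switch(datatype, float64 = 8L, float32 = 4L, uint8 = 1L)
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))

  hdr <- raw(348)
  put <- function(hdr, off, x, what, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  shape <- dim(v$data)
  hdr <- put(hdr, 0, 348L, "integer", 4)
  hdr <- put(hdr, 40, as.integer(c(3, shape, 1, 1, 1, 1)), "integer", 2)
  hdr <- put(hdr, 70, dt_code, "integer", 2)
  hdr <- put(hdr, 72, as.integer(dt_size * 8L), "integer", 2)
  hdr <- put(hdr, 76, c(1, v$spacing, 0, 0, 0, 0), "double", 4)
  hdr <- put(hdr, 108, 352, "double", 4)          # vox_offset
  hdr <- put(hdr, 112, c(1, 0), "double", 4)      # scl_slope, scl_inter
  hdr <- put(hdr, 254, 2L, "integer", 2)          # sform_code (aligned)
  hdr <- put(hdr, 280, as.numeric(t(v$affine[1:3, ])), "double", 4)
  hdr[345:348] <- as.raw(c(110L, 43L, 49L, 0L))   # "n+1\0"

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  writeBin(raw(4), con)  # no header extensions
  vals <- as.numeric(v$data)
  if (datatype == "uint8") {
    writeBin(as.integer(round(vals)), con, size = 1, endian = "little")
  } else {
    writeBin(vals, con, size = dt_size, endian = "little")
  }
  invisible(path)
}
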