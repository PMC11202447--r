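#' Window and normalize CT-like intensities
#'
#' Clips intensities to `[lo, hi]` and rescales them linearly so that `lo`
#' maps to 0 and `hi` to 1 — the standard CT soft-tissue windowing step used
#' to standardize the intensity range before training. The default window of
#' \eqn{[-200, 200]} HU covers abdominal soft tissue. Spacing and affine are
#' unchanged; the op is monotone and idempotent once the range is `[0, 1]`
#' (with `lo = 0`, `hi = 1`).
#'
#' @param v a [volume()].
#' @param lo,hi window endpoints in the input intensity units; `lo < hi`.
#' @return A windowed [volume()] with values in `[0, 1]`.
#' @export
window_intensity <- function(v, lo = -200, hi = 200) {
  stopifnot(is_volume(v))
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("`lo` must be strictly less than `hi`.")
  }
  x <- pmin(pmax(v$data, lo), hi)
  v$data <- array((x - lo) / (hi - lo), dim = dim(v$data))
  v$meta$window <- c(lo = lo, hi = hi)
  v
}

#' Resize a volume or mask to a target grid
#'
#' Images are resampled with trilinear interpolation; masks with
#' nearest-neighbour so that binarity is preserved exactly. Voxel spacing is
#' rescaled so the physical extent of the field is unchanged. Output voxel
#' centres are mapped into the input grid with the half-voxel-aligned
#' convention `c_in = (i + 0.5) * n_in / n_out - 0.5`.
#'
#' @param v a [volume()] or [binary_mask()].
#' @param target_shape integer length-3, all >= 1.
#' @param kind `"image"` (trilinear) or `"mask"` (nearest-neighbour); defaults
#'   to `"mask"` when `v` is a [binary_mask()].
#' @return A resized object of the same class as `v`.
#' @export
resize_volume <- function(v, target_shape, kind = NULL) {
  stopifnot(is_volume(v))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3 || any(is.na(target_shape)) || any(target_shape < 1)) {
    abort("`target_shape` must be 3 positive integers.")
  }
  if (is.null(kind)) kind <- if (is_binary_mask(v)) "mask" else "image"
  kind <- match.arg(kind, c("image", "mask"))
  src <- dim(v$data)
  coords <- lapply(1:3, function(ax) {
    ci <- (seq_len(target_shape[ax]) - 0.5) * src[ax] / target_shape[ax] - 0.5
    pmin(pmax(ci, 0), src[ax] - 1)
  })
  out <- if (kind == "mask") {
    idx <- lapply(1:3, function(ax) as.integer(round(coords[[ax]])) + 1L)
    v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    trilinear_gather(v$data, coords)
  }
  new_spacing <- v$spacing * src / target_shape
  res <- v
  res$data <- array(out, dim = target_shape)
  res$spacing <- new_spacing
  res$affine <- v$affine %*% diag(c(src / target_shape, 1))
  if (kind == "mask") check_binary(res$data, "resized mask")
  res
}

trilinear_gather <- function(arr, coords) {
  src <- dim(arr)
  f <- lapply(coords, floor)
  w <- Map(function(c, fl) c - fl, coords, f)
  i0 <- lapply(seq_along(f), function(ax) pmin(f[[ax]], src[ax] - 1) + 1)
  i1 <- lapply(seq_along(f), function(ax) pmin(f[[ax]] + 1, src[ax] - 1) + 1)
  nd <- vapply(coords, length, 1L)
  # accumulate the 8 corner contributions on the output grid
  out <- array(0, dim = nd)
  wd <- array(rep(w[[1]], times = nd[2] * nd[3]), dim = nd)
  wh <- array(rep(rep(w[[2]], each = nd[1]), times = nd[3]), dim = nd)
  ww <- array(rep(w[[3]], each = nd[1] * nd[2]), dim = nd)
  for (bd in 0:1) for (bh in 0:1) for (bw in 0:1) {
    id <- if (bd == 0) i0[[1]] else i1[[1]]
    ih <- if (bh == 0) i0[[2]] else i1[[2]]
    iw <- if (bw == 0) i0[[3]] else i1[[3]]
    wt <- (if (bd == 0) 1 - wd else wd) *
      (if (bh == 0) 1 - wh else wh) *
      (if (bw == 0) 1 - ww else ww)
    out <- out + wt * arr[id, ih, iw, drop = FALSE]
  }
  out
}

#' One-hot encode a binary mask
#'
#' Expands a mask into the 2-channel label field the network head is trained
#' against: channel 1 is background (`1 - m`), channel 2 foreground (`m`);
#' the channels sum to one at every voxel.
#'
#' @param m a [binary_mask()] or binary 3D array.
#' @return A numeric array with dim `c(2, dim(m))` (channel-first).
#' @export
to_onehot <- function(m) {
  data <- if (is_volume(m)) m$data else squeeze_3d(m)
  check_binary(data)
  d <- dim(data)
  out <- array(0, dim = c(2L, d))
  out[1, , , ] <- 1 - data
  out[2, , , ] <- data
  out
}
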