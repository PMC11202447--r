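#' Define a phantom task family
#'
#' A family is the synthetic analogue of one organ-segmentation task: every
#' render draws a single foreground structure of the family's base shape,
#' with per-subject variation in size, position, orientation and intensity.
#' Intensities are in raw CT-like units (HU-ish): background and foreground
#' levels are drawn per render from `intensity_bg` / `intensity_fg`, and
#' voxelwise Gaussian texture noise is added, so that after the standard
#' \eqn{[-200, 200]} window the contrast resembles soft tissue (bg ~0.35,
#' fg ~0.65). By construction the two levels differ by at least 2 pooled
#' standard deviations, so tasks are learnable.
#'
#' @param name family label.
#' @param base_shape `"ellipsoid"`, `"lobed_blob"` or `"capsule"`.
#' @param size_range fraction of the volume extent occupied by the structure
#'   diameter, length-2 range.
#' @param position_jitter centre jitter as a fraction of the extent.
#' @param centre nominal centre in fractional coordinates.
#' @param intensity_fg,intensity_bg `c(mean, sd)` of the per-render
#'   foreground/background levels (pre-windowing units).
#' @param texture_noise_sd voxelwise noise sd (pre-windowing units).
#' @return A `phantom_family`.
#' @export
phantom_family <- function(name,
                           base_shape = c("ellipsoid", "lobed_blob", "capsule"),
                           size_range = c(0.25, 0.4),
                           position_jitter = 0.05,
                           centre = c(0.5, 0.5, 0.5),
                           intensity_fg = c(60, 20),
                           intensity_bg = c(-60, 25),
                           texture_noise_sd = 15) {
  base_shape <- match.arg(base_shape)
  if (length(size_range) != 2 || size_range[1] <= 0 || size_range[2] >= 0.95 ||
      size_range[1] > size_range[2]) {
    abort("`size_range` must be an increasing range within (0, 0.95).")
  }
  pooled_sd <- sqrt((intensity_fg[2]^2 + intensity_bg[2]^2) / 2)
  if (abs(intensity_fg[1] - intensity_bg[1]) < 2 * pooled_sd) {
    abort("foreground/background means must differ by >= 2 pooled sd.")
  }
  structure(
    list(name = name, base_shape = base_shape, size_range = size_range,
         position_jitter = position_jitter, centre = centre,
         intensity_fg = intensity_fg, intensity_bg = intensity_bg,
         texture_noise_sd = texture_noise_sd),
    class = "phantom_family"
  )
}

#' The default four-task phantom roster
#'
#' Stand-ins for the four abdominal organ tasks: a large lobed structure
#' ("hepatic"), an elongated capsule ("splenic"), and two small lateralized
#' ellipsoids ("renal_r", "renal_l").
#'
#' @return List of four [phantom_family()] objects.
#' @export
phantom_families_default <- function() {
  list(
    phantom_family("hepatic", "lobed_blob", size_range = c(0.38, 0.52),
                   position_jitter = 0.05, centre = c(0.44, 0.5, 0.5)),
    phantom_family("splenic", "capsule", size_range = c(0.3, 0.42),
                   position_jitter = 0.07, centre = c(0.62, 0.45, 0.5)),
    phantom_family("renal_r", "ellipsoid", size_range = c(0.22, 0.32),
                   position_jitter = 0.07, centre = c(0.36, 0.6, 0.45)),
    phantom_family("renal_l", "ellipsoid", size_range = c(0.22, 0.32),
                   position_jitter = 0.07, centre = c(0.64, 0.6, 0.45))
  )
}

#' Render one phantom image/mask pair
#'
#' Deterministic for a fixed `(family, shape, seed)`: the mask is nonempty
#' and lies strictly inside a 1-voxel boundary ring; the image is the
#' background level plus the foreground offset on the mask plus voxel noise,
#' in raw (pre-windowing) intensity units.
#'
#' @param family a [phantom_family()].
#' @param shape integer length-3 grid size.
#' @param seed integer seed.
#' @param spacing voxel spacing in mm (default 1.5 isotropic).
#' @return `list(image = volume, mask = binary_mask)`.
#' @export
render_phantom <- function(family, shape, seed, spacing = c(1.5, 1.5, 1.5)) {
  stopifnot(inherits(family, "phantom_family"))
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8)) {
    abort("`shape` must be 3 integers >= 8.")
  }
  with_preserved_rng(seed, {
    ext <- min(shape)
    frac <- runif(1, family$size_range[1], family$size_range[2])
    aniso <- runif(3, 0.75, 1.25)
    semi <- pmax(frac * ext / 2 * aniso, 1.6)          # semi-axes in voxels
    lobe_amp <- if (family$base_shape == "lobed_blob") 0.18 else 0
    margin <- 2.2
    reach <- max(semi) * (1 + lobe_amp)
    allowed <- (min(shape) - 1) / 2 - margin
    if (reach > allowed) {
      # shrink to fit the grid; refuse only impossible geometries
      semi <- semi * allowed / reach
      reach <- allowed
      if (max(semi) < 1.6) {
        abort(sprintf("family '%s': structure does not fit a %s grid.",
                      family$name, paste(shape, collapse = "x")))
      }
    }
    ctr <- family$centre * shape +
      runif(3, -1, 1) * family$position_jitter * shape
    ctr <- pmin(pmax(ctr, reach + margin), shape - 1 - reach - margin)

    g <- lapply(1:3, function(ax) seq_len(shape[ax]) - 1)
    ux <- (g[[1]] - ctr[1]) / semi[1]
    uy <- (g[[2]] - ctr[2]) / semi[2]
    uz <- (g[[3]] - ctr[3]) / semi[3]
    UX <- array(rep(ux, times = shape[2] * shape[3]), dim = shape)
    UY <- array(rep(rep(uy, each = shape[1]), times = shape[3]), dim = shape)
    UZ <- array(rep(uz, each = shape[1] * shape[2]), dim = shape)

    mask_arr <- switch(family$base_shape,
      ellipsoid = (UX^2 + UY^2 + UZ^2) <= 1,
      lobed_blob = {
        rho <- sqrt(UX^2 + UY^2 + UZ^2)
        theta <- atan2(UY, UX)
        phase <- runif(1, 0, 2 * pi)
        n_lobes <- sample(2:4, 1)
        bump <- lobe_amp * sin(n_lobes * theta + phase) *
          (1 - UZ^2 / pmax(rho^2, 1e-9))
        rho <= 1 + bump
      },
      capsule = {
        # segment along a jittered long axis, radius = min semi-axis
        axis <- c(1, runif(1, -0.35, 0.35), runif(1, -0.35, 0.35))
        axis <- axis / sqrt(sum(axis^2))
        r <- min(semi) * 0.75
        half_len <- max(semi) - r
        PX <- UX * semi[1]; PY <- UY * semi[2]; PZ <- UZ * semi[3]
        t <- PX * axis[1] + PY * axis[2] + PZ * axis[3]
        tc <- pmin(pmax(t, -half_len), half_len)
        d2 <- (PX - tc * axis[1])^2 + (PY - tc * axis[2])^2 +
          (PZ - tc * axis[3])^2
        d2 <= r^2
      }
    )
    mask_arr <- array(as.numeric(mask_arr), dim = shape)
    if (sum(mask_arr) == 0) abort("rendered mask is empty (geometry too small).")

    bg_level <- rnorm(1, family$intensity_bg[1], family$intensity_bg[2])
    fg_level <- rnorm(1, family$intensity_fg[1], family$intensity_fg[2])
    img <- bg_level + (fg_level - bg_level) * mask_arr +
      rnorm(prod(shape), 0, family$texture_noise_sd)
    list(
      image = volume(array(img, dim = shape), spacing = spacing,
                     meta = list(family = family$name, seed = seed)),
      mask = binary_mask(mask_arr, spacing = spacing,
                         meta = list(family = family$name, seed = seed))
    )
  })
}

#' Generate a phantom segmentation task
#'
#' Renders `n` independent seeded pairs from one family and (by default)
#' applies the standard intensity window so images are training-ready in
#' `[0, 1]`.
#'
#' @param family a [phantom_family()].
#' @param n pool size.
#' @param shape grid size, length 3.
#' @param seed master seed for the pool (each render gets a derived seed).
#' @param window length-2 window endpoints, or `NULL` to keep raw
#'   intensities.
#' @param spacing voxel spacing in mm.
#' @return A [seg_task()].
#' @export
make_task <- function(family, n, shape = c(32, 32, 32), seed = 1L,
                      window = c(-200, 200), spacing = c(1.5, 1.5, 1.5)) {
  if (n < 1) abort("`n` must be >= 1.")
  sub_seeds <- with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L, n))
  pool <- lapply(sub_seeds, function(s) {
    pr <- render_phantom(family, shape, seed = s, spacing = spacing)
    if (!is.null(window)) pr$image <- window_intensity(pr$image, window[1], window[2])
    pr
  })
  seg_task(family$name, pool)
}

#' Corrupt a windowed volume with Gaussian noise
#'
#' The robustness protocol: adds independent voxelwise Gaussian noise with
#' the given mean and standard deviation (on the windowed `[0, 1]` intensity
#' scale) and re-clips to `[0, 1]`. Masks are untouched.
#'
#' @param v a windowed [volume()] (values in `[0, 1]`).
#' @param mean,sd noise moments; defaults mean 0.0, sd 0.2.
#' @param seed optional seed (`NULL` uses the current RNG stream).
#' @return The corrupted [volume()].
#' @export
add_gaussian_noise <- function(v, mean = 0.0, sd = 0.2, seed = NULL) {
  stopifnot(is_volume(v))
  if (sd < 0) abort("`sd` must be >= 0.")
  if (min(v$data) < -1e-9 || max(v$data) > 1 + 1e-9) {
    abort("volume must be windowed to [0, 1] before adding noise.")
  }
  if (sd == 0) return(v)
  draw <- function() rnorm(length(v$data), mean, sd)
  noise <- if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
  v$data <- array(pmin(pmax(v$data + noise, 0), 1), dim = dim(v$data))
  v$meta$noise <- c(mean = mean, sd = sd)
  v
}

#' Build the four-task experiment plan from phantom families
#'
#' Mirrors the published split design on synthetic tasks: three families
#' become meta-training tasks, each with an episode pool (support + query
#' drawn per epoch) and a disjoint evaluation set; the held-out family
#' provides `k` training shots and a disjoint test set.
#'
#' @param families list of exactly 4 [phantom_family()] objects with
#'   distinct names (default [phantom_families_default()]).
#' @param holdout_index which family (1..4) is the meta-test task.
#' @param k meta-test training shots, 5 or 10.
#' @param seed master seed; all pools and splits derive from it.
#' @param shape grid size per volume.
#' @param n_support,n_query,n_eval,n_test per-task split sizes
#'   (default 10/10/10/10 as in the published design).
#' @param window intensity window applied to every image.
#' @return An [experiment_plan()].
#' @export
build_plan <- function(families = phantom_families_default(),
                       holdout_index = 1L, k = 5L, seed = 1L,
                       shape = c(32, 32, 32),
                       n_support = 10L, n_query = 10L, n_eval = 10L,
                       n_test = 10L, window = c(-200, 200)) {
  if (length(families) != 4) abort("exactly 4 phantom families are required.")
  nms <- vapply(families, function(f) f$name, "")
  if (anyDuplicated(nms)) abort("duplicate family names.")
  if (!holdout_index %in% 1:4) abort("`holdout_index` must be in 1..4.")
  if (!k %in% c(5L, 10L)) abort("`k` must be 5 or 10.")
  task_seeds <- with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L, 4))

  pool_train <- n_support + n_query
  meta_train <- list()
  for (i in setdiff(1:4, holdout_index)) {
    task <- make_task(families[[i]], n = pool_train + n_eval, shape = shape,
                      seed = task_seeds[i], window = window)
    meta_train[[length(meta_train) + 1L]] <- list(
      task = task,
      episode_idx = seq_len(pool_train),
      n_support = n_support, n_query = n_query,
      eval_idx = pool_train + seq_len(n_eval)
    )
  }
  ho <- make_task(families[[holdout_index]], n = k + n_test, shape = shape,
                  seed = task_seeds[holdout_index], window = window)
  experiment_plan(
    meta_train = meta_train,
    meta_test = list(task = ho, train_idx = seq_len(k),
                     test_idx = k + seq_len(n_test), k = k)
  )
}
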