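#' Configuration of the enhanced residual 3D U-Net backbone
#'
#' The backbone follows the enhanced-U-Net design: stride-2 convolutions for
#' down-sampling, stride-2 transpose convolutions for up-sampling, residual
#' units (two conv+norm+PReLU blocks plus an identity/projection skip) at
#' every level, one learned PReLU slope per activation layer, affine
#' instance normalization, and dropout. The default configuration (5 levels,
#' channels 16..256 doubling, 2 residual units) yields exactly 4,808,917
#' learnable parameters.
#'
#' @param in_channels input image channels (CT: 1).
#' @param out_channels output classes (background/foreground: 2).
#' @param channels feature channels per level, length >= 2.
#' @param strides down/up-sampling factors, length `length(channels) - 1`.
#' @param num_res_units residual units per level (>= 1).
#' @param dropout dropout probability in `[0, 1)`.
#' @param norm `"instance"` (default) or `"batch"`. With the batch size of 1
#'   used throughout, both normalize each sample's feature maps per channel;
#'   both carry learnable scale and shift.
#' @param kernel_size convolution kernel edge (odd).
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(in_channels = 1L, out_channels = 2L,
                            channels = c(16L, 32L, 64L, 128L, 256L),
                            strides = c(2L, 2L, 2L, 2L),
                            num_res_units = 2L, dropout = 0.1,
                            norm = c("instance", "batch"),
                            kernel_size = 3L) {
  norm <- match.arg(norm)
  channels <- as.integer(channels); strides <- as.integer(strides)
  if (length(channels) < 2) abort("`channels` needs at least 2 levels.")
  if (length(strides) != length(channels) - 1) {
    abort("`strides` must have length(channels) - 1 entries.")
  }
  if (any(channels < 1) || any(strides < 1)) abort("channels and strides must be >= 1.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  if (num_res_units < 1) abort("`num_res_units` must be >= 1.")
  if (kernel_size %% 2 != 1) abort("`kernel_size` must be odd.")
  structure(
    list(in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         channels = channels, strides = strides,
         num_res_units = as.integer(num_res_units),
         dropout = dropout, norm = norm,
         kernel_size = as.integer(kernel_size)),
    class = "backbone_config"
  )
}

# residual unit: `subunits` conv blocks (first carries the stride) with
# norm -> dropout -> PReLU after each conv, plus a projection/identity skip.
# The skip is a strided kernel-k conv when the stride is not 1, a 1x1x1
# projection when only the channel count changes, identity otherwise.
arch_residual_unit <- function(prefix, inc, outc, stride, cfg, subunits,
                               last_conv_only = FALSE) {
  body <- list()
  cin <- inc
  for (su in seq_len(subunits)) {
    s <- if (su == 1) stride else 1L
    p <- sprintf("%s.u%d", prefix, su)
    body <- c(body, list(nn_conv(paste0(p, ".conv"), cin, outc,
                                 k = cfg$kernel_size, stride = s)))
    if (!(last_conv_only && su == subunits)) {
      body <- c(body, list(
        nn_norm(paste0(p, ".norm"), outc, mode = cfg$norm),
        nn_dropout(cfg$dropout),
        nn_prelu(paste0(p, ".act"))
      ))
    }
    cin <- outc
  }
  shortcut <- NULL
  if (stride != 1 || inc != outc) {
    rk <- if (stride != 1) cfg$kernel_size else 1L
    shortcut <- nn_conv(paste0(prefix, ".res"), inc, outc, k = rk, stride = stride)
  }
  nn_residual(nn_seq(body), shortcut)
}

arch_up_layer <- function(prefix, inc, outc, stride, cfg, is_top) {
  up <- list(
    nn_conv(paste0(prefix, ".tconv"), inc, outc, k = cfg$kernel_size,
            stride = stride, transposed = TRUE),
    nn_norm(paste0(prefix, ".norm"), outc, mode = cfg$norm),
    nn_dropout(cfg$dropout),
    nn_prelu(paste0(prefix, ".act"))
  )
  ru <- arch_residual_unit(paste0(prefix, ".ru"), outc, outc, 1L, cfg,
                           subunits = 1L, last_conv_only = is_top)
  nn_seq(c(up, list(ru)))
}

# recursive encoder/decoder assembly: each level is
#   sequence(down residual unit, skip-concat(inner levels), up layer)
# and the innermost level is a stride-1 residual unit ("bottom").
arch_unet <- function(cfg) {
  build <- function(inc, outc, channels, strides, is_top, prefix) {
    c0 <- channels[1]; s <- strides[1]
    if (length(channels) > 2) {
      sub <- build(c0, c0, channels[-1], strides[-1], FALSE, paste0(prefix, ".sub"))
      upc <- 2L * c0
    } else {
      sub <- arch_residual_unit(paste0(prefix, ".bottom"), c0, channels[2], 1L,
                                cfg, cfg$num_res_units)
      upc <- c0 + channels[2]
    }
    down <- arch_residual_unit(paste0(prefix, ".down"), inc, c0, s, cfg,
                               cfg$num_res_units)
    up <- arch_up_layer(paste0(prefix, ".up"), upc, outc, s, cfg, is_top)
    nn_seq(list(down, nn_skipcat(sub), up))
  }
  build(cfg$in_channels, cfg$out_channels, cfg$channels, cfg$strides,
        TRUE, "L1")
}

#' Build a backbone model state
#'
#' Constructs the network graph for a [backbone_config()] and draws a seeded,
#' reproducible random initialization (uniform Kaiming-style for convolutions,
#' unit scale / zero shift for normalizations, 0.25 for PReLU slopes).
#'
#' @param cfg a [backbone_config()].
#' @param rng_seed integer seed; the same seed yields bitwise-identical
#'   initial parameters.
#' @return A `backbone_state`: list with `config`, `arch`, `params`.
#' @export
build_backbone <- function(cfg = backbone_config(), rng_seed = 1L) {
  stopifnot(inherits(cfg, "backbone_config"))
  arch <- arch_unet(cfg)
  params <- with_preserved_rng(rng_seed, nn_init_params(arch))
  structure(list(config = cfg, arch = arch, params = params),
            class = "backbone_state")
}

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Count learnable parameters
#'
#' Sum of element counts of every learnable array: convolution weights and
#' biases, normalization scales and shifts, PReLU slopes.
#'
#' @param state a `backbone_state` (or any list with a `params` field, or a
#'   bare named parameter list).
#' @return Integer count.
#' @export
count_parameters <- function(state) {
  params <- if (!is.null(state$params)) state$params else state
  sum(vapply(params, length, 0L))
}

#' @export
print.backbone_state <- function(x, ...) {
  cat(sprintf(
    "<backbone_state> channels (%s), strides (%s), %d residual unit(s), %s norm, dropout %.2g\n  %s learnable parameters\n",
    paste(x$config$channels, collapse = ","),
    paste(x$config$strides, collapse = ","),
    x$config$num_res_units, x$config$norm, x$config$dropout,
    format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Parametric ReLU
#'
#' \eqn{f(y) = y} for \eqn{y > 0}, \eqn{f(y) = a\,y} otherwise, with one
#' learned slope `a` shared by all channels of a layer.
#'
#' @param y numeric input.
#' @param slope slope coefficient for the non-positive branch.
#' @return Activation values, same shape as `y`.
#' @export
prelu <- function(y, slope) {
  ifelse(y > 0, y, slope * y)
}

as_input_mat <- function(x) {
  # accepts volume, 3D array, or (C,D,H,W) array -> list(mat, sdim)
  if (is_volume(x)) x <- x$data
  d <- dim(x)
  if (length(d) == 3) {
    list(mat = matrix(as.numeric(x), nrow = 1), sdim = as.integer(d))
  } else if (length(d) == 4) {
    list(mat = matrix(as.numeric(aperm(x, c(1, 2, 3, 4))), nrow = d[1]),
         sdim = as.integer(d[2:4]))
  } else {
    abort("input must be a volume, 3D array, or (C,D,H,W) array.")
  }
}

check_divisible <- function(sdim, cfg) {
  tot <- prod(cfg$strides)
  bad <- which(sdim %% tot != 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "spatial extent %d on axis %d is not divisible by the stride product %d",
      sdim[bad[1]], bad[1], tot
    ))
  }
}

#' Forward pass of the backbone
#'
#' @param state a `backbone_state`.
#' @param batch a [volume()], 3D array, `(C,D,H,W)` array, or a list of such
#'   inputs (processed sample by sample; normalization is per sample).
#' @param train_mode logical; enables dropout. Evaluation mode is
#'   deterministic.
#' @return Logits array of dim `c(n, out_channels, D, H, W)`.
#' @export
forward_backbone <- function(state, batch, train_mode = FALSE) {
  stopifnot(inherits(state, "backbone_state"))
  if (!is.list(batch) || is_volume(batch)) batch <- list(batch)
  outs <- lapply(batch, function(b) {
    x <- as_input_mat(b)
    check_divisible(x$sdim, state$config)
    if (nrow(x$mat) != state$config$in_channels) {
      abort(sprintf("expected %d input channel(s), got %d",
                    state$config$in_channels, nrow(x$mat)))
    }
    r <- nn_forward(state$arch, state$params, x, train = train_mode)
    array(r$x$mat, dim = c(state$config$out_channels, r$x$sdim))
  })
  d1 <- dim(outs[[1]])
  out <- array(0, dim = c(length(outs), d1))
  for (i in seq_along(outs)) out[i, , , , ] <- outs[[i]]
  out
}

#' Predict a binary mask for one volume
#'
#' Evaluation-mode forward pass followed by argmax over the two class
#' channels (equivalently, foreground softmax probability > 0.5).
#'
#' @param state a `backbone_state`.
#' @param v a [volume()] (windowed to `[0,1]`).
#' @return A [binary_mask()] with `v`'s geometry.
#' @export
predict_mask <- function(state, v) {
  x <- as_input_mat(v)
  check_divisible(x$sdim, state$config)
  r <- nn_forward(state$arch, state$params, x, train = FALSE)
  fg <- r$x$mat[2, ] > r$x$mat[1, ]
  sp <- if (is_volume(v)) v$spacing else c(1, 1, 1)
  af <- if (is_volume(v)) v$affine else NULL
  binary_mask(array(as.numeric(fg), dim = x$sdim), spacing = sp, affine = af)
}

# foreground softmax probability over a 2 x N logit matrix
softmax_fg <- function(logits) {
  1 / (1 + exp(logits[1, ] - logits[2, ]))
}

# mean soft-Dice loss and parameter gradient over a list of (volume, mask)
# pairs; the network-facing training objective.
backbone_loss_grad <- function(state, params, pairs, train = TRUE,
                               smooth = 1e-5, want_grad = TRUE) {
  stopifnot(length(pairs) > 0)
  grads <- new.env(parent = emptyenv())
  total <- 0
  for (pr in pairs) {
    x <- as_input_mat(pr$image)
    g <- as.numeric(if (is_volume(pr$mask)) pr$mask$data else pr$mask)
    r <- nn_forward(state$arch, params, x, train = train)
    p <- softmax_fg(r$x$mat)
    num <- 2 * sum(p * g) + smooth
    den <- sum(p) + sum(g) + smooth
    total <- total + (1 - num / den)
    if (want_grad) {
      dp <- (num / den^2) - (2 * g / den)
      s <- p * (1 - p) * dp
      dlog <- rbind(-s, s)
      nn_backward(state$arch, params, r$cache, dlog, grads)
    }
  }
  n <- length(pairs)
  loss <- total / n
  if (!want_grad) return(list(loss = loss, grad = NULL))
  grad <- params_zero_like(params)
  for (nm in ls(grads)) grad[[nm]] <- grads[[nm]] / n
  if (!is.finite(loss) || any(!vapply(grad, function(g) all(is.finite(g)), TRUE))) {
    abort("non-finite loss or gradient in backbone training step")
  }
  list(loss = loss, grad = grad)
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the configuration together with the named parameter
#' arrays; loading rebuilds the graph from the embedded configuration.
#'
#' @param state a `backbone_state`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` (save) or a `backbone_state` (load).
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "backbone_state"))
  saveRDS(list(config = unclass(state$config), params = state$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(backbone_config, obj$config[setdiff(names(obj$config), NULL)])
  state <- build_backbone(cfg, rng_seed = 0L)
  if (!identical(sort(names(state$params)), sort(names(obj$params)))) {
    abort("checkpoint is incompatible with its embedded configuration")
  }
  state$params <- obj$params[names(state$params)]
  state
}
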