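# ---------------------------------------------------------------------------
# Minimal volumetric network engine with hand-written backpropagation.
#
# Activations travel as a list(mat, sdim): `mat` is a C x N matrix whose
# columns enumerate the voxels of a (D,H,W) grid in column-major order, so
# matrix(array(c(C,D,H,W)), nrow = C) is a no-copy reinterpretation.
# Parameters live in a flat named list; gradients are accumulated into an
# environment keyed by the same names. Convolutions are im2col + GEMM
# (src/nn_ops.cpp provides the patch gather/scatter).
# ---------------------------------------------------------------------------

nn_conv <- function(name, in_ch, out_ch, k = 3L, stride = 1L,
                    transposed = FALSE) {
  pad <- (k - 1L) %/% 2L
  list(type = "conv", name = name, in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), k = as.integer(k),
       stride = as.integer(stride), pad = pad,
       transposed = isTRUE(transposed),
       outpad = if (transposed) as.integer(stride - 1L) else 0L)
}

nn_norm <- function(name, ch, mode = "instance", eps = 1e-5) {
  list(type = "norm", name = name, ch = as.integer(ch), mode = mode, eps = eps)
}

nn_dropout <- function(p) list(type = "dropout", p = p)

nn_prelu <- function(name) list(type = "prelu", name = name)

nn_seq <- function(...) {
  children <- list(...)
  if (length(children) == 1 && is.null(children[[1]]$type)) children <- children[[1]]
  list(type = "seq", children = children)
}

nn_residual <- function(body, shortcut = NULL) {
  list(type = "residual", body = body, shortcut = shortcut)
}

nn_skipcat <- function(sub) list(type = "skipcat", sub = sub)

# --- initialization ---------------------------------------------------------

# PyTorch-style kaiming-uniform init: weights and biases U(-1/sqrt(fan_in), +).
nn_init_params <- function(node) {
  out <- list()
  walk <- function(nd) {
    switch(nd$type,
      conv = {
        k3 <- nd$k^3
        if (nd$transposed) {
          fan_in <- nd$out_ch * k3
          w <- matrix(runif(nd$in_ch * nd$out_ch * k3, -1, 1) / sqrt(fan_in),
                      nrow = nd$in_ch)
        } else {
          fan_in <- nd$in_ch * k3
          w <- matrix(runif(nd$out_ch * nd$in_ch * k3, -1, 1) / sqrt(fan_in),
                      nrow = nd$out_ch)
        }
        b <- runif(nd$out_ch, -1, 1) / sqrt(fan_in)
        out[[paste0(nd$name, ".W")]] <<- w
        out[[paste0(nd$name, ".b")]] <<- b
      },
      norm = {
        out[[paste0(nd$name, ".g")]] <<- rep(1, nd$ch)
        out[[paste0(nd$name, ".b")]] <<- rep(0, nd$ch)
      },
      prelu = {
        out[[paste0(nd$name, ".a")]] <<- 0.25
      },
      dropout = NULL,
      seq = lapply(nd$children, walk),
      residual = {
        walk(nd$body)
        if (!is.null(nd$shortcut)) walk(nd$shortcut)
      },
      skipcat = walk(nd$sub),
      abort(sprintf("unknown node type '%s'", nd$type))
    )
    invisible(NULL)
  }
  walk(node)
  out
}

# --- forward ----------------------------------------------------------------

conv_out_sdim <- function(nd, sdim) {
  if (nd$transposed) {
    (sdim - 1L) * nd$stride - 2L * nd$pad + nd$k + nd$outpad
  } else {
    os <- (sdim + 2L * nd$pad - nd$k) %/% nd$stride + 1L
    if (any(os < 1)) {
      abort(sprintf("spatial extent %s too small for kernel %d / stride %d",
                    paste(sdim, collapse = "x"), nd$k, nd$stride))
    }
    os
  }
}

nn_forward <- function(node, params, x, train = FALSE) {
  switch(node$type,
    conv = {
      W <- params[[paste0(node$name, ".W")]]
      b <- params[[paste0(node$name, ".b")]]
      if (node$transposed) {
        out_sdim <- conv_out_sdim(node, x$sdim)
        cols <- crossprod(W, x$mat)            # (out*k^3) x N_in
        y <- col2im3(cols, node$out_ch, out_sdim, node$k, node$stride, node$pad)
        y <- y + b
        list(x = list(mat = y, sdim = out_sdim),
             cache = list(xmat = x$mat, in_sdim = x$sdim, out_sdim = out_sdim))
      } else {
        cols <- im2col3(x$mat, x$sdim, node$k, node$stride, node$pad)
        out_sdim <- conv_out_sdim(node, x$sdim)
        y <- W %*% cols + b
        list(x = list(mat = y, sdim = out_sdim),
             cache = list(cols = cols, in_sdim = x$sdim))
      }
    },
    norm = {
      g <- params[[paste0(node$name, ".g")]]
      be <- params[[paste0(node$name, ".b")]]
      mu <- rowMeans(x$mat)
      xc <- x$mat - mu
      v <- rowMeans(xc * xc)
      inv <- 1 / sqrt(v + node$eps)
      xhat <- xc * inv
      list(x = list(mat = g * xhat + be, sdim = x$sdim),
           cache = list(xhat = xhat, inv = inv))
    },
    dropout = {
      if (train && node$p > 0) {
        keep <- matrix(
          (runif(length(x$mat)) >= node$p) / (1 - node$p),
          nrow = nrow(x$mat)
        )
        list(x = list(mat = x$mat * keep, sdim = x$sdim), cache = list(keep = keep))
      } else {
        list(x = x, cache = NULL)
      }
    },
    prelu = {
      a <- params[[paste0(node$name, ".a")]]
      pos <- x$mat > 0
      y <- x$mat * (a + (1 - a) * pos)
      list(x = list(mat = y, sdim = x$sdim), cache = list(xmat = x$mat, pos = pos))
    },
    seq = {
      caches <- vector("list", length(node$children))
      cur <- x
      for (i in seq_along(node$children)) {
        r <- nn_forward(node$children[[i]], params, cur, train)
        cur <- r$x
        caches[[i]] <- r$cache
      }
      list(x = cur, cache = caches)
    },
    residual = {
      rb <- nn_forward(node$body, params, x, train)
      if (is.null(node$shortcut)) {
        y <- rb$x$mat + x$mat
        list(x = list(mat = y, sdim = rb$x$sdim),
             cache = list(body = rb$cache, shortcut = NULL))
      } else {
        rs <- nn_forward(node$shortcut, params, x, train)
        list(x = list(mat = rb$x$mat + rs$x$mat, sdim = rb$x$sdim),
             cache = list(body = rb$cache, shortcut = rs$cache))
      }
    },
    skipcat = {
      rs <- nn_forward(node$sub, params, x, train)
      if (!identical(rs$x$sdim, x$sdim)) {
        abort("skip connection spatial dims mismatch (check stride divisibility)")
      }
      list(x = list(mat = rbind(x$mat, rs$x$mat), sdim = x$sdim),
           cache = list(sub = rs$cache, cx = nrow(x$mat)))
    },
    abort(sprintf("unknown node type '%s'", node$type))
  )
}

# --- backward ---------------------------------------------------------------

acc_grad <- function(grads, name, g) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

nn_backward <- function(node, params, cache, dy, grads) {
  switch(node$type,
    conv = {
      W <- params[[paste0(node$name, ".W")]]
      if (node$transposed) {
        dcols <- im2col3(dy, cache$out_sdim, node$k, node$stride, node$pad)
        acc_grad(grads, paste0(node$name, ".W"), tcrossprod(cache$xmat, dcols))
        acc_grad(grads, paste0(node$name, ".b"), rowSums(dy))
        W %*% dcols
      } else {
        acc_grad(grads, paste0(node$name, ".W"), tcrossprod(dy, cache$cols))
        acc_grad(grads, paste0(node$name, ".b"), rowSums(dy))
        dcols <- crossprod(W, dy)
        col2im3(dcols, node$in_ch, cache$in_sdim, node$k, node$stride, node$pad)
      }
    },
    norm = {
      g <- params[[paste0(node$name, ".g")]]
      xhat <- cache$xhat
      acc_grad(grads, paste0(node$name, ".g"), rowSums(dy * xhat))
      acc_grad(grads, paste0(node$name, ".b"), rowSums(dy))
      dxhat <- g * dy
      n <- ncol(xhat)
      (cache$inv / n) * (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
    },
    dropout = {
      if (is.null(cache)) dy else dy * cache$keep
    },
    prelu = {
      a <- params[[paste0(node$name, ".a")]]
      acc_grad(grads, paste0(node$name, ".a"), sum(dy * cache$xmat * !cache$pos))
      dy * (a + (1 - a) * cache$pos)
    },
    seq = {
      cur <- dy
      for (i in rev(seq_along(node$children))) {
        cur <- nn_backward(node$children[[i]], params, cache[[i]], cur, grads)
      }
      cur
    },
    residual = {
      dbody <- nn_backward(node$body, params, cache$body, dy, grads)
      if (is.null(node$shortcut)) {
        dbody + dy
      } else {
        dbody + nn_backward(node$shortcut, params, cache$shortcut, dy, grads)
      }
    },
    skipcat = {
      cx <- cache$cx
      dx_direct <- dy[seq_len(cx), , drop = FALSE]
      dsub <- dy[(cx + 1):nrow(dy), , drop = FALSE]
      dx_direct + nn_backward(node$sub, params, cache$sub, dsub, grads)
    },
    abort(sprintf("unknown node type '%s'", node$type))
  )
}

# --- flat parameter-vector helpers (finite-difference oracles, optimizers) --

params_flatten <- function(params) {
  unlist(params, use.names = FALSE)
}

params_unflatten <- function(flat, template) {
  out <- template
  i <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    chunk <- flat[i:(i + n - 1L)]
    if (is.matrix(template[[nm]])) {
      out[[nm]] <- matrix(chunk, nrow = nrow(template[[nm]]))
    } else {
      out[[nm]] <- chunk
    }
    i <- i + n
  }
  out
}

params_axpy <- function(x, a, y) {
  # x + a*y elementwise over matching named lists
  mapply(function(xi, yi) xi + a * yi, x, y, SIMPLIFY = FALSE)
}

params_norm <- function(x) sqrt(sum(vapply(x, function(v) sum(v^2), 0)))

params_zero_like <- function(x) lapply(x, function(v) v * 0)
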