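# shared fixtures and independent oracles for the test suite

# a small random blob mask in an n^3 grid (always nonempty)
random_blob_mask <- function(n = 20, seed = NULL) {
  draw <- function() {
    ctr <- runif(3, n * 0.3, n * 0.7)
    r <- runif(3, n * 0.1, n * 0.25)
    g <- seq_len(n) - 1
    ux <- (g - ctr[1]) / r[1]
    uy <- (g - ctr[2]) / r[2]
    uz <- (g - ctr[3]) / r[3]
    UX <- array(rep(ux, times = n * n), dim = c(n, n, n))
    UY <- array(rep(rep(uy, each = n), times = n), dim = c(n, n, n))
    UZ <- array(rep(uz, each = n * n), dim = c(n, n, n))
    m <- array(as.numeric(UX^2 + UY^2 + UZ^2 <= 1), dim = c(n, n, n))
    if (sum(m) == 0) m[ceiling(n / 2), ceiling(n / 2), ceiling(n / 2)] <- 1
    m
  }
  if (is.null(seed)) draw() else metaseg:::with_preserved_rng(seed, draw())
}

# triple-loop boundary extraction: foreground voxel with any background
# 6-neighbour (outside the array counts as background)
oracle_boundary <- function(m) {
  d <- dim(m)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] != 1) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
      if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
      if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0
    )
    if (any(nb == 0)) out <- rbind(out, c(i, j, k) - 1)
  }
  out
}

# exhaustive all-pairs pooled symmetric 95th-percentile surface distance
oracle_hd95 <- function(a, b, spacing, percentile = 95) {
  ba <- oracle_boundary(a)
  bb <- oracle_boundary(b)
  am <- sweep(ba, 2, spacing, `*`)
  bm <- sweep(bb, 2, spacing, `*`)
  dmat <- outer(seq_len(nrow(am)), seq_len(nrow(bm)), Vectorize(function(i, j) {
    sqrt(sum((am[i, ] - bm[j, ])^2))
  }))
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  unname(quantile(pooled, percentile / 100, type = 7))
}

# independent per-layer enumeration of backbone learnable parameters,
# following the architecture rules (not the builder)
oracle_count_params <- function(channels, strides, in_ch = 1, out_ch = 2,
                                units = 2, k = 3) {
  k3 <- k^3
  conv <- function(ci, co, kk = k) co * ci * kk^3 + co
  norm <- function(co) 2 * co
  ru <- function(ci, co, stride, subunits, last_conv_only = FALSE) {
    tot <- 0
    cin <- ci
    for (su in seq_len(subunits)) {
      tot <- tot + conv(cin, co)
      if (!(last_conv_only && su == subunits)) tot <- tot + norm(co) + 1
      cin <- co
    }
    if (stride != 1 || ci != co) {
      tot <- tot + conv(ci, co, if (stride != 1) k else 1)
    }
    tot
  }
  up <- function(ci, co, is_top) {
    conv(ci, co) + norm(co) + 1 + ru(co, co, 1, 1, last_conv_only = is_top)
  }
  total <- 0
  n <- length(channels)
  ins <- c(in_ch, channels[seq_len(n - 2)])
  for (i in seq_len(n - 1)) {
    total <- total + ru(ins[i], channels[i], strides[i], units)
  }
  total <- total + ru(channels[n - 1], channels[n], 1, units)  # bottom
  upcs <- c(if (n > 2) 2 * channels[seq_len(n - 2)], channels[n - 1] + channels[n])
  outs <- c(out_ch, channels[seq_len(n - 2)])
  for (i in seq_len(n - 1)) {
    total <- total + up(upcs[i], outs[i], is_top = (i == 1))
  }
  total
}

# tiny backbone configs used across tests
tiny_backbone <- function(dropout = 0) {
  backbone_config(channels = c(2L, 4L), strides = c(2L),
                  num_res_units = 1L, dropout = dropout)
}

micro_backbone <- function() {
  # 315 learnable parameters; used for finite-difference meta-gradient checks
  backbone_config(channels = c(1L, 1L), strides = c(2L),
                  num_res_units = 1L, dropout = 0)
}

random_pair <- function(n = 4, p = 0.4) {
  list(image = array(runif(n^3), c(n, n, n)),
       mask = array(rbinom(n^3, 1, p), c(n, n, n)))
}

# quadratic toy task family: L_c(theta) = mean((theta - c)^2)
quad_model <- function(theta0) {
  generic_model(
    list(theta = theta0),
    function(params, data) {
      cs <- data$c
      list(loss = mean((params$theta - cs)^2),
           grad = list(theta = mean(2 * (params$theta - cs))))
    }
  )
}

quad_episode <- function(c_val) {
  list(task_name = paste0("c", c_val), support = list(c = c_val),
       query = list(c = c_val))
}

# numeric finite-difference gradient of a scalar function of flat params
fd_gradient <- function(f, flat, h = 1e-5) {
  vapply(seq_along(flat), function(i) {
    p1 <- flat; p1[i] <- p1[i] + h
    p2 <- flat; p2[i] <- p2[i] - h
    (f(p1) - f(p2)) / (2 * h)
  }, 0)
}

# --- cached desk-scale experiment shared by the acceptance tests -----------
# One meta-training run plus five paired fine-tuning seeds (meta-initialized
# vs randomly initialized, same shots, same budget). Cached so the few-shot
# benefit and the noise-robustness checks share the same trained models.

desk_settings <- function() {
  list(
    backbone = backbone_config(channels = c(4L, 8L, 16L), strides = c(2L, 2L),
                               num_res_units = 1L, dropout = 0.1),
    meta = meta_config(inner_lr = 0.05, outer_lr = 5e-3, fine_tune_lr = 2e-3,
                       patience_meta_train = 5L, max_epochs = 30L,
                       patience_fine_tune = 3L, fine_tune_max_epochs = 6L,
                       first_order = TRUE, seed = 101L),
    shape = c(32L, 32L, 32L),
    holdout = 1L,
    k = 5L,
    n_paired_seeds = 5L
  )
}

desk_experiment <- function() {
  cache <- metaseg:::the
  if (!is.null(cache$desk_experiment)) return(cache$desk_experiment)
  st <- desk_settings()
  plan <- build_plan(holdout_index = st$holdout, k = st$k, seed = st$meta$seed,
                     shape = st$shape)
  mt <- meta_train(plan, st$meta, backbone = st$backbone)
  ho <- plan$meta_test$task
  # enlarge the held-out pool so each paired seed draws fresh shots/tests
  ho_big <- make_task(phantom_families_default()[[st$holdout]], n = 15L,
                      shape = st$shape, seed = st$meta$seed + 7L)
  paired <- lapply(seq_len(st$n_paired_seeds), function(sd) {
    split <- metaseg:::with_preserved_rng(1000L + sd,
                                          sample(seq_along(ho_big$pool), 15L))
    shot_idx <- split[1:5]
    test_idx <- split[6:15]
    ft_meta <- fine_tune(mt$state, ho_big, st$k, st$meta,
                         shot_idx = shot_idx, seed = sd)
    rnd <- build_backbone(st$backbone, rng_seed = 5000L + sd)
    ft_rand <- fine_tune(rnd, ho_big, st$k, st$meta,
                         shot_idx = shot_idx, seed = sd)
    test_pairs <- ho_big$pool[test_idx]
    list(
      seed = sd,
      ft_meta = ft_meta,
      test_pairs = test_pairs,
      dsc_meta = glance(final_test(ft_meta$state, test_pairs))$mean_dsc,
      dsc_rand = glance(final_test(ft_rand$state, test_pairs))$mean_dsc
    )
  })
  cache$desk_experiment <- list(plan = plan, mt = mt, paired = paired,
                                settings = st)
  cache$desk_experiment
}
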