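make_toy_task <- function(n = 8, seed = 1, shape = c(12L, 12L, 12L)) {
  make_task(phantom_families_default()[[3]], n = n, shape = shape, seed = seed)
}

test_that("episodes partition the pool, disjointly and reproducibly", {
  tk <- make_toy_task(n = 20, seed = 4, shape = c(12L, 12L, 12L))
  ep <- sample_episode(tk, 10, 10, seed = 3)
  expect_length(intersect(ep$support_idx, ep$query_idx), 0)
  expect_setequal(c(ep$support_idx, ep$query_idx), 1:20)
  ep2 <- sample_episode(tk, 10, 10, seed = 3)
  expect_identical(ep$support_idx, ep2$support_idx)
  expect_identical(ep$query_idx, ep2$query_idx)
  expect_error(sample_episode(tk, 15, 10, seed = 1), "smaller")
})

test_that("episode sampling is uniform over the pool", {
  tk <- make_toy_task(n = 4, seed = 5)
  set.seed(11)
  n_draw <- 10000
  counts <- integer(4)
  for (i in seq_len(n_draw)) {
    ep <- sample_episode(tk, 1, 1)
    counts[ep$support_idx] <- counts[ep$support_idx] + 1L
  }
  # binomial sampling: each item lands in the support slot w.p. 1/4
  se <- sqrt(0.25 * 0.75 / n_draw)
  expect_true(all(abs(counts / n_draw - 0.25) < 3 * se))
})

test_that("the inner step reproduces gradient descent analytically", {
  # L(theta) = theta^2, theta = 1, alpha = 0.1, 1 step -> 0.8
  m <- quad_model(1)
  ad <- inner_adapt(m, list(c = 0), meta_config(inner_lr = 0.1))
  expect_equal(ad$params$theta, 0.8)
  expect_equal(m$params$theta, 1)  # theta untouched (pure function)

  # stationary point: zero gradient leaves theta unchanged
  m0 <- quad_model(0.5)
  ad0 <- inner_adapt(m0, list(c = 0.5), meta_config(inner_lr = 0.1))
  expect_equal(ad0$params$theta, 0.5)

  # two steps compose
  ad2 <- inner_adapt(quad_model(1), list(c = 0),
                     meta_config(inner_lr = 0.1, inner_steps = 2))
  expect_equal(ad2$params$theta, 0.8 * 0.8)
})

test_that("outer objective is additive and reduces to plain loss at alpha 0", {
  cfg <- meta_config(inner_lr = 0.25)
  ep <- quad_episode(1)
  expect_equal(outer_objective(quad_model(0), list(ep, ep), cfg),
               2 * outer_objective(quad_model(0), list(ep), cfg))
  cfg0 <- meta_config(inner_lr = 0)
  expect_equal(outer_objective(quad_model(0.3), list(quad_episode(1)), cfg0),
               (0.3 - 1)^2)
})

test_that("meta-gradient matches the quadratic closed form", {
  # tasks c = +1, -1: theta_i' = theta - 2 alpha (theta - c_i),
  # meta-gradient = sum 2 (theta_i' - c_i)(1 - 2 alpha)
  a <- 0.25
  cfg <- meta_config(inner_lr = a)
  eps <- list(quad_episode(1), quad_episode(-1))
  for (th in c(0, 0.3, -0.7)) {
    mg <- meta_gradient(quad_model(th), eps, cfg)
    tp <- function(cc) th - 2 * a * (th - cc)
    closed <- sum(vapply(c(1, -1), function(cc) 2 * (tp(cc) - cc) * (1 - 2 * a), 0))
    expect_equal(mg$grad$theta, closed, tolerance = 1e-6)
  }
  # symmetric tasks at theta = 0: gradients cancel exactly
  expect_equal(meta_gradient(quad_model(0), eps, cfg)$grad$theta, 0,
               tolerance = 1e-10)
})

test_that("second-order meta-gradient matches finite differences on a network", {
  st <- build_backbone(micro_backbone(), rng_seed = 5)
  expect_lte(count_parameters(st), 500)
  set.seed(11)
  episodes <- lapply(1:2, function(i) {
    list(task_name = paste0("t", i),
         support = list(random_pair(4), random_pair(4)),
         query = list(random_pair(4), random_pair(4)))
  })
  cfg <- meta_config(inner_lr = 0.05, inner_steps = 2, first_order = FALSE)
  mg <- meta_gradient(st, episodes, cfg)
  flat <- metaseg:::params_flatten(st$params)
  g <- metaseg:::params_flatten(mg$grad[names(st$params)])
  fd <- fd_gradient(function(p) {
    outer_objective(metaseg:::set_params(st, metaseg:::params_unflatten(p, st$params)),
                    episodes, cfg)
  }, flat)
  expect_lt(sqrt(sum((fd - g)^2)) / sqrt(sum(fd^2)), 1e-3)
})

test_that("first-order and second-order gradients differ but correlate", {
  st <- build_backbone(micro_backbone(), rng_seed = 8)
  set.seed(21)
  episodes <- list(list(task_name = "t", support = list(random_pair(4)),
                        query = list(random_pair(4))))
  g2 <- meta_gradient(st, episodes, meta_config(inner_lr = 0.2))$grad
  g1 <- meta_gradient(st, episodes,
                      meta_config(inner_lr = 0.2, first_order = TRUE))$grad
  f1 <- metaseg:::params_flatten(g1)
  f2 <- metaseg:::params_flatten(g2)
  expect_false(isTRUE(all.equal(f1, f2)))
  expect_gt(cor(f1, f2), 0.9)
})

test_that("meta_train at alpha = 0 equals joint training on the query sets", {
  st <- build_backbone(micro_backbone(), rng_seed = 3)
  set.seed(5)
  episodes <- lapply(1:2, function(i) {
    list(task_name = paste0("t", i), support = list(random_pair(4)),
         query = list(random_pair(4)))
  })
  cfg0 <- meta_config(inner_lr = 0)
  mg <- meta_gradient(st, episodes, cfg0)
  pooled <- lapply(episodes, function(e) {
    metaseg:::backbone_loss_grad(st, st$params, e$query, train = TRUE)$grad
  })
  joint <- metaseg:::params_axpy(pooled[[1]], 1, pooled[[2]])
  expect_equal(metaseg:::params_flatten(mg$grad[names(st$params)]),
               metaseg:::params_flatten(joint[names(st$params)]),
               tolerance = 1e-10)
})

test_that("a zero meta-gradient leaves parameters unchanged without decay", {
  m <- quad_model(0)
  cfg <- meta_config(inner_lr = 0.25, outer_lr = 0.1, weight_decay = 0)
  eps <- list(quad_episode(1), quad_episode(-1))
  st <- meta_step(m, eps, cfg)
  expect_equal(st$state$params$theta, 0, tolerance = 1e-12)
})

test_that("meta-training early-stops exactly `patience` epochs after the best", {
  fams <- phantom_families_default()
  mk <- function(i) make_task(fams[[i]], n = 6, shape = c(12L, 12L, 12L), seed = i)
  plan <- experiment_plan(
    meta_train = lapply(1:3, function(i) {
      list(task = mk(i), episode_idx = 1:4, n_support = 2L, n_query = 2L,
           eval_idx = 5:6)
    }),
    meta_test = list(task = mk(4), train_idx = 1:2, test_idx = 3:4)
  )
  # an outer rate of ~0 freezes theta, so the eval DSC never improves after
  # epoch 1 and training must stop at epoch 1 + patience
  cfg <- meta_config(inner_lr = 0.01, outer_lr = 1e-12, first_order = TRUE,
                     patience_meta_train = 2L, max_epochs = 50L, seed = 9)
  res <- meta_train(plan, cfg, backbone = tiny_backbone())
  expect_identical(res$stopped_epoch, res$best_epoch + 2L)
  expect_lte(res$stopped_epoch - res$best_epoch, cfg$patience_meta_train)

  # fixed seed: bitwise-identical history across reruns
  res2 <- meta_train(plan, cfg, backbone = tiny_backbone())
  expect_identical(res$history, res2$history)
  expect_identical(res$state$params, res2$state$params)
})

test_that("fine-tuning never returns a worse checkpoint than its start", {
  tk <- make_toy_task(n = 6, seed = 13)
  st <- build_backbone(tiny_backbone(), rng_seed = 2)
  cfg <- meta_config(fine_tune_lr = 1e-3, patience_fine_tune = 1L,
                     fine_tune_max_epochs = 30L, seed = 3)
  ft <- fine_tune(st, tk, 2, cfg, shot_idx = 1:2)
  base <- metaseg:::backbone_loss_grad(st, st$params, tk$pool[1:2],
                                       train = FALSE, want_grad = FALSE)$loss
  expect_lte(ft$best_loss, base)
  # patience 1: stops one epoch after the best
  last_epoch <- max(ft$history$epoch)
  expect_lte(last_epoch - ft$best_epoch, 1)
})

test_that("final_test scores a perfect and a constant predictor correctly", {
  tk <- make_toy_task(n = 3, seed = 17)
  pairs <- tk$pool
  # perfect predictor: feed the ground truth masks straight through
  perfect <- lapply(pairs, function(p) p$mask)
  rep <- evaluate_masks(perfect, lapply(pairs, `[[`, "mask"))
  expect_equal(unname(rep$means["dsc"]), 1.0)
  expect_equal(unname(rep$means["hd95"]), 0.0)
  # constant-background predictor: DSC 0, HD95 undefined everywhere
  empty <- lapply(pairs, function(p) {
    binary_mask(array(0, dim(p$mask$data)), p$mask$spacing)
  })
  rep0 <- evaluate_masks(empty, lapply(pairs, `[[`, "mask"))
  expect_equal(unname(rep0$means["dsc"]), 0.0)
  expect_true(is.na(rep0$means["hd95"]))
  expect_equal(rep0$n_hd95_excluded, 3L)
  # means equal hand-averaged per-case values
  expect_equal(unname(rep$means["iou"]), mean(tidy(rep)$iou))
})

test_that("experiment plans reject overlapping or inconsistent splits", {
  tk1 <- make_toy_task(n = 6, seed = 1)
  tk2 <- make_toy_task(n = 6, seed = 2)
  tk2$name <- "other_task"
  mt <- list(list(task = tk1, episode_idx = 1:4, n_support = 2L,
                  n_query = 2L, eval_idx = 5:6))
  expect_error(
    experiment_plan(mt, list(task = tk1, train_idx = 1:2, test_idx = 3:4)),
    "must not appear"
  )
  expect_error(
    experiment_plan(mt, list(task = tk2, train_idx = 1:2, test_idx = 2:4)),
    "overlap"
  )
  bad <- list(list(task = tk1, episode_idx = 1:3, n_support = 2L,
                   n_query = 2L, eval_idx = 5:6))
  expect_error(
    experiment_plan(bad, list(task = tk2, train_idx = 1:2, test_idx = 3:4)),
    "smaller"
  )
})
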