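test_that("rendered phantoms satisfy the volume/mask contracts", {
  fams <- phantom_families_default()
  for (fam in fams) {
    pr <- render_phantom(fam, c(24, 24, 24), seed = 31)
    m <- pr$mask$data
    expect_gt(sum(m), 0)
    # strictly inside a 1-voxel boundary ring
    expect_true(all(m[1, , ] == 0) && all(m[24, , ] == 0))
    expect_true(all(m[, 1, ] == 0) && all(m[, 24, ] == 0))
    expect_true(all(m[, , 1] == 0) && all(m[, , 24] == 0))
    expect_true(all(m %in% c(0, 1)))
    expect_identical(dim(pr$image$data), dim(m))
    expect_equal(pr$image$spacing, pr$mask$spacing)
  }
})

test_that("rendering is bitwise reproducible per seed", {
  fam <- phantom_families_default()[[2]]
  a <- render_phantom(fam, c(20, 20, 20), seed = 77)
  b <- render_phantom(fam, c(20, 20, 20), seed = 77)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  c <- render_phantom(fam, c(20, 20, 20), seed = 78)
  expect_false(identical(a$mask$data, c$mask$data))
})

test_that("foreground/background contrast matches the family specification", {
  fam <- phantom_family("probe", "ellipsoid", size_range = c(0.3, 0.4),
                        intensity_fg = c(60, 20), intensity_bg = c(-60, 25),
                        texture_noise_sd = 15)
  diffs <- vapply(1:40, function(s) {
    pr <- render_phantom(fam, c(20, 20, 20), seed = s)
    m <- pr$mask$data == 1
    mean(pr$image$data[m]) - mean(pr$image$data[!m])
  }, 0)
  # contrast estimator: mean difference of per-render level draws,
  # sd ~ sqrt(20^2 + 25^2) per render
  se <- sqrt((20^2 + 25^2) / length(diffs))
  expect_lt(abs(mean(diffs) - 120), 3 * se)
})

test_that("tasks assemble windowed, distinct pools of the requested size", {
  fam <- phantom_families_default()[[3]]
  tk <- make_task(fam, n = 8, shape = c(16, 16, 16), seed = 5)
  expect_s3_class(tk, "seg_task")
  expect_length(tk$pool, 8)
  vols <- vapply(tk$pool, function(p) sum(p$mask$data), 0)
  expect_gt(length(unique(vols)), 1)  # inter-subject variability
  for (p in tk$pool) {
    expect_gte(min(p$image$data), 0)
    expect_lte(max(p$image$data), 1)
  }
  # same seed -> identical task; families with different size ranges differ
  tk2 <- make_task(fam, n = 8, shape = c(16, 16, 16), seed = 5)
  expect_identical(tk$pool[[1]]$image$data, tk2$pool[[1]]$image$data)
  big <- phantom_family("big", "ellipsoid", size_range = c(0.5, 0.6))
  small <- phantom_family("small", "ellipsoid", size_range = c(0.2, 0.3))
  vb <- mean(vapply(make_task(big, 6, c(20, 20, 20), seed = 1)$pool,
                    function(p) sum(p$mask$data), 0))
  vs <- mean(vapply(make_task(small, 6, c(20, 20, 20), seed = 1)$pool,
                    function(p) sum(p$mask$data), 0))
  expect_gt(vb, vs)
})

test_that("gaussian corruption has the stated moments and determinism", {
  v <- window_intensity(volume(array(0, c(24, 24, 24))), -200, 200)  # all 0.5
  expect_identical(add_gaussian_noise(v, sd = 0)$data, v$data)
  n1 <- add_gaussian_noise(v, mean = 0, sd = 0.2, seed = 3)
  n2 <- add_gaussian_noise(v, mean = 0, sd = 0.2, seed = 3)
  expect_identical(n1$data, n2$data)
  # all values start at 0.5; ~1% of draws clip at the [0,1] rails, which
  # shaves a little off the observed sd, hence the 0.01 slack
  delta <- n1$data - v$data
  n <- length(delta)
  expect_lt(abs(mean(delta) - 0), 3 * 0.2 / sqrt(n) + 0.002)
  expect_lt(abs(sd(delta) - 0.2), 0.01)
  expect_gte(min(n1$data), 0)
  expect_lte(max(n1$data), 1)
  expect_error(add_gaussian_noise(v, sd = -1), ">= 0")
  raw <- volume(array(100, c(8, 8, 8)))
  expect_error(add_gaussian_noise(raw), "windowed")
})

test_that("plans mirror the published split design", {
  shape <- c(16, 16, 16)
  plan <- build_plan(holdout_index = 2, k = 5, seed = 3, shape = shape,
                     n_support = 3, n_query = 3, n_eval = 2, n_test = 4)
  expect_s3_class(plan, "experiment_plan")
  nms <- vapply(plan$meta_train, function(mt) mt$task$name, "")
  expect_length(nms, 3)
  expect_false("splenic" %in% nms)  # holdout absent from meta-training
  expect_identical(plan$meta_test$task$name, "splenic")
  expect_length(plan$meta_test$train_idx, 5)
  expect_length(plan$meta_test$test_idx, 4)
  expect_length(intersect(plan$meta_test$train_idx, plan$meta_test$test_idx), 0)

  # k = 5 vs k = 10 differ only in the shot count
  p10 <- build_plan(holdout_index = 2, k = 10, seed = 3, shape = shape,
                    n_support = 3, n_query = 3, n_eval = 2, n_test = 4)
  expect_length(p10$meta_test$train_idx, 10)
  expect_identical(
    vapply(p10$meta_train, function(mt) mt$task$name, ""), nms
  )

  # four holdout rotations reproduce the four-experiment design
  held <- vapply(1:4, function(h) {
    build_plan(holdout_index = h, k = 5, seed = 3, shape = shape,
               n_support = 2, n_query = 2, n_eval = 2,
               n_test = 2)$meta_test$task$name
  }, "")
  expect_setequal(held, vapply(phantom_families_default(),
                               function(f) f$name, ""))
  expect_error(build_plan(holdout_index = 5), "holdout")
  expect_error(build_plan(k = 7), "5 or 10")
})
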