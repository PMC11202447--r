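test_that("the default backbone reproduces the published parameter count", {
  st <- build_backbone(backbone_config(), rng_seed = 1)
  expect_identical(count_parameters(st), 4808917L)
})

test_that("parameter counts match an independent per-layer enumeration", {
  cases <- list(
    list(channels = c(4L, 8L), strides = 2L, units = 1L),
    list(channels = c(2L, 4L), strides = 2L, units = 1L),
    list(channels = c(4L, 8L, 16L), strides = c(2L, 2L), units = 2L),
    list(channels = c(16L, 32L, 64L, 128L, 256L), strides = c(2L, 2L, 2L, 2L),
         units = 2L)
  )
  for (cs in cases) {
    st <- build_backbone(
      backbone_config(channels = cs$channels, strides = cs$strides,
                      num_res_units = cs$units),
      rng_seed = 1
    )
    expect_identical(count_parameters(st),
                     as.integer(oracle_count_params(cs$channels, cs$strides,
                                                    units = cs$units)))
  }
  # frozen value for the smallest case, enumerated by hand:
  # down RU(1->4,s2): 112+1+8+112; bottom RU(4->8): 872+1+16+40;
  # up tconv(12->2): 650+4+1; top RU(2->2, conv only): 110  => 1927
  st <- build_backbone(backbone_config(channels = c(4L, 8L), strides = 2L,
                                       num_res_units = 1L), 1)
  expect_identical(count_parameters(st), 1927L)
})

test_that("initialization is seeded and the count is seed-invariant", {
  cfg <- tiny_backbone()
  a <- build_backbone(cfg, rng_seed = 11)
  b <- build_backbone(cfg, rng_seed = 11)
  c <- build_backbone(cfg, rng_seed = 12)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
  expect_identical(count_parameters(a), count_parameters(c))
})

test_that("PReLU follows its two branches and is continuous at zero", {
  expect_equal(prelu(3, 0.9), 3)
  expect_equal(prelu(-2, 0.25), -0.5)
  expect_equal(prelu(0, 0.7), 0)
  expect_equal(prelu(c(-1, 1), 1), c(-1, 1))  # slope 1 is the identity
  eps <- 1e-12
  expect_lt(abs(prelu(eps, 0.3) - prelu(-eps, 0.3)), 1e-11)
})

test_that("forward pass obeys the shape contract and eval determinism", {
  st <- build_backbone(tiny_backbone(dropout = 0.1), rng_seed = 2)
  x <- array(rnorm(8^3), c(8, 8, 8))
  out <- forward_backbone(st, x)
  expect_identical(dim(out), c(1L, 2L, 8L, 8L, 8L))
  expect_identical(out, forward_backbone(st, x))  # eval mode: deterministic
  # train mode engages dropout and differs across calls
  set.seed(1)
  t1 <- forward_backbone(st, x, train_mode = TRUE)
  t2 <- forward_backbone(st, x, train_mode = TRUE)
  expect_false(identical(t1, t2))
  expect_error(forward_backbone(st, array(0, c(7, 8, 8))), "axis 1")
})

test_that("equal parameters give identical outputs; states are pure values", {
  cfg <- tiny_backbone()
  a <- build_backbone(cfg, rng_seed = 5)
  b <- build_backbone(cfg, rng_seed = 99)
  b$params <- a$params
  x <- array(runif(8^3), c(8, 8, 8))
  expect_identical(forward_backbone(a, x), forward_backbone(b, x))
})

test_that("the analytic gradient matches central finite differences", {
  st <- build_backbone(tiny_backbone(), rng_seed = 7)
  set.seed(3)
  pr <- random_pair(4)
  lg <- metaseg:::backbone_loss_grad(st, st$params, list(pr), train = FALSE)
  flat <- metaseg:::params_flatten(st$params)
  gflat <- metaseg:::params_flatten(lg$grad[names(st$params)])
  idx <- sort(sample(length(flat), 50))
  f <- function(p) {
    metaseg:::backbone_loss_grad(
      st, metaseg:::params_unflatten(p, st$params), list(pr),
      train = FALSE, want_grad = FALSE
    )$loss
  }
  fd <- vapply(idx, function(i) {
    p1 <- flat; p1[i] <- p1[i] + 1e-5
    p2 <- flat; p2[i] <- p2[i] - 1e-5
    (f(p1) - f(p2)) / 2e-5
  }, 0)
  expect_equal(gflat[idx], fd, tolerance = 1e-6)
})

test_that("constant inputs produce stride-periodic constant interiors", {
  # translation consistency: strided down/up-sampling makes the network
  # equivariant to shifts on the stride lattice, so a constant field maps,
  # away from padding effects, to logits that are constant within each
  # period-2 phase of the interior
  st <- build_backbone(tiny_backbone(), rng_seed = 4)
  out <- forward_backbone(st, array(0.5, c(32, 32, 32)))
  for (ch in 1:2) {
    for (pd in 0:1) for (ph in 0:1) for (pw in 0:1) {
      vals <- out[1, ch, seq(12 + pd, 20 + pd, 2), seq(12 + ph, 20 + ph, 2),
                  seq(12 + pw, 20 + pw, 2)]
      expect_lt(max(vals) - min(vals), 1e-10)
    }
  }
})

test_that("prediction binarizes by argmax and keeps geometry", {
  st <- build_backbone(tiny_backbone(), rng_seed = 6)
  v <- volume(array(runif(8^3), c(8, 8, 8)), spacing = c(1.5, 1.5, 1.5))
  m <- predict_mask(st, v)
  expect_s3_class(m, "binary_mask")
  expect_equal(m$spacing, v$spacing)
  pr <- forward_backbone(st, v)
  fg <- as.numeric(pr[1, 2, , , ] > pr[1, 1, , , ])
  expect_equal(as.numeric(m$data), fg)
})

test_that("checkpoints round-trip parameters and configuration", {
  st <- build_backbone(tiny_backbone(dropout = 0.05), rng_seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  re <- load_checkpoint(path)
  expect_identical(re$params, st$params)
  expect_equal(unclass(re$config), unclass(st$config))
  x <- array(runif(8^3), c(8, 8, 8))
  expect_identical(forward_backbone(re, x), forward_backbone(st, x))
})

test_that("configuration invariants are enforced", {
  expect_error(backbone_config(channels = c(8, 16), strides = c(2, 2)),
               "length")
  expect_error(backbone_config(dropout = 1), "dropout")
  expect_error(backbone_config(channels = 16L), "levels")
})
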