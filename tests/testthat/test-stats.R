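test_that("the statistic reproduces the negative-correlation worked example", {
  res <- hotelling_williams_t(-0.6, 0, 0, 100)
  expect_equal(res$t, -5.0, tolerance = 0.011)  # one printed decimal
  expect_equal(res$df, 97)
  expect_true(res$valid)
  expect_lt(p_from_t(res$t, res$df)$p, 0.001)
})

test_that("the statistic agrees with an independent transcription", {
  # value pinned from the straight transcription before the main build
  expect_equal(hotelling_williams_t(0.5, 0.3, 0.2, 50)$t,
               1.252284753373, tolerance = 1e-10)
  set.seed(7)
  n_cases <- 2000
  checked <- 0
  while (checked < n_cases) {
    r <- runif(3, -0.9, 0.9)
    det_R <- 1 - sum(r^2) + 2 * prod(r)
    if (det_R <= 0) next  # only PSD triples are comparable
    ess <- runif(1, 10, 500)
    mine <- hotelling_williams_t(r[1], r[2], r[3], ess)
    if (!mine$valid) next
    oracle <- williams_oracle(r[1], r[2], r[3], ess)
    expect_equal(mine$t, oracle, tolerance = 1e-10)
    checked <- checked + 1
  }
})

test_that("t is zero iff the correlations are equal, signed by their order", {
  expect_equal(hotelling_williams_t(0.4, 0.4, 0.1, 80)$t, 0)
  expect_gt(hotelling_williams_t(0.5, 0.2, 0.1, 80)$t, 0)
  expect_lt(hotelling_williams_t(0.2, 0.5, 0.1, 80)$t, 0)
})

test_that("swapping the references negates t and fixes df and p", {
  set.seed(8)
  for (i in 1:50) {
    r <- runif(3, 0, 0.7)
    ess <- runif(1, 20, 200)
    a <- hotelling_williams_t(r[1], r[2], r[3], ess)
    b <- hotelling_williams_t(r[2], r[1], r[3], ess)
    if (!a$valid) next
    expect_equal(a$t, -b$t, tolerance = 1e-12)
    expect_equal(a$df, b$df)
    expect_equal(p_from_t(a$t, a$df)$p, p_from_t(b$t, b$df)$p,
                 tolerance = 1e-12)
  }
})

test_that("t increases monotonically in r_sr over the PSD region", {
  grid <- seq(-0.5, 0.9, by = 0.02)
  for (rsb in c(0, 0.3)) for (rrb in c(0, 0.4)) {
    tt <- hotelling_williams_t(grid, rsb, rrb, 100)
    keep <- tt$valid
    expect_true(all(diff(tt$t[keep]) > 0))
  }
})

test_that("non-PSD triples are routed through the configured policy", {
  # |R| = 1 - 0.81 - 0.81 < 0: inconsistent after clipping
  bad <- hotelling_williams_t(0.9, 0.9, 0, 50)
  expect_false(bad$valid)
  expect_lt(bad$det_R, 0)
  # clipped (1.0, 0.0, 0.0) stays computable
  ok <- hotelling_williams_t(1.0, 0.0, 0.0, 50)
  expect_true(ok$valid)

  triple <- data.frame(r_sr = c(0.9, 0.2), r_sb = c(0.9, 0.1),
                       r_rb = c(0, 0.3),
                       raw_sr = c(0.9, 0.2), raw_sb = c(0.9, 0.1),
                       raw_rb = c(0.75, 0.3), invalid = FALSE)
  inv <- handle_non_psd(triple, c(50, 50), policy = "invalidate")
  expect_false(inv$valid[1]); expect_true(inv$valid[2])
  expect_equal(inv$n_non_psd, 1)

  raw <- handle_non_psd(triple, c(50, 50), policy = "raw_correlations")
  expect_true(raw$valid[1])
  expect_equal(raw$method, c("williams_raw", "williams"))
  expect_equal(raw$t[1],
               hotelling_williams_t(0.9, 0.9, 0.75, 50)$t)
  # the policy only touches the flagged voxel
  expect_equal(raw$t[2], inv$t[2])

  fz <- handle_non_psd(triple, c(50, 50), policy = "fisher_z")
  expect_true(fz$valid[1])
  expect_equal(fz$method[1], "fisher_z")
  expect_equal(fz$t[2], inv$t[2])
  # Fisher fallback for equal correlations is exactly null
  expect_equal(fz$t[1], 0, tolerance = 1e-12)
})

test_that("p values match quadrature of the t density", {
  cases <- expand.grid(t = c(0.5, 2.1, 5.0), df = c(12.5, 97, 400))
  for (i in seq_len(nrow(cases))) {
    t <- cases$t[i]; df <- cases$df[i]
    quad <- 2 * integrate(function(x) dt(x, df), t, Inf,
                          rel.tol = 1e-12)$value
    expect_equal(p_from_t(t, df)$p, quad, tolerance = 1e-6)
    expect_equal(p_from_t(-t, df)$p, quad, tolerance = 1e-6)
  }
  expect_equal(p_from_t(0, 50)$p, 1)
  expect_false(p_from_t(1, -2)$valid)
  expect_equal(p_from_t(2, 97, sided = "greater")$p,
               p_from_t(2, 97)$p / 2, tolerance = 1e-12)
})

test_that("BH correction matches a by-hand step-up computation", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.368)
  expected_q <- c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.105714,
                  0.235556, 0.235556, 0.368)
  fdr <- fdr_correct(p, q_threshold = 0.05)
  expect_equal(fdr$q, expected_q, tolerance = 1e-5)
  expect_equal(sum(fdr$survives), 2)
  expect_equal(fdr$m, 10)

  # all p = 1: nothing survives; single small p survives with q = p
  expect_false(any(fdr_correct(rep(1, 20))$survives))
  single <- fdr_correct(0.01)
  expect_true(single$survives)
  expect_equal(single$q, 0.01)

  # invalid voxels do not enter m
  with_na <- fdr_correct(c(p, NA, NA))
  expect_equal(with_na$m, 10)
  expect_equal(with_na$q[1:10], fdr$q)
})

test_that("voxel classification follows the r/t thresholds", {
  triple <- data.frame(r_sr = c(0.02, 0.5, 0.6, 0.05, 0.5),
                       r_sb = c(0.03, 0.52, 0.05, 0.6, 0.48))
  result <- list(t = c(0.1, 0.4, 6, -6, 0.3),
                 p = c(0.9, 0.7, 1e-6, 1e-6, 0.8),
                 q = c(0.9, 0.8, 1e-4, 1e-4, 0.9),
                 valid = rep(TRUE, 5))
  cls <- classify_voxels(triple, result)
  expect_equal(cls, c("non_responsive", "non_selective", "red_selective",
                      "blue_selective", "non_selective"))
  result$valid[2] <- FALSE
  expect_true(is.na(classify_voxels(triple, result)[2]))
})

test_that("group-level propagation recovers a common effect", {
  expect_error(group_level(list(1:5)), "at least 2")
  expect_error(group_level(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "aligned")

  # identical maps: group sign matches the common map everywhere
  common <- c(-3, -1, 0.5, 2, 4)
  maps <- list(common + 1e-9, common - 1e-9, common)
  g <- group_level(maps)
  expect_equal(sign(g$t), sign(common))

  # common effect + between-subject noise: effect voxels recovered
  set.seed(9)
  effect <- c(rep(3, 20), rep(0, 80))
  subj <- lapply(1:12, function(i) effect + rnorm(100, sd = 1))
  g2 <- group_level(subj)
  expect_gt(mean(g2$survives[1:20]), 0.9)
  expect_lt(mean(g2$survives[21:100]), 0.1)
})
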