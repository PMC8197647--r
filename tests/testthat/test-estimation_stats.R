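test_that("degenerate inputs give collapsed intervals and flagged p", {
  r <- meanDifference(c(1, 2, 3), c(1, 2, 3), design = "paired", seed = 1)
  expect_equal(effectSize(r), 0)
  expect_equal(confInt(r), c(0, 0))
  expect_true("degenerate" %in% r@flags)
  expect_true(is.na(permP(r)))
  # one-sample vs 0.5 with all values equal: effect 0.4, CI degenerate
  r2 <- meanDifference(rep(0.9, 6), null_value = 0.5, design = "one_sample",
                       seed = 1)
  expect_equal(effectSize(r2), 0.4)
  expect_equal(confInt(r2), c(0.4, 0.4))
})

test_that("resampling is seed-deterministic", {
  x <- rnorm(8, 1); y <- rnorm(8)
  a <- meanDifference(x, y, design = "unpaired", n_boot = 500, n_perm = 500,
                      seed = 42)
  b <- meanDifference(x, y, design = "unpaired", n_boot = 500, n_perm = 500,
                      seed = 42)
  expect_identical(confInt(a), confInt(b))
  expect_identical(permP(a), permP(b))
  c_ <- meanDifference(x, y, design = "unpaired", n_boot = 500, n_perm = 500,
                       seed = 43)
  expect_false(identical(confInt(a), confInt(c_)))
})

test_that("paired n=3 resampling matches exhaustive enumeration", {
  d <- c(1, 2, 3)
  # exhaustive permutation null: all 2^3 sign patterns
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  t_stat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  t_obs <- t_stat(d)
  t_all <- apply(signs, 1, function(s) t_stat(s * d))
  p_exact <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
  # exhaustive bootstrap: all 3^3 resamples of the differences
  idx <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  boot_all <- apply(idx, 1, function(i) mean(d[i]))
  r <- meanDifference(d + 5, rep(5, 3), design = "paired",
                      n_boot = 5000, n_perm = 5000, seed = 7)
  # Monte-Carlo permutation p vs enumeration, within 3 binomial SE
  # (both estimators use the (count+1)/(n+1) correction scale)
  se_p <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(permP(r) - (p_exact * 5000 + 1) / 5001), 3 * se_p + 1e-6)
  # bootstrap distribution functionals vs enumeration
  set.seed(7)
  boot_mc <- rowMeans(matrix(sample(d, 3 * 5000, replace = TRUE), 5000, 3))
  for (q in c(1.2, 2, 2.5)) {
    p_q <- mean(boot_all <= q)
    se_q <- sqrt(p_q * (1 - p_q) / 5000)
    expect_lt(abs(mean(boot_mc <= q) - p_q), 3 * se_q + 1e-6)
  }
  expect_equal(effectSize(r), 2)
})

test_that("BCa reduces to the percentile interval for a symmetric bootstrap", {
  # perfectly symmetric data: bootstrap distribution symmetric about the
  # mean, jackknife skew zero => z0 ~ 0, a = 0
  x <- c(-3, -2, -1, 0, 1, 2, 3)
  r <- meanDifference(x, null_value = 0, design = "one_sample",
                      n_boot = 4000, n_perm = 100, seed = 11)
  set.seed(11)
  boot <- rowMeans(matrix(sample(x, 7 * 4000, replace = TRUE), 4000, 7))
  perc <- unname(quantile(boot, c(0.025, 0.975)))
  ci <- confInt(r)
  expect_lt(abs(ci[1] - perc[1]), 0.15)
  expect_lt(abs(ci[2] - perc[2]), 0.15)
})

test_that("permutation p is super-uniform under the null", {
  set.seed(123)
  n_sim <- 300
  p <- replicate(n_sim, {
    x <- rnorm(6); y <- rnorm(6)
    permP(meanDifference(x, y, design = "unpaired", n_boot = 50,
                         n_perm = 199, seed = sample.int(1e6, 1)))
  })
  for (alpha in c(0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / n_sim)
    expect_lte(mean(p <= alpha), alpha + 3 * se)
  }
})

test_that("per-rat classification matches the closed-form pooled t", {
  cas <- c(5, 6, 7); mal <- c(1, 2, 3)
  cl <- classifyRat(cas, mal, rat_id = "r")
  # pooled t: (6 - 2) / sqrt(1 * (1/3 + 1/3)) = 4 * sqrt(3/2)
  expect_equal(cl$t_statistic, 4 * sqrt(3 / 2), tolerance = 1e-12)
  expect_identical(cl$label, "casein")
  cl2 <- classifyRat(mal, cas)
  expect_identical(cl2$label, "maltodextrin")
  expect_equal(abs(cl2$t_statistic), abs(cl$t_statistic))
  # insufficient trials
  expect_identical(classifyRat(1, c(1, 2))$flag, "insufficient_trials")
})

test_that("latency correlation reproduces hand-computed values", {
  # five fixed points: r = 8 / sqrt(10 * 10) = 0.8
  x <- c(0, 1, 2, 3, 4); y <- c(0, 2, 1, 4, 3)
  out <- latencyCorrelation(x, y)
  expect_equal(out$r, 0.8, tolerance = 1e-12)
  expect_equal(out$r, unname(cor(x, y)))
  # collinear
  expect_equal(latencyCorrelation(x, 2 * x + 1)$r, 1)
  expect_error(latencyCorrelation(x, rep(2, 5)), "zero variance")
  expect_error(latencyCorrelation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("rank comparison uses the exact distribution for small samples", {
  out <- rankCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(out$U), 0)
  expect_equal(out$p, 0.1)     # 2 / choose(6, 3)
  expect_identical(out$method, "exact")
  # identical multisets with midranks: U = n^2 / 2
  out2 <- rankCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(out2$U), 4.5)
  expect_gt(out2$p, 0.9)
  # large shift at n = 100: overwhelming evidence
  set.seed(4)
  out3 <- rankCompare(rnorm(100), rnorm(100) + 5)
  expect_lt(out3$p, 1e-6)
  expect_identical(out3$method, "normal_tie_corrected")
})

test_that("preference regression recovers a known slope and rejects rank deficiency", {
  set.seed(21)
  slopes <- replicate(100, {
    z <- rnorm(14, 0, 3)
    pref <- 0.5 + 0.05 * z + rnorm(14, 0, 0.03)
    preferenceRegression(pref, z)$coefficients[["photometry"]]
  })
  expect_lt(abs(mean(slopes) - 0.05), 3 * sd(slopes) / sqrt(100))
  # perfect correlation
  z <- 1:6
  expect_equal(preferenceRegression(0.1 * z, z)$r, 1)
  # constant predictor
  expect_error(preferenceRegression(runif(5), rep(2, 5)), "rank-deficient")
  # multivariate fit returns named betas including the test-day coefficient
  out <- preferenceRegression(c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9),
                              c(1, 2, 1.5, 3, 2.5, 4),
                              test_day = c(1, 1, 2, 2, 3, 3))
  expect_named(out$coefficients, c("intercept", "photometry", "test_day"))
})
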