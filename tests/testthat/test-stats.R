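test_that("the penalized spline collapses to a straight line when the truth is linear", {
  set.seed(42)
  age <- runif(200, 20, 81)
  y <- 3 + 0.05 * age + rnorm(200, 0, 0.01)
  fit <- fit_age_gam(y, age, k = 10)
  expect_gte(fit$smooth[["edf"]], 1)
  expect_lte(fit$smooth[["edf"]], 1.2)
  expect_lte(fit$smooth[["edf"]], fit$k - 1)

  # with the penalty forced very large the fit IS ordinary least squares
  big <- fit_age_gam(y, age, k = 10, sp = 1e10)
  ols <- lm(y ~ age)
  expect_equal(unname(fitted(big$model)), unname(fitted(ols)),
               tolerance = 1e-6)

  expect_error(fit_age_gam(y[1:5], age[1:5], k = 10), "n >= k")
  expect_error(fit_age_gam(rep(1, 50), age[1:50], k = 10), "constant")
})

test_that("partial correlation matches the closed-form identity and its invariances", {
  set.seed(7)
  n <- 60
  z <- runif(n, 20, 81)
  x <- 0.4 * z + rnorm(n)
  y <- -0.2 * z + 0.5 * x + rnorm(n)
  pc <- partial_corr(x, y, z)
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  r_ref <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(pc$r, r_ref, tolerance = 1e-12)

  # symmetry and affine invariance
  expect_equal(partial_corr(y, x, z)$r, pc$r, tolerance = 1e-12)
  expect_equal(partial_corr(3 * x - 5, 0.1 * y + 2, 10 * z - 7)$r, pc$r,
               tolerance = 1e-12)

  # identical vectors (with variance left after the covariate) -> r = 1
  expect_equal(partial_corr(x, x, z)$r, 1)

  # consistency: truly null partial correlation vanishes at large n
  set.seed(8)
  n2 <- 5000
  z2 <- runif(n2, 20, 81)
  x2 <- 0.3 * z2 + rnorm(n2)
  y2 <- -0.5 * z2 + rnorm(n2)
  expect_lt(abs(partial_corr(x2, y2, z2)$r), 0.05)

  expect_error(partial_corr(x[1:3], y[1:3], z[1:3]), "n >= 4")
  expect_error(partial_corr(0.2 * z, y, z), "residual variance")
})

test_that("Benjamini-Hochberg step-up matches the hand-worked example", {
  res <- bh_adjust(c(0.01, 0.02, 0.04, 0.5), q = 0.05)
  # p(3) = 0.04 > 3 * 0.05 / 4 = 0.0375, so only the first two are rejected
  expect_identical(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$adjusted, p.adjust(c(0.01, 0.02, 0.04, 0.5), "BH"))
  # adjusted p-values preserve the order of the raw ones
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)$adjusted
  expect_identical(order(p), order(adj, p))

  expect_identical(bh_adjust(rep(0, 5))$reject, rep(TRUE, 5))
  expect_true(bh_adjust(0.049, q = 0.05)$reject)
  expect_false(bh_adjust(0.051, q = 0.05)$reject)
  expect_error(bh_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("the correlation screen enforces the prefilter, the family FDR and the effect cut", {
  set.seed(21)
  n <- 39
  age <- seq(20, 81, length.out = n)
  # metric with a strong age effect and a tightly coupled score
  m1 <- -0.04 * pmax(0, age - 50) + rnorm(n, 0, 0.15)
  s1 <- 2 * m1 + rnorm(n, 0, 0.15)
  # age-flat metric (should fail the prefilter regardless of correlation)
  m0 <- rnorm(n)
  s0 <- m0 + rnorm(n, 0, 0.1)
  df <- data.frame(age = age, m1 = m1, m0 = m0, s1 = s1, s0 = s0)
  out <- screen_correlations(df, metrics = c("m1", "m0"),
                             scores = c("s1", "s0"),
                             family = c(m1 = "segregation", m0 = "global"),
                             k = 12)
  expect_true(all(out$metric == "m1"))  # m0 removed by the GAM prefilter
  expect_true(out$reported[out$score == "s1"])
  expect_equal(out$r, out$r[order(-abs(out$r))])

  # |r| barely below the cut is not reported however small its p-value:
  # construct residual vectors with exact partial correlation 0.39
  rx <- residuals(lm(rnorm(n) ~ age))
  rz <- residuals(lm(rnorm(n) ~ age))
  rz <- residuals(lm(rz ~ rx))                     # orthogonal to rx
  ry <- 0.39 * rx / sd(rx) + sqrt(1 - 0.39^2) * rz / sd(rz)
  pc <- partial_corr(rx, ry, age)
  expect_equal(abs(pc$r), 0.39, tolerance = 1e-10)
  df2 <- data.frame(age = age, m = m1, s = ry + 0)
  df2$m <- m1
  out2 <- screen_correlations(
    transform(df2, s = ry), metrics = "m", scores = "s", k = 12,
    min_abs_r = 0.400)
  if (nrow(out2) > 0) expect_false(any(out2$reported & abs(out2$r) <= 0.4))

  # the |r| cut is applied after FDR: the same strong pair is excluded
  # when the cut exceeds its correlation, however small its q-value
  out_cut <- screen_correlations(df, metrics = "m1", scores = "s1",
                                 family = c(m1 = "segregation"), k = 12,
                                 min_abs_r = 0.999)
  expect_false(any(out_cut$reported))
  expect_true(all(out_cut$q_bh < 0.05))

  # empty candidate set is an empty report, not an error
  df3 <- data.frame(age = age, m = rnorm(n), s = rnorm(n))
  out3 <- screen_correlations(df3, metrics = "m", scores = "s", k = 12)
  expect_s3_class(out3, "data.frame")
  expect_true(nrow(out3) %in% c(0L, 1L))
})
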