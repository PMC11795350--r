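test_that("wPLI separates zero-lag from quarter-cycle coupling", {
  # identical signals + independent noise: Im(cross-spectrum) symmetric,
  # so the estimate is a null draw; check the average over seeds
  zl <- vapply(1:5, function(s) {
    narrowband_wpli(pair_epochs(40, lag = 0, noise = 2, seed = s),
                    10)["ch1", "ch2"]
  }, numeric(1))
  expect_lt(mean(zl), 0.3)

  # constant pi/2 lag, no noise: Im single-signed -> exactly 1
  ql <- pair_epochs(20, lag = pi / 2, noise = 0, seed = 2)
  expect_equal(narrowband_wpli(ql, 10)["ch1", "ch2"], 1, tolerance = 1e-9)

  # invariances: channel-wise rescaling and joint sign flip
  ep <- pair_epochs(15, lag = pi / 3, noise = 1, seed = 3)
  w0 <- narrowband_wpli(ep, 10)
  sc <- ep; sc$data[, 1, ] <- 7 * sc$data[, 1, ]
  fl <- ep; fl$data <- -fl$data
  expect_equal(narrowband_wpli(sc, 10), w0, tolerance = 1e-10)
  expect_equal(narrowband_wpli(fl, 10), w0, tolerance = 1e-12)

  expect_error(narrowband_wpli(ep, 0.4), "too low")
  expect_error(narrowband_wpli(ep, 128), "too high")
  expect_error(narrowband_wpli(pair_epochs(5, pi / 2), 10), ">= 8")
})

test_that("the compiled estimator agrees with a plain-R reference", {
  for (s in 1:3) {
    ep <- pair_epochs(12, lag = runif(1, 0.3, 2.5), noise = 1.5,
                      seed = 100 + s)
    for (f0 in c(4, 10, 23)) {
      expect_equal(narrowband_wpli(ep, f0)["ch1", "ch2"],
                   wpli_pair_R(ep, f0), tolerance = 2e-3)
    }
  }
})

test_that("the spectrum peaks at the injected coupling frequency", {
  ep <- simulate_epochs(list(age = 30), "shape", single_pair_profile(1),
                        n_epochs = 60, seed = 5)
  spec <- suppressMessages(wpli_spectrum(ep))
  expect_equal(dim(spec$w), c(48, 30, 30))
  expect_equal(spec$freqs, 1:48)
  i <- montage_index("O1"); j <- montage_index("O2")
  expect_true(which.max(spec$w[, i, j]) %in% 9:11)
  # invariants on every matrix
  for (k in c(1, 10, 48)) {
    m <- spec$w[k, , ]
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("independent channels stay inside their permutation null", {
  n_perm <- 200
  inside <- 0
  for (p in 1:3) {
    ep <- noise_pair_epochs(60, seed = 20 + p)
    obs <- narrowband_wpli(ep, 10)["ch1", "ch2"]
    null <- vapply(seq_len(n_perm), function(b) {
      perm <- ep
      set.seed(1000 + b)
      perm$data[, 2, ] <- perm$data[sample(60), 2, ]
      narrowband_wpli(perm, 10)["ch1", "ch2"]
    }, numeric(1))
    if (obs < quantile(null, 0.95)) inside <- inside + 1
  }
  expect_gte(inside, 2)
})

test_that("band aggregation averages exactly the nominal band centers", {
  counts <- c(delta = 3, theta = 4, alpha = 6, beta = 16, gamma = 19)
  for (b in names(counts)) {
    expect_length(band_centers(b), counts[[b]])
  }
  expect_error(band_centers("mu"), "unknown band")

  ep <- pair_epochs(10, lag = pi / 3, noise = 1, seed = 6)
  spec <- suppressMessages(wpli_spectrum(ep))
  for (b in c("delta", "alpha", "gamma")) {
    m <- aggregate_band(spec, b)
    idx <- match(band_centers(b), spec$freqs)
    expect_equal(unclass(m)[1, 2], mean(spec$w[idx, 1, 2]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # bounded by the entrywise min and max of the member matrices
    expect_gte(m[1, 2], min(spec$w[idx, 1, 2]))
    expect_lte(m[1, 2], max(spec$w[idx, 1, 2]))
  }
  # a spectrum of identical matrices aggregates to that matrix
  spec2 <- spec
  for (k in seq_along(spec2$freqs)) spec2$w[k, , ] <- spec$w[10, , ]
  expect_equal(unclass(aggregate_band(spec2, "beta")), spec$w[10, , ],
               ignore_attr = TRUE)
})
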