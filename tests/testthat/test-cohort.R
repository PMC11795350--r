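test_that("cohorts cover the age range, pass screening and are reproducible", {
  coh <- simulate_cohort(39, 20, 81, seed = 1)
  expect_equal(nrow(coh), 39)
  expect_true(all(coh$age >= 20 & coh$age <= 81))
  # stratified sampling: one subject per equal-width stratum
  breaks <- seq(20, 81, length.out = 40)
  expect_true(all(table(cut(coh$age, breaks)) == 1))
  expect_true(all(coh$mmse >= 27 & coh$mmse <= 30))
  expect_true(all(coh$bdi >= 0 & coh$bdi <= 17))
  expect_true(all(coh$acc_shape >= 0 & coh$acc_shape <= 100))
  expect_true(all(coh$rt_shape >= 200 & coh$rt_binding >= 200))

  expect_identical(coh, simulate_cohort(39, 20, 81, seed = 1))
  expect_false(identical(coh, simulate_cohort(39, 20, 81, seed = 2)))

  tight <- simulate_cohort(2, 30, 30.01, seed = 1)
  expect_true(all(abs(tight$age - 30) < 0.02))

  expect_error(simulate_cohort(1, 20, 81, seed = 1), "n_subjects")
  expect_error(simulate_cohort(10, 81, 20, seed = 1), "age_min")
  expect_error(simulate_cohort(10, 20, 81), "seed")
})

test_that("cognition reduces to its mean curves at zero noise", {
  sd0 <- setNames(rep(0, 12), names(bindnet:::cognition_noise_defaults()))
  cur <- cognition_curves()
  for (age in c(20, 35, 45, 50, 62.5, 70, 81)) {
    z <- simulate_cognition(age, seed = 1, noise_sd = sd0)
    for (dm in names(z$domain_scores)) {
      expect_equal(z$domain_scores[[dm]], cur[[dm]](age), tolerance = 1e-12)
    }
    expect_equal(z$accuracy[["shape"]], cur$acc_shape(age), tolerance = 1e-12)
  }
  # qualitative lifespan shapes
  acc <- function(a) simulate_cognition(a, seed = 1, noise_sd = sd0)$accuracy
  expect_gt(acc(20)[["shape"]], acc(80)[["shape"]])
  lang <- function(a) cur$language(a)
  expect_gte(lang(45), lang(25))
  expect_gte(lang(45), lang(70))
  # visuospatial declines much faster after 70 than before
  expect_lt(cur$visuospatial(75) - cur$visuospatial(71),
            5 * (cur$visuospatial(65) - cur$visuospatial(61)))

  # same mean curve, different noise draws
  a <- simulate_cognition(40, seed = 1)
  b <- simulate_cognition(40, seed = 2)
  expect_false(identical(a$domain_scores, b$domain_scores))
  expect_error(simulate_cognition(150), "outside")
})

test_that("trial sequences implement the paradigm structure", {
  tr <- simulate_trials(seed = 1)
  expect_equal(nrow(tr), 96)
  expect_equal(unname(table(tr$condition)[c("binding", "shape")]),
               c(48L, 48L), ignore_attr = TRUE)
  expect_true(all(tr$study_duration_ms == 1000))
  expect_true(all(tr$delay_ms == 1200))
  # counterbalanced blocks of 12: condition constant within each block,
  # alternating across blocks
  blocks <- matrix(tr$condition, nrow = 12)
  per_block <- apply(blocks, 2, function(b) length(unique(b)))
  expect_true(all(per_block == 1))
  expect_true(all(blocks[1, -1] != blocks[1, -8]))
  expect_identical(tr, simulate_trials(seed = 1))
  expect_false(identical(tr$probe_type, simulate_trials(seed = 2)$probe_type))
  expect_setequal(unique(tr$probe_type), c("same", "different"))
})
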