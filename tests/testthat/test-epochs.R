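test_that("simulated epochs have canonical dimensions and are reproducible", {
  ep <- simulate_epochs(list(age = 40), "shape", default_coupling_profile(),
                        n_epochs = 10, seed = 3)
  expect_s3_class(ep, "epoch_array")
  expect_equal(dim(ep$data), c(10, 30, 256))
  expect_identical(dimnames(ep$data)[[2]], as.character(montage_1020()))
  expect_true(all(is.finite(ep$data)))
  expect_equal(ep$srate, 256)
  expect_equal(ep$epoch_len_ms, 1000)

  ep2 <- simulate_epochs(list(age = 40), "shape", default_coupling_profile(),
                         n_epochs = 10, seed = 3)
  expect_identical(ep$data, ep2$data)

  expect_error(simulate_epochs(list(age = 40), "shape",
                               default_coupling_profile(),
                               n_epochs = 5, seed = 1), ">= 8")
  expect_error(coupling_profile(bands = list(
    alpha = list(pairs = list(c("O1", "Nope")), lag = 1,
                 strength = list(type = "constant", g = 1)))),
    "unknown channel")
  expect_error(coupling_profile(bands = list(
    alpha = list(pairs = list(c("O1", "O2")), lag = pi,
                 strength = list(type = "constant", g = 1)))),
    "lag")
})

test_that("estimated wPLI of a coupled pair is monotone in coupling strength", {
  w <- vapply(c(0, 0.5, 1), function(g) {
    ep <- simulate_epochs(list(age = 40), "shape", single_pair_profile(g),
                          n_epochs = 100, seed = 7)
    narrowband_wpli(ep, 10)["O1", "O2"]
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  expect_gt(w[3], 0.8)       # full coupling approaches 1
  expect_lt(w[1], 0.3)       # uncoupled pair stays at the null level
})

test_that("drawn epoch counts follow the truncated count model", {
  set.seed(5)
  ns <- replicate(300, draw_epoch_count("shape"))
  nb <- replicate(300, draw_epoch_count("binding"))
  expect_true(all(ns >= 20 & ns <= 48))
  expect_true(all(ns == round(ns)))
  expect_equal(mean(ns), 38.05, tolerance = 0.05)  # relative tolerance
  expect_gt(mean(nb), mean(ns) - 1)
})

test_that("artifact injection honours its contracts per kind", {
  ep <- clean_epochs(n_ep = 6)
  amp <- inject_artifacts(ep, "amplitude", 3, magnitude = 100, seed = 2)
  expect_gte(max(abs(amp$data[3, , ])), 100)
  expect_identical(amp$data[-3, , ], ep$data[-3, , ])

  stp <- inject_artifacts(ep, "step", 2, magnitude = 80, seed = 2)
  jumps <- apply(stp$data[2, , ], 1, function(v) max(abs(diff(v))))
  expect_gte(max(jumps), 80 - max(abs(diff(t(ep$data[2, , ])))))

  flat <- inject_artifacts(ep, "flatline", 1, magnitude = 0.4, seed = 2)
  w <- round(0.100 * ep$srate)
  ranges <- bindnet:::sliding_min_max(matrix(flat$data[1, , ], 30, 256),
                                      as.integer(w))
  expect_lt(min(ranges$max - ranges$min), 0.4)

  expect_identical(inject_artifacts(ep, "amplitude", integer(0), 10), ep)
  expect_error(inject_artifacts(ep, "amplitude", 99, 10), "out of range")
  expect_error(inject_artifacts(ep, "amplitude", 1, -5), "magnitude")
})
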