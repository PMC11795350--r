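test_that("the ring-lattice reference has the prescribed structure", {
  g60 <- lattice_reference(30, 60)
  expect_true(all(rowSums(g60$weights) == 4))  # k = 2 per side
  expect_equal(g60$retained_edges, 60)
  # closed form for a k-ring: C = 3(k-1) / (2(2k-1)) = 0.5 at k = 2
  expect_equal(clustering_onnela(g60)$C, 0.5)

  g239 <- lattice_reference(30, 239)
  expect_equal(g239$retained_edges, 239)
  expect_true(all(g239$weights %in% c(0, 1)))

  expect_error(lattice_reference(30, 436), "exceeds")
})

test_that("small-world ratios obey their definitional identities", {
  # a lattice referenced against itself: gamma = lambda = sigma = 1
  lat <- lattice_reference(30, 239)
  swl <- small_world(lat, reference = lat)
  expect_equal(swl$gamma, 1)
  expect_equal(swl$lambda, 1)
  expect_equal(swl$sigma, 1)

  # sigma == gamma / lambda to machine precision on arbitrary graphs
  for (s in 1:5) {
    g <- threshold_proportional(rand_wgraph(30, 1, seed = 200 + s), 0.55)
    sw <- small_world(g)
    expect_identical(sw$sigma, sw$gamma / sw$lambda)
    expect_true(all(c(sw$L, sw$C, sw$L_rand, sw$C_rand) > 0))
  }

  # the printed convention divides L by the lattice L; the customary one
  # divides C by the reference C
  g <- threshold_proportional(rand_wgraph(30, 1, seed = 300), 0.55)
  ap <- small_world(g, convention = "as_printed")
  ws <- small_world(g, reference = lattice_reference(30, 239),
                    convention = "watts_strogatz")
  expect_equal(ap$gamma, ws$lambda)
  expect_equal(ap$lambda, ws$gamma)

  # mismatched reference is an error
  expect_error(small_world(g, reference = lattice_reference(30, 100)),
               "edge count")
})
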