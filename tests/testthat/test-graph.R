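test_that("proportional thresholding keeps exactly floor(p * n_pairs) edges", {
  m <- rand_wgraph(30, p_edge = 1, seed = 1)
  g <- threshold_proportional(m, 0.55)
  expect_equal(g$retained_edges, 239)  # floor(0.55 * 435)
  expect_equal(sum(g$weights[upper.tri(g$weights)] != 0), 239)
  # retained weights unchanged, removed exactly zero
  kept <- g$weights != 0
  expect_identical(g$weights[kept], m[kept])

  expect_equal(threshold_proportional(m, 1)$weights, m, ignore_attr = TRUE)

  toy <- matrix(0, 5, 5)
  toy[1, 2] <- toy[2, 3] <- toy[3, 4] <- toy[4, 5] <- toy[1, 5] <- 0.5
  toy <- toy + t(toy)
  gt <- threshold_proportional(toy, 0.55)
  expect_equal(gt$retained_edges, 5)  # floor(0.55 * 10)
  expect_equal(sum(gt$weights != 0) / 2, 5)
  expect_true(all(gt$weights[toy > 0] == 0.5))

  # ties broken by ascending (row, col): all-equal weights keep pairs
  # (1,2), (1,3), (1,4) - positions 1, 2 and 4 in upper-triangle order
  eq <- matrix(1, 4, 4); diag(eq) <- 0
  ge <- threshold_proportional(eq, 0.5)  # floor(0.5 * 6) = 3
  expect_equal(ge$retained_edges, 3)
  expect_true(all(ge$weights[1, 2:4] == 1))
  expect_true(all(ge$weights[2:4, 2:4] == 0))

  expect_error(threshold_proportional(matrix(rnorm(16), 4, 4)), "symmetric")
  expect_error(threshold_proportional(eq, 0), "proportion")
})

test_that("path metrics match hand-computed toys", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  pm <- path_metrics(as_thresholded_graph(path3))
  expect_equal(pm$L, 4 / 3)
  expect_equal(pm$E_glob, 5 / 6)
  expect_false(pm$disconnected)

  full <- matrix(1, 4, 4); diag(full) <- 0
  pf <- path_metrics(as_thresholded_graph(full))
  expect_equal(pf$L, 1)
  expect_equal(pf$E_glob, 1)

  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[3, 4] <- 1
  dyads <- dyads + t(dyads)
  pd <- path_metrics(as_thresholded_graph(dyads))
  expect_equal(pd$E_glob, 1 / 3)
  expect_equal(pd$L, 1)
  expect_true(pd$disconnected)

  expect_error(path_metrics(as_thresholded_graph(matrix(0, 3, 3))),
               "edgeless")
})

test_that("betweenness and clustering match their defining toys", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  bc <- betweenness_w(as_thresholded_graph(star))
  expect_equal(unname(bc), c(1, 0, 0, 0, 0))

  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_true(all(betweenness_w(as_thresholded_graph(full)) == 0))

  tri <- matrix(1, 3, 3); diag(tri) <- 0
  cl <- clustering_onnela(as_thresholded_graph(tri))
  expect_equal(unname(cl$cc), c(1, 1, 1))
  expect_equal(cl$C, 1)
  expect_true(all(clustering_onnela(as_thresholded_graph(star))$cc == 0))
})

test_that("community detection resolves planted structure deterministically", {
  two_cliques <- matrix(0, 8, 8)
  two_cliques[1:4, 1:4] <- 1
  two_cliques[5:8, 5:8] <- 1
  diag(two_cliques) <- 0
  g <- as_thresholded_graph(two_cliques)
  cm <- communities_louvain(g, seed = 1)
  expect_equal(length(unique(cm$membership)), 2)
  expect_equal(cm$Q, 0.5)  # two equal disconnected cliques
  expect_equal(length(unique(cm$membership[1:4])), 1)

  full <- matrix(1, 6, 6); diag(full) <- 0
  cf <- communities_louvain(as_thresholded_graph(full), seed = 1)
  expect_equal(length(unique(cf$membership)), 1)

  m <- rand_wgraph(12, 0.4, seed = 3)
  g2 <- as_thresholded_graph(m)
  expect_identical(communities_louvain(g2, seed = 5)$membership,
                   communities_louvain(g2, seed = 5)$membership)
})

test_that("participation coefficient follows its algebraic contract", {
  two_cliques <- matrix(0, 8, 8)
  two_cliques[1:4, 1:4] <- 1; two_cliques[5:8, 5:8] <- 1
  diag(two_cliques) <- 0
  g <- as_thresholded_graph(two_cliques)
  memb <- setNames(rep(1:2, each = 4), g$labels)
  hb <- hubness(g, memb)
  expect_true(all(hb$participation == 0))  # all strength intramodular
  expect_false(any(hb$hub_flag))

  # one node bridging the cliques with equal strength on both sides
  bridge <- two_cliques
  bridge[1, 5] <- bridge[5, 1] <- 3  # node 1: 3 inside (1+1+1), 3 outside
  gb <- as_thresholded_graph(bridge)
  hbb <- hubness(gb, memb)
  expect_equal(unname(hbb$participation[1]), 0.5)
  expect_true(hbb$hub_flag[1])

  # bound: P <= 1 - 1/|modules|
  m <- rand_wgraph(10, 0.6, seed = 8)
  gg <- as_thresholded_graph(m)
  cm <- communities_louvain(gg, seed = 1)
  hg <- hubness(gg, cm$membership)
  nmod <- length(unique(cm$membership))
  expect_true(all(hg$participation <= 1 - 1 / nmod + 1e-12))
  expect_true(all(hg$participation >= 0))

  # zero-strength node has P = 0 by convention
  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 1
  gi <- as_thresholded_graph(iso)
  expect_equal(unname(hubness(gi, setNames(c(1, 1, 2, 2),
                                           gi$labels))$participation[3]), 0)
})

test_that("weighted metrics equal brute-force oracles on a seeded battery", {
  for (s in 1:50) {
    n <- sample(4:8, 1)
    w <- rand_wgraph(n, p_edge = 0.55, seed = 1000 + s)
    if (all(w == 0)) next
    g <- as_thresholded_graph(w)
    oracle <- oracle_L_Eglob(w)
    pm <- path_metrics(g)
    expect_equal(pm$L, oracle$L, tolerance = 1e-9)
    expect_equal(pm$E_glob, oracle$E_glob, tolerance = 1e-9)
    expect_equal(pm$disconnected, oracle$disconnected)
    expect_equal(unname(betweenness_w(g)), oracle_betweenness(w),
                 tolerance = 1e-9)
    cl <- clustering_onnela(g)
    ocl <- oracle_clustering(w)
    expect_equal(unname(cl$cc), ocl$cc, tolerance = 1e-9)
    expect_equal(cl$C, ocl$C, tolerance = 1e-9)
  }
})

test_that("metrics respond to a global weight rescaling as dictated by their definitions", {
  w <- rand_wgraph(12, 0.5, seed = 77)
  g1 <- as_thresholded_graph(w)
  g2 <- as_thresholded_graph(3.7 * w)
  p1 <- path_metrics(g1); p2 <- path_metrics(g2)
  expect_equal(p2$L, p1$L / 3.7, tolerance = 1e-12)
  expect_equal(p2$E_glob, p1$E_glob * 3.7, tolerance = 1e-12)
  expect_equal(rank(betweenness_w(g1)), rank(betweenness_w(g2)))
  expect_equal(clustering_onnela(g1)$cc, clustering_onnela(g2)$cc,
               tolerance = 1e-12)
  expect_identical(communities_louvain(g1, seed = 2)$membership,
                   communities_louvain(g2, seed = 2)$membership)
  m <- communities_louvain(g1, seed = 2)$membership
  expect_equal(hubness(g1, m)$participation, hubness(g2, m)$participation,
               tolerance = 1e-12)
})
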