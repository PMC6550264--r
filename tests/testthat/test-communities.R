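test_that("modularity closed forms hold at gamma = 1", {
  net <- barbell_network()
  one <- setNames(rep(0L, 6), net$nodes)
  expect_equal(resolution_modularity(net, one)$q, 0)

  sing <- setNames(0:5, net$nodes)
  g <- carefrag:::as_work_graph(net)
  k <- carefrag:::work_degrees(g)
  expect_equal(resolution_modularity(net, sing)$q, -sum((k / sum(k))^2))

  triangles <- setNames(c(0, 0, 0, 1, 1, 1), c("A", "B", "C", "D", "E", "F"))
  expect_equal(resolution_modularity(net, triangles)$q, 10 / 28)

  empty <- carefrag:::new_network("A", data.table(provider_a = character(),
                                                  provider_b = character(),
                                                  weight = integer()))
  expect_error(resolution_modularity(empty, c(A = 0L)),
               class = "carefrag_empty_network")
  expect_error(resolution_modularity(net, triangles, gamma = 0),
               class = "carefrag_invalid_gamma")
})

test_that("modularity matches igraph on random weighted graphs", {
  for (s in 1:10) {
    net <- random_network(sample(5:9, 1), seed = 100 + s)
    part <- setNames(sample(0:2, length(net$nodes), replace = TRUE), net$nodes)
    ig <- as_igraph(net)
    mem <- part[igraph::V(ig)$name] + 1
    for (gamma in c(0.5, 1, 1.8)) {
      expect_equal(resolution_modularity(net, part, gamma)$q,
                   igraph::modularity(ig, membership = mem,
                                      weights = igraph::E(ig)$weight,
                                      resolution = gamma))
    }
  }
})

test_that("modularity is invariant under label permutation", {
  net <- random_network(8, seed = 33)
  part <- setNames(sample(0:3, 8, replace = TRUE), net$nodes)
  q1 <- resolution_modularity(net, part)$q
  relab <- setNames(c(3L, 2L, 0L, 1L)[part + 1L], names(part))
  expect_equal(resolution_modularity(net, relab)$q, q1)
})

test_that("exhaustive search finds known optima and guards its limits", {
  pair <- carefrag:::new_network(c("A", "B"), data.table(provider_a = "A",
                                                         provider_b = "B",
                                                         weight = 1L))
  best <- exhaustive_best_partition(pair)
  expect_equal(best$modularity$q, 0)
  expect_equal(unname(best$partition), c(0L, 0L))   # splitting scores -1/2

  bb <- exhaustive_best_partition(barbell_network())
  expect_equal(bb$modularity$q, 10 / 28)
  expect_equal(unname(bb$partition), c(0L, 0L, 0L, 1L, 1L, 1L))

  empty <- carefrag:::new_network(c("A", "B"), data.table(provider_a = character(),
                                                          provider_b = character(),
                                                          weight = integer()))
  expect_error(exhaustive_best_partition(empty), class = "carefrag_empty_network")
  expect_error(exhaustive_best_partition(random_network(11, seed = 1)),
               class = "carefrag_too_large")
})

test_that("louvain recovers clique structure for any sweep order", {
  net <- two_cliques_network(4)
  truth <- setNames(rep(0:1, each = 4), net$nodes)
  for (s in 1:5) {
    lv <- louvain(net, seed = s)
    expect_equal(adjusted_rand_index(lv$partition, truth), 1)
  }
  # a single clique never splits
  k5 <- random_network(5, seed = 1, p_edge = 1, max_weight = 1)
  expect_equal(louvain(k5, seed = 2)$n_communities, 1L)
  # errors
  expect_error(louvain(net, gamma = -1), class = "carefrag_invalid_gamma")
})

test_that("louvain is deterministic per seed with canonical byte-stable labels", {
  net <- random_network(9, seed = 50, p_edge = 0.5)
  a <- louvain(net, seed = 7)
  b <- louvain(net, seed = 7)
  expect_identical(a$partition, b$partition)
  labs <- unique(unname(a$partition[order(names(a$partition))]))
  expect_equal(labs, seq_along(labs) - 1L)   # first-appearance 0-based labels
})

test_that("accepted moves only ever raise modularity across levels", {
  for (s in 1:5) {
    net <- random_network(sample(6:9, 1), seed = 200 + s)
    lv <- louvain(net, seed = s)
    expect_true(all(diff(lv$q_levels) >= -1e-12))
    expect_equal(lv$modularity$q, max(lv$q_levels))
  }
})

test_that("resolution limits flip between one community and singletons", {
  net <- barbell_network()
  tiny <- louvain(net, gamma = 1e-6, seed = 1)
  expect_equal(tiny$n_communities, 1L)
  g <- carefrag:::as_work_graph(net)
  k <- carefrag:::work_degrees(g)
  two_m <- sum(k)
  kk <- outer(k, k)[cbind(g$ea, g$eb)]
  gamma_big <- two_m * max(g$w) / min(kk) * 1.01
  huge <- exhaustive_best_partition(net, gamma = gamma_big)
  expect_equal(length(unique(huge$partition)), 6L)
})

test_that("adjusted Rand index matches mclust and handles degenerate cases", {
  set.seed(4)
  a <- sample(1:3, 20, replace = TRUE)
  b <- sample(1:3, 20, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)  # both trivial
  p1 <- setNames(c(0, 0, 1), c("x", "y", "z"))
  p2 <- setNames(c(5, 1, 1), c("z", "y", "x"))   # same grouping, names scrambled
  expect_equal(adjusted_rand_index(p1, p2), 1)
  expect_error(adjusted_rand_index(p1, setNames(0:1, c("x", "y"))),
               class = "carefrag_invalid_partition")
})

test_that("stability sweep flags reproducible partitions", {
  # two disconnected cliques: unique optimum, perfect agreement at gamma 1
  a <- two_cliques_network(4)
  disc <- carefrag:::new_network(a$nodes, a$edges[provider_a != "A4"])
  sw <- stability_sweep(disc, gammas = 1, n_seeds = 4)
  expect_equal(sw$summary$mean_pairwise_ari, 1)
  expect_true(sw$summary$stable)
  expect_equal(sw$summary$modal_n_communities, 2L)

  # a gamma list of length 1 is just a multi-seed run
  expect_equal(nrow(sw$summary), 1L)
  expect_error(stability_sweep(disc, gammas = 1, n_seeds = 1),
               class = "carefrag_invalid_config")
  expect_error(stability_sweep(disc, gammas = c(1, -2), n_seeds = 3),
               class = "carefrag_invalid_gamma")

  # dense weight-1 graph: agreement across seeds should be poor, no flag
  set.seed(77)
  nodes <- sprintf("n%02d", 1:16)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.55
  er <- carefrag:::new_network(nodes, data.table(provider_a = pairs[keep, 1],
                                                 provider_b = pairs[keep, 2],
                                                 weight = 1L))
  sw2 <- stability_sweep(er, gammas = 1, n_seeds = 6)
  expect_lt(sw2$summary$mean_pairwise_ari, 0.95)
  expect_false(sw2$summary$stable)
})
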