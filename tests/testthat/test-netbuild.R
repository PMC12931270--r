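test_that("group down-sampling equalizes sizes deterministically", {
  cfg <- cohortConfig(groupSizes = c(non = 8L, I = 7L, II = 5L, III = 4L),
                      nTaxa = 20L, depthRange = c(300L, 400L),
                      plantedModules = list(non = list(), I = list(),
                                            II = list(), III = list()),
                      nContaminantTaxa = 0L, nSingletonTaxa = 0L,
                      seed = 3L)
  ae <- generateCohort(cfg)
  out <- downsampleGroups(ae, seed = 9)
  expect_equal(unname(vapply(out, ncol, integer(1))), rep(4L, 4))
  ## the group already at the target keeps its full sample set
  expect_setequal(colnames(countMatrix(out$III)),
                  colnames(countMatrix(ae))[sampleMetadata(ae)$grade ==
                                              "III"])
  out2 <- downsampleGroups(ae, seed = 9)
  expect_identical(lapply(out, countMatrix), lapply(out2, countMatrix))
  expect_error(downsampleGroups(ae, targetN = 6), "smaller than targetN")
})

test_that("network construction applies both the r and p clauses strictly", {
  ids <- letters[1:4]
  cor <- corFixture(list(list("a", "b", 0.5), list("b", "c", -0.4),
                         list("a", "c", 0.31), list("a", "d", 0.3)), ids)
  ## no p values: threshold-only; r = 0.3 exactly is excluded
  net <- buildNetwork(cor, threshold = 0.3, alpha = 0.05)
  expect_equal(igraph::vcount(net@graph), 3)  # d isolated, dropped
  expect_equal(igraph::ecount(net@graph), 3)
  ## with p: an edge with large p disappears
  p <- matrix(0.01, 4, 4, dimnames = list(ids, ids))
  p["a", "b"] <- p["b", "a"] <- 0.2
  diag(p) <- NA
  cor2 <- methods::initialize(cor, p = p, nResamples = 99L,
                              resamplingMode = "permutation")
  net2 <- buildNetwork(cor2, threshold = 0.3, alpha = 0.05)
  ek <- apply(igraph::as_edgelist(net2@graph), 1,
              function(e) paste(sort(e), collapse = "|"))
  expect_setequal(ek, c("b|c", "a|c"))
})

test_that("topology identities and closed forms hold", {
  ## complete graph K5
  k5 <- asNetwork(igraph::make_full_graph(5))
  t5 <- networkTopology(k5)
  expect_equal(t5$density, 1)
  expect_equal(t5$average_path_length, 1)
  expect_equal(t5$diameter, 1)
  expect_equal(t5$clustering_coefficient, 1)
  expect_equal(t5$average_degree, 2 * t5$edges / t5$nodes)
  ## star K1,5: Freeman degree centralization 1, no triangles
  st <- asNetwork(igraph::make_star(6, mode = "undirected"))
  ts <- networkTopology(st)
  expect_equal(ts$degree_centralization, 1)
  expect_equal(ts$betweenness_centralization, 1)
  expect_true(ts$clustering_coefficient == 0 ||
                is.nan(ts$clustering_coefficient))
  ## vertex-transitive graphs centralize to 0
  ring <- networkTopology(asNetwork(igraph::make_ring(7)))
  expect_equal(ring$degree_centralization, 0)
  expect_equal(ring$betweenness_centralization, 0)
  expect_equal(ring$closeness_centralization, 0, tolerance = 1e-10)
  ## empty network: nodes 0, metrics NA
  e <- networkTopology(asNetwork(igraph::make_empty_graph(0,
                                                          directed = FALSE)))
  expect_equal(e$nodes, 0)
  expect_true(is.na(e$average_path_length))
})

test_that("average degree and density identities hold on random graphs", {
  set.seed(42)
  for (i in 1:10) {
    g <- igraph::sample_gnp(sample(5:30, 1), runif(1, 0.1, 0.5))
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    if (igraph::vcount(g) < 2) next
    t <- networkTopology(asNetwork(g))
    expect_equal(t$average_degree, 2 * t$edges / t$nodes)
    expect_equal(t$density, t$edges / (t$nodes * (t$nodes - 1) / 2))
    expect_true(is.na(t$modularity) || t$modularity >= -0.5)
  }
})

test_that("path metrics and betweenness agree with brute-force oracles", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.3)
    adj <- adj + t(adj)
    keep <- rowSums(adj) > 0
    adj <- adj[keep, keep, drop = FALSE]
    if (nrow(adj) < 3) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    t <- networkTopology(asNetwork(g))
    D <- floydWarshall(adj)
    fin <- is.finite(D) & upper.tri(D)
    expect_equal(t$average_path_length, mean(D[fin]))
    expect_equal(t$diameter, max(D[fin]))
    net <- asNetwork(g)
    ks <- keystoneScores(net)
    expect_equal(unname(ks$betweenness), bruteBetweenness(adj),
                 tolerance = 1e-9)
  }
})

test_that("dissimilarity-weighted path metrics use 1 - |r| edge lengths", {
  g <- igraph::make_graph(~ a - b, b - c)
  igraph::E(g)$r <- c(0.9, -0.5)
  net <- asNetwork(g)
  t <- networkTopology(net, mode = "dissimilarity_weighted")
  ## path a-b = 0.1, b-c = 0.5, a-c = 0.6
  expect_equal(t$diameter, 0.6)
  expect_equal(t$average_path_length, mean(c(0.1, 0.5, 0.6)))
})

test_that("keystone flags exactly the top decile with deterministic ties", {
  ## 29 nodes -> ceil(2.9) = 3 keystones
  set.seed(2)
  g <- igraph::sample_gnp(29, 0.2)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  while (igraph::vcount(g) < 29) {
    g <- igraph::add_vertices(g, 1)
    g <- igraph::add_edges(g, c(igraph::vcount(g), 1))
  }
  ks <- keystoneScores(asNetwork(g))
  expect_equal(sum(ks$keystone_flag), 3)
  ## dominance: a node best on all positive measures and minimal
  ## betweenness has maximal composite for any non-negative weights
  star <- asNetwork(igraph::make_full_graph(4) + igraph::make_ring(4))
  expect_error(keystoneScores(star, weights = c(0, 0, 0, 0)), "weight")
})

test_that("keystone composite equals an independent z-score recomputation", {
  set.seed(9)
  g <- igraph::sample_gnp(10, 0.45)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  net <- asNetwork(g)
  w <- c(0.4, 0.3, 0.2, 0.1)
  ks <- keystoneScores(net, weights = w)
  z <- function(x) if (sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / sd(x)
  manual <- w[1] * z(ks$degree) + w[2] * z(ks$closeness) +
    w[3] * z(ks$local_transitivity) - w[4] * z(ks$betweenness)
  expect_equal(ks$keystone_composite, manual)
  expect_equal(order(-ks$keystone_composite)[seq_len(sum(ks$keystone_flag))],
               which(ks$keystone_flag)[order(-ks$keystone_composite[
                 ks$keystone_flag])])
})

test_that("raising the threshold never increases edge counts", {
  set.seed(33)
  ids <- paste0("t", 1:15)
  r <- matrix(0, 15, 15, dimnames = list(ids, ids))
  vals <- runif(15 * 14 / 2, -0.6, 0.6)
  r[upper.tri(r)] <- vals
  r <- r + t(r); diag(r) <- 1
  cor <- AirwayNet:::newCorrelationResult(r, "sparcc")
  sens <- thresholdSensitivity(cor, thresholds = c(0.2, 0.3, 0.4),
                               alpha = 1)
  expect_true(all(diff(sens$topology$edges) <= 0))
  expect_equal(unname(diag(sens$jaccard)), rep(1, 3))
  expect_true(all(sens$jaccard >= 0 & sens$jaccard <= 1, na.rm = TRUE))
})
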