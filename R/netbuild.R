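#' Down-sample every group to a common size
#'
#' Reduces each group's sample set to exactly `targetN` by seeded sampling
#' without replacement (default: the smallest group size), so per-group
#' network estimates rest on equal sample support.
#'
#' @param ae an [AmpliconExperiment-class] with a `grade` column.
#' @param targetN samples per group; default `min(group sizes)`.
#' @param seed integer RNG seed.
#' @return named list of [AmpliconExperiment-class], one per grade present.
#' @export
downsampleGroups <- function(ae, targetN = NULL, seed = NULL) {
  grades <- sampleGrades(ae)
  if (is.null(grades)) stop("metadata has no 'grade' column")
  tab <- table(grades)
  tab <- tab[tab > 0]
  if (is.null(targetN)) targetN <- min(tab)
  small <- names(tab)[tab < targetN]
  if (length(small))
    stop("group smaller than targetN = ", targetN, ": ", small[1L])
  withSeed(seed, {
    out <- lapply(names(tab), function(g) {
      idx <- which(grades == g)
      if (length(idx) > targetN) idx <- sort(sample(idx, targetN))
      subsetSamples(ae, idx)
    })
    names(out) <- names(tab)
    out
  })
}

#' Build a co-occurrence network from a correlation result
#'
#' Retains edge (i, j) iff |r_ij| > `threshold` (strict) AND p_ij <
#' `alpha`; isolated nodes are dropped, so the node count is the number of
#' taxa with at least one retained edge. If the correlation result carries
#' no p values (all NA), the p clause is skipped.
#'
#' @param cor a [CorrelationResult-class].
#' @param threshold |r| cutoff in (0, 1) (default 0.3).
#' @param alpha edge significance level (default 0.05).
#' @param abundance optional named vector of mean relative abundances
#'   stored as a node attribute.
#' @param group group label recorded on the network.
#' @return a [CoNetwork-class].
#' @export
buildNetwork <- function(cor, threshold = 0.3, alpha = 0.05,
                         abundance = NULL, group = NA_character_) {
  stopifnot(threshold > 0, threshold < 1, alpha > 0, alpha <= 1)
  r <- cor@r
  p <- cor@p
  keep <- abs(r) > threshold
  if (!all(is.na(p))) keep <- keep & !is.na(p) & (p < alpha)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ids <- cor@taxonIds
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1L], idx[, 2L]))
    igraph::E(g)$r <- r[idx]
  }
  if (!is.null(abundance))
    igraph::V(g)$abundance <- unname(abundance[ids])
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  methods::new("CoNetwork", graph = g, threshold = threshold,
               group = as.character(group))
}

#' Topology profile of a co-occurrence network
#'
#' Path metrics are averaged over connected node pairs only; the diameter
#' is the longest shortest path over connected pairs. In
#' `"dissimilarity_weighted"` mode each edge has length 1 - |r|. The
#' clustering coefficient is the global transitivity (3 x triangles /
#' triads), with the mean local coefficient also reported. Modularity is
#' the value of a seeded Louvain partition. Centralizations use Freeman's
#' form (sum of differences from the most central node, normalized by the
#' star-graph theoretical maximum). An empty network yields nodes = 0 with
#' all other metrics NA.
#'
#' @param net a [CoNetwork-class].
#' @param mode `"unweighted"` (default) or `"dissimilarity_weighted"`.
#' @param seed integer seed for the community detection.
#' @return one-row data.frame (see fields in the source of
#'   `emptyTopology()`).
#' @export
networkTopology <- function(net, mode = c("unweighted",
                                          "dissimilarity_weighted"),
                            seed = 1L) {
  mode <- match.arg(mode)
  g <- net@graph
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N == 0L) return(emptyTopology())
  ## the whole profile runs under the seed: community detection and the
  ## ARPACK eigenvector solver both draw random starts
  withSeed(seed, networkTopologyImpl(g, E, N, mode))
}

networkTopologyImpl <- function(g, E, N, mode) {
  w <- if (mode == "dissimilarity_weighted") 1 - abs(igraph::E(g)$r)
       else rep(1, E)
  dm <- igraph::distances(g, weights = if (E) w else NULL)
  finite <- is.finite(dm) & upper.tri(dm)
  apl <- if (any(finite)) mean(dm[finite]) else NA_real_
  diam <- if (any(finite)) max(dm[finite]) else NA_real_
  memb <- igraph::cluster_louvain(g)
  knn <- igraph::knn(g, weights = NA)$knn
  data.frame(
    nodes = N, edges = E,
    average_degree = 2 * E / N,
    average_path_length = apl,
    diameter = diam,
    density = if (N > 1) E / (N * (N - 1) / 2) else NA_real_,
    clustering_coefficient = igraph::transitivity(g, type = "global"),
    clustering_local_mean = igraph::transitivity(
      g, type = "localaverage", isolates = "zero"),
    modularity = if (E) igraph::modularity(memb) else NA_real_,
    degree_centralization =
      igraph::centr_degree(g, loops = FALSE)$centralization,
    betweenness_centralization =
      igraph::centr_betw(g, directed = FALSE)$centralization,
    closeness_centralization =
      suppressWarnings(igraph::centr_clo(g, mode = "all")$centralization),
    eigenvector_centralization =
      igraph::centr_eigen(g, directed = FALSE)$centralization,
    degree_assortativity =
      if (E > 1) igraph::assortativity_degree(g) else NA_real_,
    average_nearest_neighbor_degree = mean(knn[is.finite(knn)]))
}

emptyTopology <- function() {
  data.frame(nodes = 0L, edges = 0L, average_degree = NA_real_,
             average_path_length = NA_real_, diameter = NA_real_,
             density = NA_real_, clustering_coefficient = NA_real_,
             clustering_local_mean = NA_real_, modularity = NA_real_,
             degree_centralization = NA_real_,
             betweenness_centralization = NA_real_,
             closeness_centralization = NA_real_,
             eigenvector_centralization = NA_real_,
             degree_assortativity = NA_real_,
             average_nearest_neighbor_degree = NA_real_)
}

#' Keystone-taxon composite scores
#'
#' Keystones display high degree, high closeness, high local transitivity
#' and low betweenness. Each centrality is z-scored within the network and
#' combined as `wDeg z(degree) + wClose z(closeness) + wTrans
#' z(transitivity) - wBetw z(betweenness)`; the top `ceiling(0.10 N)` nodes
#' are flagged, ties broken by higher degree then lexicographic id.
#'
#' @param net a [CoNetwork-class].
#' @param weights non-negative `c(wDeg, wClose, wTrans, wBetw)`, default
#'   equal.
#' @param topFraction fraction of nodes flagged (default 0.10).
#' @param seed integer seed fixing the eigenvector solver's random start.
#' @return data.frame per node: `degree`, `betweenness`, `closeness`,
#'   `eigenvector`, `local_transitivity`, `keystone_composite`,
#'   `keystone_flag`.
#' @export
keystoneScores <- function(net, weights = c(0.25, 0.25, 0.25, 0.25),
                           topFraction = 0.10, seed = 1L) {
  stopifnot(length(weights) == 4L, all(weights >= 0))
  if (sum(weights) == 0) stop("at least one keystone weight must be > 0")
  g <- net@graph
  N <- igraph::vcount(g)
  if (N == 0L)
    return(data.frame(degree = numeric(0), betweenness = numeric(0),
                      closeness = numeric(0), eigenvector = numeric(0),
                      local_transitivity = numeric(0),
                      keystone_composite = numeric(0),
                      keystone_flag = logical(0)))
  deg <- igraph::degree(g)
  betw <- igraph::betweenness(g, weights = NA)
  clo <- suppressWarnings(igraph::closeness(g, mode = "all"))
  clo[!is.finite(clo)] <- 0
  eig <- withSeed(seed, igraph::eigen_centrality(g)$vector)
  trans <- igraph::transitivity(g, type = "local", isolates = "zero")
  zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / sd(x)
  composite <- weights[1] * zs(deg) + weights[2] * zs(clo) +
    weights[3] * zs(trans) - weights[4] * zs(betw)
  ids <- igraph::V(g)$name
  k <- ceiling(topFraction * N)
  ord <- order(-composite, -deg, ids)
  flag <- logical(N)
  flag[ord[seq_len(k)]] <- TRUE
  data.frame(degree = deg, betweenness = betw, closeness = as.numeric(clo),
             eigenvector = eig, local_transitivity = trans,
             keystone_composite = composite, keystone_flag = flag,
             row.names = ids)
}

#' Multi-threshold sensitivity analysis
#'
#' Rebuilds the network at each |r| threshold and reports per-threshold
#' topology, keystone sets, and the pairwise Jaccard similarity of the
#' keystone sets across thresholds.
#'
#' @param cor a [CorrelationResult-class].
#' @param thresholds at least two |r| cutoffs (default 0.2, 0.3, 0.4).
#' @param alpha edge significance level.
#' @param weights keystone weights (see [keystoneScores()]).
#' @return list with `topology` (one row per threshold), `keystones`
#'   (named list of id vectors) and `jaccard` (symmetric matrix).
#' @export
thresholdSensitivity <- function(cor, thresholds = c(0.2, 0.3, 0.4),
                                 alpha = 0.05,
                                 weights = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(length(thresholds) >= 2L)
  nets <- lapply(thresholds, function(th)
    buildNetwork(cor, threshold = th, alpha = alpha))
  topo <- do.call(rbind, lapply(nets, networkTopology))
  topo <- cbind(threshold = thresholds, topo)
  keys <- lapply(nets, function(nt) {
    ks <- keystoneScores(nt, weights)
    rownames(ks)[ks$keystone_flag]
  })
  names(keys) <- as.character(thresholds)
  J <- outer(seq_along(keys), seq_along(keys),
             Vectorize(function(i, j) jaccardIndex(keys[[i]], keys[[j]])))
  dimnames(J) <- list(names(keys), names(keys))
  list(topology = topo, keystones = keys, jaccard = J)
}
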