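#' Permutation comparison of two group networks
#'
#' The observed statistic per topology metric is the difference between the
#' two group networks built under identical pipeline settings. The null
#' pools the samples of both groups, re-splits them at the original sizes,
#' rebuilds both networks, and records |difference|; p = (1 +
#' #\{|diff_perm| >= |diff_obs|\}) / (nValid + 1), where permutations in
#' which a metric is undefined (e.g., an empty network) are excluded from
#' its count.
#'
#' By default the networks inside the permutation loop are rebuilt at
#' reduced fidelity (`nOuter = 5`, no per-edge significance resampling);
#' raise `nOuter` / `nResamples` for full fidelity.
#'
#' @param aeA,aeB [AmpliconExperiment-class] objects sharing the taxon
#'   universe.
#' @param metrics topology columns to compare (see [networkTopology()]).
#' @param nPerm permutations (default 1000).
#' @param seed integer RNG seed.
#' @param threshold,alpha network construction settings.
#' @param nOuter SparCC outer iterations inside the loop.
#' @param nResamples per-edge significance resamples inside the loop (0 =
#'   threshold-only).
#' @param method `"sparcc"` or `"spearman"` correlation.
#' @return list with `observed` (per-group metric values and differences),
#'   `p` (named vector), `nPerm`, `nValid`.
#' @export
permuteCompare <- function(aeA, aeB,
                           metrics = c("edges", "density",
                                       "average_degree",
                                       "average_path_length",
                                       "clustering_coefficient",
                                       "modularity"),
                           nPerm = 1000L, seed = NULL,
                           threshold = 0.3, alpha = 0.05,
                           nOuter = 5L, nResamples = 0L,
                           method = c("sparcc", "spearman")) {
  method <- match.arg(method)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  cA <- countMatrix(aeA); cB <- countMatrix(aeB)
  if (!identical(rownames(cA), rownames(cB)))
    stop("the two tables must share the same taxon universe")
  nA <- ncol(cA)
  pooled <- cbind(cA, cB)
  ## count-based metrics need no graph library inside the permutation loop
  fastSet <- c("nodes", "edges", "density", "average_degree")
  fast <- all(metrics %in% fastSet) && nResamples == 0L
  metricVec <- function(m) {
    if (fast) {
      ## skip container construction inside the permutation loop
      r <- if (method == "sparcc") sparccPointEstimate(m, nOuter)
           else spearmanOnCounts(m)
      return(edgeCountMetricsRaw(r, NULL, threshold, alpha)[metrics])
    }
    cor <- groupCorrelation(m, nOuter, nResamples, method)
    topo <- networkTopology(buildNetwork(cor, threshold = threshold,
                                         alpha = alpha))
    unlist(topo[1L, metrics])
  }
  withSeed(seed, {
    obsA <- metricVec(cA)
    obsB <- metricVec(cB)
    dObs <- obsA - obsB
    hits <- setNames(numeric(length(metrics)), metrics)
    valid <- setNames(numeric(length(metrics)), metrics)
    for (b in seq_len(nPerm)) {
      idx <- sample.int(ncol(pooled))
      dPerm <- metricVec(pooled[, idx[seq_len(nA)], drop = FALSE]) -
        metricVec(pooled[, idx[-seq_len(nA)], drop = FALSE])
      ok <- !is.na(dPerm) & !is.na(dObs)
      valid[ok] <- valid[ok] + 1
      hits[ok] <- hits[ok] + (abs(dPerm[ok]) >= abs(dObs[ok]))
    }
    p <- (1 + hits) / (valid + 1)
    p[is.na(dObs)] <- NA_real_
    list(observed = data.frame(metric = metrics, groupA = unname(obsA),
                               groupB = unname(obsB),
                               difference = unname(dObs)),
         p = p, nPerm = nPerm, nValid = valid)
  })
}

## correlation estimate (optionally with significance) for one count table
groupCorrelation <- function(counts, nOuter, nResamples, method) {
  cor <- if (method == "sparcc") {
    newCorrelationResult(sparccPointEstimate(counts, nOuter),
                         method = "sparcc",
                         nOuterIterations = as.integer(nOuter))
  } else {
    spearmanCorrelation(counts)
  }
  if (nResamples > 0L)
    cor <- edgeSignificance(counts, cor, nResamples = nResamples,
                            nOuterResample = nOuter)
  cor
}

## correlation -> thresholded network -> topology, for one count table
groupTopology <- function(counts, threshold, alpha, nOuter, nResamples,
                          method) {
  cor <- groupCorrelation(counts, nOuter, nResamples, method)
  networkTopology(buildNetwork(cor, threshold = threshold, alpha = alpha))
}

## nodes/edges/density/average degree straight from the matrices
edgeCountMetrics <- function(cor, threshold, alpha)
  edgeCountMetricsRaw(cor@r, cor@p, threshold, alpha)

edgeCountMetricsRaw <- function(r, p, threshold, alpha) {
  keep <- abs(r) > threshold
  if (!is.null(p) && !all(is.na(p)))
    keep <- keep & !is.na(p) & (p < alpha)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  E <- sum(keep)
  deg <- rowSums(keep) + colSums(keep)
  N <- sum(deg > 0)
  c(nodes = N, edges = E,
    density = if (N > 1) E / (N * (N - 1) / 2) else NA_real_,
    average_degree = if (N > 0) 2 * E / N else NA_real_)
}

#' Jaccard similarity of most-central node sets
#'
#' Each network contributes its nodes whose centrality exceeds that
#' network's empirical `quantile`; J = |A intersect B| / |A union B|. Tail
#' probabilities come from the hypergeometric model of random overlap over
#' the union of the two node universes.
#'
#' @param netA,netB non-empty [CoNetwork-class] objects.
#' @param measure `"degree"`, `"betweenness"`, `"closeness"` or
#'   `"eigenvector"`.
#' @param quantile cutoff defining "most central" (default 0.75).
#' @return list with `jaccard`, `pLe`, `pGe`, `setA`, `setB`; `jaccard` is
#'   NA if either top set is empty.
#' @export
jaccardCentral <- function(netA, netB,
                           measure = c("degree", "betweenness",
                                       "closeness", "eigenvector"),
                           quantile = 0.75) {
  measure <- match.arg(measure)
  if (igraph::vcount(netA@graph) == 0L || igraph::vcount(netB@graph) == 0L)
    stop("both networks must be non-empty")
  topSet <- function(net) {
    g <- net@graph
    v <- switch(measure,
      degree = igraph::degree(g),
      betweenness = igraph::betweenness(g, weights = NA),
      closeness = {
        x <- suppressWarnings(igraph::closeness(g, mode = "all"))
        x[!is.finite(x)] <- 0; x
      },
      eigenvector = withSeed(1L, igraph::eigen_centrality(g)$vector))
    igraph::V(g)$name[v > stats::quantile(v, quantile)]
  }
  A <- topSet(netA); B <- topSet(netB)
  if (!length(A) || !length(B))
    return(list(jaccard = NA_real_, pLe = NA_real_, pGe = NA_real_,
                setA = A, setB = B))
  universe <- union(igraph::V(netA@graph)$name,
                    igraph::V(netB@graph)$name)
  N <- length(universe); K <- length(A); n <- length(B)
  k <- length(intersect(A, B))
  list(jaccard = jaccardIndex(A, B),
       pLe = phyper(k, K, N - K, n),
       pGe = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       setA = A, setB = B)
}

#' Network dissimilarity coefficient (D-measure)
#'
#' A structural distance in \[0, 1\] combining (i) the Jensen-Shannon
#' divergence between the networks' mean node-distance distributions, (ii)
#' the difference in network node dispersion (the within-graph heterogeneity
#' of node-distance distributions, normalized by log(diameter + 1)), and
#' (iii) the divergence of alpha-centrality profiles of the graphs and
#' their complements. D(G, G) = 0 and D is symmetric; the triangle
#' inequality is not asserted.
#'
#' @param netA,netB non-empty [CoNetwork-class] objects.
#' @param weights the three component weights; must sum to 1 (default 0.45,
#'   0.45, 0.10).
#' @return scalar dissimilarity.
#' @export
networkDissimilarity <- function(netA, netB,
                                 weights = c(0.45, 0.45, 0.10)) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  gA <- netA@graph; gB <- netB@graph
  if (igraph::vcount(gA) == 0L || igraph::vcount(gB) == 0L)
    stop("both networks must be non-empty")
  ddA <- distanceDistributions(gA)
  ddB <- distanceDistributions(gB)
  term1 <- sqrt(jsDivergence(ddA$mu, ddB$mu) / log(2))
  term2 <- abs(sqrt(ddA$nnd) - sqrt(ddB$nnd))
  pa <- function(g) sort(alphaProfile(g))
  term3 <- (sqrt(jsDivergence(pa(gA), pa(gB)) / log(2)) +
            sqrt(jsDivergence(pa(igraph::complementer(gA)),
                              pa(igraph::complementer(gB))) / log(2))) / 2
  weights[1] * term1 + weights[2] * term2 + weights[3] * term3
}

## per-node distance distributions, their mean, and network node dispersion
distanceDistributions <- function(g) {
  N <- igraph::vcount(g)
  dm <- igraph::distances(g)
  if (N == 1L)
    return(list(mu = 1, nnd = 0))
  bins <- seq_len(N)  # distance 1..N-1 plus bin N for unreachable
  P <- t(vapply(seq_len(N), function(i) {
    d <- dm[i, -i]
    d[!is.finite(d)] <- N
    tabulate(pmin(d, N), nbins = N) / (N - 1)
  }, numeric(N)))
  mu <- colMeans(P)
  finite <- dm[is.finite(dm) & dm > 0]
  diam <- if (length(finite)) max(finite) else 1
  J <- entropyNat(mu) - mean(apply(P, 1L, entropyNat))
  list(mu = mu, nnd = max(0, J) / log(diam + 1))
}

## alpha-centrality profile as a probability vector
alphaProfile <- function(g) {
  N <- igraph::vcount(g)
  x <- igraph::alpha_centrality(g, alpha = 1 / N, exo = 1)
  x <- abs(x)
  x / sum(x)
}

#' Edge-set agreement between two correlation methods
#'
#' Builds both networks at identical threshold and alpha and reports the
#' edge counts and the Jaccard index of the edge sets (edges as unordered
#' taxon pairs).
#'
#' @param corA,corB [CorrelationResult-class] objects over the same taxon
#'   universe.
#' @param threshold,alpha network construction settings.
#' @return list with `edgesA`, `edgesB`, `shared`, `jaccard`.
#' @export
methodAgreement <- function(corA, corB, threshold = 0.3, alpha = 0.05) {
  if (!identical(corA@taxonIds, corB@taxonIds))
    stop("correlation results cover different taxa")
  edgeKeys <- function(cor) {
    g <- buildNetwork(cor, threshold = threshold, alpha = alpha)@graph
    if (igraph::ecount(g) == 0L) return(character(0))
    el <- igraph::as_edgelist(g, names = TRUE)
    apply(el, 1L, function(e) paste(sort(e), collapse = "|"))
  }
  eA <- edgeKeys(corA); eB <- edgeKeys(corB)
  list(edgesA = length(eA), edgesB = length(eB),
       shared = length(intersect(eA, eB)),
       jaccard = if (length(union(eA, eB)) == 0L) NA_real_
                 else jaccardIndex(eA, eB))
}
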