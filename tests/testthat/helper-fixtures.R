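# Fixtures built in code: tiny count tables, correlation matrices and graphs.

toyCounts <- function(m = NULL) {
  if (is.null(m))
    m <- matrix(c(5, 0, 2,
                  7, 3, 0,
                  1, 1, 9), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(paste0("ASV", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

toyExperiment <- function(m = NULL) ampliconExperiment(toyCounts(m))

## symmetric correlation matrix from an upper-triangle specification
corFixture <- function(entries, ids) {
  d <- length(ids)
  r <- diag(d)
  dimnames(r) <- list(ids, ids)
  for (e in entries) r[e[[1]], e[[2]]] <- r[e[[2]], e[[1]]] <- e[[3]]
  AirwayNet:::newCorrelationResult(r, method = "sparcc")
}

## wrap an igraph (edges given r = 0.5 unless set) as a CoNetwork
asNetwork <- function(g, threshold = 0.3, group = NA_character_) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$r))
    igraph::E(g)$r <- 0.5
  methods::new("CoNetwork", graph = g, threshold = threshold,
               group = as.character(group))
}

## Floyd-Warshall all-pairs shortest hop distances (independent oracle)
floydWarshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

## brute-force betweenness by path enumeration over the FW structure
bruteBetweenness <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- igraph::all_shortest_paths(g, from = s, to = t)$vpaths
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) setdiff(as.integer(p),
                                                      c(s, t))))
    if (length(inner)) {
      tab <- table(inner)
      btw[as.integer(names(tab))] <- btw[as.integer(names(tab))] +
        as.numeric(tab) / length(paths)
    }
  }
  btw
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)
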