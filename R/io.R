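#' Read an ASV count table from TSV
#'
#' Tab-separated with a header row; the first column holds row identifiers.
#' Either orientation is accepted; internally taxa are stored as rows.
#'
#' @param path file path.
#' @param orientation `"taxa_as_rows"` (default) or `"samples_as_rows"`.
#' @return an [AmpliconExperiment-class] with counts only.
#' @export
readCountTable <- function(path,
                           orientation = c("taxa_as_rows",
                                           "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- readTsvStrict(path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate id in first column: ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate id in header: ",
         colnames(m)[duplicated(colnames(m))][1L])
  if (!is.numeric(m)) stop("non-numeric entries in count table")
  if (any(m < 0)) stop("negative count entries are not allowed")
  if (!isWholeNumber(as.vector(m))) stop("non-integer count entries")
  rownames(m) <- ids
  if (orientation == "samples_as_rows") m <- t(m)
  ampliconExperiment(m)
}

#' Write a count table to TSV
#' @param ae an [AmpliconExperiment-class].
#' @param path output file.
#' @param orientation row orientation for the file.
#' @export
writeCountTable <- function(ae, path,
                            orientation = c("taxa_as_rows",
                                            "samples_as_rows")) {
  orientation <- match.arg(orientation)
  m <- countMatrix(ae)
  if (orientation == "samples_as_rows") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' First column = taxon id; remaining columns = ranked lineage
#' (domain..genus); missing ranks may be empty.
#' @param path file path.
#' @return data.frame, rownames = taxon ids.
#' @export
readTaxonomyTable <- function(path) {
  df <- readTsvStrict(path, numeric = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate taxon id: ", ids[duplicated(ids)][1L])
  out <- df[, -1L, drop = FALSE]
  if (ncol(out) > 6L) stop("lineage has more than 6 ranks")
  rownames(out) <- ids
  out
}

#' Read sample metadata from TSV
#'
#' First column = sample id; a `grade` column is coerced to the ordered
#' 4-level factor.
#' @param path file path.
#' @return data.frame, rownames = sample ids.
#' @export
readSampleMetadata <- function(path) {
  df <- readTsvStrict(path, numeric = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1L])
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  if ("grade" %in% colnames(out)) {
    bad <- setdiff(unique(out$grade), gradeLevels())
    if (length(bad)) stop("unknown grade label: ", bad[1L])
    out$grade <- factor(out$grade, levels = gradeLevels(), ordered = TRUE)
  }
  out
}

## strict TSV reader: header row, rectangular, first column ids
readTsvStrict <- function(path, numeric = TRUE) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  ## count separators, not fields: strsplit drops trailing empties
  nfield <- vapply(gregexpr("\t", lines, fixed = TRUE),
                   function(x) if (x[1L] == -1L) 1L else length(x) + 1L,
                   integer(1))
  if (length(unique(nfield)) != 1L) {
    bad <- which(nfield != nfield[1L])[1L]
    stop("ragged row at line ", bad, " of ", path)
  }
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a co-occurrence network to disk
#'
#' GraphML preserves typed node/edge/graph attributes (including the |r|
#' threshold and group label); the 3-column edge list
#' (`taxon_a`, `taxon_b`, `r`) is provided for diffability.
#'
#' @param net a [CoNetwork-class].
#' @param path output file.
#' @param format `"graphml"` or `"edge_list_tsv"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml",
                                               "edge_list_tsv")) {
  if (!format[1L] %in% c("graphml", "edge_list_tsv"))
    stop("unknown format '", format[1L],
         "'; supported: graphml, edge_list_tsv")
  format <- match.arg(format)
  g <- net@graph
  if (format == "graphml") {
    g <- igraph::set_graph_attr(g, "threshold", net@threshold)
    g <- igraph::set_graph_attr(g, "group", as.character(net@group))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    df <- data.frame(taxon_a = el[, 1L], taxon_b = el[, 2L],
                     r = if (igraph::ecount(g)) igraph::E(g)$r else numeric(0))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a co-occurrence network written by [writeNetwork()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge_list_tsv"`.
#' @param threshold required for edge-list input (GraphML stores it).
#' @param group group label for edge-list input.
#' @return a [CoNetwork-class].
#' @export
readNetwork <- function(path, format = c("graphml", "edge_list_tsv"),
                        threshold = NULL, group = NA_character_) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::delete_vertex_attr(g, "id")
    thr <- igraph::graph_attr(g, "threshold")
    grp <- igraph::graph_attr(g, "group")
    g <- igraph::delete_graph_attr(g, "threshold")
    g <- igraph::delete_graph_attr(g, "group")
    methods::new("CoNetwork", graph = g, threshold = as.numeric(thr),
                 group = as.character(grp))
  } else {
    if (is.null(threshold))
      stop("threshold must be supplied for edge-list input")
    df <- read.delim(path, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      df[, c("taxon_a", "taxon_b")], directed = FALSE)
    igraph::E(g)$r <- df$r
    methods::new("CoNetwork", graph = g, threshold = threshold,
                 group = as.character(group))
  }
}

#' @describeIn CoNetwork-class compact display.
#' @param object a CoNetwork.
#' @export
setMethod("show", "CoNetwork", function(object) {
  g <- object@graph
  cat("CoNetwork (group ", object@group, "): ",
      igraph::vcount(g), " nodes, ", igraph::ecount(g),
      " edges, |r| > ", object@threshold, "\n", sep = "")
  invisible(NULL)
})

#' @describeIn CorrelationResult-class compact display.
#' @param object a CorrelationResult.
#' @export
setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult (", object@method, "): ",
      length(object@taxonIds), " taxa; ",
      object@nOuterIterations, " outer iterations, ",
      object@nResamples, " ", object@resamplingMode, " resamples\n",
      sep = "")
  invisible(NULL)
})
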