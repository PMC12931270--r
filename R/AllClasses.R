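#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' AmpliconExperiment: a validated amplicon count container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `"counts"`
#' assay holding non-negative integer read counts with taxa (ASVs) as rows
#' and samples as columns. Taxonomic lineages (domain..genus) live in
#' `rowData`; sample metadata — including the ordinal disease grade — in
#' `colData`.
#'
#' Validity requires: a `"counts"` assay of non-negative, integral values;
#' unique, non-empty taxon and sample identifiers.
#'
#' @seealso [ampliconExperiment()] for construction,
#'   [readCountTable()] for reading from TSV.
#' @export
setClass("AmpliconExperiment", contains = "SummarizedExperiment")

setValidity("AmpliconExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(m)))
    return(paste0("duplicate taxon id: ",
                  rownames(m)[duplicated(rownames(m))][1L]))
  if (anyDuplicated(colnames(m)))
    return(paste0("duplicate sample id: ",
                  colnames(m)[duplicated(colnames(m))][1L]))
  if (any(!is.finite(m)) || any(m < 0))
    return("counts must be finite and non-negative")
  if (!isWholeNumber(as.vector(m)))
    return("counts must be integral")
  TRUE
})

#' CorrelationResult: pairwise taxon correlations with edge significance
#'
#' Symmetric taxon-by-taxon correlation estimates (`r`, unit diagonal,
#' entries in \[-1, 1\]) with per-pair pseudo-p values (`p`, in (0, 1\],
#' diagonal NA) and resampling provenance.
#'
#' @slot taxonIds character, taxon identifiers (row/column order of `r`).
#' @slot r symmetric correlation matrix.
#' @slot p symmetric p-value matrix (all-NA until significance is computed).
#' @slot method `"sparcc"` or `"spearman"`.
#' @slot nOuterIterations integer, outer (Dirichlet) iterations used.
#' @slot nResamples integer, significance resamples used (0 if none).
#' @slot resamplingMode `"permutation"`, `"bootstrap"` or `"none"`.
#' @export
setClass("CorrelationResult",
  representation(taxonIds = "character", r = "matrix", p = "matrix",
                 method = "character", nOuterIterations = "integer",
                 nResamples = "integer", resamplingMode = "character"))

setValidity("CorrelationResult", function(object) {
  r <- object@r; p <- object@p
  d <- length(object@taxonIds)
  if (!all(dim(r) == d) || !all(dim(p) == d))
    return("r and p must be square over taxonIds")
  if (anyDuplicated(object@taxonIds)) return("duplicate taxon ids")
  if (max(abs(r - t(r))) > 1e-8) return("r must be symmetric")
  if (any(abs(r) > 1 + 1e-8)) return("|r| must be <= 1")
  if (d > 0 && max(abs(diag(r) - 1)) > 1e-8) return("diag(r) must be 1")
  off <- p[upper.tri(p)]
  off <- off[!is.na(off)]
  if (length(off) && (any(off <= 0) || any(off > 1)))
    return("off-diagonal p must lie in (0, 1]")
  pt <- p; diag(pt) <- 0
  if (d > 1 && !isTRUE(all.equal(pt, t(pt), tolerance = 1e-8)))
    return("p must be symmetric")
  if (!object@method %in% c("sparcc", "spearman"))
    return("method must be 'sparcc' or 'spearman'")
  TRUE
})

#' CoNetwork: a thresholded microbial co-occurrence network
#'
#' An undirected simple graph whose nodes are taxa (with a mean
#' relative-abundance attribute where available) and whose edges are
#' retained correlations with signed weight `r`. The |r| threshold that
#' produced the network and the group label are recorded.
#'
#' @slot graph an `igraph` object; edge attribute `r`, optional node
#'   attribute `abundance`.
#' @slot threshold numeric |r| cutoff; every retained edge has |r| >
#'   threshold.
#' @slot group character label of the cohort subgroup (may be `NA`).
#' @export
setClass("CoNetwork",
  representation(graph = "ANY", threshold = "numeric", group = "character"))

setValidity("CoNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    return("graph must be simple (no loops or multi-edges)")
  if (igraph::ecount(g) > 0) {
    r <- igraph::E(g)$r
    if (is.null(r)) return("edges must carry attribute 'r'")
    if (any(abs(r) > 1 + 1e-8)) return("edge r must lie in [-1, 1]")
    if (any(abs(r) <= object@threshold))
      return("every edge must satisfy |r| > threshold")
  }
  if (length(object@threshold) != 1L || object@threshold < 0)
    return("threshold must be a single non-negative number")
  TRUE
})

#' OrdinalFit: a fitted proportional-odds model
#'
#' Result of maximizing the proportional-odds likelihood
#' logit P(Y <= k) = theta_k - x'beta by damped Newton iterations, so a
#' positive coefficient (odds ratio > 1) means higher odds of a more severe
#' grade.
#'
#' @slot coefficients named numeric, slopes beta.
#' @slot se named numeric, Wald standard errors from the observed
#'   information (slopes only).
#' @slot oddsRatios exp(beta).
#' @slot cutpoints strictly increasing theta.
#' @slot logLik maximized log-likelihood.
#' @slot converged logical.
#' @slot iterations integer Newton iterations used.
#' @slot dropped data.frame of covariates excluded during stepwise
#'   selection with the reason (singular information / non-convergence).
#' @slot fitted n x K matrix of category probabilities.
#' @slot pValues two-sided Wald p-values for the slopes.
#' @slot singularInfo TRUE when the observed information was numerically
#'   singular at the final iterate.
#' @export
setClass("OrdinalFit",
  representation(coefficients = "numeric", se = "numeric",
                 oddsRatios = "numeric", cutpoints = "numeric",
                 logLik = "numeric", converged = "logical",
                 iterations = "integer", dropped = "data.frame",
                 fitted = "matrix", pValues = "numeric",
                 singularInfo = "logical"))

setValidity("OrdinalFit", function(object) {
  th <- object@cutpoints
  if (length(th) > 1 && any(diff(th) <= 0))
    return("cutpoints must be strictly increasing")
  if (any(object@oddsRatios <= 0)) return("odds ratios must be positive")
  TRUE
})
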