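#' Remove singleton taxa
#'
#' Drops every taxon whose grand total count across all samples is exactly
#' one, the standard guard against sequencing artifacts.
#'
#' @param ae an [AmpliconExperiment-class].
#' @return the filtered [AmpliconExperiment-class]; samples unchanged.
#' @export
removeSingletons <- function(ae) {
  keep <- rowSums(countMatrix(ae)) >= 2
  subsetTaxa(ae, keep)
}

#' Remove organelle (mitochondrial / chloroplast) taxa
#'
#' Drops taxa whose lineage contains "mitochondria" or "chloroplast" as a
#' case-insensitive substring at any rank.
#'
#' @param ae an [AmpliconExperiment-class] whose rowData holds the lineage
#'   ranks, or supply `taxonomy` explicitly.
#' @param taxonomy optional data.frame of lineage ranks (rownames = taxon
#'   ids) overriding rowData.
#' @return the filtered [AmpliconExperiment-class].
#' @export
removeOrganelles <- function(ae, taxonomy = NULL) {
  if (is.null(taxonomy)) taxonomy <- taxonomyTable(ae)
  ids <- rownames(countMatrix(ae))
  missing <- setdiff(ids, rownames(taxonomy))
  if (length(missing))
    stop("taxon missing from taxonomy: ", missing[1L])
  lineage <- apply(taxonomy[ids, , drop = FALSE], 1L, function(x)
    paste(as.character(x), collapse = ";"))
  hit <- grepl("mitochondria", lineage, ignore.case = TRUE) |
    grepl("chloroplast", lineage, ignore.case = TRUE)
  subsetTaxa(ae, !hit)
}

#' Rarefy samples to a common depth
#'
#' Samples below the target depth are dropped (with a warning); remaining
#' samples are subsampled without replacement to exactly `depth` reads.
#' Deterministic under `seed`.
#'
#' @param ae an [AmpliconExperiment-class].
#' @param depth target read depth (> 0).
#' @param seed integer RNG seed.
#' @return the rarefied [AmpliconExperiment-class].
#' @export
rarefyCounts <- function(ae, depth = 22000, seed = NULL) {
  stopifnot(depth > 0)
  d <- sampleDepths(ae)
  keep <- d >= depth
  if (!any(keep))
    stop("all samples are below the rarefaction depth ", depth)
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(head(names(d)[!keep], 5L), collapse = ", "))
  ae <- subsetSamples(ae, keep)
  m <- countMatrix(ae)
  ## rrarefy's advisory warning about count magnitudes is noise here; the
  ## dropped-sample warning above is the one that matters
  sub <- withSeed(seed, t(suppressWarnings(vegan::rrarefy(t(m), depth))))
  out <- ae
  SummarizedExperiment::assay(out, "counts") <- sub
  methods::validObject(out)
  out
}

#' Abundance and prevalence filter for network analysis
#'
#' Retains taxa satisfying both clauses: relative grand total strictly
#' greater than `minRelTotal` (default 0.01%) and presence (count > 0) in
#' at least `ceiling(minPrevFrac * nSamples)` samples (default 5%).
#'
#' @param ae an [AmpliconExperiment-class].
#' @param minRelTotal minimum taxon share of the table grand total
#'   (strict inequality).
#' @param minPrevFrac minimum fraction of samples with non-zero count
#'   (ceiling rule).
#' @param abundanceMode `"grand_total"` (taxon total / table total, the
#'   default) or `"sample_mean"` (mean per-sample relative abundance).
#' @return the filtered [AmpliconExperiment-class].
#' @export
abundancePrevalenceFilter <- function(ae, minRelTotal = 1e-4,
                                      minPrevFrac = 0.05,
                                      abundanceMode = c("grand_total",
                                                        "sample_mean")) {
  abundanceMode <- match.arg(abundanceMode)
  m <- countMatrix(ae)
  rel <- if (abundanceMode == "grand_total") {
    rowSums(m) / sum(m)
  } else {
    rowMeans(sweep(m, 2, colSums(m), "/"))
  }
  prevCut <- ceiling(minPrevFrac * ncol(m))
  keep <- (rel > minRelTotal) & (rowSums(m > 0) >= prevCut)
  if (!any(keep))
    stop("no taxa pass the abundance/prevalence filter; ",
         "consider relaxing minRelTotal or minPrevFrac")
  subsetTaxa(ae, keep)
}

#' Per-sample relative abundances
#'
#' @param ae an [AmpliconExperiment-class]; every sample depth must be > 0.
#' @return taxa x samples matrix of fractions; each column sums to 1.
#' @export
relativeAbundance <- function(ae) {
  m <- countMatrix(ae)
  d <- colSums(m)
  if (any(d <= 0))
    stop("zero-depth sample: ", colnames(m)[which(d <= 0)[1L]])
  sweep(m, 2, d, "/")
}
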