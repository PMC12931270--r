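#' Construct an AmpliconExperiment
#'
#' @param counts numeric matrix of non-negative integer read counts, taxa as
#'   rows and samples as columns (both dimnames required).
#' @param taxonomy optional data.frame of lineage ranks (subset of
#'   domain, phylum, class, order, family, genus), one row per taxon;
#'   missing ranks may be empty strings.
#' @param metadata optional data.frame of per-sample covariates; a column
#'   `grade` is coerced to an ordered factor with levels
#'   `c("non", "I", "II", "III")` when present.
#' @return an [AmpliconExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
#' ae <- ampliconExperiment(m)
#' sampleDepths(ae)
#' @export
ampliconExperiment <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "numeric"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry taxon (row) and sample (column) names")
  rowdat <- if (is.null(taxonomy)) {
    S4Vectors::DataFrame(row.names = rownames(counts))
  } else {
    taxonomy <- as.data.frame(taxonomy)
    missing <- setdiff(rownames(counts), rownames(taxonomy))
    if (length(missing))
      stop("taxon missing from taxonomy: ", missing[1L])
    S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }
  coldat <- if (is.null(metadata)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    metadata <- as.data.frame(metadata)
    missing <- setdiff(colnames(counts), rownames(metadata))
    if (length(missing))
      stop("sample missing from metadata: ", missing[1L])
    metadata <- metadata[colnames(counts), , drop = FALSE]
    if ("grade" %in% colnames(metadata))
      metadata$grade <- factor(metadata$grade, levels = gradeLevels(),
                               ordered = TRUE)
    S4Vectors::DataFrame(metadata)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rowdat, colData = coldat)
  methods::new("AmpliconExperiment", se)
}

#' Ordinal disease-grade levels
#'
#' The four-level ordered outcome used throughout: no disease, then grades
#' I, II, III of increasing severity.
#' @return character vector of level labels in increasing severity.
#' @export
gradeLevels <- function() c("non", "I", "II", "III")

#' Access the count matrix of an AmpliconExperiment
#' @param ae an [AmpliconExperiment-class].
#' @return taxa x samples numeric matrix.
#' @export
countMatrix <- function(ae) SummarizedExperiment::assay(ae, "counts")

#' Per-sample sequencing depths (column sums of counts)
#' @param ae an [AmpliconExperiment-class].
#' @return named numeric vector.
#' @export
sampleDepths <- function(ae) colSums(countMatrix(ae))

#' Taxonomic lineages as a data.frame
#' @param ae an [AmpliconExperiment-class].
#' @return data.frame with one row per taxon.
#' @export
taxonomyTable <- function(ae)
  as.data.frame(SummarizedExperiment::rowData(ae))

#' Sample metadata as a data.frame
#' @param ae an [AmpliconExperiment-class].
#' @return data.frame with one row per sample.
#' @export
sampleMetadata <- function(ae)
  as.data.frame(SummarizedExperiment::colData(ae))

#' Ordinal disease grade per sample
#' @param ae an [AmpliconExperiment-class].
#' @return ordered factor, or NULL if no `grade` column is present.
#' @export
sampleGrades <- function(ae) {
  md <- SummarizedExperiment::colData(ae)
  if (!"grade" %in% colnames(md)) return(NULL)
  md$grade
}

#' @describeIn AmpliconExperiment-class compact display.
#' @param object an AmpliconExperiment.
#' @export
setMethod("show", "AmpliconExperiment", function(object) {
  m <- countMatrix(object)
  cat("AmpliconExperiment:", nrow(m), "taxa x", ncol(m), "samples\n")
  d <- colSums(m)
  if (length(d))
    cat("  depth range:", paste(range(d), collapse = " - "), "\n")
  g <- sampleGrades(object)
  if (!is.null(g))
    cat("  grades:", paste(sprintf("%s=%d", levels(g), table(g)),
                           collapse = " "), "\n")
  invisible(NULL)
})

## internal: subset samples keeping class and metadata
subsetSamples <- function(ae, keep) {
  methods::new("AmpliconExperiment", ae[, keep])
}

## internal: subset taxa keeping class and metadata
subsetTaxa <- function(ae, keep) {
  methods::new("AmpliconExperiment", ae[keep, ])
}
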