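#' Default pipeline parameters
#'
#' One place for every analysis default: 0.01% abundance / 5% prevalence
#' filters, rarefaction depth 22,000, |r| > 0.3 with alpha = 0.05, 20 outer
#' SparCC iterations, 100 significance resamples, down-sampling to the
#' smallest group, top-10% keystones, and the comparison permutation count.
#'
#' @param ... overrides for any named default.
#' @return named list of parameters.
#' @export
pipelineParams <- function(...) {
  p <- list(minRelTotal = 1e-4, minPrevFrac = 0.05,
            rarefactionDepth = 22000, threshold = 0.3, alpha = 0.05,
            nOuter = 20L, nResamples = 100L, nOuterResample = 5L,
            significanceMode = "permutation",
            keystoneTopFraction = 0.10,
            keystoneWeights = c(0.25, 0.25, 0.25, 0.25),
            comparePermutations = 1000L, compareOuter = 5L,
            diversityPermutations = 999L,
            sensitivityThresholds = c(0.2, 0.3, 0.4))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown pipeline parameter: ", bad[1L])
  p[names(over)] <- over
  p
}

#' Run the full analysis pipeline
#'
#' Stages: input (synthetic cohort or TSV tables), preprocessing
#' (singletons, organelles, rarefaction, abundance/prevalence filter),
#' diversity statistics, per-group SparCC correlation with edge
#' significance, network construction with topology and keystone scoring
#' (plus a Spearman comparison network), pairwise network comparison, and
#' the ordinal outcome model. Each stage writes TSV/GraphML/JSON artifacts
#' under `outDir`; a manifest records parameters, seeds and artifact
#' checksums, so reruns with an identical configuration are bit-identical.
#'
#' @param outDir output directory (created if needed).
#' @param synthetic a [cohortConfig()] to simulate the cohort, or NULL to
#'   read tables.
#' @param countsPath,taxonomyPath,metadataPath input TSVs when `synthetic`
#'   is NULL.
#' @param params a [pipelineParams()] list.
#' @param seed master seed; every stage derives a named sub-seed from it.
#' @return invisibly, a list with the per-stage results and the manifest
#'   path.
#' @export
runPipeline <- function(outDir, synthetic = NULL, countsPath = NULL,
                        taxonomyPath = NULL, metadataPath = NULL,
                        params = pipelineParams(), seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(outDir, f)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  ## --- input ---------------------------------------------------------
  ae <- if (!is.null(synthetic)) {
    cfg <- synthetic
    cfg$seed <- subSeed(seed, "simulate")
    generateCohort(cfg)
  } else {
    if (is.null(countsPath)) stop("stage input: no counts supplied")
    ae0 <- readCountTable(countsPath)
    tax <- if (!is.null(taxonomyPath)) readTaxonomyTable(taxonomyPath)
    md <- if (!is.null(metadataPath)) readSampleMetadata(metadataPath)
    ampliconExperiment(countMatrix(ae0), tax, md)
  }
  note("input: ", nrow(ae), " taxa x ", ncol(ae), " samples")
  writeCountTable(ae, art("counts_raw.tsv"))

  ## --- preprocess ----------------------------------------------------
  ae1 <- removeSingletons(ae)
  note("singleton filter: ", nrow(ae) - nrow(ae1), " taxa removed")
  ae2 <- removeOrganelles(ae1)
  note("organelle filter: ", nrow(ae1) - nrow(ae2), " taxa removed")
  aeRare <- suppressWarnings(
    rarefyCounts(ae2, params$rarefactionDepth,
                 seed = subSeed(seed, "preprocess")))
  aeNet <- abundancePrevalenceFilter(ae2, params$minRelTotal,
                                     params$minPrevFrac)
  note("abundance/prevalence filter: ", nrow(aeNet), " taxa retained")
  writeCountTable(aeNet, art("counts_filtered.tsv"))

  ## --- diversity -----------------------------------------------------
  alpha <- alphaDiversity(aeRare)
  write.table(data.frame(sample = rownames(alpha), alpha),
              art("alpha_diversity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  grades <- sampleGrades(aeRare)
  divStats <- NULL
  if (!is.null(grades) && nlevels(droplevels(grades)) >= 2) {
    d <- brayCurtis(aeRare)
    sd1 <- subSeed(seed, "diversity")
    an <- anosimTest(d, grades, params$diversityPermutations, seed = sd1)
    pm <- permanovaTest(d, grades, params$diversityPermutations,
                        seed = sd1 + 1L)
    pd <- permdispTest(d, grades, params$diversityPermutations,
                       seed = sd1 + 2L)
    divStats <- data.frame(
      statistic = c("anosim_R", "permanova_pseudoF", "permanova_R2",
                    "permdisp_F"),
      value = c(an$R, pm$pseudoF, pm$R2, pd$F),
      p = c(an$p, pm$p, pm$p, pd$p),
      n_perm = params$diversityPermutations)
    write.table(divStats, art("beta_statistics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## --- correlate (per group, after down-sampling) --------------------
  sdCor <- subSeed(seed, "correlate")
  groupsList <- downsampleGroups(aeNet, seed = sdCor)
  cors <- list()
  spearmans <- list()
  for (k in seq_along(groupsList)) {
    g <- names(groupsList)[k]
    aeG <- groupsList[[k]]
    cor <- sparccCorrelation(aeG, nOuter = params$nOuter,
                             seed = sdCor + 10L * k)
    cor <- edgeSignificance(aeG, cor, nResamples = params$nResamples,
                            mode = params$significanceMode,
                            seed = sdCor + 10L * k + 1L,
                            nOuterResample = params$nOuterResample)
    cors[[g]] <- cor
    sp <- spearmanCorrelation(aeG)
    sp <- edgeSignificance(aeG, sp, nResamples = params$nResamples,
                           mode = params$significanceMode,
                           seed = sdCor + 10L * k + 2L)
    spearmans[[g]] <- sp
    writeSquareTsv(cor@r, art(paste0("sparcc_r_", g, ".tsv")))
    writeSquareTsv(cor@p, art(paste0("sparcc_p_", g, ".tsv")))
  }
  jsonlite::write_json(
    list(seed = seed, nOuter = params$nOuter,
         nResamples = params$nResamples,
         mode = params$significanceMode),
    art("correlation_meta.json"), auto_unbox = TRUE)

  ## --- networks ------------------------------------------------------
  sdNet <- subSeed(seed, "network")
  nets <- list()
  keystones <- list()
  topo <- NULL
  agree <- NULL
  for (g in names(cors)) {
    ab <- rowMeans(relativeAbundance(groupsList[[g]]))
    net <- buildNetwork(cors[[g]], params$threshold, params$alpha,
                        abundance = ab, group = g)
    nets[[g]] <- net
    writeNetwork(net, art(paste0("network_", g, ".graphml")), "graphml")
    writeNetwork(net, art(paste0("network_", g, ".tsv")), "edge_list_tsv")
    topoG <- networkTopology(net, seed = sdNet)
    topo <- rbind(topo, cbind(group = g, topoG))
    ks <- keystoneScores(net, params$keystoneWeights,
                         params$keystoneTopFraction)
    keystones[[g]] <- ks
    if (nrow(ks))
      write.table(data.frame(taxon = rownames(ks), ks),
                  art(paste0("keystones_", g, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    ma <- methodAgreement(cors[[g]], spearmans[[g]], params$threshold,
                          params$alpha)
    agree <- rbind(agree,
                   data.frame(group = g, sparcc_edges = ma$edgesA,
                              spearman_edges = ma$edgesB,
                              jaccard = ma$jaccard))
  }
  ## topology table shaped metrics x groups
  tt <- t(topo[, -1, drop = FALSE])
  colnames(tt) <- topo$group
  write.table(data.frame(feature = rownames(tt), tt),
              art("topology.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(agree, art("method_agreement.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## --- compare -------------------------------------------------------
  sdCmp <- subSeed(seed, "compare")
  gs <- names(groupsList)
  cmpRows <- NULL
  dis <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  if (length(gs) >= 2) {
    pairs <- utils::combn(gs, 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      pc <- permuteCompare(groupsList[[a]], groupsList[[b]],
                           nPerm = params$comparePermutations,
                           seed = sdCmp + k,
                           threshold = params$threshold,
                           alpha = params$alpha,
                           nOuter = params$compareOuter)
      cmpRows <- rbind(cmpRows,
                       cbind(pair = paste(a, "vs", b), pc$observed,
                             p = unname(pc$p)))
      okPair <- igraph::vcount(nets[[a]]@graph) > 0 &&
        igraph::vcount(nets[[b]]@graph) > 0
      dis[a, b] <- dis[b, a] <- if (okPair)
        networkDissimilarity(nets[[a]], nets[[b]]) else NA_real_
    }
    write.table(cmpRows, art("pairwise_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeSquareTsv(dis, art("dissimilarity_matrix.tsv"))
  }

  ## --- outcome model -------------------------------------------------
  fit <- NULL
  md <- sampleMetadata(aeNet)
  if (!is.null(grades <- sampleGrades(aeNet)) &&
      nlevels(droplevels(grades)) >= 2 && !is.null(topo)) {
    dens <- setNames(topo$density, topo$group)[as.character(grades)]
    fitTry <- tryCatch({
      base <- matrix(standardize(as.numeric(dens)), ncol = 1,
                     dimnames = list(NULL, "network_density"))
      cand <- md[, intersect(c("gender", "gestational_age",
                               "birth_weight", "delivery_mode",
                               "antibiotic_type", "ACS", "MSF", "EUGR",
                               "intrauterine_distress",
                               "length_of_stay"), colnames(md)),
                 drop = FALSE]
      forwardStepwise(droplevels(grades), base, cand)
    }, error = function(e) {
      note("outcome model skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(fitTry)) {
      fit <- fitTry
      tab <- data.frame(predictor = names(fit@coefficients),
                        beta = fit@coefficients, se = fit@se,
                        OR = fit@oddsRatios,
                        ci_low = exp(fit@coefficients - 1.96 * fit@se),
                        ci_high = exp(fit@coefficients + 1.96 * fit@se),
                        p = fit@pValues)
      write.table(tab, art("ordinal_model.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (nrow(fit@dropped))
        write.table(fit@dropped, art("ordinal_model_dropped.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## --- manifest ------------------------------------------------------
  writeLines(log, art("pipeline_log.txt"))
  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  sums <- tools::md5sum(file.path(outDir, files))
  manifest <- list(package = "AirwayNet",
                   version = as.character(utils::packageVersion("AirwayNet")),
                   seed = seed,
                   params = params,
                   artifacts = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(experiment = ae, filtered = aeNet, alpha = alpha,
                 betaStatistics = divStats, correlations = cors,
                 networks = nets, topology = topo, keystones = keystones,
                 methodAgreement = agree, comparisons = cmpRows,
                 dissimilarity = dis, ordinalFit = fit,
                 manifest = art("manifest.json")))
}

writeSquareTsv <- function(m, path) {
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
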