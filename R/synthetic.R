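#' Configure a synthetic amplicon cohort
#'
#' The generator emulates the structure the downstream analysis assumes:
#' four ordinal severity groups, log-normal basis abundances dominated by a
#' handful of taxa, multinomial read sampling at realistic depths, organelle
#' contaminant lineages, singleton ASVs, and group-specific planted
#' basis-correlation blocks whose density collapses in the most severe
#' group.
#'
#' @param groupSizes named integer vector over [gradeLevels()].
#' @param nTaxa total number of taxa, including contaminants and singletons.
#' @param depthRange integer range of per-sample read depths (uniform draw).
#' @param plantedModules named list (one entry per grade) of blocks, each a
#'   `list(size =, rho =)` giving the within-block basis correlation.
#' @param baselineLogMean,baselineLogSd log-scale basis abundance
#'   distribution for ordinary taxa.
#' @param nDominantTaxa,dominantBoost number of high-abundance taxa and the
#'   additive boost to their log-mean (emulates a community dominated by a
#'   few genera).
#' @param nContaminantTaxa taxa assigned mitochondrial/chloroplast lineages.
#' @param nSingletonTaxa taxa whose grand total count is exactly 1.
#' @param overdispersion Dirichlet-multinomial precision; 0 (default) gives
#'   plain multinomial sampling, smaller positive values give more
#'   overdispersion.
#' @param gaBase,gaSlope,bwBase,bwSlope linear grade-rank trends for
#'   gestational age (weeks) and birth weight (g).
#' @param seed integer RNG seed.
#' @return a validated list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(groupSizes = c(non = 31L, I = 31L, II = 20L,
                                        III = 16L),
                         nTaxa = 300L,
                         depthRange = c(22026L, 72630L),
                         plantedModules = list(
                           non = list(list(size = 6L, rho = 0.6)),
                           I   = list(list(size = 8L, rho = 0.6),
                                      list(size = 5L, rho = 0.5)),
                           II  = list(list(size = 12L, rho = 0.7),
                                      list(size = 6L, rho = 0.6)),
                           III = list(list(size = 3L, rho = 0.4))),
                         baselineLogMean = 0, baselineLogSd = 1,
                         nDominantTaxa = 5L, dominantBoost = 4,
                         nContaminantTaxa = 8L, nSingletonTaxa = 10L,
                         overdispersion = 0,
                         gaBase = 30.6, gaSlope = -0.9,
                         bwBase = 1500, bwSlope = -150,
                         seed = 1L) {
  stopifnot(setequal(names(groupSizes), gradeLevels()),
            all(groupSizes >= 2L),
            nTaxa >= 4L,
            length(depthRange) == 2L, all(depthRange >= 1),
            diff(depthRange) >= 0,
            overdispersion >= 0)
  nRegular <- nTaxa - nContaminantTaxa - nSingletonTaxa
  if (nRegular < 4L)
    stop("config error: fewer than 4 regular taxa after reserving ",
         "contaminants and singletons")
  for (g in names(plantedModules)) {
    if (!g %in% gradeLevels()) stop("unknown group in plantedModules: ", g)
    sizes <- vapply(plantedModules[[g]], function(b) b$size, numeric(1))
    rhos <- vapply(plantedModules[[g]], function(b) b$rho, numeric(1))
    if (any(abs(rhos) >= 1)) stop("config error: block rho must be in (-1, 1)")
    if (sum(sizes) > nRegular)
      stop("config error: planted blocks for group ", g,
           " exceed the number of regular taxa")
  }
  cfg <- list(groupSizes = groupSizes[gradeLevels()], nTaxa = as.integer(nTaxa),
              depthRange = as.integer(depthRange),
              plantedModules = plantedModules,
              baselineLogMean = baselineLogMean,
              baselineLogSd = baselineLogSd,
              nDominantTaxa = as.integer(nDominantTaxa),
              dominantBoost = dominantBoost,
              nContaminantTaxa = as.integer(nContaminantTaxa),
              nSingletonTaxa = as.integer(nSingletonTaxa),
              overdispersion = overdispersion,
              gaBase = gaBase, gaSlope = gaSlope,
              bwBase = bwBase, bwSlope = bwSlope,
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  cfg
}

genusPool <- function() c(
  "Acinetobacter", "Pseudomonas", "Sphingomonas", "Pelomonas",
  "Stenotrophomonas", "Escherichia-Shigella", "Streptococcus",
  "Chryseobacterium", "Staphylococcus", "Enterococcus", "Bacteroides",
  "Fusobacterium", "Brevundimonas", "Aquabacterium", "Devosia",
  "Ralstonia", "Delftia", "Cupriavidus", "Lactobacillus", "Prevotella")

#' Generate a synthetic cohort
#'
#' Basis abundances are drawn per sample as the exponential of a
#' multivariate normal whose correlation matrix carries the planted blocks
#' of the sample's group (identity elsewhere); fractions are the closure of
#' the basis; counts are multinomial at a uniformly drawn depth. Singleton
#' taxa receive exactly one read (carved from the most abundant taxon of a
#' random sample so depths are preserved); contaminant taxa carry
#' "Mitochondria" or "Chloroplast" lineages. Covariate means shift linearly
#' with grade rank (gestational age and birth weight decrease with
#' severity).
#'
#' @param config a [cohortConfig()].
#' @return an [AmpliconExperiment-class] with counts, taxonomy and
#'   metadata.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  withSeed(config$seed, generateCohortImpl(config))
}

generateCohortImpl <- function(cfg) {
  nTaxa <- cfg$nTaxa
  nCont <- cfg$nContaminantTaxa
  nSing <- cfg$nSingletonTaxa
  nReg <- nTaxa - nCont - nSing
  taxonIds <- sprintf("ASV%04d", seq_len(nTaxa))
  regIdx <- seq_len(nReg)
  contIdx <- if (nCont) nReg + seq_len(nCont) else integer(0)
  singIdx <- if (nSing) nReg + nCont + seq_len(nSing) else integer(0)

  ## log-mean profile: a handful of dominant taxa, then baseline; organelle
  ## contaminants at baseline so filters have work to do
  mu <- rep(cfg$baselineLogMean, nTaxa)
  nd <- min(cfg$nDominantTaxa, nReg)
  if (nd) mu[seq_len(nd)] <- cfg$baselineLogMean + cfg$dominantBoost

  groups <- rep(gradeLevels(), cfg$groupSizes)
  nSamples <- length(groups)
  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  depthSeq <- seq.int(cfg$depthRange[1], cfg$depthRange[2])
  depths <- depthSeq[sample.int(length(depthSeq), nSamples,
                                replace = TRUE)]

  counts <- matrix(0, nTaxa, nSamples,
                   dimnames = list(taxonIds, sampleIds))
  basisSd <- cfg$baselineLogSd
  for (g in gradeLevels()) {
    cols <- which(groups == g)
    if (!length(cols)) next
    C <- diag(nReg + nCont)
    blocks <- cfg$plantedModules[[g]]
    at <- nd  # plant blocks just after the dominant taxa
    for (b in seq_along(blocks)) {
      sz <- blocks[[b]]$size; rho <- blocks[[b]]$rho
      idx <- at + seq_len(sz)
      C[idx, idx] <- rho
      diag(C)[idx] <- 1
      at <- at + sz
    }
    L <- chol(C * basisSd^2)
    z <- t(L) %*% matrix(rnorm((nReg + nCont) * length(cols)),
                         nReg + nCont, length(cols))
    z <- z + mu[c(regIdx, contIdx)]
    basis <- exp(z)
    frac <- sweep(basis, 2, colSums(basis), "/")
    for (k in seq_along(cols)) {
      p <- frac[, k]
      if (cfg$overdispersion > 0) {
        a <- rgamma(length(p), shape = p * cfg$overdispersion)
        p <- a / sum(a)
      }
      counts[c(regIdx, contIdx), cols[k]] <-
        rmultinom(1, depths[cols[k]], p)
    }
  }

  ## carve singleton reads out of the largest count of a random sample
  for (s in singIdx) {
    j <- sample.int(nSamples, 1L)
    donor <- which.max(counts[, j])
    counts[donor, j] <- counts[donor, j] - 1
    counts[s, j] <- 1
  }

  taxonomy <- syntheticTaxonomy(taxonIds, regIdx, contIdx, singIdx)
  metadata <- syntheticMetadata(sampleIds, groups, cfg)
  ampliconExperiment(counts, taxonomy, metadata)
}

syntheticTaxonomy <- function(taxonIds, regIdx, contIdx, singIdx) {
  n <- length(taxonIds)
  pool <- genusPool()
  genus <- pool[1 + (seq_len(n) - 1) %% length(pool)]
  domain <- rep("Bacteria", n)
  phylum <- rep("Pseudomonadota", n)
  class <- rep("Gammaproteobacteria", n)
  order <- rep("Pseudomonadales", n)
  family <- rep("Moraxellaceae", n)
  for (i in contIdx) {
    if (i %% 2 == 0) {
      order[i] <- "Chloroplast"; family[i] <- ""; genus[i] <- ""
      domain[i] <- "Bacteria"; phylum[i] <- "Cyanobacteria"
    } else {
      order[i] <- "Rickettsiales"; family[i] <- "Mitochondria"; genus[i] <- ""
      phylum[i] <- "Pseudomonadota"
    }
  }
  data.frame(domain = domain, phylum = phylum, class = class, order = order,
             family = family, genus = genus, row.names = taxonIds,
             stringsAsFactors = FALSE)
}

syntheticMetadata <- function(sampleIds, groups, cfg) {
  rank <- match(groups, gradeLevels()) - 1L  # 0..3
  n <- length(sampleIds)
  data.frame(
    grade = groups,
    gender = ifelse(rbinom(n, 1, 0.65) == 1, "male", "female"),
    gestational_age = round(cfg$gaBase + cfg$gaSlope * rank +
                              rnorm(n, 0, 1.6), 2),
    birth_weight = round(cfg$bwBase + cfg$bwSlope * rank +
                           rnorm(n, 0, 250)),
    delivery_mode = ifelse(rbinom(n, 1, 0.4 + 0.08 * rank) == 1,
                           "cesarean", "vaginal"),
    antibiotic_type = ifelse(rbinom(n, 1, 0.25 + 0.15 * rank) == 1,
                             "combination", "monotherapy"),
    ACS = rbinom(n, 1, 0.7),
    chorioamnionitis = rbinom(n, 1, 0.2),
    MSF = rbinom(n, 1, 0.1),
    EUGR = rbinom(n, 1, 0.2 + 0.1 * rank),
    intrauterine_distress = rbinom(n, 1, 0.15),
    length_of_stay = round(pmax(10, 38 + 9 * rank + rnorm(n, 0, 10))),
    row.names = sampleIds, stringsAsFactors = FALSE)
}

#' Generate a null cohort with independent basis abundances
#'
#' Counts are multinomial over the closure of independent log-normal basis
#' abundances — no planted correlation. Used for type-I-error and
#' spurious-correlation calibration; with a `dominantShare`, one taxon is
#' given that expected share of the community to exercise the closure
#' artifact naive correlations suffer from.
#'
#' @param nSamples,nTaxa,depth positive integers.
#' @param seed integer RNG seed.
#' @param logMean,logSd basis log-abundance parameters.
#' @param dominantShare optional expected relative abundance (0-1) of taxon
#'   1.
#' @return an [AmpliconExperiment-class] with counts only.
#' @export
generateNullCohort <- function(nSamples, nTaxa, depth, seed = NULL,
                               logMean = 0, logSd = 1,
                               dominantShare = NULL) {
  stopifnot(nSamples >= 1, nTaxa >= 1, depth >= 1)
  withSeed(seed, {
    mu <- rep(logMean, nTaxa)
    if (!is.null(dominantShare)) {
      stopifnot(dominantShare > 0, dominantShare < 1)
      ## boost so that E[basis_1] / E[sum basis] equals dominantShare
      mu[1] <- logMean + log(dominantShare / (1 - dominantShare) *
                               (nTaxa - 1))
    }
    z <- matrix(rnorm(nTaxa * nSamples, mu, logSd), nTaxa, nSamples)
    basis <- exp(z)
    frac <- sweep(basis, 2, colSums(basis), "/")
    counts <- vapply(seq_len(nSamples),
                     function(j) rmultinom(1, depth, frac[, j])[, 1],
                     numeric(nTaxa))
    dimnames(counts) <- list(sprintf("ASV%04d", seq_len(nTaxa)),
                             sprintf("S%03d", seq_len(nSamples)))
    ampliconExperiment(counts)
  })
}
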