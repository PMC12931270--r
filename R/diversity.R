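#' Alpha diversity indices per sample
#'
#' Chao1 uses the bias-corrected form S_obs + F1(F1-1)/(2(F2+1)) (defined
#' even without doubletons; the classical form is available via
#' `chao1Mode`); Shannon is -sum p log p (natural log); Simpson is reported
#' as the complement 1 - sum p^2, with the raw concentration also emitted;
#' Good's coverage is 1 - F1/N.
#'
#' @param ae an [AmpliconExperiment-class] of integer counts
#'   (post-rarefaction recommended).
#' @param chao1Mode `"bias_corrected"` (default) or `"classic"`
#'   (S + F1^2/(2 F2)).
#' @return data.frame, one row per sample: `observed`, `chao1`, `shannon`,
#'   `simpson` (complement), `simpson_concentration`, `goods_coverage`.
#' @export
alphaDiversity <- function(ae, chao1Mode = c("bias_corrected", "classic")) {
  chao1Mode <- match.arg(chao1Mode)
  m <- countMatrix(ae)
  d <- colSums(m)
  if (any(d <= 0))
    stop("zero-depth sample: ", colnames(m)[which(d <= 0)[1L]])
  out <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    S <- length(x)
    F1 <- sum(x == 1)
    F2 <- sum(x == 2)
    chao1 <- if (chao1Mode == "bias_corrected") {
      S + F1 * (F1 - 1) / (2 * (F2 + 1))
    } else {
      if (F2 == 0) S + F1 * (F1 - 1) / 2 else S + F1^2 / (2 * F2)
    }
    p <- x / sum(x)
    conc <- sum(p^2)
    data.frame(observed = S, chao1 = chao1,
               shannon = entropyNat(p),
               simpson = 1 - conc, simpson_concentration = conc,
               goods_coverage = 1 - F1 / sum(x))
  })
  out <- do.call(rbind, out)
  rownames(out) <- colnames(m)
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' @param ae an [AmpliconExperiment-class] (>= 2 samples).
#' @return a symmetric `dist`-backed square matrix with zero diagonal.
#' @export
brayCurtis <- function(ae) {
  m <- countMatrix(ae)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' ANOSIM with pairwise Bonferroni-adjusted comparisons
#'
#' Global analysis of similarity on a distance matrix plus all pairwise
#' group comparisons, with pairwise p-values multiplied by the number of
#' pairs (capped at 1).
#'
#' @param d square distance matrix (or `dist`).
#' @param groups factor-like group labels (>= 2 groups of size >= 2).
#' @param nPerm permutations.
#' @param seed integer RNG seed.
#' @return list with `R`, `p`, `nPerm`, and data.frame `pairwise`
#'   (`groupA`, `groupB`, `R`, `p`, `pBonferroni`).
#' @export
anosimTest <- function(d, groups, nPerm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  checkGroups(groups)
  global <- withSeed(seed, vegan::anosim(stats::as.dist(d), groups,
                                         permutations = nPerm))
  pairs <- utils::combn(levels(groups), 2L)
  nPairs <- ncol(pairs)
  pw <- lapply(seq_len(nPairs), function(k) {
    sel <- groups %in% pairs[, k]
    fit <- withSeed(if (is.null(seed)) NULL else seed + k,
                    vegan::anosim(stats::as.dist(d[sel, sel]),
                                  droplevels(groups[sel]),
                                  permutations = nPerm))
    data.frame(groupA = pairs[1L, k], groupB = pairs[2L, k],
               R = unname(fit$statistic), p = fit$signif)
  })
  pw <- do.call(rbind, pw)
  pw$pBonferroni <- pmin(1, pw$p * nPairs)
  list(R = unname(global$statistic), p = global$signif, nPerm = nPerm,
       pairwise = pw)
}

#' PERMANOVA (single factor) on a distance matrix
#'
#' Partitions the Gower-centred total sum of squared distances into
#' between/within components; permutation p uses the add-one estimator.
#'
#' @inheritParams anosimTest
#' @return list with `pseudoF`, `R2`, `p`, `nPerm`.
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  checkGroups(groups)
  df <- data.frame(group = groups)
  fit <- withSeed(seed, vegan::adonis2(stats::as.dist(d) ~ group,
                                       data = df, permutations = nPerm))
  list(pseudoF = fit$F[1L], R2 = fit$R2[1L], p = fit$`Pr(>F)`[1L],
       nPerm = nPerm)
}

#' Marginal per-covariate PERMANOVA scan
#'
#' One single-factor model per covariate (rows with missing values dropped
#' per covariate).
#'
#' @param d square distance matrix.
#' @param covariates data.frame, one row per sample (same order as `d`).
#' @param nPerm permutations.
#' @param seed integer RNG seed.
#' @return data.frame with `covariate`, `pseudoF`, `R2`, `p`.
#' @export
permanovaScan <- function(d, covariates, nPerm = 999, seed = NULL) {
  d <- as.matrix(d)
  out <- lapply(seq_along(covariates), function(k) {
    x <- covariates[[k]]
    ok <- !is.na(x)
    xf <- if (is.numeric(x)) x[ok] else factor(x[ok])
    if ((is.factor(xf) && nlevels(xf) < 2) ||
        (is.numeric(xf) && sd(xf) == 0))
      return(data.frame(covariate = names(covariates)[k],
                        pseudoF = NA_real_, R2 = NA_real_, p = NA_real_))
    df <- data.frame(x = xf)
    fit <- withSeed(if (is.null(seed)) NULL else seed + k,
                    vegan::adonis2(stats::as.dist(d[ok, ok]) ~ x,
                                   data = df, permutations = nPerm))
    data.frame(covariate = names(covariates)[k], pseudoF = fit$F[1L],
               R2 = fit$R2[1L], p = fit$`Pr(>F)`[1L])
  })
  do.call(rbind, out)
}

#' PERMDISP: homogeneity of multivariate dispersion
#'
#' Per-sample distance to the group centroid in principal-coordinate space
#' with a permutation F test; run before PERMANOVA to validate its
#' location interpretation.
#'
#' @inheritParams anosimTest
#' @return list with `F`, `p`, `nPerm`.
#' @export
permdispTest <- function(d, groups, nPerm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  checkGroups(groups)
  bd <- vegan::betadisper(stats::as.dist(d), groups)
  pt <- withSeed(seed, vegan::permutest(bd, permutations = nPerm))
  list(F = pt$tab$F[1L], p = pt$tab$`Pr(>F)`[1L], nPerm = nPerm)
}

#' Kruskal-Wallis effect sizes for alpha diversity contrasts
#'
#' Both common rank-based effect-size definitions are returned since
#' conventions differ: eta-squared (H - k + 1)/(n - k) and epsilon-squared
#' H/((n^2 - 1)/(n + 1)).
#'
#' @param x numeric response (e.g., one alpha index).
#' @param groups group labels.
#' @return list with `H`, `p`, `etaSquared`, `epsilonSquared`.
#' @export
kruskalEffectSize <- function(x, groups) {
  groups <- factor(groups)
  kt <- stats::kruskal.test(x, groups)
  H <- unname(kt$statistic)
  n <- length(x)
  k <- nlevels(groups)
  list(H = H, p = kt$p.value,
       etaSquared = (H - k + 1) / (n - k),
       epsilonSquared = H / ((n^2 - 1) / (n + 1)))
}

checkGroups <- function(groups) {
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group of size < 2: ", names(tab)[tab < 2L][1L])
  invisible(TRUE)
}
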