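#' Log-ratio variance matrix
#'
#' T_ij is the sample variance (n-1 denominator) of ln(f_i / f_j) across
#' samples; the diagonal is zero. This is the compositionally invariant
#' summary from which basis correlations are recovered: multiplying every
#' sample's basis by a constant leaves every ratio, hence T, unchanged.
#'
#' @param fractions strictly positive taxa x samples matrix whose columns
#'   sum to 1 (apply a pseudocount first if needed).
#' @return symmetric D x D matrix with zero diagonal.
#' @export
logRatioVariances <- function(fractions) {
  if (any(fractions <= 0))
    stop("fractions must be strictly positive; pseudocount the zeros first")
  lf <- log(fractions)
  V <- cov(t(lf))  # covariance of log fractions across samples
  v <- diag(V)
  T <- outer(v, v, "+") - 2 * V
  T[T < 0] <- 0  # guard tiny negative round-off
  diag(T) <- 0
  dimnames(T) <- list(rownames(fractions), rownames(fractions))
  T
}

#' Basis correlations from log-ratio variances
#'
#' Solves M omega = t for the basis (log-abundance) variances omega, where
#' t_i = sum_j T_ij, M has D-1 on the diagonal and 1 elsewhere — the
#' sparsity approximation that most taxon pairs are uncorrelated. Estimated
#' correlations rho_ij = (omega_i + omega_j - T_ij) / (2 sqrt(omega_i
#' omega_j)) are clipped to [-1, 1]. The strongest off-diagonal pair
#' exceeding `exclusionThreshold` is then iteratively excluded from the row
#' sums (decrementing the matching diagonal entries of M and zeroing its
#' off-diagonal entry) and the system re-solved, up to `maxExclusions`
#' rounds.
#'
#' @param T symmetric log-ratio variance matrix, zero diagonal, D >= 4.
#' @param exclusionThreshold |rho| above which strongly correlated pairs
#'   are removed from the sparsity approximation (default 0.1).
#' @param maxExclusions maximum exclusion rounds (default 10).
#' @param varianceFloor clamp for non-positive basis-variance estimates.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
basisCorrelations <- function(T, exclusionThreshold = 0.1,
                              maxExclusions = 10L,
                              varianceFloor = 1e-6) {
  D <- nrow(T)
  if (D < 4L)
    stop("need at least 4 taxa: the sparsity approximation is ",
         "unidentifiable below D = 4")
  out <- basisCorrelationsCpp(T, exclusionThreshold,
                              as.integer(maxExclusions), varianceFloor)
  if (out$clamped)
    warning("non-positive basis-variance estimate(s) clamped to ",
            varianceFloor)
  rho <- out$rho
  dimnames(rho) <- dimnames(T)
  rho
}

## One SparCC point estimate: Dirichlet-resampled fractions per outer
## iteration, elementwise median across iterations.
sparccPointEstimate <- function(counts, nOuter, prior = 1,
                                exclusionThreshold = 0.1,
                                maxExclusions = 10L) {
  D <- nrow(counts)
  n <- ncol(counts)
  acc <- array(NA_real_, c(D, D, nOuter))
  for (it in seq_len(nOuter)) {
    g <- matrix(rgamma(D * n, shape = counts + prior), D, n)
    frac <- sweep(g, 2, colSums(g), "/")
    T <- logRatioVariances(frac)
    acc[, , it] <- suppressWarnings(
      basisCorrelations(T, exclusionThreshold, maxExclusions))
  }
  r <- matrix(matrixStats::rowMedians(matrix(acc, D * D, nOuter)), D, D)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(rownames(counts), rownames(counts))
  r
}

#' SparCC correlation estimate
#'
#' For each of `nOuter` outer iterations, per-sample fractions are drawn
#' from Dirichlet(counts + prior), basis correlations are computed from the
#' log-ratio variances, and the elementwise median across iterations is
#' returned. Deterministic under `seed`.
#'
#' @param ae an [AmpliconExperiment-class] (or a taxa x samples count
#'   matrix) of filtered counts.
#' @param nOuter outer iterations (default 20).
#' @param seed integer RNG seed.
#' @param prior Dirichlet prior pseudocount added to each count (default 1;
#'   0.5 selectable).
#' @param exclusionThreshold,maxExclusions passed to
#'   [basisCorrelations()].
#' @return a [CorrelationResult-class] with `method = "sparcc"` and p all
#'   NA (see [edgeSignificance()]).
#' @export
sparccCorrelation <- function(ae, nOuter = 20L, seed = NULL, prior = 1,
                              exclusionThreshold = 0.1,
                              maxExclusions = 10L) {
  counts <- if (methods::is(ae, "AmpliconExperiment")) countMatrix(ae)
            else as.matrix(ae)
  stopifnot(nOuter >= 1)
  r <- withSeed(seed, sparccPointEstimate(counts, nOuter, prior,
                                          exclusionThreshold,
                                          maxExclusions))
  newCorrelationResult(r, method = "sparcc",
                       nOuterIterations = as.integer(nOuter))
}

#' Spearman rank correlation on relative abundances
#'
#' The conventional (compositionally naive) alternative to SparCC; ties use
#' mid-ranks. Pairs involving a constant taxon are undefined and reported
#' as 0, with the affected taxa listed in the `constantTaxa` attribute of
#' the result's `r` slot.
#'
#' @param ae an [AmpliconExperiment-class] (or taxa x samples count
#'   matrix).
#' @return a [CorrelationResult-class] with `method = "spearman"`.
#' @export
spearmanCorrelation <- function(ae) {
  counts <- if (methods::is(ae, "AmpliconExperiment")) countMatrix(ae)
            else as.matrix(ae)
  r <- spearmanOnCounts(counts)
  newCorrelationResult(r, method = "spearman", nOuterIterations = 0L)
}

spearmanOnCounts <- function(counts) {
  frac <- sweep(counts, 2, colSums(counts), "/")
  r <- suppressWarnings(stats::cor(t(frac), method = "spearman"))
  constant <- rownames(counts)[apply(frac, 1L, function(x) sd(x) == 0)]
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "constantTaxa") <- constant
  r
}

#' Resampling-based edge significance
#'
#' Permutation mode (default, a proper null): each resample independently
#' shuffles every taxon's counts across samples, re-estimates the
#' correlation matrix, and p_ij = (1 + #\{|r_resample| >= |r_obs|\}) /
#' (nResamples + 1). Bootstrap mode resamples samples with replacement and
#' scores two-sided sign-instability: p_ij = (1 + #\{r_resample * r_obs <=
#' 0\}) / (nResamples + 1).
#'
#' @param ae the [AmpliconExperiment-class] (or count matrix) the estimate
#'   came from.
#' @param cor a [CorrelationResult-class] from [sparccCorrelation()] or
#'   [spearmanCorrelation()].
#' @param nResamples number of resamples (default 100).
#' @param mode `"permutation"` or `"bootstrap"`.
#' @param seed integer RNG seed.
#' @param nOuterResample outer SparCC iterations per resample (default 5;
#'   raise for full fidelity, ignored for Spearman).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment of the off-diagonal p values.
#' @return the [CorrelationResult-class] with `p` filled.
#' @export
edgeSignificance <- function(ae, cor, nResamples = 100L,
                             mode = c("permutation", "bootstrap"),
                             seed = NULL, nOuterResample = 5L,
                             adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (nResamples < 1L) stop("nResamples must be >= 1")
  counts <- if (methods::is(ae, "AmpliconExperiment")) countMatrix(ae)
            else as.matrix(ae)
  stopifnot(identical(rownames(counts), cor@taxonIds))
  estimator <- if (cor@method == "sparcc") {
    function(m) sparccPointEstimate(m, nOuterResample)
  } else {
    function(m) spearmanOnCounts(m)
  }
  rObs <- cor@r
  D <- nrow(rObs)
  n <- ncol(counts)
  hits <- matrix(0L, D, D)
  withSeed(seed, {
    for (b in seq_len(nResamples)) {
      mb <- if (mode == "permutation") {
        t(apply(counts, 1L, sample, size = n))
      } else {
        counts[, sample.int(n, n, replace = TRUE), drop = FALSE]
      }
      rb <- estimator(mb)
      hits <- hits + if (mode == "permutation") {
        (abs(rb) >= abs(rObs))
      } else {
        (rb * rObs <= 0)
      }
    }
  })
  p <- (1 + hits) / (nResamples + 1)
  p <- (p + t(p)) / 2
  if (adjust == "BH") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rObs)
  methods::initialize(cor, p = p, nResamples = as.integer(nResamples),
                      resamplingMode = mode)
}

newCorrelationResult <- function(r, method, nOuterIterations = 0L) {
  D <- nrow(r)
  p <- matrix(NA_real_, D, D, dimnames = dimnames(r))
  cleanR <- r
  attributes(cleanR) <- attributes(r)[c("dim", "dimnames")]
  methods::new("CorrelationResult",
               taxonIds = rownames(r), r = cleanR, p = p, method = method,
               nOuterIterations = nOuterIterations, nResamples = 0L,
               resamplingMode = "none")
}
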