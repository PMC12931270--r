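#' @importFrom stats var sd median quantile rnorm runif rbinom rmultinom rgamma
#'   cov complete.cases setNames phyper plogis qlogis dist cmdscale ks.test
#' @importFrom utils head read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib AirwayNet, .registration = TRUE
NULL

## Run an expression under a fixed RNG state without disturbing the caller's
## stream; seed = NULL leaves the current stream in place.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## Derive a stage-specific sub-seed from a base seed; keeps results of one
## stage reproducible in isolation. Stays below .Machine$integer.max.
subSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, preprocess = 23L, diversity = 37L,
               correlate = 53L, network = 71L, compare = 89L, model = 101L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

## Add-one permutation p-value estimator (never returns 0).
permPValue <- function(nExtreme, nPerm) (1 + nExtreme) / (nPerm + 1)

## Shannon entropy of a probability vector (natural log), ignoring zeros.
entropyNat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

## Jensen-Shannon divergence (natural log) between two probability vectors
## padded to common length.
jsDivergence <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  entropyNat(m) - (entropyNat(p) + entropyNat(q)) / 2
}

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
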