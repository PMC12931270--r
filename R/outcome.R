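#' Z-score standardization (optionally after log transform)
#'
#' With `logTransform`, zeros are offset by half the minimum positive value
#' before taking logs (the usual relative-abundance convention); the output
#' has mean 0 and sample standard deviation 1.
#'
#' @param x numeric vector.
#' @param logTransform logical.
#' @return standardized numeric vector.
#' @export
standardize <- function(x, logTransform = FALSE) {
  stopifnot(is.numeric(x))
  if (logTransform) {
    if (any(x < 0)) stop("log transform requires non-negative values")
    pos <- x[x > 0]
    if (!length(pos)) stop("log transform requires some positive values")
    x <- log(ifelse(x == 0, min(pos) / 2, x))
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant vector (sd = 0)")
  (x - mean(x)) / s
}

#' Fit a proportional-odds ordinal regression by damped Newton iterations
#'
#' Maximizes the cumulative-logit likelihood with parameterization
#' logit P(Y <= k) = theta_k - x'beta, so a positive beta (OR > 1) means
#' higher odds of a more severe grade. Newton steps on the analytic
#' gradient (Hessian by central differences of the gradient) with step
#' halving whenever the likelihood would decrease, the cutpoint ordering
#' would break, or the likelihood is non-finite. Convergence when the
#' gradient max-norm falls below `gradTol` or after `maxIter` iterations;
#' Wald standard errors come from the observed information. A singular
#' information matrix (reciprocal condition number < 1e-10) or a non-finite
#' likelihood sets the non-convergence flag rather than erroring.
#'
#' @param y ordinal outcome: ordered factor or integer codes 1..K (>= 2
#'   observed levels).
#' @param X numeric predictor matrix (n x p), typically standardized;
#'   column names become coefficient names.
#' @param maxIter,gradTol Newton controls.
#' @return an [OrdinalFit-class].
#' @export
fitProportionalOdds <- function(y, X, maxIter = 100L, gradTol = 1e-8) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  keepLevels <- sort(unique(y))
  y <- match(y, keepLevels)
  K <- length(keepLevels)
  n <- length(y)
  p <- ncol(X)
  if (K < 2L) stop("need at least 2 observed outcome levels")
  if (n <= p + 3L) stop("too few observations for ", p, " predictors")

  ## start: cutpoints at the empirical cumulative logits, slopes 0
  cum <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / n
  par <- c(qlogis(cum), rep(0, p))

  nllGrad <- function(par) {
    th <- par[seq_len(K - 1L)]
    beta <- par[-seq_len(K - 1L)]
    xb <- if (p) drop(X %*% beta) else rep(0, n)
    etaU <- ifelse(y < K, th[pmin(y, K - 1L)] - xb, Inf)
    etaL <- ifelse(y > 1L, th[pmax(y - 1L, 1L)] - xb, -Inf)
    cu <- plogis(etaU); cl <- plogis(etaL)
    pi <- cu - cl
    if (any(pi <= 0) || any(!is.finite(pi)))
      return(list(ll = -Inf, grad = rep(NA_real_, length(par))))
    phiU <- ifelse(is.finite(etaU), cu * (1 - cu), 0)
    phiL <- ifelse(is.finite(etaL), cl * (1 - cl), 0)
    w <- (phiU - phiL) / pi
    gTh <- vapply(seq_len(K - 1L), function(m)
      sum(phiU[y == m] / pi[y == m]) -
        sum(phiL[y == m + 1L] / pi[y == m + 1L]), numeric(1))
    gBeta <- if (p) -drop(crossprod(X, w)) else numeric(0)
    list(ll = sum(log(pi)), grad = c(gTh, gBeta))
  }

  cur <- nllGrad(par)
  iter <- 0L
  converged <- FALSE
  singular <- FALSE
  h <- 1e-5
  numHessian <- function(par) {
    q <- length(par)
    H <- matrix(0, q, q)
    for (j in seq_len(q)) {
      e <- rep(0, q); e[j] <- h
      H[, j] <- (nllGrad(par + e)$grad - nllGrad(par - e)$grad) / (2 * h)
    }
    (H + t(H)) / 2
  }
  while (iter < maxIter) {
    iter <- iter + 1L
    if (max(abs(cur$grad)) < gradTol) { converged <- TRUE; break }
    H <- numHessian(par)
    info <- -H
    if (!all(is.finite(info)) || rcond(info) < 1e-10) {
      singular <- TRUE
      break
    }
    step <- drop(solve(info, cur$grad))
    lambda <- 1
    improved <- FALSE
    for (half in 1:25) {
      cand <- par + lambda * step
      thC <- cand[seq_len(K - 1L)]
      if (all(diff(thC) > 0) || K == 2L) {
        new <- nllGrad(cand)
        if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) {
          par <- cand; cur <- new; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  if (converged && max(abs(cur$grad)) >= gradTol) converged <- FALSE

  ## a perfectly predicted outcome (every observation's category probability
  ## at 1) means the MLE ran off to infinity: complete separation
  thTmp <- par[seq_len(K - 1L)]
  betaTmp <- par[-seq_len(K - 1L)]
  xbTmp <- if (p) drop(X %*% betaTmp) else rep(0, n)
  cuT <- plogis(ifelse(y < K, thTmp[pmin(y, K - 1L)] - xbTmp, Inf))
  clT <- plogis(ifelse(y > 1L, thTmp[pmax(y - 1L, 1L)] - xbTmp, -Inf))
  if (all(cuT - clT > 1 - 1e-6)) converged <- FALSE

  info <- -numHessian(par)
  okInfo <- all(is.finite(info)) && rcond(info) >= 1e-10
  se <- rep(NA_real_, p)
  if (okInfo && p) {
    vc <- solve(info)
    se <- sqrt(diag(vc)[K - 1L + seq_len(p)])
  }
  if (!okInfo) { converged <- FALSE; singular <- TRUE }

  th <- par[seq_len(K - 1L)]
  beta <- par[-seq_len(K - 1L)]
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  xb <- if (p) drop(X %*% beta) else rep(0, n)
  cumAll <- cbind(0, plogis(outer(-xb, th, "+")), 1)
  fitted <- cumAll[, -1L, drop = FALSE] -
    cumAll[, -ncol(cumAll), drop = FALSE]
  colnames(fitted) <- as.character(keepLevels)
  pv <- 2 * stats::pnorm(-abs(beta / se))
  fit <- methods::new("OrdinalFit",
    coefficients = beta, se = se, oddsRatios = exp(beta),
    cutpoints = th, logLik = cur$ll, converged = converged,
    iterations = iter,
    dropped = data.frame(covariate = character(0), reason = character(0),
                         stringsAsFactors = FALSE),
    fitted = fitted, pValues = pv, singularInfo = singular)
  fit
}

#' @describeIn OrdinalFit-class coefficient summary display.
#' @param object an OrdinalFit.
#' @export
setMethod("show", "OrdinalFit", function(object) {
  cat("OrdinalFit (proportional odds):",
      if (object@converged) "converged" else "NOT converged",
      "in", object@iterations, "iterations; logLik",
      format(object@logLik, digits = 6), "\n")
  if (length(object@coefficients)) {
    tab <- data.frame(beta = object@coefficients, se = object@se,
                      OR = object@oddsRatios, p = object@pValues)
    print(tab, digits = 4)
  }
  if (nrow(object@dropped)) {
    cat("dropped covariates:\n")
    print(object@dropped, row.names = FALSE)
  }
  invisible(NULL)
})

#' Forward stepwise covariate selection with stability gating
#'
#' Starting from the base predictors, candidate covariates are added one at
#' a time in the supplied order of clinical importance. A candidate is kept
#' only if the augmented model converges with a non-singular observed
#' information; covariates causing singularity or non-convergence are
#' recorded as dropped and skipped. There is no significance-based entry
#' criterion by default (gating is on stability, not p-values); set
#' `entryP` to add one.
#'
#' @param y ordinal outcome.
#' @param base numeric matrix/data.frame of base predictors (e.g., a
#'   keystone-taxon abundance or one topology metric), already
#'   standardized.
#' @param candidates data.frame of candidate covariates in order of
#'   priority; numeric columns are z-scored, factors expanded to dummies.
#' @param entryP optional p-value gate: a candidate is also rejected when
#'   all its terms have Wald p above this value.
#' @return the final [OrdinalFit-class], with the audit trail in `@dropped`.
#' @export
forwardStepwise <- function(y, base, candidates = NULL, entryP = NULL) {
  X <- as.matrix(base)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("base", seq_len(ncol(X)))
  fit <- fitProportionalOdds(y, X)
  if (!fit@converged)
    stop("base model did not converge; cannot start stepwise selection")
  dropped <- data.frame(covariate = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(candidates)) {
    for (nm in colnames(candidates)) {
      cols <- tryCatch(expandCovariate(candidates[[nm]], nm),
                       error = function(e) NULL)
      if (is.null(cols)) {
        dropped <- rbind(dropped,
                         data.frame(covariate = nm, reason = "constant"))
        next
      }
      Xtry <- cbind(X, cols)
      trial <- tryCatch(fitProportionalOdds(y, Xtry),
                        error = function(e) NULL)
      bad <- is.null(trial) || !trial@converged || trial@singularInfo
      if (bad) {
        reason <- if (!is.null(trial) && trial@singularInfo)
          "singular information" else "non-convergence"
        dropped <- rbind(dropped,
                         data.frame(covariate = nm, reason = reason))
        next
      }
      if (!is.null(entryP)) {
        newIdx <- ncol(X) + seq_len(ncol(cols))
        if (all(trial@pValues[newIdx] > entryP, na.rm = TRUE)) {
          dropped <- rbind(dropped,
                           data.frame(covariate = nm,
                                      reason = "not significant"))
          next
        }
      }
      X <- Xtry
      fit <- trial
    }
  }
  fit@dropped <- dropped
  fit
}

## one covariate -> standardized numeric column(s)
expandCovariate <- function(x, name) {
  if (is.numeric(x)) {
    out <- matrix(standardize(x), ncol = 1,
                  dimnames = list(NULL, name))
    return(out)
  }
  f <- factor(x)
  if (nlevels(f) < 2L) stop("constant factor")
  mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  colnames(mm) <- paste0(name, levels(f)[-1L])
  mm
}

#' Per-sample network-metric predictors
#'
#' A group-level topology metric becomes an individual-level regressor in
#' one of two explicit modes: `"group"` assigns every sample its group
#' network's metric; `"loo"` recomputes the group network leaving the
#' sample out, giving each sample its own value.
#'
#' @param ae an [AmpliconExperiment-class] with a `grade` column (already
#'   filtered for network analysis).
#' @param metric one topology column (see [networkTopology()]).
#' @param mode `"group"` or `"loo"` (leave-one-out).
#' @param threshold,alpha,nOuter network settings (threshold-only
#'   construction).
#' @param seed integer RNG seed.
#' @return named numeric vector over samples.
#' @export
sampleNetworkMetrics <- function(ae, metric = "density",
                                 mode = c("group", "loo"),
                                 threshold = 0.3, alpha = 0.05,
                                 nOuter = 5L, seed = NULL) {
  mode <- match.arg(mode)
  grades <- sampleGrades(ae)
  if (is.null(grades)) stop("metadata has no 'grade' column")
  counts <- countMatrix(ae)
  out <- setNames(rep(NA_real_, ncol(counts)), colnames(counts))
  withSeed(seed, {
    for (g in levels(droplevels(grades))) {
      cols <- which(grades == g)
      if (mode == "group") {
        topo <- groupTopology(counts[, cols, drop = FALSE], threshold,
                              alpha, nOuter, 0L, "sparcc")
        out[cols] <- topo[[metric]]
      } else {
        for (j in cols) {
          topo <- groupTopology(counts[, setdiff(cols, j), drop = FALSE],
                                threshold, alpha, nOuter, 0L, "sparcc")
          out[j] <- topo[[metric]]
        }
      }
    }
  })
  out
}
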