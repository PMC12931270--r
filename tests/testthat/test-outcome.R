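simOrdinal <- function(n, beta, seed, K = 4,
                       cuts = c(-1, 0.5, 2)) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    cum <- plogis(outer(-x * beta, cuts, "+"))
    y <- rowSums(runif(n) > cum) + 1L
    list(x = x, y = y)
  })
}

test_that("standardization produces exact z-scores and rejects constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  z <- standardize(rexp(50))
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_error(standardize(rep(4, 10)), "constant")
  ## log transform with half-minimum pseudocount for zeros
  x <- c(0, 1, 4, 16)
  z2 <- standardize(x, logTransform = TRUE)
  manual <- log(c(0.5, 1, 4, 16))
  expect_equal(z2, (manual - mean(manual)) / sd(manual))
})

test_that("the Newton fitter matches MASS::polr on simulated data", {
  skip_if_not_installed("MASS")
  sim <- simOrdinal(400, 1, seed = 20)
  X <- matrix(sim$x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fitProportionalOdds(sim$y, X)
  pf <- MASS::polr(factor(sim$y, ordered = TRUE) ~ sim$x,
                   method = "logistic", Hess = TRUE)
  expect_true(fit@converged)
  expect_equal(unname(fit@coefficients), unname(coef(pf)),
               tolerance = 1e-5)
  expect_equal(unname(fit@cutpoints), unname(pf$zeta), tolerance = 1e-5)
  expect_equal(fit@logLik, as.numeric(logLik(pf)), tolerance = 1e-8)
  expect_equal(unname(fit@se), unname(sqrt(diag(vcov(pf)))[1]),
               tolerance = 1e-4)
  expect_equal(unname(fit@oddsRatios), exp(unname(coef(pf))),
               tolerance = 1e-5)
})

test_that("fitted category probabilities sum to one and cutpoints increase", {
  sim <- simOrdinal(200, 0.5, seed = 31)
  fit <- fitProportionalOdds(sim$y, matrix(sim$x, ncol = 1))
  expect_true(all(abs(rowSums(fit@fitted) - 1) < 1e-12))
  expect_true(all(diff(fit@cutpoints) > 0))
})

test_that("with two outcome levels the fit reduces to binary logistic regression", {
  sim <- simOrdinal(300, 0.8, seed = 7)
  y2 <- as.integer(sim$y > 2) + 1L
  fit <- fitProportionalOdds(y2, matrix(sim$x, ncol = 1,
                                        dimnames = list(NULL, "x")))
  ## oracle: glm on P(Y <= 1); slope flips sign under the cumulative
  ## parameterization logit P(Y <= k) = theta - x beta
  gb <- glm(I(y2 == 1) ~ sim$x, family = binomial)
  expect_equal(unname(fit@coefficients), -unname(coef(gb)[2]),
               tolerance = 1e-6)
  expect_equal(unname(fit@cutpoints), unname(coef(gb)[1]),
               tolerance = 1e-6)
})

test_that("Wald coverage is near nominal and null predictors give OR near 1", {
  covered <- logical(40)
  nullOK <- logical(40)
  for (s in seq_len(40)) {
    sim <- simOrdinal(500, 1, seed = 100 + s)
    fit <- fitProportionalOdds(sim$y, matrix(sim$x, ncol = 1))
    ci <- fit@coefficients + c(-1.96, 1.96) * fit@se
    covered[s] <- ci[1] <= 1 && 1 <= ci[2]
    simN <- simOrdinal(500, 0, seed = 500 + s)
    fitN <- fitProportionalOdds(simN$y, matrix(simN$x, ncol = 1))
    nullOK[s] <- abs(fitN@coefficients) < 3 * fitN@se
  }
  expect_gte(mean(covered), 0.85)
  expect_gte(mean(nullOK), 0.9)
})

test_that("perfect separation raises the non-convergence flag", {
  x <- c(rep(-1, 12), rep(1, 12))
  y <- c(rep(1L, 12), rep(3L, 12))
  fit <- fitProportionalOdds(y, matrix(x, ncol = 1))
  expect_false(fit@converged)
})

test_that("forward stepwise drops exact collinearity and honours an empty list", {
  sim <- simOrdinal(250, 1, seed = 3)
  base <- matrix(sim$x, ncol = 1, dimnames = list(NULL, "x"))
  cand <- data.frame(a = rnorm(250))
  cand$b <- cand$a  # exact copy
  cand$c <- rep(2, 250)  # constant
  sw <- forwardStepwise(sim$y, base, cand)
  expect_true("b" %in% sw@dropped$covariate)
  expect_equal(sw@dropped$reason[sw@dropped$covariate == "b"],
               "singular information")
  expect_true("c" %in% sw@dropped$covariate)
  expect_true("a" %in% names(sw@coefficients))
  ## empty candidate set returns the base fit
  sw0 <- forwardStepwise(sim$y, base, NULL)
  f0 <- fitProportionalOdds(sim$y, base)
  expect_equal(sw0@coefficients, f0@coefficients)
})

test_that("a planted protective effect is recovered with OR below 1", {
  ors <- numeric(10); sig <- logical(10)
  for (s in 1:10) {
    sim <- simOrdinal(300, -2, seed = 900 + s)
    cand <- withr::with_seed(1000 + s,
      data.frame(cov1 = rnorm(300), cov2 = rbinom(300, 1, 0.5)))
    sw <- forwardStepwise(sim$y,
                          matrix(sim$x, ncol = 1,
                                 dimnames = list(NULL, "density")),
                          cand)
    ors[s] <- sw@oddsRatios[["density"]]
    sig[s] <- sw@pValues[["density"]] < 0.05
  }
  expect_lt(median(ors), 1)
  expect_gte(mean(sig), 0.7)
})

test_that("per-sample network predictors exist in both assignment modes", {
  cfg <- cohortConfig(groupSizes = c(non = 6L, I = 6L, II = 6L, III = 6L),
                      nTaxa = 12L, depthRange = c(800L, 1000L),
                      plantedModules = list(
                        non = list(list(size = 5, rho = 0.8)),
                        I = list(), II = list(), III = list()),
                      nContaminantTaxa = 0L, nSingletonTaxa = 0L,
                      nDominantTaxa = 0L, seed = 12L)
  ae <- generateCohort(cfg)
  v <- sampleNetworkMetrics(ae, "density", mode = "group", nOuter = 1,
                            seed = 4)
  expect_equal(length(v), 24)
  md <- sampleMetadata(ae)
  expect_equal(length(unique(v[md$grade == "non"])), 1)
  vl <- sampleNetworkMetrics(ae, "density", mode = "loo", nOuter = 1,
                             seed = 4)
  expect_equal(length(vl), 24)
})
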