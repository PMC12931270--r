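test_that("log-ratio variances match hand computation and ratio invariances", {
  f <- rbind(a = c(0.2, 0.5, 0.8), b = c(0.8, 0.5, 0.2))
  T <- logRatioVariances(f)
  expect_equal(T["a", "b"], var(log(c(0.25, 1, 4))))
  expect_equal(T["a", "b"], 1.921812, tolerance = 1e-6)
  expect_true(all(diag(T) == 0))
  ## scale invariance: multiplying the basis by a constant per taxon set
  ## shared across samples changes nothing about within-pair ratios of the
  ## same scaling -- here: global per-sample rescaling (closure) is a no-op
  f2 <- rbind(a = c(2, 5, 8), b = c(8, 5, 2)) / 10
  expect_equal(logRatioVariances(f2), T)
  fbad <- f; fbad[1, 1] <- 0
  expect_error(logRatioVariances(fbad), "pseudocount")
})

test_that("basis correlations recover an analytically uncorrelated basis", {
  ## T built from a diagonal basis covariance: T_ij = omega_i + omega_j
  om <- c(0.5, 1, 1.5, 2, 3)
  T <- outer(om, om, "+")
  diag(T) <- 0
  dimnames(T) <- list(letters[1:5], letters[1:5])
  rho <- basisCorrelations(T)
  expect_lt(max(abs(rho[upper.tri(rho)])), 1e-10)
  expect_true(all(diag(rho) == 1))
  expect_error(basisCorrelations(T[1:3, 1:3]), "at least 4")
})

test_that("the compiled kernel matches a direct-solve reference implementation", {
  ## reference: explicit M, re-solved from scratch after every exclusion
  refBasis <- function(T, th = 0.1, mx = 10, floor = 1e-6) {
    D <- nrow(T)
    M <- matrix(1, D, D); diag(M) <- D - 1
    tv <- rowSums(T)
    excl <- matrix(FALSE, D, D)
    rho <- NULL
    for (round in seq_len(mx + 1)) {
      om <- solve(M, tv)
      om[om < floor] <- floor
      rho <- (outer(om, om, "+") - T) / (2 * sqrt(outer(om, om)))
      rho[rho > 1] <- 1; rho[rho < -1] <- -1; diag(rho) <- 1
      if (round > mx) break
      cand <- abs(rho); cand[excl] <- 0; diag(cand) <- 0
      if (max(cand) <= th) break
      ij <- arrayInd(which.max(cand), dim(cand))
      i <- ij[1]; j <- ij[2]
      excl[i, j] <- excl[j, i] <- TRUE
      M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
      M[i, j] <- M[j, i] <- 0
      tv[i] <- tv[i] - T[i, j]; tv[j] <- tv[j] - T[i, j]
    }
    rho
  }
  set.seed(4)
  for (k in 1:6) {
    D <- sample(5:60, 1)
    f <- matrix(rgamma(D * 30, 1), D, 30)
    f <- sweep(f, 2, colSums(f), "/")
    T <- logRatioVariances(f)
    a <- suppressWarnings(basisCorrelations(T))
    b <- suppressWarnings(refBasis(T))
    dimnames(a) <- dimnames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("independent basis data give small estimated correlations", {
  ae <- generateNullCohort(200, 50, 5000, seed = 42)
  cr <- sparccCorrelation(ae, nOuter = 10, seed = 1)
  expect_lt(max(abs(cr@r[upper.tri(cr@r)])), 0.3)
})

test_that("a planted basis pair is recovered near its true correlation", {
  est <- vapply(1:5, function(s) {
    cfg <- cohortConfig(groupSizes = c(non = 2L, I = 2L, II = 2L,
                                       III = 200L),
                        nTaxa = 30L, depthRange = c(5000L, 5000L),
                        plantedModules = list(
                          non = list(), I = list(), II = list(),
                          III = list(list(size = 2, rho = 0.8))),
                        nContaminantTaxa = 0L, nSingletonTaxa = 0L,
                        nDominantTaxa = 0L, seed = 400L + s)
    ae <- generateCohort(cfg)
    g3 <- countMatrix(ae)[, sampleMetadata(ae)$grade == "III"]
    sparccCorrelation(g3, nOuter = 5, seed = s)@r[1, 2]
  }, numeric(1))
  expect_lt(abs(median(est) - 0.8), 0.15)
})

test_that("sparcc estimates are deterministic under seed with unit diagonal", {
  ae <- generateNullCohort(30, 10, 1000, seed = 2)
  a <- sparccCorrelation(ae, nOuter = 3, seed = 7)
  b <- sparccCorrelation(ae, nOuter = 3, seed = 7)
  expect_identical(a@r, b@r)
  expect_true(all(diag(a@r) == 1))
  expect_equal(a@r, t(a@r))
})

test_that("permutation edge significance is symmetric, bounded and calibrated-ish", {
  ae <- generateNullCohort(40, 8, 2000, seed = 5)
  cr <- sparccCorrelation(ae, nOuter = 2, seed = 1)
  cr <- edgeSignificance(ae, cr, nResamples = 49, seed = 3,
                         nOuterResample = 1)
  p <- cr@p
  expect_true(all(is.na(diag(p))))
  off <- p[upper.tri(p)]
  expect_true(all(off > 0 & off <= 1))
  expect_equal(p, t(p))
  ## add-one floor
  expect_true(all(off >= 1 / 50))
  ## determinism
  cr2 <- edgeSignificance(ae, sparccCorrelation(ae, nOuter = 2, seed = 1),
                          nResamples = 49, seed = 3, nOuterResample = 1)
  expect_identical(cr@p, cr2@p)
  expect_error(edgeSignificance(ae, cr, nResamples = 0), ">= 1")
})

test_that("a strong planted pair reaches the permutation resolution floor", {
  cfg <- cohortConfig(groupSizes = c(non = 2L, I = 2L, II = 2L,
                                     III = 150L),
                      nTaxa = 12L, depthRange = c(5000L, 5000L),
                      plantedModules = list(
                        non = list(), I = list(), II = list(),
                        III = list(list(size = 2, rho = 0.85))),
                      nContaminantTaxa = 0L, nSingletonTaxa = 0L,
                      nDominantTaxa = 0L, seed = 77L)
  ae <- generateCohort(cfg)
  m <- countMatrix(ae)[, sampleMetadata(ae)$grade == "III"]
  cr <- sparccCorrelation(m, nOuter = 3, seed = 1)
  cr <- edgeSignificance(m, cr, nResamples = 39, seed = 2,
                         nOuterResample = 1)
  expect_equal(cr@p[1, 2], 1 / 40)
})

test_that("bootstrap mode scores sign instability", {
  ae <- generateNullCohort(30, 6, 1000, seed = 8)
  cr <- sparccCorrelation(ae, nOuter = 2, seed = 1)
  crb <- edgeSignificance(ae, cr, nResamples = 19, mode = "bootstrap",
                          seed = 4, nOuterResample = 1)
  expect_equal(crb@resamplingMode, "bootstrap")
  off <- crb@p[upper.tri(crb@p)]
  expect_true(all(off > 0 & off <= 1))
})

test_that("spearman correlation matches a brute-force rank oracle", {
  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(rpois(60, 20), 6, 10,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
    cr <- spearmanCorrelation(m)
    frac <- sweep(m, 2, colSums(m), "/")
    oracle <- matrix(1, 6, 6)
    for (i in 1:5) for (j in (i + 1):6) {
      ri <- rank(frac[i, ]); rj <- rank(frac[j, ])
      oracle[i, j] <- oracle[j, i] <-
        sum((ri - mean(ri)) * (rj - mean(rj))) /
        sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
    }
    expect_equal(unname(cr@r), oracle, tolerance = 1e-12)
  }
  ## monotone pair and two-taxon closure
  m2 <- rbind(a = 1:6, b = (1:6)^2)
  colnames(m2) <- paste0("s", 1:6)
  expect_equal(spearmanCorrelation(m2)@r["a", "b"], -1)  # closure: b grows
  m3 <- rbind(a = c(10, 20, 30, 40), b = c(40, 30, 20, 10))
  colnames(m3) <- paste0("s", 1:4)
  expect_equal(spearmanCorrelation(m3)@r["a", "b"], -1)
  ## a taxon with constant relative abundance: undefined pairs reported 0
  m4 <- rbind(a = c(2, 4, 6), b = c(1, 1, 3), c = c(1, 3, 3))
  colnames(m4) <- paste0("s", 1:3)
  cr4 <- spearmanCorrelation(m4)
  expect_equal(cr4@r["a", "b"], 0)
  expect_true("a" %in% attr(AirwayNet:::spearmanOnCounts(m4),
                            "constantTaxa"))
})

test_that("sparcc suppresses closure-driven spurious correlation vs spearman", {
  meds <- vapply(1:6, function(s) {
    ae <- generateNullCohort(60, 25, 3000, seed = 900 + s,
                             dominantShare = 0.8)
    m <- countMatrix(ae)
    rs <- sparccCorrelation(m, nOuter = 3, seed = s)@r
    rp <- spearmanCorrelation(m)@r
    c(median(abs(rs[upper.tri(rs)])), median(abs(rp[upper.tri(rp)])))
  }, numeric(2))
  expect_lt(mean(meds[1, ]), mean(meds[2, ]))
})

test_that("permutation p-values are invariant to taxon relabeling", {
  ae <- generateNullCohort(25, 6, 800, seed = 31)
  m <- countMatrix(ae)
  cr <- sparccCorrelation(m, nOuter = 2, seed = 1)
  p1 <- edgeSignificance(m, cr, nResamples = 19, seed = 5,
                         nOuterResample = 1)@p
  m2 <- m
  rownames(m2) <- paste0("renamed_", rownames(m))
  cr2 <- sparccCorrelation(m2, nOuter = 2, seed = 1)
  p2 <- edgeSignificance(m2, cr2, nResamples = 19, seed = 5,
                         nOuterResample = 1)@p
  expect_equal(unname(p1), unname(p2))
})
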