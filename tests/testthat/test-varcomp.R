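# REML variance components, heritability and likelihood-ratio tests.

test_that("REML optimum dominates a grid search over the variance plane", {
  for (s in 1:20) {
    set.seed(400 + s)
    n <- sample(30:60, 1)
    g <- randomPanel(n, 80, seed = 400 + s)
    G <- grmValues(computeGRM(g))
    h2true <- runif(1, 0.1, 0.8)
    u <- drop(chol(G + diag(1e-6, n)) %*% rnorm(n)) * sqrt(h2true)
    y <- 5 + u + rnorm(n, 0, sqrt(1 - h2true))
    fit <- fitREML(y, G)
    X <- matrix(1, n, 1)
    vy <- var(y)
    grid <- as.matrix(expand.grid(sg = seq(0.02, 1.6, length.out = 11) * vy,
                                  se = seq(0.02, 1.6, length.out = 11) * vy))
    gll <- apply(grid, 1, function(th)
      oracleREMLLogLik(y, X, G, th[1], th[2]))
    expect_gte(logLikREML(fit), max(gll) - 1e-3)
  }
})

test_that("package and oracle restricted likelihoods agree pointwise", {
  g <- randomPanel(40, 60, seed = 31)
  G <- grmValues(computeGRM(g))
  set.seed(32)
  y <- rnorm(40, 10, 2)
  for (th in list(c(1, 1), c(0.3, 2.5), c(4, 0.2))) {
    expect_equal(remlLogLik(y, G, th),
                 oracleREMLLogLik(y, matrix(1, 40, 1), G, th[1], th[2]),
                 tolerance = 1e-8)
  }
})

test_that("null simulations keep heritability near the zero boundary", {
  hits <- 0
  for (s in 1:20) {
    g <- simulateGenotypes(simConfig(nIndividuals = 300, nChromosomes = 4,
                                     nMarkersPerChrom = 100,
                                     nFounderHaplotypes = 4,
                                     recombRate = 3, seed = s))
    tr <- simulateTrait(g, traitConfig(h2Target = 0, nQTL = 10,
                                       seed = 900 + s))
    fit <- fitREML(tr$phenotypes$tar, computeGRM(g))
    hits <- hits + (heritability(fit)$h2 <= 0.05)
  }
  expect_gte(hits, 16)
})

test_that("perfect repeatability drives heritability to the upper boundary", {
  base <- randomPanel(30, 50, seed = 77)
  d <- dosageMatrix(base)
  d2 <- rbind(d, d)
  rownames(d2) <- c(paste0("a", 1:30), paste0("b", 1:30))
  g <- genotypeData(d2, chrom = markerInfo(base)$chrom,
                    pos = markerInfo(base)$pos)
  G <- computeGRM(g)
  set.seed(78)
  gv <- drop(scale(dosageMatrix(base) %*% rnorm(50)))
  y <- c(gv, gv)                      # duplicated, noiseless
  fit <- fitREML(y, G)
  expect_gte(heritability(fit)$h2, 0.98)
})

test_that("heritability is the variance ratio with a delta-method SE", {
  f <- new("VarCompFit", sigma2 = c(genetic = 7, residual = 3),
           se = c(1, 1), loglik = 0, h2 = 0.7, h2Se = 0.05, nIter = 1L,
           converged = TRUE, boundary = c(FALSE, FALSE), n = 100L,
           nFixed = 1L)
  expect_equal(heritability(f)$h2, 0.7)
  f@sigma2 <- c(genetic = 0, residual = 3)
  expect_equal(heritability(f)$h2, 0)
  f@sigma2 <- c(genetic = 2.5, residual = 2.5)
  expect_equal(heritability(f)$h2, 0.5)
  # SE behaves sensibly on a real fit
  g <- randomPanel(80, 100, seed = 41)
  set.seed(42)
  y <- rnorm(80)
  fit <- fitREML(y, computeGRM(g))
  expect_true(heritability(fit)$se >= 0)
})

test_that("likelihood-ratio test matches the chi-square convention", {
  mk <- function(ll, k = 1) new("VarCompFit",
    sigma2 = setNames(rep(1, k + 1), c(paste0("g", seq_len(k)), "residual")),
    se = rep(1, k + 1), loglik = ll, h2 = 0.5, h2Se = 0.1, nIter = 1L,
    converged = TRUE, boundary = rep(FALSE, k + 1), n = 100L, nFixed = 1L)
  mkNull <- function(ll) new("VarCompFit", sigma2 = c(residual = 1),
    se = 1, loglik = ll, h2 = numeric(), h2Se = numeric(), nIter = 1L,
    converged = TRUE, boundary = FALSE, n = 100L, nFixed = 1L)
  same <- lrtGenetic(mk(-100), mkNull(-100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  big <- lrtGenetic(mk(-100), mkNull(-198.95))
  expect_equal(big$statistic, 197.9)
  expect_lt(big$p, 1e-40)
  bad <- mkNull(-100); bad@nFixed <- 2L
  expect_error(lrtGenetic(mk(-100), bad), "fixed effects")
  expect_warning(lrtGenetic(mk(-101), mkNull(-100)), "exceeds")
})

test_that("type-I error of the boundary LRT is conservative", {
  rej <- 0
  for (s in 1:200) {
    g <- randomPanel(60, 80, seed = 6000 + s)
    set.seed(7000 + s)
    y <- rnorm(60, 30, 8)
    full <- fitREML(y, computeGRM(g))
    null <- fitREML(y, list())
    rej <- rej + (lrtGenetic(full, null)$p < 0.05)
  }
  rate <- rej / 200
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("generative heritability is recovered across the range", {
  for (h2 in c(0.3, 0.5, 0.7)) {
    est <- vapply(1:12, function(s) {
      g <- simulateGenotypes(simConfig(nIndividuals = 400,
                                       nChromosomes = 6,
                                       nMarkersPerChrom = 200,
                                       seed = 1000 * h2 + s))
      tr <- simulateTrait(g, traitConfig(h2Target = h2, nQTL = 300,
                                         seed = 2000 * h2 + s))
      heritability(fitREML(tr$phenotypes$tar, computeGRM(g)))$h2
    }, numeric(1))
    expect_lt(abs(mean(est) - h2), 0.06)
  }
})

test_that("variance components are scale-equivariant", {
  g <- randomPanel(80, 120, seed = 51)
  G <- grmValues(computeGRM(g))
  set.seed(52)
  u <- drop(chol(G + diag(1e-6, 80)) %*% rnorm(80))
  y <- 3 + u + rnorm(80)
  f1 <- fitREML(y, G)
  f2 <- fitREML(10 * y, G)
  expect_equal(unname(varComp(f2)), unname(varComp(f1)) * 100,
               tolerance = 1e-6)
  expect_equal(heritability(f2)$h2, heritability(f1)$h2, tolerance = 1e-8)
})

test_that("non-convergence is flagged, never silent", {
  g <- randomPanel(50, 60, seed = 61)
  set.seed(62)
  y <- rnorm(50)
  fit <- fitREML(y, computeGRM(g), maxIter = 1)
  expect_false(isConverged(fit))
  expect_error(fitREML(y[1:5], computeGRM(g)), "at least 10|match")
  expect_error(fitREML(y, computeGRM(randomPanel(30, 20, seed = 1))),
               "dimensions")
})
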