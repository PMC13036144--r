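# The twelve genomic-prediction models behind one train/predict contract.

makeTrainTest <- function(n = 150, m = 240, h2 = 0.7, nQTL = 100, seed = 1,
                          nTest = 30) {
  g <- simulateGenotypes(simConfig(nIndividuals = n, nChromosomes = 3,
                                   nMarkersPerChrom = ceiling(m / 3),
                                   seed = seed))
  tr <- simulateTrait(g, traitConfig(h2Target = h2, nQTL = nQTL,
                                     seed = seed + 5000))
  idx <- seq_len(n) > (n - nTest)
  list(gTrain = polyGS:::.subsetGeno(g, sampleKeep = !idx),
       gTest = polyGS:::.subsetGeno(g, sampleKeep = idx),
       pheno = tr$phenotypes,
       phTrain = tr$phenotypes[!idx, ], phTest = tr$phenotypes[idx, ],
       geno = g)
}

test_that("rrBLUP and GBLUP produce identical training GEBVs", {
  for (s in 1:3) {
    tt <- makeTrainTest(n = 120, m = 180, seed = 10 + s)
    a <- predict(trainModel("rrBLUP", tt$geno, tt$pheno, seed = s), tt$geno)
    b <- predict(trainModel("GBLUP", tt$geno, tt$pheno, seed = s), tt$geno)
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("LASSO penalty limits recover OLS and the null model", {
  set.seed(21)
  n <- 80; m <- 20
  d <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n, 2, p))
  g <- genotypeData(d, chrom = "chr1", pos = seq_len(m) * 100)
  beta <- rnorm(m, 0, 0.3)
  y <- 10 + drop(d %*% beta) + rnorm(n, 0, 0.5)
  ph <- data.frame(sample_id = sampleIDs(g), tar = y)
  fit0 <- trainModel("LASSO", g, ph, config = list(lambda = 0), seed = 1)
  ols <- lm(y ~ dosageMatrix(g))
  expect_lt(max(abs(fit0@markerEffects - unname(coef(ols)[-1]))), 1e-6)
  fitInf <- trainModel("LASSO", g, ph, config = list(lambda = 1e6),
                       seed = 1)
  expect_true(all(fitInf@markerEffects == 0))
  expect_equal(unname(predict(fitInf, g)[1]), mean(y), tolerance = 1e-6)
})

test_that("Bayes C with inclusion forced to one degenerates to BRR", {
  tt <- makeTrainTest(n = 120, m = 180, seed = 31)
  cfg <- list(nIter = 4000, burnIn = 1000)
  bc <- trainModel("BayesC", tt$geno, tt$pheno,
                   config = c(cfg, piIn = 1), seed = 7)
  brr <- trainModel("BRR", tt$geno, tt$pheno, config = cfg, seed = 7)
  expect_gte(cor(bc@markerEffects, brr@markerEffects), 0.99)
})

test_that("BRR converges to the rrBLUP solution at fixed prior variances", {
  tt <- makeTrainTest(n = 120, m = 180, seed = 41)
  rr <- trainModel("rrBLUP", tt$geno, tt$pheno, seed = 1)
  # fix the Gibbs variances at the REML values on the standardized scale
  # center-only marker coding puts BRR on the same scale as rrBLUP
  p <- colMeans(dosageMatrix(tt$geno)) / 2
  sa2 <- rr@hyperparams$sigma2g / sum(2 * p * (1 - p))
  brr <- trainModel("BRR", tt$geno, tt$pheno,
                    config = list(nIter = 30000, burnIn = 3000, thin = 5,
                                  standardize = FALSE,
                                  fixVar = TRUE, fixedSa2 = sa2,
                                  fixedS2e = rr@hyperparams$sigma2e),
                    seed = 3)
  expect_gte(cor(brr@markerEffects, rr@markerEffects), 0.995)
})

test_that("RKHS kernel collapses to an intercept as bandwidth vanishes", {
  tt <- makeTrainTest(n = 100, m = 150, seed = 51)
  m0 <- trainModel("RKHS", tt$gTrain, tt$phTrain, config = list(h = 1e-9),
                   seed = 1)
  pr <- predict(m0, tt$gTest)
  expect_lt(sd(pr), 1e-3 * sd(tt$phTrain$tar))
})

test_that("prediction contract: consistency, duplicates, marker mismatch", {
  tt <- makeTrainTest(n = 100, m = 150, seed = 61)
  rr <- trainModel("rrBLUP", tt$gTrain, tt$phTrain, seed = 1)
  p1 <- predict(rr, tt$gTrain)
  p2 <- predict(rr, tt$gTrain)
  expect_identical(p1, p2)
  # duplicated individual gets an identical GEBV
  d <- dosageMatrix(tt$gTest)
  d2 <- rbind(d, d[1, , drop = FALSE])
  rownames(d2) <- c(rownames(d), "dupX")
  mk <- markerInfo(tt$gTest)
  gdup <- genotypeData(d2, chrom = mk$chrom, pos = mk$pos, id = mk$id)
  for (mn in c("rrBLUP", "GBLUP", "RKHS")) {
    fit <- trainModel(mn, tt$gTrain, tt$phTrain, seed = 1)
    pd <- predict(fit, gdup)
    expect_equal(unname(pd["dupX"]), unname(pd[rownames(d)[1]]))
  }
  # missing training markers are reported by id
  sub <- polyGS:::.subsetGeno(tt$gTest,
                              markerKeep = seq_len(nMarkers(tt$gTest) - 5))
  expect_error(predict(rr, sub), "training marker")
  expect_error(trainModel("nonsense", tt$geno, tt$pheno), "unknown model")
})

test_that("near-noiseless traits are predicted almost perfectly", {
  g <- simulateGenotypes(simConfig(nIndividuals = 300, nChromosomes = 3,
                                   nMarkersPerChrom = 120,
                                   nFounderHaplotypes = 4, seed = 71))
  tr <- simulateTrait(g, traitConfig(h2Target = 0.99, nQTL = 100,
                                     seed = 72))
  idx <- seq_len(300) > 250
  rr <- trainModel("rrBLUP", polyGS:::.subsetGeno(g, sampleKeep = !idx),
                   tr$phenotypes[!idx, ], seed = 1)
  pr <- predict(rr, polyGS:::.subsetGeno(g, sampleKeep = idx))
  expect_gte(cor(pr, tr$phenotypes$tar[idx]), 0.95)
})

test_that("held-out accuracy respects the additive ceiling for all models", {
  cap <- sqrt(0.7) + 0.05
  cfg <- list(nIter = 3000, burnIn = 500)
  for (s in 1:5) {
    tt <- makeTrainTest(n = 180, m = 240, h2 = 0.7, nQTL = 150,
                        seed = 80 + s)
    for (mn in gsModelNames()) {
      fit <- trainModel(mn, tt$gTrain, tt$phTrain, config = cfg,
                        seed = s)
      r <- cor(predict(fit, tt$gTest), tt$phTest$tar)
      expect_lte(r, cap)
    }
  }
})

test_that("MCMC training is reproducible and carries diagnostics", {
  tt <- makeTrainTest(n = 100, m = 120, seed = 91)
  cfg <- list(nIter = 2000, burnIn = 500)
  a <- trainModel("BayesB", tt$geno, tt$pheno, config = cfg, seed = 5)
  b <- trainModel("BayesB", tt$geno, tt$pheno, config = cfg, seed = 5)
  expect_identical(a@markerEffects, b@markerEffects)
  expect_equal(a@mcmc$nSamples, 300)
  expect_gt(a@mcmc$essSigma2e, 1)
  d <- trainModel("BayesB", tt$geno, tt$pheno, config = cfg, seed = 6)
  expect_false(identical(a@markerEffects, d@markerEffects))
})

test_that("fitted models survive a text serialization round trip", {
  tt <- makeTrainTest(n = 80, m = 100, nQTL = 60, seed = 95)
  for (mn in c("rrBLUP", "GBLUP", "RKHS")) {
    fit <- trainModel(mn, tt$gTrain, tt$phTrain, seed = 2)
    path <- withr::local_tempfile(fileext = ".yaml")
    writeGSModel(fit, path)
    back <- readGSModel(path)
    expect_equal(predict(back, tt$gTest), predict(fit, tt$gTest),
                 tolerance = 1e-8)
  }
})
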