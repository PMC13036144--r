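# Genotype I/O, QC filtering, imputation and concordance.

test_that("VCF GT codes map to dosages and multiallelic records are skipped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- c(
    "chr1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "chr1\t200\ts2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0/0\t0/1",
    "chr1\t300\ts3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2\t1/2")
  writeVCFFixture(path, rows, c("a", "b", "c", "d"))
  expect_message(g <- readGenotypes(path, "vcf"), "skipped")
  expect_equal(nMarkers(g), 2)
  expect_equal(unname(dosageMatrix(g)[, "s1"]), c(0, 1, 2, NA))
  expect_equal(unname(dosageMatrix(g)[, "s2"]), c(1, 2, 0, 1))
})

test_that("a ten-record VCF with one triallelic site loads nine markers", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- sprintf("chr1\t%d\tm%d\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1", 1:10 * 10,
                  1:10)
  rows[4] <- "chr1\t40\tm4\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2"
  writeVCFFixture(path, rows, c("a", "b"))
  expect_message(g <- readGenotypes(path, "vcf"), "1 non-biallelic")
  expect_equal(nMarkers(g), 9)
})

test_that("VCF and dosage TSV round-trips preserve the panel", {
  g <- simulateGenotypes(simConfig(nIndividuals = 25, nChromosomes = 2,
                                   nMarkersPerChrom = 40, seed = 6))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypes(g, vcf, "vcf")
  g2 <- readGenotypes(vcf, "vcf")
  expect_equal(unname(dosageMatrix(g2)), unname(dosageMatrix(g)))
  expect_equal(markerInfo(g2)$pos, markerInfo(g)$pos)
  expect_equal(sampleIDs(g2), sampleIDs(g))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(g, tsv, "dosage_tsv")
  g3 <- readGenotypes(tsv, "dosage_tsv")
  expect_equal(dosageMatrix(g3), dosageMatrix(g))
})

test_that("PLINK bed/bim/fam triples are read", {
  # 4 individuals x 3 SNPs, SNP-major; 2-bit codes 00=homA1(2) 01=miss
  # 10=het(1) 11=homA2(0)
  prefix <- file.path(withr::local_tempdir(), "toy")
  dos <- rbind(c(2, 1, 0), c(1, 0, NA), c(0, 2, 1), c(2, 2, 2))
  code <- function(x) if (is.na(x)) 1L else c(3L, 2L, 0L)[x + 1]
  bytes <- raw(0)
  for (j in 1:3) {
    b <- 0L
    for (i in 1:4) b <- bitwOr(b, bitwShiftL(code(dos[i, j]), 2L * (i - 1L)))
    bytes <- c(bytes, as.raw(b))
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), paste0(prefix, ".bed"))
  writeLines(sprintf("1\tsnp%d\t0\t%d\tA\tG", 1:3, c(100, 200, 300)),
             paste0(prefix, ".bim"))
  writeLines(sprintf("f%d i%d 0 0 0 -9", 1:4, 1:4), paste0(prefix, ".fam"))
  g <- readGenotypes(prefix, "plink")
  expect_equal(unname(dosageMatrix(g)), unname(dos))
  expect_equal(sampleIDs(g), paste0("i", 1:4))
})

test_that("QC filters remove markers per rule with conserved counts", {
  set.seed(1)
  clean <- matrix(rbinom(20 * 6, 2, 0.4), 20, 6)
  lowmaf <- matrix(c(rep(0, 19), 1), 20, 1)         # MAF 0.025
  missing6 <- matrix(rbinom(20, 2, 0.4), 20, 1)
  missing6[1:12] <- NA                               # 60% missing
  lowdep <- matrix(rbinom(20 * 2, 2, 0.4), 20, 2)
  d <- cbind(clean, lowdep, lowmaf, missing6)
  depth <- c(rep(10, 6), 1.5, 1.5, 10, 10)
  g <- genotypeData(d, chrom = "chr1", pos = 1:10 * 100, meanDepth = depth)
  out <- applyFilters(g, minDepth = 2, minMAF = 0.03, maxMissing = 0.5)
  expect_equal(nMarkers(out$geno), 6)
  rep <- out$report
  expect_equal(rep@removedDepth, 2L)
  expect_equal(rep@removedMAF, 1L)
  expect_equal(rep@removedMissing, 1L)
  expect_equal(rep@nMarkersIn - rep@removedDepth - rep@removedMAF -
                 rep@removedMissing, rep@nMarkersOut)
})

test_that("monomorphic markers fall to the MAF rule; no-op bounds pass all", {
  d <- cbind(rep(2, 12), c(rep(0, 6), rep(1, 4), rep(2, 2)))
  g <- genotypeData(d, chrom = "chr1", pos = c(5, 10),
                    meanDepth = c(10, 10))
  out <- applyFilters(g, minMAF = 0.03)
  expect_equal(markerInfo(out$geno)$pos, 10)
  expect_equal(out$report@removedMAF, 1L)
  g2 <- randomPanel(30, 8, seed = 2)
  noop <- suppressWarnings(applyFilters(g2, minDepth = 0, minMAF = 0,
                                        maxMissing = 1))
  expect_equal(dosageMatrix(noop$geno), dosageMatrix(g2))
  expect_error(applyFilters(g, minMAF = 0.45), "all markers")
})

test_that("filtering is idempotent on degraded panels", {
  for (s in 1:4) {
    g <- degradeGenotypes(
      simulateGenotypes(simConfig(nIndividuals = 60, nChromosomes = 2,
                                  nMarkersPerChrom = 80, seed = s)),
      siteMissingRate = 0.25, indivMissingRate = 0.1, depthMean = 4,
      seed = s)
    suppressMessages({
      once <- applyFilters(g)
      twice <- applyFilters(once$geno)
    })
    expect_identical(dosageMatrix(twice$geno), dosageMatrix(once$geno))
    expect_equal(twice$report@removedDepth +
                   twice$report@removedMAF +
                   twice$report@removedMissing, 0L)
  }
})

test_that("filters skip the depth rule without metadata, with a warning", {
  g <- randomPanel(30, 10, seed = 3)
  expect_warning(out <- applyFilters(g), "depth")
  expect_equal(out$report@removedDepth, 0L)
})

test_that("imputation fills by site mean or mode and is a no-op when full", {
  d <- matrix(c(0, 2, NA,
                0, 0, 2,
                1, 1, 1), 3, 3)
  d <- cbind(d, c(0, 0, 2))
  d[1, 4] <- NA                               # column [NA,0,2] -> mode 0
  g <- genotypeData(d, chrom = "chr1", pos = 1:4 * 10)
  gm <- imputeMissing(g, "site_mean")
  expect_equal(unname(dosageMatrix(gm)[3, 1]), 1.0)
  gmode <- imputeMissing(g, "site_mode")
  expect_equal(unname(dosageMatrix(gmode)[1, 4]), 0)
  full <- randomPanel(10, 5, seed = 4)
  expect_identical(imputeMissing(full, "site_mean"), full)
  dbad <- d; dbad[, 2] <- NA
  gbad <- genotypeData(dbad, chrom = "chr1", pos = 1:4 * 10)
  expect_error(imputeMissing(gbad), "applyFilters")
})

test_that("concordance counts jointly observed equal dosages", {
  a <- randomPanel(10, 10, seed = 5)
  expect_equal(genotypeConcordance(a, a)$overall, 1)
  # flipped homozygotes disagree everywhere except het cells
  d <- dosageMatrix(a)
  flip <- genotypeData(2 - d, chrom = markerInfo(a)$chrom,
                       pos = markerInfo(a)$pos)
  conc <- genotypeConcordance(a, flip)
  expect_equal(conc$overall, mean(d == 1))
  # constructed fixture: 9 of 10 comparable cells equal
  d1 <- matrix(c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2), 2, 5)
  d2 <- d1; d2[1, 1] <- 2
  ga <- genotypeData(d1, chrom = "chr1", pos = 1:5)
  gb <- genotypeData(d2, chrom = "chr1", pos = 1:5)
  expect_equal(genotypeConcordance(ga, gb)$overall, 0.9)
  off <- genotypeData(d1, chrom = "chr9", pos = 1:5)
  expect_error(genotypeConcordance(ga, off), "overlap")
})
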