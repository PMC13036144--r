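# Regional heritability mapping: windows, window model, summaries.

test_that("the window lattice starts at 1 on a 500-kb grid", {
  map <- data.frame(chrom = "chr17", length_bp = 14e6)
  mk <- data.frame(chrom = "chr17", pos = seq(1e4, 14e6, by = 1e4))
  w <- makeWindows(map, mk)@windows
  expect_equal(w$start, 1 + (seq_len(nrow(w)) - 1) * 5e5)
  expect_equal(w$start[25], 12000001)
  expect_equal(w$end[25], 14000000)
  # short chromosome: starts while start <= length, ends truncated
  map2 <- data.frame(chrom = "c", length_bp = 2e6)
  mk2 <- data.frame(chrom = "c", pos = seq(1e4, 2e6, by = 2e4))
  w2 <- makeWindows(map2, mk2)@windows
  expect_equal(nrow(w2), 4)
  expect_equal(w2$end, rep(2e6, 4))
})

test_that("width equal to step tiles markers into exactly one window", {
  g <- simulateGenotypes(simConfig(nIndividuals = 30, nChromosomes = 2,
                                   nMarkersPerChrom = 200,
                                   chromLengthBp = 1e7, seed = 4))
  w <- makeWindows(g, widthBp = 2e6, stepBp = 2e6, minMarkers = 1)@windows
  mk <- markerInfo(g)
  counts <- integer(nrow(mk))
  for (i in seq_len(nrow(w))) {
    inw <- mk$chrom == w$chrom[i] & mk$pos >= w$start[i] & mk$pos <= w$end[i]
    counts <- counts + inw
  }
  expect_true(all(counts == 1))
  expect_error(makeWindows(g, widthBp = 1e6, stepBp = 2e6), "widthBp")
  expect_message(makeWindows(g, minMarkers = 50), "dropped")
})

test_that("local and background scopes must be disjoint", {
  g <- simulateGenotypes(simConfig(nIndividuals = 60, nChromosomes = 2,
                                   nMarkersPerChrom = 60, seed = 8))
  tr <- simulateTrait(g, traitConfig(h2Target = 0.5, nQTL = 40, seed = 9))
  mk <- markerInfo(g)
  sel <- which(mk$chrom == "chr1")[1:20]
  local <- computeGRM(g, markerSubset = sel, scope = "window(chr1:1-99)")
  expect_error(fitWindowModel(tr$phenotypes$tar, local, local, "chr1"),
               "disjoint|loco")
  loco <- computeLocoGRM(g, "chr2")
  expect_error(fitWindowModel(tr$phenotypes$tar, local, loco, "chr1"),
               "loco")
})

test_that("summaries rank by VG1 with exact cumulative fractions", {
  res <- data.frame(chrom = c("c1", "c1", "c2", "c2"),
                    start = c(1, 11, 1, 11), end = c(10, 20, 10, 20),
                    n_markers = 5, vg1 = c(4, 2, 3, 1), vg2 = 1, ve = 1,
                    share = 0.5, lrt = 1, p = 0.3, converged = TRUE)
  s <- summarizeScan(res)
  expect_equal(s$ranked$vg1, c(4, 3, 2, 1))
  expect_equal(s$ranked$cumulative_fraction, c(0.4, 0.7, 0.9, 1.0))
  expect_true(all(diff(s$ranked$cumulative_fraction) >= 0))
  expect_equal(s$ranked$cumulative_fraction[4], 1.0)
  pc <- s$perChromosome
  expect_equal(pc$fraction[pc$chrom == "c1"], 0.6)
  expect_equal(pc$fraction[pc$chrom == "c2"], 0.4)
  one <- summarizeScan(res[1, ])
  expect_equal(one$ranked$cumulative_fraction, 1.0)
  resz <- res; resz$vg1 <- 0
  expect_error(summarizeScan(resz), "zero")
  resn <- res; resn$converged <- FALSE
  expect_error(summarizeScan(resn), "converged")
})

test_that("an enriched window rises to the top of the scan", {
  g <- simulateGenotypes(simConfig(nIndividuals = 250, nChromosomes = 2,
                                   nMarkersPerChrom = 300,
                                   chromLengthBp = 8e6, recombRate = 4,
                                   seed = 55))
  fw <- list(chrom = "chr1", start_bp = 2000001, end_bp = 4000000)
  hits <- 0
  for (s in 1:5) {
    tr <- simulateTrait(g, traitConfig(h2Target = 0.7, nQTL = 150,
                                       focalWindow = fw,
                                       focalFraction = 0.5,
                                       seed = 700 + s))
    sc <- suppressMessages(scanRegions(g, tr$phenotypes, makeWindows(g)))
    lead <- summarizeScan(sc)$lead
    hits <- hits + (lead$chrom == "chr1" && lead$start <= fw$end_bp &&
                      lead$end >= fw$start_bp)
  }
  expect_gte(hits, 4)
})

test_that("detection power grows with the focal variance fraction", {
  g <- simulateGenotypes(simConfig(nIndividuals = 150, nChromosomes = 2,
                                   nMarkersPerChrom = 150,
                                   chromLengthBp = 6e6, recombRate = 3,
                                   seed = 66))
  fw <- list(chrom = "chr1", start_bp = 2000001, end_bp = 4000000)
  det <- vapply(c(0.1, 0.3, 0.5), function(f) {
    hits <- 0
    for (s in 1:20) {
      tr <- simulateTrait(g, traitConfig(h2Target = 0.7, nQTL = 100,
                                         focalWindow = fw,
                                         focalFraction = f,
                                         seed = 800 + s))
      sc <- suppressMessages(scanRegions(g, tr$phenotypes, makeWindows(g)))
      lead <- summarizeScan(sc)$lead
      hits <- hits + (lead$chrom == "chr1" && lead$start <= fw$end_bp &&
                        lead$end >= fw$start_bp)
    }
    hits / 20
  }, numeric(1))
  expect_true(all(diff(det) >= 0))
})

test_that("windows on chromosomes without causal variants stay quiet", {
  # under a LOCO background a window must absorb its own chromosome's
  # polygenic signal, so the proper null for the local component is a
  # chromosome carrying no QTLs: here all genetic variance sits on chr3
  okShare <- 0; rej <- 0; tot <- 0
  for (s in 1:8) {
    g <- simulateGenotypes(simConfig(nIndividuals = 150, nChromosomes = 3,
                                     nMarkersPerChrom = 120,
                                     chromLengthBp = 6e6, recombRate = 3,
                                     seed = 90 + s))
    tr <- simulateTrait(g, traitConfig(
      h2Target = 0.7, nQTL = 150,
      focalWindow = list(chrom = "chr3", start_bp = 1, end_bp = 6e6),
      focalFraction = 1, seed = 190 + s))
    sc <- suppressMessages(scanRegions(g, tr$phenotypes, makeWindows(g)))
    conv <- sc[sc$converged & !is.na(sc$share) & sc$chrom != "chr3", ]
    okShare <- okShare + all(conv$share <= 0.5 + 1e-9)
    rej <- rej + sum(conv$p < 0.05)
    tot <- tot + nrow(conv)
  }
  expect_gte(okShare, 6)
  expect_lte(rej / tot, 0.05 + 2 * sqrt(0.05 * 0.95 / tot))
})
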