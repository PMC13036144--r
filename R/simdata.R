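# Founder-haplotype mosaic genotype simulator and additive trait generator.
# All randomness flows through explicit integer seeds; the caller's RNG
# state is saved and restored.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.markerStats <- function(dosages) {
  miss <- colMeans(is.na(dosages))
  p <- colMeans(dosages, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  list(maf = pmin(p, 1 - p), missing_rate = miss, p_alt = p)
}

#' Construct a GenotypeData object from a dosage matrix
#'
#' MAF and missing rate are computed from the data (non-missing calls only);
#' mean depth is optional metadata.
#'
#' @param dosages numeric matrix (samples x markers), entries in [0, 2] or NA.
#'   Rownames are sample ids; if absent, ids are generated.
#' @param chrom,pos character/integer vectors of marker coordinates (1-based).
#' @param ref,alt allele labels (defaults "A"/"G").
#' @param id marker ids; default \code{chrom_pos}.
#' @param meanDepth optional per-marker mean sequencing depth.
#' @param genomeMap optional data.frame(chrom, length_bp).
#' @return a \linkS4class{GenotypeData}.
#' @export
genotypeData <- function(dosages, chrom, pos, ref = NULL, alt = NULL,
                         id = NULL, meanDepth = NULL, genomeMap = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind%0*d", nchar(nrow(dosages)),
                                 seq_len(nrow(dosages)))
  chrom <- as.character(chrom)
  if (is.null(id)) id <- paste(chrom, pos, sep = "_")
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(meanDepth)) meanDepth <- rep(NA_real_, m)
  st <- .markerStats(dosages)
  markers <- data.frame(id = id, chrom = chrom, pos = as.integer(pos),
                        ref = ref, alt = alt, maf = st$maf,
                        mean_depth = meanDepth,
                        missing_rate = st$missing_rate,
                        stringsAsFactors = FALSE)
  # order by chromosome then position
  o <- order(factor(markers$chrom, levels = unique(markers$chrom)),
             markers$pos)
  markers <- markers[o, , drop = FALSE]
  dosages <- dosages[, o, drop = FALSE]
  colnames(dosages) <- markers$id
  rownames(markers) <- NULL
  if (is.null(genomeMap))
    genomeMap <- data.frame(chrom = character(), length_bp = numeric())
  new("GenotypeData", dosages = dosages, markers = markers,
      genomeMap = genomeMap)
}

#' Simulation configuration constructors
#'
#' \code{simConfig} describes a founder-haplotype mosaic genotype panel;
#' \code{traitConfig} an additive polygenic trait on top of it. Defaults
#' describe a desk-scale GBS-like diversity panel: 436 individuals, 24
#' chromosomes, block-wise LD from 10 founder haplotypes, MAF floor 0.03.
#'
#' @param nIndividuals,nChromosomes,nMarkersPerChrom,nFounderHaplotypes counts.
#' @param chromLengthBp chromosome length (bp).
#' @param recombRate expected crossovers per chromosome per gamete.
#' @param mafFloor minimum realized minor allele frequency, in (0, 0.5).
#' @param seed integer seed.
#' @return a \linkS4class{SimConfig} / \linkS4class{TraitConfig}.
#' @export
simConfig <- function(nIndividuals = 436, nChromosomes = 24,
                      chromLengthBp = 6e7, nMarkersPerChrom = 210,
                      nFounderHaplotypes = 10, recombRate = 15,
                      mafFloor = 0.03, seed = 1) {
  new("SimConfig", nIndividuals = as.integer(nIndividuals),
      nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.numeric(chromLengthBp),
      nMarkersPerChrom = as.integer(nMarkersPerChrom),
      nFounderHaplotypes = as.integer(nFounderHaplotypes),
      recombRate = as.numeric(recombRate), mafFloor = as.numeric(mafFloor),
      seed = as.integer(seed))
}

#' @param h2Target generative narrow-sense heritability in [0, 1); default
#'   0.70, a strongly heritable leaf-chemistry trait.
#' @param nQTL number of causal markers (default 500: dense polygenic
#'   architecture).
#' @param focalWindow optional list(chrom, start_bp, end_bp) whose QTLs are
#'   assigned \code{focalFraction} of the genetic variance.
#' @param focalFraction fraction in [0, 1].
#' @param phenotypeMean trait mean, mg/cigarette scale (default 29.7).
#' @param phenotypeVar total phenotypic variance (default 64, i.e. sd
#'   8 mg/cigarette).
#' @rdname simConfig
#' @export
traitConfig <- function(h2Target = 0.70, nQTL = 500, focalWindow = NULL,
                        focalFraction = 0, phenotypeMean = 29.7,
                        phenotypeVar = 64, seed = 1) {
  if (is.null(focalWindow)) focalWindow <- list()
  else {
    stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(focalWindow)))
    focalWindow <- focalWindow[c("chrom", "start_bp", "end_bp")]
  }
  new("TraitConfig", h2Target = as.numeric(h2Target), nQTL = as.integer(nQTL),
      focalWindow = focalWindow, focalFraction = as.numeric(focalFraction),
      phenotypeMean = as.numeric(phenotypeMean),
      phenotypeVar = as.numeric(phenotypeVar), seed = as.integer(seed))
}

# one chromosome's worth of haplotypes: founder mosaic with Poisson crossovers
.mosaicChrom <- function(nGametes, founders, pos, L, recombRate) {
  m <- length(pos)
  nf <- nrow(founders)
  out <- matrix(0L, nGametes, m)
  for (g in seq_len(nGametes)) {
    ncross <- rpois(1, recombRate)
    if (ncross == 0) {
      out[g, ] <- founders[sample.int(nf, 1), ]
    } else {
      bp <- sort(runif(ncross, 1, L))
      seg <- findInterval(pos, bp) + 1L        # segment index per marker
      fo <- sample.int(nf, ncross + 1L, replace = TRUE)
      out[g, ] <- founders[cbind(fo[seg], seq_len(m))]
    }
  }
  out
}

#' Simulate a genotype panel under the founder-haplotype mosaic model
#'
#' Per chromosome, founder haplotypes are drawn with allele frequencies from
#' a Beta(0.5, 0.5) spectrum truncated to \code{[mafFloor, 1 - mafFloor]};
#' each individual's two haplotypes are mosaics of founders with
#' Poisson(\code{recombRate}) crossovers per gamete. Markers whose realized
#' minor allele frequency falls below \code{mafFloor} are dropped, so every
#' retained marker satisfies the floor exactly. Deterministic under a fixed
#' seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{GenotypeData} with its genome map attached.
#' @examples
#' g <- simulateGenotypes(simConfig(nIndividuals = 50, nChromosomes = 2,
#'                                  nMarkersPerChrom = 40, seed = 1))
#' g
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@nIndividuals
  lens <- rep_len(config@chromLengthBp, config@nChromosomes)
  .withSeed(config@seed, {
    chromNames <- paste0("chr", seq_len(config@nChromosomes))
    dosList <- list(); chromV <- list(); posV <- list()
    for (ci in seq_len(config@nChromosomes)) {
      L <- lens[ci]
      m <- config@nMarkersPerChrom
      pos <- sort(sample.int(L, m))
      # truncated Beta(0.5, 0.5) founder allele frequencies
      p <- rbeta(m, 0.5, 0.5)
      bad <- p < config@mafFloor | p > 1 - config@mafFloor
      while (any(bad)) {
        p[bad] <- rbeta(sum(bad), 0.5, 0.5)
        bad <- p < config@mafFloor | p > 1 - config@mafFloor
      }
      founders <- matrix(rbinom(config@nFounderHaplotypes * m, 1L,
                                rep(p, each = config@nFounderHaplotypes)),
                         nrow = config@nFounderHaplotypes)
      h1 <- .mosaicChrom(n, founders, pos, L, config@recombRate)
      h2 <- .mosaicChrom(n, founders, pos, L, config@recombRate)
      dos <- h1 + h2
      keep <- {
        pa <- colMeans(dos) / 2
        pmin(pa, 1 - pa) >= config@mafFloor
      }
      dosList[[ci]] <- dos[, keep, drop = FALSE]
      chromV[[ci]] <- rep(chromNames[ci], sum(keep))
      posV[[ci]] <- pos[keep]
    }
    dos <- do.call(cbind, dosList)
    if (!ncol(dos)) stop("no marker survived the MAF floor; lower mafFloor")
    rownames(dos) <- sprintf("ind%0*d", max(3L, nchar(n)), seq_len(n))
    genotypeData(dos, chrom = unlist(chromV), pos = unlist(posV),
                 genomeMap = data.frame(chrom = chromNames,
                                        length_bp = lens))
  })
}

#' TrueEffects: ground truth of a simulated trait
#'
#' @slot qtlMarkerIDs ids of the causal markers.
#' @slot qtlEffects named numeric of additive allele-substitution effects for
#'   every marker (zero off the QTLs).
#' @slot realizedH2 realized variance ratio var(g)/var(y) in the sample.
#' @slot geneticValues named numeric of true breeding values.
#' @export
setClass("TrueEffects",
  slots = c(qtlMarkerIDs = "character", qtlEffects = "numeric",
            realizedH2 = "numeric", geneticValues = "numeric"))

setMethod("show", "TrueEffects", function(object) {
  cat(sprintf("TrueEffects: %d QTLs, realized h2 = %.3f\n",
              length(object@qtlMarkerIDs), object@realizedH2))
})

#' Simulate an additive polygenic trait on a genotype panel
#'
#' QTLs are sampled uniformly among markers; effects are drawn Normal(0, 1)
#' and jointly rescaled so the realized genetic variance matches
#' \code{h2Target} within the finite-sample draw. When a focal window is
#' set, effects are first rescaled so the frequency-weighted variance
#' contribution of focal-window QTLs equals \code{focalFraction} of the
#' total (at least one QTL is placed in the window).
#'
#' @param geno a fully observed \linkS4class{GenotypeData}.
#' @param config a \linkS4class{TraitConfig}.
#' @return list with \code{phenotypes} (data.frame sample_id, tar) and
#'   \code{effects} (a \linkS4class{TrueEffects}).
#' @export
simulateTrait <- function(geno, config) {
  stopifnot(is(geno, "GenotypeData"), is(config, "TraitConfig"))
  validObject(config)
  mk <- markerInfo(geno)
  m <- nrow(mk)
  if (config@nQTL > m)
    stop("nQTL exceeds the number of markers (", m, ")")
  if (anyNA(dosageMatrix(geno)))
    stop("trait simulation requires fully observed dosages; impute first")
  inFocal <- rep(FALSE, m)
  if (length(config@focalWindow)) {
    fw <- config@focalWindow
    inFocal <- mk$chrom == fw$chrom & mk$pos >= fw$start_bp &
      mk$pos <= fw$end_bp
    if (!any(inFocal))
      stop(sprintf("focal window %s:%d-%d contains no markers", fw$chrom,
                   as.integer(fw$start_bp), as.integer(fw$end_bp)))
  }
  .withSeed(config@seed, {
    qtl <- sort(sample.int(m, config@nQTL))
    if (any(inFocal) && config@focalFraction > 0 && !any(inFocal[qtl])) {
      # guarantee the enriched window carries at least one causal marker
      qtl[sample.int(length(qtl), 1)] <- sample(which(inFocal), 1)
      qtl <- sort(unique(qtl))
    }
    a <- rnorm(length(qtl))
    X <- dosageMatrix(geno)[, qtl, drop = FALSE]
    p <- colMeans(X) / 2
    vw <- 2 * p * (1 - p)                       # HW variance weight per QTL
    if (any(inFocal[qtl]) && length(config@focalWindow)) {
      f <- config@focalFraction
      foc <- inFocal[qtl]
      Sf <- sum(vw[foc] * a[foc]^2); Sn <- sum(vw[!foc] * a[!foc]^2)
      Tt <- Sf + Sn
      if (Sf > 0) a[foc] <- a[foc] * sqrt(f * Tt / Sf)
      if (Sn > 0) a[!foc] <- a[!foc] * sqrt((1 - f) * Tt / max(Sn, 1e-300))
    }
    W <- sweep(X, 2, 2 * p)                     # centered dosages
    g <- drop(W %*% a)
    V0 <- config@phenotypeVar
    h2 <- config@h2Target
    if (h2 > 0 && var(g) > 0) {
      sc <- sqrt(h2 * V0 / var(g))
      a <- a * sc; g <- g * sc
    } else {
      a <- a * 0; g <- g * 0
    }
    e <- rnorm(length(g), 0, sqrt((1 - h2) * V0))
    y <- config@phenotypeMean + g + e
    eff <- setNames(numeric(m), mk$id)
    eff[qtl] <- a
    te <- new("TrueEffects", qtlMarkerIDs = mk$id[qtl], qtlEffects = eff,
              realizedH2 = if (var(y) > 0) var(g) / var(y) else 0,
              geneticValues = setNames(g, sampleIDs(geno)))
    list(phenotypes = data.frame(sample_id = sampleIDs(geno), tar = y,
                                 stringsAsFactors = FALSE),
         effects = te)
  })
}

#' Degrade a genotype panel for QC testing
#'
#' Masks dosages to missing under compound per-site / per-individual
#' missingness and attaches per-site mean depths drawn from a Gamma
#' distribution with the requested mean (shape 4). The input object is not
#' modified.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param siteMissingRate,indivMissingRate masking probabilities in [0, 1);
#'   an entry is masked with probability
#'   \code{1 - (1 - site)(1 - indiv)}.
#' @param depthMean mean per-site sequencing depth.
#' @param seed integer seed.
#' @return a new \linkS4class{GenotypeData} with missing entries and depth
#'   metadata; MAF and missing rates recomputed.
#' @export
degradeGenotypes <- function(geno, siteMissingRate = 0.1,
                             indivMissingRate = 0.05, depthMean = 8,
                             seed = 1) {
  stopifnot(is(geno, "GenotypeData"))
  if (siteMissingRate < 0 || siteMissingRate >= 1 ||
      indivMissingRate < 0 || indivMissingRate >= 1)
    stop("missing rates must lie in [0, 1)")
  .withSeed(seed, {
    d <- dosageMatrix(geno)
    pmiss <- 1 - (1 - siteMissingRate) * (1 - indivMissingRate)
    if (pmiss > 0) {
      mask <- matrix(runif(length(d)) < pmiss, nrow(d))
      d[mask] <- NA_real_
    }
    mk <- markerInfo(geno)
    depth <- rgamma(ncol(d), shape = 4, rate = 4 / depthMean)
    genotypeData(d, chrom = mk$chrom, pos = mk$pos, ref = mk$ref,
                 alt = mk$alt, id = mk$id, meanDepth = depth,
                 genomeMap = genomeMap(geno))
  })
}

#' Write the ground-truth effects of a simulated trait to TSV
#'
#' @param effects a \linkS4class{TrueEffects}.
#' @param path output file.
#' @export
writeTrueEffects <- function(effects, path) {
  df <- data.frame(marker_id = names(effects@qtlEffects),
                   effect = unname(effects@qtlEffects),
                   is_qtl = names(effects@qtlEffects) %in%
                     effects@qtlMarkerIDs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
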