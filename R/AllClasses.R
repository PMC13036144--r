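#' @import methods
#' @importFrom stats var cor sd rnorm runif rbinom rpois rgamma optimize
#'   pchisq pnorm qnorm lm coef resid median setNames quantile ecdf ks.test
#'   complete.cases
#' @importFrom utils read.table write.table head packageVersion
NULL

#' GenotypeData: an individuals-by-markers SNP dosage panel
#'
#' Container for biallelic SNP genotypes coded as alt-allele dosages in
#' \code{[0, 2]} (fractional values allowed after mean imputation, \code{NA}
#' for missing), together with per-marker metadata and an optional genome map.
#'
#' @slot dosages numeric matrix, samples in rows (rownames are sample ids),
#'   markers in columns (colnames are marker ids).
#' @slot markers data.frame with one row per marker: \code{id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{ref}, \code{alt}, \code{maf},
#'   \code{mean_depth}, \code{missing_rate}.
#' @slot genomeMap data.frame with columns \code{chrom}, \code{length_bp}
#'   (may have zero rows when no map is known).
#'
#' @export
setClass("GenotypeData",
  slots = c(dosages = "matrix", markers = "data.frame",
            genomeMap = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosages
  mk <- object@markers
  need <- c("id", "chrom", "pos", "ref", "alt", "maf", "mean_depth",
            "missing_rate")
  if (!all(need %in% names(mk)))
    msg <- c(msg, paste("markers lacks columns:",
                        paste(setdiff(need, names(mk)), collapse = ", ")))
  if (ncol(d) != nrow(mk))
    msg <- c(msg, "ncol(dosages) != nrow(markers)")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msg <- c(msg, "sample ids (rownames) must be present and unique")
  rng <- range(d, na.rm = TRUE)
  if (ncol(d) && (rng[1] < -1e-9 || rng[2] > 2 + 1e-9))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (all(need %in% names(mk)) && nrow(mk)) {
    bad <- tapply(mk$pos, mk$chrom, function(p) any(diff(p) <= 0))
    if (any(unlist(bad)))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
    if (any(mk$maf < -1e-12 | mk$maf > 0.5 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' GRM: a genomic relationship matrix
#'
#' Symmetric positive-semidefinite marker-based relationship matrix with the
#' sample ids it covers, the number of markers that entered it, and a scope
#' descriptor (\code{"all"}, \code{"window(chrom:start-end)"} or
#' \code{"loco(chrom)"}).
#'
#' @slot sampleIDs character vector of sample ids (matrix dimnames).
#' @slot values numeric n-by-n symmetric matrix.
#' @slot nMarkersUsed integer count of (polymorphic) markers used.
#' @slot scope character scope descriptor.
#' @export
setClass("GRM",
  slots = c(sampleIDs = "character", values = "matrix",
            nMarkersUsed = "integer", scope = "character"))

setValidity("GRM", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v) || nrow(v) != length(object@sampleIDs))
    msg <- c(msg, "values must be square and match sampleIDs")
  else {
    if (max(abs(v - t(v))) > 1e-10)
      msg <- c(msg, "values must be symmetric within 1e-10")
    ev <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-6 * max(1, max(abs(diag(v)))))
      msg <- c(msg, sprintf("GRM has negative eigenvalue %.3g", ev))
  }
  if (length(msg)) msg else TRUE
})

#' VarCompFit: REML variance-component estimates
#'
#' @slot sigma2 named numeric: one entry per genetic component plus
#'   \code{"residual"} (trait units squared).
#' @slot se numeric standard errors (inverse average-information matrix).
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot h2 heritability per genetic component,
#'   \eqn{\sigma^2_{g_i} / (\sum_j \sigma^2_{g_j} + \sigma^2_e)}.
#' @slot h2Se delta-method standard error of h2 (single-component fits).
#' @slot nIter iterations used.
#' @slot converged logical convergence flag.
#' @slot boundary logical per-component flag: estimate clamped at the zero
#'   boundary.
#' @slot n number of individuals.
#' @slot nFixed number of fixed-effect columns.
#' @export
setClass("VarCompFit",
  slots = c(sigma2 = "numeric", se = "numeric", loglik = "numeric",
            h2 = "numeric", h2Se = "numeric", nIter = "integer",
            converged = "logical", boundary = "logical", n = "integer",
            nFixed = "integer"))

setValidity("VarCompFit", function(object) {
  if (any(object@sigma2 < -1e-12)) "variance components must be >= 0" else TRUE
})

#' QCReport: marker/sample filtering audit
#'
#' Counts removed per rule in the fixed order depth, MAF, site missingness,
#' then individual missingness; each removed marker is attributed to the
#' first rule it fails.
#'
#' @slot nSamplesIn,nMarkersIn input counts.
#' @slot removedDepth,removedMAF,removedMissing markers removed per rule.
#' @slot samplesRemoved individuals removed for missingness.
#' @slot nSamplesOut,nMarkersOut output counts.
#' @slot thresholds list of the thresholds used.
#' @export
setClass("QCReport",
  slots = c(nSamplesIn = "integer", nMarkersIn = "integer",
            removedDepth = "integer", removedMAF = "integer",
            removedMissing = "integer", samplesRemoved = "integer",
            nSamplesOut = "integer", nMarkersOut = "integer",
            thresholds = "list"))

setValidity("QCReport", function(object) {
  ok <- object@nMarkersIn - object@removedDepth - object@removedMAF -
    object@removedMissing == object@nMarkersOut &&
    object@nSamplesIn - object@samplesRemoved == object@nSamplesOut
  if (ok) TRUE else "counts are not conserved (input != output + removed)"
})

#' GSModel: a fitted genomic-prediction model
#'
#' One container for all twelve statistical models. Marker-effect models
#' store an intercept and per-marker effects on the training scaling;
#' kinship/kernel models store the training context needed for kernel
#' regression on new samples.
#'
#' @slot modelName one of the names listed in [gsModelNames()].
#' @slot intercept numeric fixed intercept.
#' @slot markerEffects numeric per-marker effects (length 0 for pure
#'   kinship/kernel models).
#' @slot markerIDs training marker ids, in order.
#' @slot scaling list with per-marker \code{center} and \code{scale} used at
#'   training time (so new genotypes are placed on the same scale).
#' @slot trainContext list: kinship/kernel machinery (training dosages,
#'   variance components, weights) for GBLUP/RKHS-type predictions.
#' @slot hyperparams list of the hyperparameters actually used.
#' @slot mcmc list of MCMC diagnostics for Bayesian models (chain length,
#'   burn-in, thinning, effective sample size of the residual variance).
#' @slot seed integer RNG seed used for training.
#' @export
setClass("GSModel",
  slots = c(modelName = "character", intercept = "numeric",
            markerEffects = "numeric", markerIDs = "character",
            scaling = "list", trainContext = "list", hyperparams = "list",
            mcmc = "list", seed = "integer"))

#' CVReport: seeded k-fold cross-validation results
#'
#' @slot k number of folds.
#' @slot seed partition seed.
#' @slot foldAssignment named integer: fold index per sample.
#' @slot perFold data.frame (model, fold, n, r).
#' @slot summary data.frame (model, pooled_r, mean_fold_r, sd_fold_r,
#'   runtime_s) — pooled_r is the Pearson correlation between concatenated
#'   out-of-fold predictions and observed phenotypes.
#' @slot predictions data.frame (sample_id, fold, model, gebv, observed).
#' @export
setClass("CVReport",
  slots = c(k = "integer", seed = "integer", foldAssignment = "integer",
            perFold = "data.frame", summary = "data.frame",
            predictions = "data.frame"))

#' SimConfig: founder-haplotype mosaic genotype simulation settings
#'
#' @slot nIndividuals,nChromosomes,nMarkersPerChrom,nFounderHaplotypes counts.
#' @slot chromLengthBp chromosome length in bp (recycled over chromosomes).
#' @slot recombRate expected crossovers per chromosome per gamete.
#' @slot mafFloor minimum realized minor allele frequency, in (0, 0.5).
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  slots = c(nIndividuals = "integer", nChromosomes = "integer",
            chromLengthBp = "numeric", nMarkersPerChrom = "integer",
            nFounderHaplotypes = "integer", recombRate = "numeric",
            mafFloor = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nFounderHaplotypes < 2) msg <- c(msg, "need >= 2 founder haplotypes")
  if (object@mafFloor <= 0) msg <- c(msg, "mafFloor must be > 0")
  if (object@mafFloor >= 0.5) msg <- c(msg, "mafFloor must be < 0.5")
  if (object@nMarkersPerChrom < 1) msg <- c(msg, "nMarkersPerChrom must be >= 1")
  if (object@nIndividuals < 1 || object@nChromosomes < 1)
    msg <- c(msg, "counts must be positive")
  if (object@recombRate < 0) msg <- c(msg, "recombRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TraitConfig: additive polygenic trait simulation settings
#'
#' @slot h2Target generative narrow-sense heritability in [0, 1).
#' @slot nQTL number of causal markers.
#' @slot focalWindow optional list(chrom, start_bp, end_bp) enriched region
#'   (empty list for none).
#' @slot focalFraction fraction of genetic variance assigned to QTLs inside
#'   the focal window.
#' @slot phenotypeMean trait mean (mg/cigarette for the tar use case).
#' @slot phenotypeVar total phenotypic variance (trait units squared).
#' @slot seed integer RNG seed.
#' @export
setClass("TraitConfig",
  slots = c(h2Target = "numeric", nQTL = "integer", focalWindow = "list",
            focalFraction = "numeric", phenotypeMean = "numeric",
            phenotypeVar = "numeric", seed = "integer"))

setValidity("TraitConfig", function(object) {
  msg <- character()
  if (object@h2Target < 0 || object@h2Target >= 1)
    msg <- c(msg, "h2Target must lie in [0, 1)")
  if (object@focalFraction < 0 || object@focalFraction > 1)
    msg <- c(msg, "focalFraction must lie in [0, 1]")
  if (!length(object@focalWindow) && object@focalFraction != 0)
    msg <- c(msg, "focalFraction must be 0 when no focalWindow is set")
  if (object@phenotypeVar <= 0) msg <- c(msg, "phenotypeVar must be > 0")
  if (object@nQTL < 1) msg <- c(msg, "nQTL must be >= 1")
  if (length(msg)) msg else TRUE
})
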