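#' @describeIn GenotypeData-accessors sample ids in matrix order
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @describeIn GenotypeData-accessors number of individuals
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @describeIn GenotypeData-accessors number of markers
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @describeIn GenotypeData-accessors the dosage matrix (samples x markers)
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @describeIn GenotypeData-accessors per-marker metadata data.frame
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @describeIn GenotypeData-accessors chromosome length table
#' @export
setGeneric("genomeMap", function(x) standardGeneric("genomeMap"))
#' @rdname grmValues
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))
#' @rdname grmValues
#' @export
setGeneric("markerScope", function(x) standardGeneric("markerScope"))
#' @rdname grmValues
#' @export
setGeneric("nMarkersUsed", function(x) standardGeneric("nMarkersUsed"))
#' @rdname varComp
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname varComp
#' @export
setGeneric("logLikREML", function(x) standardGeneric("logLikREML"))
#' @rdname varComp
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Accessors for GenotypeData
#'
#' @param x a \linkS4class{GenotypeData}.
#' @name GenotypeData-accessors
#' @aliases sampleIDs nSamples nMarkers dosageMatrix markerInfo genomeMap
NULL

#' @rdname GenotypeData-accessors
#' @export
setMethod("sampleIDs", "GenotypeData", function(x) rownames(x@dosages))
#' @rdname GenotypeData-accessors
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosages))
#' @rdname GenotypeData-accessors
#' @export
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@dosages))
#' @rdname GenotypeData-accessors
#' @export
setMethod("dosageMatrix", "GenotypeData", function(x) x@dosages)
#' @rdname GenotypeData-accessors
#' @export
setMethod("markerInfo", "GenotypeData", function(x) x@markers)
#' @rdname GenotypeData-accessors
#' @export
setMethod("genomeMap", "GenotypeData", function(x) x@genomeMap)

#' Accessors for GRM objects
#'
#' @param x a \linkS4class{GRM}.
#' @return \code{grmValues}: the n-by-n matrix; \code{markerScope}: the scope
#'   descriptor; \code{nMarkersUsed}: marker count behind the matrix.
#' @rdname grmValues
#' @export
setMethod("grmValues", "GRM", function(x) x@values)
#' @rdname grmValues
#' @export
setMethod("markerScope", "GRM", function(x) x@scope)
#' @rdname grmValues
#' @export
setMethod("nMarkersUsed", "GRM", function(x) x@nMarkersUsed)
#' @rdname grmValues
#' @export
setMethod("sampleIDs", "GRM", function(x) x@sampleIDs)

#' Accessors for VarCompFit objects
#'
#' @param x a \linkS4class{VarCompFit}.
#' @return \code{varComp}: named vector of variance components;
#'   \code{logLikREML}: restricted log-likelihood; \code{isConverged}:
#'   convergence flag.
#' @rdname varComp
#' @export
setMethod("varComp", "VarCompFit", function(x) x@sigma2)
#' @rdname varComp
#' @export
setMethod("logLikREML", "VarCompFit", function(x) x@loglik)
#' @rdname varComp
#' @export
setMethod("isConverged", "VarCompFit", function(x) x@converged)

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d samples x %d markers on %d chromosome(s)\n",
              nrow(object@dosages), ncol(object@dosages),
              length(unique(object@markers$chrom))))
  nm <- sum(is.na(object@dosages))
  cat(sprintf("  missing dosages: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(object@dosages))))
  if (nrow(object@markers))
    cat(sprintf("  MAF range: %.3f-%.3f\n",
                min(object@markers$maf, na.rm = TRUE),
                max(object@markers$maf, na.rm = TRUE)))
})

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM (%s): %d samples, %d markers used\n", object@scope,
              length(object@sampleIDs), object@nMarkersUsed))
  cat(sprintf("  mean diagonal: %.3f\n", mean(diag(object@values))))
})

setMethod("show", "VarCompFit", function(object) {
  cat(sprintf("VarCompFit (n = %d, %s, %d iterations)\n", object@n,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
  comps <- names(object@sigma2)
  for (i in seq_along(comps))
    cat(sprintf("  %-10s %10.4f (SE %.4f)%s\n", comps[i], object@sigma2[i],
                object@se[i],
                if (i <= length(object@boundary) && object@boundary[i])
                  " [boundary]" else ""))
  if (length(object@h2))
    cat(sprintf("  h2 = %.3f (SE %.3f)\n", object@h2[1], object@h2Se[1]))
  cat(sprintf("  restricted logLik = %.4f\n", object@loglik))
})

setMethod("show", "QCReport", function(object) {
  cat("QC report\n")
  cat(sprintf("  input : %d samples, %d markers\n", object@nSamplesIn,
              object@nMarkersIn))
  cat(sprintf("  removed markers: depth %d, MAF %d, missingness %d\n",
              object@removedDepth, object@removedMAF, object@removedMissing))
  cat(sprintf("  removed samples: %d\n", object@samplesRemoved))
  cat(sprintf("  output: %d samples, %d markers\n", object@nSamplesOut,
              object@nMarkersOut))
})

setMethod("show", "GSModel", function(object) {
  cat(sprintf("GSModel '%s': %d training markers\n", object@modelName,
              length(object@markerIDs)))
  if (length(object@markerEffects))
    cat(sprintf("  marker effects stored (intercept %.4f)\n",
                object@intercept))
  else cat("  kinship/kernel prediction context stored\n")
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: k = %d, seed = %d, %d samples\n", object@k,
              object@seed, length(object@foldAssignment)))
  print(object@summary, row.names = FALSE)
})
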