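# Regional heritability mapping: sliding windows, per-window two-component
# REML (local + LOCO background + residual) and VG1-share summaries.

#' WindowSet: sliding genomic windows
#'
#' @slot windows data.frame(chrom, start, end, n_markers), 1-based inclusive.
#' @slot widthBp,stepBp lattice parameters.
#' @slot minMarkers marker floor per retained window.
#' @export
setClass("WindowSet",
  slots = c(windows = "data.frame", widthBp = "numeric", stepBp = "numeric",
            minMarkers = "integer"))

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows (width %g bp, step %g bp, >= %d markers)\n",
              nrow(object@windows), object@widthBp, object@stepBp,
              object@minMarkers))
})

#' Build sliding windows over a genome
#'
#' Per chromosome, windows start at \code{1 + k * stepBp} while the start
#' does not exceed the chromosome length; trailing windows are truncated at
#' the chromosome end. Windows holding fewer than \code{minMarkers} markers
#' are dropped with a logged count.
#'
#' @param map data.frame(chrom, length_bp) or a \linkS4class{GenotypeData}
#'   whose genome map is used.
#' @param markers marker data.frame (\code{chrom}, \code{pos}); defaults to
#'   the markers of \code{map} when that is a GenotypeData.
#' @param widthBp window width (default 2 Mb).
#' @param stepBp step size (default 500 kb); \code{widthBp >= stepBp > 0}.
#' @param minMarkers minimum markers per window (default 10).
#' @return a \linkS4class{WindowSet}.
#' @export
makeWindows <- function(map, markers = NULL, widthBp = 2e6, stepBp = 5e5,
                        minMarkers = 10) {
  if (is(map, "GenotypeData")) {
    if (is.null(markers)) markers <- markerInfo(map)
    map <- genomeMap(map)
  }
  stopifnot(widthBp >= stepBp, stepBp > 0)
  if (is.null(markers) || !nrow(markers)) stop("empty marker set")
  if (!nrow(map))
    map <- data.frame(chrom = unique(markers$chrom),
                      length_bp = tapply(markers$pos,
                        factor(markers$chrom,
                               levels = unique(markers$chrom)), max))
  out <- list()
  for (i in seq_len(nrow(map))) {
    L <- map$length_bp[i]
    starts <- seq(1, L, by = stepBp)
    ends <- pmin(starts + widthBp - 1, L)
    pos <- markers$pos[markers$chrom == map$chrom[i]]
    cnt <- vapply(seq_along(starts), function(j)
      sum(pos >= starts[j] & pos <= ends[j]), integer(1))
    out[[i]] <- data.frame(chrom = map$chrom[i], start = starts, end = ends,
                           n_markers = cnt, stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, out)
  drop <- win$n_markers < minMarkers
  if (any(drop))
    message(sum(drop), " window(s) dropped below the ", minMarkers,
            "-marker floor")
  win <- win[!drop, , drop = FALSE]
  rownames(win) <- NULL
  new("WindowSet", windows = win, widthBp = widthBp, stepBp = stepBp,
      minMarkers = as.integer(minMarkers))
}

#' Fit the two-genetic-component window model
#'
#' \eqn{y = Xb + u_1 + u_2 + e} with \eqn{u_1} structured by the local
#' (window) GRM and \eqn{u_2} by the LOCO background GRM. The two GRMs'
#' marker scopes must be disjoint: the background must be the
#' leave-one-chromosome-out matrix of the window's chromosome.
#'
#' @param y phenotype vector aligned with the GRMs.
#' @param localGRM,backgroundGRM \linkS4class{GRM} objects; scopes are
#'   validated (\code{window(...)} vs \code{loco(<chrom>)}).
#' @param chrom the window's chromosome (for scope validation).
#' @param nullFit optional precomputed background-only
#'   \linkS4class{VarCompFit} (cached per chromosome by [scanRegions()]).
#' @param init optional starting values for (vg1, vg2, ve).
#' @return list with the full fit, the null fit, the LRT and the VG1 share.
#' @export
fitWindowModel <- function(y, localGRM, backgroundGRM, chrom,
                           nullFit = NULL, init = NULL) {
  stopifnot(is(localGRM, "GRM"), is(backgroundGRM, "GRM"))
  if (!identical(markerScope(backgroundGRM), sprintf("loco(%s)", chrom)))
    stop("background GRM scope must be loco(", chrom,
         "); local and background marker scopes must be disjoint")
  if (identical(markerScope(localGRM), markerScope(backgroundGRM)))
    stop("local and background GRMs must not share marker scope")
  full <- fitREML(y, list(localGRM, backgroundGRM),
                  componentNames = c("local", "background"), init = init)
  if (is.null(nullFit)) nullFit <- fitREML(y, backgroundGRM,
                                           componentNames = "background")
  lrt <- lrtGenetic(full, nullFit, df = 1)
  vg1 <- varComp(full)[["local"]]; vg2 <- varComp(full)[["background"]]
  share <- if (vg1 + vg2 > 0) vg1 / (vg1 + vg2) else NA_real_
  list(full = full, null = nullFit, lrt = lrt, share = share)
}

#' Regional heritability scan
#'
#' For each window: a local GRM from the window's markers, the cached
#' leave-one-chromosome-out background GRM of the window's chromosome, a
#' three-component REML fit (local + background + residual), and a df = 1
#' likelihood-ratio test against the background-only model. Non-converged
#' windows are flagged, not dropped; windows with fewer than two
#' polymorphic markers are skipped with a log entry.
#'
#' @param geno a fully observed \linkS4class{GenotypeData} spanning at least
#'   two chromosomes.
#' @param pheno data.frame with \code{sample_id} and \code{tar}.
#' @param windows a \linkS4class{WindowSet} from [makeWindows()].
#' @return data.frame with one row per scanned window: \code{chrom},
#'   \code{start}, \code{end}, \code{n_markers}, \code{vg1}, \code{vg2},
#'   \code{ve}, \code{share}, \code{lrt}, \code{p}, \code{converged}.
#' @export
scanRegions <- function(geno, pheno, windows) {
  stopifnot(is(windows, "WindowSet"))
  al <- alignSamples(geno, pheno)
  geno <- al$geno; y <- al$pheno$tar
  mk <- markerInfo(geno)
  if (length(unique(mk$chrom)) < 2)
    stop("regional scan requires >= 2 chromosomes (LOCO background)")
  win <- windows@windows
  locoCache <- list(); nullCache <- list()
  rows <- vector("list", nrow(win))
  lastInit <- NULL; lastChrom <- ""
  for (i in seq_len(nrow(win))) {
    cc <- win$chrom[i]
    if (is.null(locoCache[[cc]])) {
      locoCache[[cc]] <- computeLocoGRM(geno, cc)
      nullCache[[cc]] <- fitREML(y, locoCache[[cc]],
                                 componentNames = "background")
      lastInit <- NULL
    }
    sel <- which(mk$chrom == cc & mk$pos >= win$start[i] &
                   mk$pos <= win$end[i])
    poly <- sel[mk$maf[sel] > 0]
    if (length(poly) < 2) {
      message(sprintf("window %s:%d-%d skipped: < 2 polymorphic markers",
                      cc, win$start[i], win$end[i]))
      next
    }
    localGRM <- computeGRM(geno, markerSubset = poly,
                           scope = sprintf("window(%s:%d-%d)", cc,
                                           win$start[i], win$end[i]))
    if (lastChrom != cc) lastInit <- NULL
    fw <- fitWindowModel(y, localGRM, locoCache[[cc]], cc,
                         nullFit = nullCache[[cc]], init = lastInit)
    sc <- varComp(fw$full)
    lastInit <- unname(sc); lastChrom <- cc
    rows[[i]] <- data.frame(chrom = cc, start = win$start[i],
                            end = win$end[i], n_markers = length(poly),
                            vg1 = unname(sc[["local"]]),
                            vg2 = unname(sc[["background"]]),
                            ve = unname(sc[["residual"]]),
                            share = fw$share, lrt = fw$lrt$statistic,
                            p = fw$lrt$p, converged = isConverged(fw$full),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no window could be scanned")
  rownames(out) <- NULL
  out
}

#' Summarize a regional heritability scan
#'
#' Windows are ranked by local genetic variance (VG1) in decreasing order
#' (ties broken by chromosome then start). Cumulative fractions are with
#' respect to the summed VG1 over converged windows; because sliding
#' windows overlap, these are fractions of the VG1 sum, never a
#' decomposition of genome heritability. Per-chromosome contributions and
#' the lead window (with its VG1/(VG1+VG2) share) are reported.
#'
#' @param results scan data.frame from [scanRegions()].
#' @param topK cumulative-fraction checkpoints (default c(10, 50, 100)).
#' @return list with \code{ranked} (data.frame with
#'   \code{cumulative_fraction}), \code{topFractions},
#'   \code{perChromosome}, and \code{lead} (the top row).
#' @export
summarizeScan <- function(results, topK = c(10, 50, 100)) {
  conv <- results[results$converged, , drop = FALSE]
  if (!nrow(conv)) stop("no converged window to summarize")
  tot <- sum(conv$vg1)
  if (tot <= 0) stop("all VG1 estimates are zero; fractions are undefined")
  o <- order(-conv$vg1,
             factor(conv$chrom, levels = unique(conv$chrom)), conv$start)
  ranked <- conv[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  ranked$cumulative_fraction <- cumsum(ranked$vg1) / tot
  rownames(ranked) <- NULL
  topK <- as.integer(topK[topK <= nrow(ranked)])
  perChrom <- aggregate(vg1 ~ chrom, data = conv, FUN = sum)
  perChrom$fraction <- perChrom$vg1 / tot
  list(ranked = ranked,
       topFractions = if (length(topK))
         setNames(ranked$cumulative_fraction[topK], paste0("top", topK))
       else setNames(numeric(0), character(0)),
       perChromosome = perChrom,
       lead = ranked[1, , drop = FALSE])
}

#' Write regional-scan outputs as TSV
#'
#' @param results scan data.frame.
#' @param path scan output file.
#' @param summaryPath optional ranked-summary output file.
#' @export
writeScan <- function(results, path, summaryPath = NULL) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summaryPath)) {
    s <- summarizeScan(results)
    write.table(s$ranked, summaryPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
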