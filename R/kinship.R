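# Genomic relationship matrices: global, windowed, leave-one-chromosome-out,
# plus GRM-based PCA and GCTA-compatible I/O.

.grmFromDosage <- function(d, method = c("vanraden", "gcta"), scope = "all") {
  method <- match.arg(method)
  if (anyNA(d)) stop("GRM construction requires imputed (complete) dosages")
  if (nrow(d) < 2) stop("need at least 2 samples for a GRM")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  nmono <- sum(!poly)
  if (nmono) message(nmono, " monomorphic marker(s) excluded from GRM")
  if (sum(poly) < 2) stop("fewer than 2 polymorphic markers for GRM")
  W <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  if (method == "vanraden") {
    G <- tcrossprod(W) / sum(2 * p[poly] * (1 - p[poly]))
  } else {
    # GCTA-style: per-marker standardization before averaging
    W <- sweep(W, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
    G <- tcrossprod(W) / sum(poly)
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(d), rownames(d))
  new("GRM", sampleIDs = rownames(d), values = G,
      nMarkersUsed = as.integer(sum(poly)), scope = scope)
}

#' Compute a genomic relationship matrix
#'
#' Default is VanRaden method 1: dosages centered by twice the in-sample
#' allele frequency, \eqn{G = WW^T / \sum_j 2 p_j (1 - p_j)}. The
#' \code{"gcta"} flavor standardizes each marker before averaging.
#' Monomorphic markers are excluded with a logged count.
#'
#' @param geno a fully observed \linkS4class{GenotypeData}.
#' @param markerSubset optional logical/integer/character index of markers
#'   to use (ids matched against marker ids).
#' @param method \code{"vanraden"} (default) or \code{"gcta"}.
#' @param scope scope descriptor stored on the result.
#' @return a \linkS4class{GRM}.
#' @export
computeGRM <- function(geno, markerSubset = NULL,
                       method = c("vanraden", "gcta"), scope = NULL) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosageMatrix(geno)
  if (!is.null(markerSubset)) {
    if (is.character(markerSubset))
      markerSubset <- match(markerSubset, markerInfo(geno)$id)
    d <- d[, markerSubset, drop = FALSE]
    if (is.null(scope)) scope <- "subset"
  }
  if (is.null(scope)) scope <- "all"
  .grmFromDosage(d, method = method, scope = scope)
}

#' Leave-one-chromosome-out GRM
#'
#' Relationship matrix over all markers not on the excluded chromosome,
#' for use as the polygenic background when scanning that chromosome.
#'
#' @param geno a fully observed \linkS4class{GenotypeData}.
#' @param excludedChrom chromosome name to leave out.
#' @param method GRM flavor, see [computeGRM()].
#' @return a \linkS4class{GRM} with scope \code{loco(<chrom>)}.
#' @export
computeLocoGRM <- function(geno, excludedChrom,
                           method = c("vanraden", "gcta")) {
  mk <- markerInfo(geno)
  chroms <- unique(mk$chrom)
  if (length(chroms) < 2)
    stop("LOCO background requires at least 2 chromosomes")
  if (!excludedChrom %in% chroms)
    stop("chromosome not present: ", excludedChrom)
  keep <- mk$chrom != excludedChrom
  computeGRM(geno, markerSubset = keep, method = method,
             scope = sprintf("loco(%s)", excludedChrom))
}

#' Principal components of a GRM
#'
#' Eigendecomposition of the double-centered relationship matrix.
#' Variance-explained fractions are eigenvalues over the sum of the
#' non-negative eigenvalues; components are ordered by decreasing
#' eigenvalue, with the sign convention that the largest-magnitude loading
#' of each component is positive.
#'
#' @param grm a \linkS4class{GRM}.
#' @param k number of components to return (at most n - 1).
#' @return list with \code{scores} (n x k matrix), \code{varExplained}
#'   (length-k fractions) and \code{eigenvalues}.
#' @export
grmPCA <- function(grm, k = 10) {
  G <- grmValues(grm)
  n <- nrow(G)
  if (k < 1 || k > n - 1) stop("k must lie in [1, n - 1]")
  J <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(J %*% G %*% J, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(sampleIDs(grm), paste0("PC", seq_len(k)))
  list(scores = scores,
       varExplained = pos[seq_len(k)] / sum(pos),
       eigenvalues = e$values)
}

#' Write / read a GRM
#'
#' \code{format = "tsv"} writes a plain matrix with sample-id dimnames.
#' \code{format = "gcta"} writes the GCTA-compatible binary triple
#' \code{<prefix>.grm.bin} (lower triangle, single-precision floats),
#' \code{<prefix>.grm.N.bin} and \code{<prefix>.grm.id}.
#'
#' @param grm a \linkS4class{GRM}.
#' @param path file path (TSV) or prefix (GCTA triple).
#' @param format \code{"tsv"} or \code{"gcta"}.
#' @export
writeGRM <- function(grm, path, format = c("tsv", "gcta")) {
  format <- match.arg(format)
  G <- grmValues(grm)
  if (format == "tsv") {
    write.table(G, path, sep = "\t", quote = FALSE)
    return(invisible(path))
  }
  n <- nrow(G)
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  con <- file(paste0(path, ".grm.bin"), "wb")
  writeBin(as.numeric(G[idx]), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(path, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm@nMarkersUsed), nrow(idx)), con, size = 4,
           endian = "little")
  close(con)
  write.table(data.frame(fid = sampleIDs(grm), iid = sampleIDs(grm)),
              paste0(path, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param scope scope descriptor to attach on read.
#' @rdname writeGRM
#' @export
readGRM <- function(path, format = c("tsv", "gcta"), scope = "all") {
  format <- match.arg(format)
  if (format == "tsv") {
    G <- as.matrix(read.table(path, sep = "\t", check.names = FALSE))
    return(new("GRM", sampleIDs = rownames(G), values = (G + t(G)) / 2,
               nMarkersUsed = NA_integer_, scope = scope))
  }
  ids <- read.table(paste0(path, ".grm.id"), stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  nv <- n * (n + 1) / 2
  v <- readBin(paste0(path, ".grm.bin"), "numeric", n = nv, size = 4,
               endian = "little")
  Nv <- readBin(paste0(path, ".grm.N.bin"), "numeric", n = nv, size = 4,
                endian = "little")
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[lower.tri(G, diag = TRUE)] <- {
    idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    v[order(order(idx[, 1], idx[, 2]))]
  }
  G <- G + t(G) - diag(diag(G))
  new("GRM", sampleIDs = ids, values = G,
      nMarkersUsed = as.integer(round(Nv[1])), scope = scope)
}
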