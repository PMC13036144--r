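# Mixed-linear-model association scan with a polygenic background.
#
# Variance components are estimated once on the null (no-SNP) model; each
# SNP is then tested by generalized least squares under the fitted
# V = sigma2_g G + sigma2_e I, vectorized across markers through the
# eigendecomposition of G.

.mlmaScanChunk <- function(Ut, lam, sg, se2, y, X, S, markers, varY) {
  # GLS per SNP via Schur complement of the bordered normal equations
  w <- 1 / (sg * lam + se2)
  yt <- drop(Ut %*% y)
  Xt <- Ut %*% X
  St <- Ut %*% S
  WX <- Xt * w
  XtWX <- crossprod(Xt, WX)
  XtWXinv <- solve(XtWX)
  XtWy <- crossprod(WX, yt)
  WS <- St * w
  sWs <- colSums(St * WS)
  SWX <- crossprod(WS, Xt)                   # m x p
  SWy <- drop(crossprod(WS, yt))
  proj <- SWX %*% XtWXinv                    # m x p
  denom <- sWs - rowSums(proj * SWX)
  num <- SWy - drop(proj %*% XtWy)
  beta <- num / denom
  seB <- sqrt(1 / denom)
  chi2 <- (beta / seB)^2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  varS <- apply(S, 2, var)
  data.frame(marker_id = markers$id, chrom = markers$chrom,
             pos = markers$pos, beta = beta, se = seB,
             p = pmin(pmax(p, .Machine$double.xmin), 1),
             r2 = pmin(beta^2 * varS / varY, 1), stringsAsFactors = FALSE)
}

#' Mixed-linear-model association scan
#'
#' Fits the null polygenic model \eqn{y = Xb + Zu + e} once by REML, then
#' tests each SNP by generalized least squares under the fitted covariance
#' (the tested SNP stays in the background GRM, plain MLMA). With
#' \code{loco = TRUE} the background GRM and variance components are
#' re-estimated per chromosome, excluding the tested SNP's chromosome.
#' Monomorphic SNPs are skipped with a logged count. Per-SNP variance
#' explained is \eqn{r^2 = \beta^2 var(s) / var(y)}.
#'
#' @param geno a fully observed \linkS4class{GenotypeData}.
#' @param pheno data.frame with \code{sample_id} and \code{tar}.
#' @param grm optional precomputed \linkS4class{GRM} (defaults to the
#'   VanRaden GRM of \code{geno}); ignored when \code{loco = TRUE}.
#' @param covariates optional numeric matrix of fixed covariates (aligned
#'   with the genotype samples).
#' @param loco logical: leave-one-chromosome-out background (default FALSE).
#' @return data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos}, \code{beta}, \code{se}, \code{p}, \code{r2}, plus
#'   attributes \code{nullFit} (the \linkS4class{VarCompFit}) and
#'   \code{nSkipped}.
#' @export
runMLMA <- function(geno, pheno, grm = NULL, covariates = NULL,
                    loco = FALSE) {
  al <- alignSamples(geno, pheno)
  geno <- al$geno; y <- al$pheno$tar
  if (anyNA(dosageMatrix(geno)))
    stop("MLMA requires imputed (complete) dosages")
  n <- nSamples(geno)
  X <- cbind(intercept = rep(1, n), covariates)
  mk <- markerInfo(geno)
  D <- dosageMatrix(geno)
  mono <- mk$maf <= 0 | is.na(mk$maf)
  if (any(mono)) message(sum(mono), " monomorphic SNP(s) skipped")
  varY <- var(y)
  scanOne <- function(G, cols) {
    nullFit <- tryCatch(fitREML(y, G, X = X),
                        error = function(e)
                          stop("REML failed on the null model: ",
                               conditionMessage(e)))
    if (!isConverged(nullFit))
      warning("null-model REML did not converge; scan uses last iterate")
    e <- eigen(if (is(G, "GRM")) grmValues(G) else G, symmetric = TRUE)
    sg <- varComp(nullFit)[1]
    if (nullFit@boundary[1]) sg <- 0          # exact OLS in the null limit
    res <- .mlmaScanChunk(t(e$vectors), pmax(e$values, 0),
                          sg, varComp(nullFit)[2],
                          y, X, D[, cols, drop = FALSE],
                          mk[cols, , drop = FALSE], varY)
    list(res = res, fit = nullFit)
  }
  if (!loco) {
    if (is.null(grm)) grm <- computeGRM(geno)
    out <- scanOne(grm, which(!mono))
    res <- out$res; nullFit <- out$fit
  } else {
    chroms <- unique(mk$chrom)
    if (length(chroms) < 2) stop("LOCO scan requires >= 2 chromosomes")
    pieces <- lapply(chroms, function(cc) {
      cols <- which(mk$chrom == cc & !mono)
      if (!length(cols)) return(NULL)
      scanOne(computeLocoGRM(geno, cc), cols)$res
    })
    res <- do.call(rbind, pieces)
    nullFit <- fitREML(y, computeGRM(geno), X = X)
  }
  o <- order(factor(res$chrom, levels = unique(mk$chrom)), res$pos)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nullFit") <- nullFit
  attr(res, "nSkipped") <- sum(mono)
  res
}

#' Bonferroni-style genome-wide threshold
#'
#' Returns \eqn{1 / N} for \eqn{N} markers (the 1/N convention, not
#' 0.05/N).
#'
#' @param nMarkers number of tested markers (>= 1).
#' @return p-value threshold.
#' @examples
#' signif(bonferroniThreshold(95308), 3)  # 1.05e-05
#' @export
bonferroniThreshold <- function(nMarkers) {
  if (nMarkers < 1) stop("nMarkers must be >= 1")
  1 / nMarkers
}

#' Top associated markers
#'
#' Ranks by ascending p-value, breaking ties by chromosome then position.
#'
#' @param results an association data.frame from [runMLMA()].
#' @param k number of rows to return.
#' @return the top-k rows.
#' @export
topHits <- function(results, k = 10) {
  stopifnot(nrow(results) >= 1)
  o <- order(results$p, results$chrom, results$pos)
  head(results[o, , drop = FALSE], k)
}

#' Write association results as a plot-ready TSV
#'
#' The genome-wide threshold is echoed as a leading comment line.
#'
#' @param results association data.frame.
#' @param path output file.
#' @param threshold p-value threshold to record (default
#'   \code{bonferroniThreshold(nrow(results))}).
#' @export
writeAssoc <- function(results, path, threshold = NULL) {
  if (is.null(threshold)) threshold <- bonferroniThreshold(nrow(results))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genome-wide threshold p < %.6g", threshold), con)
  write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
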