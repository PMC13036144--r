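# Independent oracles and fixture builders. These deliberately avoid the
# package's computational paths: brute-force double loops, explicit matrix
# inverses, closed forms.

# VanRaden GRM by explicit double loop over sample pairs
bruteGRM <- function(d) {
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  denom <- sum(2 * p * (1 - p))
  n <- nrow(d)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (m in seq_len(ncol(d)))
      s <- s + (d[i, m] - 2 * p[m]) * (d[j, m] - 2 * p[m])
    G[i, j] <- s / denom
  }
  G
}

# restricted log-likelihood from first principles (explicit inverses)
oracleREMLLogLik <- function(y, X, G, sg, se) {
  n <- length(y); p <- ncol(X)
  V <- sg * G + diag(se, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
}

# per-SNP generalized least squares with an explicit V inverse
oracleGLS <- function(y, X, s, V) {
  Vi <- solve(V)
  C <- cbind(X, s)
  A <- solve(t(C) %*% Vi %*% C)
  b <- A %*% t(C) %*% Vi %*% y
  beta <- b[ncol(C)]
  se <- sqrt(A[ncol(C), ncol(C)])
  chi2 <- (beta / se)^2
  c(beta = beta, se = se, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# random fully-observed dosage panel (no LD structure; for algebra checks)
randomPanel <- function(n, m, seed, nChrom = 2) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  isMono <- function(x) {
    pm <- colMeans(x) / 2
    any(pm == 0 | pm == 1)
  }
  while (isMono(d))
    d <- sapply(p, function(pp) rbinom(n, 2, pp))
  chrom <- paste0("chr", rep(seq_len(nChrom), length.out = m))
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(1e6, length(ix)))), use.names = FALSE)
  genotypeData(d, chrom = chrom, pos = pos)
}

# minimal VCF text fixture
writeVCFFixture <- function(path, rows, samples) {
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000000>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               rows), path)
  path
}
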