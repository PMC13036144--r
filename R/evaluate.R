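# Seeded k-fold cross-validation, external validation and the
# runtime/memory benchmark.

#' Balanced fold assignment
#'
#' Random permutation split into k folds whose sizes differ by at most one
#' (the first \code{n mod k} folds are one larger).
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k) of length n.
#' @export
makeFolds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  .withSeed(seed, {
    perm <- sample.int(n)
    fold <- integer(n)
    fold[perm] <- rep(seq_len(k), times = sizes)
    fold
  })
}

.safeCor <- function(a, b) {
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Seeded k-fold cross-validation of genomic-prediction models
#'
#' One random seeded partition is drawn and shared across all models. For
#' each fold and model the model is trained on the remaining folds and
#' predicts the held-out fold; accuracy is the Pearson correlation between
#' predicted GEBVs and observed phenotypes, reported per fold and pooled
#' over the concatenated out-of-fold predictions (the headline number).
#' Folds with constant predictions yield a missing per-fold r with a
#' warning; the pooled r is still computed.
#'
#' @param geno a fully observed \linkS4class{GenotypeData}.
#' @param pheno data.frame with \code{sample_id} and \code{tar}.
#' @param modelNames character vector of models (see [gsModelNames()]).
#' @param k number of folds (default 5).
#' @param seed integer seed driving the partition and model training.
#' @param config per-model config overrides: a named list of lists (name =
#'   model) or one list applied to all.
#' @return a \linkS4class{CVReport}.
#' @export
kfoldCV <- function(geno, pheno, modelNames = c("rrBLUP", "GBLUP"), k = 5,
                    seed = 1, config = list()) {
  al <- alignSamples(geno, pheno)
  geno <- al$geno; pheno <- al$pheno
  n <- nSamples(geno)
  fold <- makeFolds(n, k, seed)
  ids <- sampleIDs(geno)
  perFold <- list(); predRows <- list(); sumRows <- list()
  for (mn in modelNames) {
    cfg <- if (!is.null(config[[mn]]) && is.list(config[[mn]]))
      config[[mn]] else config
    t0 <- proc.time()[3]
    preds <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      tr <- fold != f
      gTrain <- .subsetGeno(geno, sampleKeep = tr)
      fitted <- trainModel(mn, gTrain, pheno[tr, , drop = FALSE],
                           config = cfg, seed = seed + f)
      gTest <- .subsetGeno(geno, sampleKeep = !tr)
      preds[!tr] <- predict(fitted, gTest)
      r <- .safeCor(preds[!tr], pheno$tar[!tr])
      if (is.na(r))
        warning("fold ", f, " of ", mn,
                ": constant predictions, per-fold r undefined")
      perFold[[length(perFold) + 1]] <-
        data.frame(model = mn, fold = f, n = sum(!tr), r = r)
    }
    rt <- proc.time()[3] - t0
    pf <- do.call(rbind, perFold[seq(length(perFold) - k + 1,
                                     length(perFold))])
    sumRows[[mn]] <- data.frame(model = mn,
                                pooled_r = .safeCor(preds, pheno$tar),
                                mean_fold_r = mean(pf$r, na.rm = TRUE),
                                sd_fold_r = sd(pf$r[!is.na(pf$r)]),
                                runtime_s = rt)
    predRows[[mn]] <- data.frame(sample_id = ids, fold = fold, model = mn,
                                 gebv = preds, observed = pheno$tar)
  }
  new("CVReport", k = as.integer(k), seed = as.integer(seed),
      foldAssignment = setNames(fold, ids),
      perFold = do.call(rbind, perFold),
      summary = do.call(rbind, c(sumRows, make.row.names = FALSE)),
      predictions = do.call(rbind, c(predRows, make.row.names = FALSE)))
}

#' Validate a fitted model on an external panel
#'
#' Predicts GEBVs for an independent panel and reports the Pearson
#' correlation with the observed phenotypes, with the per-sample scatter
#' table.
#'
#' @param fitted a \linkS4class{GSModel}.
#' @param genoBP external-panel \linkS4class{GenotypeData} (must carry the
#'   training markers).
#' @param phenoBP data.frame with \code{sample_id} and \code{tar} for the
#'   external panel (n >= 3).
#' @return list with \code{r} and \code{table} (sample_id, gebv, observed).
#' @export
externalValidate <- function(fitted, genoBP, phenoBP) {
  al <- alignSamples(genoBP, phenoBP)
  if (nSamples(al$geno) < 3)
    stop("external validation needs at least 3 phenotyped samples")
  gebv <- predict(fitted, al$geno)
  tab <- data.frame(sample_id = sampleIDs(al$geno), gebv = unname(gebv),
                    observed = al$pheno$tar)
  list(r = .safeCor(tab$gebv, tab$observed), table = tab)
}

#' Runtime/memory benchmark across resampled population sizes
#'
#' Resamples individuals with replacement to each requested size
#' (duplicated ids disambiguated by a numeric suffix), runs [kfoldCV()] and
#' records wall time and peak memory per model. Informational only:
#' hardware-dependent, never an assertion surface.
#'
#' @param geno,pheno panel to resample.
#' @param modelNames models to benchmark.
#' @param sizes integer vector of population sizes.
#' @param seed integer seed.
#' @param k folds (default 5).
#' @return data.frame (size, model, runtime_s, peak_mem_mb, pooled_r).
#' @export
benchmarkModels <- function(geno, pheno, modelNames, sizes, seed = 1,
                            k = 5) {
  al <- alignSamples(geno, pheno)
  rows <- list()
  for (sz in sizes) {
    idx <- .withSeed(seed + sz, sample.int(nSamples(al$geno), sz,
                                           replace = TRUE))
    d <- dosageMatrix(al$geno)[idx, , drop = FALSE]
    ids <- make.unique(sampleIDs(al$geno)[idx], sep = "_r")
    rownames(d) <- ids
    mk <- markerInfo(al$geno)
    g <- genotypeData(d, chrom = mk$chrom, pos = mk$pos, ref = mk$ref,
                      alt = mk$alt, id = mk$id,
                      genomeMap = genomeMap(al$geno))
    ph <- data.frame(sample_id = ids, tar = al$pheno$tar[idx])
    for (mn in modelNames) {
      gc(reset = TRUE)
      t0 <- proc.time()[3]
      cvr <- kfoldCV(g, ph, mn, k = k, seed = seed)
      rt <- proc.time()[3] - t0
      peak <- sum(gc()[, 6])                  # peak Mb since reset
      rows[[length(rows) + 1]] <-
        data.frame(size = sz, model = mn, runtime_s = rt,
                   peak_mem_mb = peak, pooled_r = cvr@summary$pooled_r[1])
    }
  }
  do.call(rbind, rows)
}

#' Write a CV report as TSV
#'
#' @param report a \linkS4class{CVReport}.
#' @param path output file.
#' @export
writeCVReport <- function(report, path) {
  pf <- report@perFold
  s <- report@summary
  pf$pooled_r <- s$pooled_r[match(pf$model, s$model)]
  pf$runtime_s <- s$runtime_s[match(pf$model, s$model)]
  write.table(pf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
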