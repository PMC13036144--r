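# Phenotype handling: tar-mass arithmetic, replicate averaging, TSV I/O and
# genotype/phenotype joining.

#' Tar (NFDPM) mass from smoking-machine component masses
#'
#' Nicotine-free dry particulate matter is total particulate matter minus
#' water and nicotine, all in mg per cigarette.
#'
#' @param mTPM total particulate matter (mg).
#' @param mW water mass (mg).
#' @param mN nicotine mass (mg).
#' @return tar mass in mg (vectorized).
#' @examples
#' computeTarMass(30, 3, 2)  # 25
#' @export
computeTarMass <- function(mTPM, mW, mN) {
  if (any(mTPM < 0 | mW < 0 | mN < 0))
    stop("component masses must be non-negative")
  out <- mTPM - mW - mN
  if (any(out < 0))
    stop("negative tar mass: water + nicotine exceed TPM, inputs inconsistent")
  out
}

#' Average replicate tar measurements per sample
#'
#' @param records data.frame with \code{sample_id} and either a \code{tar}
#'   column or replicate columns \code{rep1..repK} (NA-padded); covariate
#'   columns are carried through.
#' @return data.frame with one row per sample; \code{tar} is the arithmetic
#'   mean of the available replicates and \code{n_reps} their count.
#' @export
aggregateReplicates <- function(records) {
  stopifnot(is.data.frame(records), "sample_id" %in% names(records))
  repCols <- grep("^rep[0-9]+$", names(records), value = TRUE)
  if (!length(repCols)) {
    if (!"tar" %in% names(records))
      stop("records need either replicate columns rep1..repK or a tar column")
    records$n_reps <- 1L
    return(records)
  }
  reps <- as.matrix(records[, repCols, drop = FALSE])
  nr <- rowSums(!is.na(reps))
  if (any(nr == 0))
    stop("sample(s) with no replicate measurement: ",
         paste(records$sample_id[nr == 0], collapse = ", "))
  out <- records[, setdiff(names(records), c(repCols, "tar")), drop = FALSE]
  out$tar <- rowMeans(reps, na.rm = TRUE)
  out$n_reps <- as.integer(nr)
  out
}

#' Read / write a phenotype TSV
#'
#' Columns: \code{sample_id}, \code{tar} (mg/cigarette), optional replicate
#' columns \code{rep1..repK}, optional mass columns \code{m_tpm}, \code{m_w},
#' \code{m_n}, optional covariates (e.g. tobacco type, origin, class). When
#' replicate columns are present and \code{tar} is absent it is derived by
#' replicate averaging; when the three mass columns are present and both
#' \code{tar} and replicates are absent, tar is derived by the NFDPM
#' subtraction.
#'
#' @param path TSV file.
#' @return data.frame with at least \code{sample_id} and \code{tar}.
#' @export
readPhenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype TSV needs sample_id")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotypes")
  if (!"tar" %in% names(df)) {
    if (length(grep("^rep[0-9]+$", names(df))))
      df <- aggregateReplicates(df)
    else if (all(c("m_tpm", "m_w", "m_n") %in% names(df)))
      df$tar <- computeTarMass(df$m_tpm, df$m_w, df$m_n)
    else stop("phenotype TSV needs tar, rep1..repK, or m_tpm/m_w/m_n")
  }
  if (any(df$tar < 0)) stop("negative tar values in phenotype table")
  df
}

#' @param pheno phenotype data.frame.
#' @rdname readPhenotypes
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a phenotype table with a genotype panel by sample id
#'
#' Join is by exact sample id; unmatched ids on either side are reported in
#' a message, never silently dropped.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param pheno data.frame with \code{sample_id} and \code{tar}.
#' @return list with \code{geno} and \code{pheno} restricted to the common
#'   samples, in genotype order.
#' @export
alignSamples <- function(geno, pheno) {
  gids <- sampleIDs(geno)
  common <- intersect(gids, pheno$sample_id)
  if (!length(common)) stop("no sample ids shared by genotypes and phenotypes")
  lostG <- setdiff(gids, common); lostP <- setdiff(pheno$sample_id, common)
  if (length(lostG))
    message(length(lostG), " genotyped sample(s) lack phenotypes: ",
            paste(head(lostG, 5), collapse = ", "),
            if (length(lostG) > 5) ", ..." else "")
  if (length(lostP))
    message(length(lostP), " phenotyped sample(s) lack genotypes: ",
            paste(head(lostP, 5), collapse = ", "),
            if (length(lostP) > 5) ", ..." else "")
  keep <- gids %in% common
  g <- if (all(keep)) geno else .subsetGeno(geno, sampleKeep = keep)
  p <- pheno[match(sampleIDs(g), pheno$sample_id), , drop = FALSE]
  rownames(p) <- NULL
  list(geno = g, pheno = p)
}
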