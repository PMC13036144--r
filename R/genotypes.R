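# Genotype I/O (VCF / PLINK / dosage TSV), QC filtering, imputation and
# call-set concordance.

.gtToDosage <- function(gt) {
  # diploid GT string -> alt-allele dosage; any missing allele -> NA
  d <- rep(NA_real_, length(gt))
  gt <- sub(":.*$", "", gt)
  known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2)
  hit <- match(gt, names(known))
  d[!is.na(hit)] <- known[hit[!is.na(hit)]]
  d
}

.readVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  fix <- vcfR::getFIX(v)
  snp <- bi & nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  nskip <- sum(!snp)
  if (nskip)
    message(nskip, " non-biallelic-SNP record(s) skipped")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  dos <- apply(gt, 2, .gtToDosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                       dimnames = list(NULL, colnames(gt)))
  dos <- t(dos)                              # samples x markers
  depth <- rep(NA_real_, sum(snp))
  dp <- tryCatch(vcfR::extract.info(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp) && !all(is.na(dp)))
    depth <- as.numeric(dp[snp]) / ncol(gt)   # mean depth per sample
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste(fix[is.na(ids) | ids == ".", "CHROM"],
                                        fix[is.na(ids) | ids == ".", "POS"],
                                        sep = "_")
  genotypeData(dos, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = fix[, "REF"], alt = fix[, "ALT"], id = ids,
               meanDepth = depth)
}

.readDosageTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("dosage TSV must have columns id, chrom, pos, ref, alt, <samples>")
  samp <- setdiff(names(df), need)
  if (!length(samp)) stop("dosage TSV contains no sample columns")
  dos <- t(as.matrix(df[, samp, drop = FALSE]))
  rownames(dos) <- samp
  genotypeData(dos, chrom = df$chrom, pos = df$pos, ref = df$ref,
               alt = df$alt, id = df$id)
}

.readPlink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * ceiling(n / 4))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: bad magic number")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  bpl <- ceiling(n / 4)
  # 2-bit codes per individual: 00 hom A1, 01 missing, 10 het, 11 hom A2
  lut <- matrix(NA_real_, 4, 256)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2 * k), 3L)
      lut[k + 1, b + 1] <- c(2, NA, 1, 0)[code + 1]
    }
  }
  dos <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    bytes <- as.integer(body[((j - 1) * bpl + 1):(j * bpl)])
    vals <- lut[, bytes + 1]
    dos[, j] <- vals[seq_len(n)]
  }
  rownames(dos) <- as.character(fam[[2]])
  # dosage counts the A1 allele, so A1 plays the alt role
  genotypeData(dos, chrom = as.character(bim$chrom), pos = bim$pos,
               ref = bim$a2, alt = bim$a1, id = bim$id)
}

#' Read genotypes from VCF, PLINK or a dosage TSV
#'
#' Only biallelic SNPs are loaded; other records are skipped with a logged
#' count. Diploid GT is mapped to alt-allele dosage (0/0 -> 0, 0/1 -> 1,
#' 1/1 -> 2, ./. -> NA). For PLINK, \code{path} is the prefix of the
#' .bed/.bim/.fam triple and dosages count the A1 allele.
#'
#' @param path input file (or PLINK prefix).
#' @param format one of \code{"vcf"}, \code{"plink"}, \code{"dosage_tsv"}.
#' @return a \linkS4class{GenotypeData}.
#' @export
readGenotypes <- function(path, format = c("vcf", "plink", "dosage_tsv")) {
  format <- match.arg(format)
  probe <- if (format == "plink") paste0(path, ".bed") else path
  if (!file.exists(probe)) stop("file not found: ", probe)
  switch(format,
         vcf = .readVCF(path),
         plink = .readPlink(path),
         dosage_tsv = .readDosageTSV(path))
}

#' Write genotypes to VCF or a dosage TSV
#'
#' VCF output carries one contig header line per chromosome and GT-only
#' genotype fields, so it requires integer dosages (error otherwise); the
#' dosage TSV keeps fractional (imputed) dosages.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param path output file.
#' @param format \code{"vcf"} or \code{"dosage_tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(geno, path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  mk <- markerInfo(geno)
  d <- dosageMatrix(geno)
  if (format == "dosage_tsv") {
    df <- cbind(mk[, c("id", "chrom", "pos", "ref", "alt")],
                as.data.frame(t(d), check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  di <- round(d)
  if (any(abs(d - di) > 1e-9, na.rm = TRUE))
    stop("VCF output requires integer dosages; write a dosage TSV instead")
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(di)
  gt[ok] <- gtmap[di[ok] + 1]
  gm <- genomeMap(geno)
  if (!nrow(gm))
    gm <- data.frame(chrom = unique(mk$chrom),
                     length_bp = tapply(mk$pos, factor(mk$chrom,
                       levels = unique(mk$chrom)), max))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", gm$chrom,
                       as.integer(gm$length_bp)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")),
             con)
  body <- cbind(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".",
                "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

.subsetGeno <- function(geno, sampleKeep = NULL, markerKeep = NULL) {
  d <- dosageMatrix(geno); mk <- markerInfo(geno)
  if (!is.null(markerKeep)) {
    d <- d[, markerKeep, drop = FALSE]
    mk <- mk[markerKeep, , drop = FALSE]
  }
  if (!is.null(sampleKeep)) d <- d[sampleKeep, , drop = FALSE]
  genotypeData(d, chrom = mk$chrom, pos = mk$pos, ref = mk$ref, alt = mk$alt,
               id = mk$id, meanDepth = mk$mean_depth,
               genomeMap = genomeMap(geno))
}

#' Apply marker and sample QC filters
#'
#' Markers are removed when mean sequencing depth is not greater than
#' \code{minDepth}, when MAF is not above \code{minMAF}, or when the site
#' missing rate reaches \code{maxMissing}; individuals are then removed when
#' their missing rate reaches \code{maxMissing}. Each removed marker is
#' attributed to the first rule it fails in the fixed order depth, MAF,
#' missingness. Because sample removal changes per-marker statistics, the
#' rules are re-applied until a fixed point, which makes the operation
#' idempotent. When no depth metadata is present the depth rule is skipped
#' with a warning.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param minDepth retain markers with mean depth strictly greater
#'   (default 2).
#' @param minMAF retain markers with MAF strictly above (default 0.03).
#' @param maxMissing remove markers/individuals with missing rate at or
#'   above this value (default 0.5).
#' @return list with \code{geno} (filtered \linkS4class{GenotypeData}) and
#'   \code{report} (a \linkS4class{QCReport}).
#' @export
applyFilters <- function(geno, minDepth = 2, minMAF = 0.03,
                         maxMissing = 0.5) {
  stopifnot(is(geno, "GenotypeData"), minDepth >= 0,
            minMAF >= 0, minMAF < 0.5, maxMissing > 0, maxMissing <= 1)
  n0 <- nSamples(geno); m0 <- nMarkers(geno)
  rmDepth <- 0L; rmMAF <- 0L; rmMiss <- 0L; rmSamp <- 0L
  cur <- geno
  haveDepth <- !all(is.na(markerInfo(geno)$mean_depth))
  if (!haveDepth)
    warning("no marker depth metadata: depth filter skipped")
  repeat {
    mk <- markerInfo(cur)
    st <- .markerStats(dosageMatrix(cur))
    failDepth <- if (haveDepth) !is.na(mk$mean_depth) &
      mk$mean_depth <= minDepth else rep(FALSE, nrow(mk))
    failMAF <- !failDepth & (is.na(st$maf) | st$maf <= minMAF)
    failMiss <- !failDepth & !failMAF & st$missing_rate >= maxMissing
    keepM <- !(failDepth | failMAF | failMiss)
    rmDepth <- rmDepth + sum(failDepth)
    rmMAF <- rmMAF + sum(failMAF)
    rmMiss <- rmMiss + sum(failMiss)
    if (!any(keepM))
      stop("all markers removed by QC filters; relax the thresholds")
    cur <- .subsetGeno(cur, markerKeep = keepM)
    indMiss <- rowMeans(is.na(dosageMatrix(cur)))
    keepS <- indMiss < maxMissing
    rmSamp <- rmSamp + sum(!keepS)
    if (!any(keepS))
      stop("all samples removed by QC filters; relax the thresholds")
    if (any(!keepS)) cur <- .subsetGeno(cur, sampleKeep = keepS)
    if (all(keepM) && all(keepS)) break   # fixed point: pass removed nothing
  }
  rep <- new("QCReport", nSamplesIn = as.integer(n0),
             nMarkersIn = as.integer(m0),
             removedDepth = as.integer(rmDepth),
             removedMAF = as.integer(rmMAF),
             removedMissing = as.integer(rmMiss),
             samplesRemoved = as.integer(rmSamp),
             nSamplesOut = nSamples(cur), nMarkersOut = nMarkers(cur),
             thresholds = list(min_depth = minDepth, min_maf = minMAF,
                               max_missing = maxMissing))
  list(geno = cur, report = rep)
}

#' Impute missing dosages by per-site mean or mode
#'
#' A simple single-site imputer: missing entries are replaced by the marker
#' mean dosage (fractional values allowed) or by the modal integer dosage
#' (ties broken toward the smaller dosage).
#'
#' @param geno a \linkS4class{GenotypeData}; every marker must have at least
#'   one non-missing call.
#' @param method \code{"site_mean"} or \code{"site_mode"}.
#' @return a fully observed \linkS4class{GenotypeData}.
#' @export
imputeMissing <- function(geno, method = c("site_mean", "site_mode")) {
  method <- match.arg(method)
  d <- dosageMatrix(geno)
  if (!anyNA(d)) return(geno)
  if (any(colSums(!is.na(d)) == 0))
    stop("fully missing marker(s) present; run applyFilters() first")
  for (j in which(colSums(is.na(d)) > 0)) {
    obs <- d[, j][!is.na(d[, j])]
    fill <- if (method == "site_mean") mean(obs) else {
      tab <- table(factor(round(obs), levels = 0:2))
      as.numeric(names(tab)[which.max(tab)])
    }
    d[is.na(d[, j]), j] <- fill
  }
  mk <- markerInfo(geno)
  genotypeData(d, chrom = mk$chrom, pos = mk$pos, ref = mk$ref, alt = mk$alt,
               id = mk$id, meanDepth = mk$mean_depth,
               genomeMap = genomeMap(geno))
}

#' Genotype concordance between two call sets
#'
#' Overlapping samples are matched by id and markers by chromosome and
#' position; concordance is the fraction of jointly non-missing cells with
#' equal dosage.
#'
#' @param a,b \linkS4class{GenotypeData} objects.
#' @return list with \code{overall} (fraction) and \code{perSample}
#'   (named numeric).
#' @export
genotypeConcordance <- function(a, b) {
  sa <- intersect(sampleIDs(a), sampleIDs(b))
  keyA <- paste(markerInfo(a)$chrom, markerInfo(a)$pos)
  keyB <- paste(markerInfo(b)$chrom, markerInfo(b)$pos)
  common <- intersect(keyA, keyB)
  if (!length(sa) || !length(common))
    stop("no overlapping samples/markers between the two call sets")
  da <- dosageMatrix(a)[sa, match(common, keyA), drop = FALSE]
  db <- dosageMatrix(b)[sa, match(common, keyB), drop = FALSE]
  ok <- !is.na(da) & !is.na(db)
  if (!any(ok)) stop("no jointly non-missing cells to compare")
  eq <- ok & (abs(da - db) < 1e-9)
  per <- rowSums(eq) / pmax(rowSums(ok), 1)
  per[rowSums(ok) == 0] <- NA_real_
  list(overall = sum(eq) / sum(ok), perSample = per)
}

#' Write a QC report as TSV
#'
#' @param report a \linkS4class{QCReport}.
#' @param path output file.
#' @export
writeQCReport <- function(report, path) {
  df <- data.frame(
    field = c("samples_in", "markers_in", "removed_depth", "removed_maf",
              "removed_missing", "samples_removed", "samples_out",
              "markers_out", "min_depth", "min_maf", "max_missing"),
    value = c(report@nSamplesIn, report@nMarkersIn, report@removedDepth,
              report@removedMAF, report@removedMissing,
              report@samplesRemoved, report@nSamplesOut, report@nMarkersOut,
              report@thresholds$min_depth, report@thresholds$min_maf,
              report@thresholds$max_missing))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
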