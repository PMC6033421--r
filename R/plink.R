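# PLINK 1 binary (.bed/.bim/.fam) input and output.
#
# .bed layout (SNP-major, the only mode supported): 3 header bytes
# 0x6C 0x1B 0x01, then ceiling(n/4) bytes per marker. Each byte packs four
# individuals, two bits each, read from the low-order pair upward:
#   00 -> 2 copies of allele A1   01 -> missing
#   10 -> heterozygote (1)        11 -> 0 copies of A1
# Genotypes are decoded as counts of the A1 allele from the .bim file.

.BED_MAGIC <- as.raw(c(0x6C, 0x1B))
.BED_SNP_MAJOR <- as.raw(0x01)
.BED_DECODE <- c(2, NA, 1, 0)   # index by 2-bit value + 1

#' Read a PLINK binary fileset
#'
#' Loads `.fam` and `.bim` eagerly and keeps the `.bed` payload as raw
#' bytes, decoding one marker at a time on demand (memory stays O(n) per
#' marker during a scan). Phenotypes are mapped 2 -> case, 1 -> control,
#' 0/-9 -> missing (excluded from analysis but kept in the container so
#' genotype rows stay aligned).
#'
#' @param prefix Path prefix: `prefix.bed`, `prefix.bim`, `prefix.fam`
#'   must all exist.
#' @return An object of class `genotype_study` with elements `fam`
#'   (data.frame FID/IID/SEX/PHENO/y), `bim` (data.frame
#'   CHR/SNP/CM/BP/A1/A2), `n`, `marker_count`, and the raw genotype
#'   payload. Use [study_genotype()] to decode a marker.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing PLINK file(s): ",
                            paste(missing, collapse = ", "))

  fam <- utils::read.table(paths[3], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("FID", "IID", "PAT", "MAT",
                                         "SEX", "PHENO"))
  bim <- utils::read.table(paths[2], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("CHR", "SNP", "CM", "BP",
                                         "A1", "A2"))
  if (anyDuplicated(bim$SNP)) {
    stop("duplicated marker ids in .bim: ",
         paste(unique(bim$SNP[duplicated(bim$SNP)]), collapse = ", "))
  }
  n <- nrow(fam)
  m <- nrow(bim)
  bpm <- ceiling(n / 4)

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:2], .BED_MAGIC)) {
    stop(".bed format error: bad magic bytes at offset 0 (expected 6c 1b)")
  }
  if (raw[3] == as.raw(0x00)) {
    stop(".bed format error: individual-major mode (byte 3 = 00) is not supported")
  }
  if (raw[3] != .BED_SNP_MAJOR) {
    stop(".bed format error: unknown mode byte at offset 2: ",
         sprintf("%02x", as.integer(raw[3])))
  }
  if (length(raw) != 3 + m * bpm) {
    stop(sprintf(
      ".bed length %d inconsistent with %d individuals x %d markers (expected %d bytes)",
      length(raw), n, m, 3 + m * bpm))
  }

  y <- ifelse(fam$PHENO == 2, 1, ifelse(fam$PHENO == 1, 0, NA))
  fam$y <- y

  structure(
    list(fam = fam, bim = bim, n = n, marker_count = m,
         bed = raw[-(1:3)], bytes_per_marker = bpm),
    class = "genotype_study"
  )
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("genotype_study: %d individuals, %d markers\n",
              x$n, x$marker_count))
  invisible(x)
}

#' Decode one marker of a genotype study
#'
#' @param study A `genotype_study` from [read_plink()].
#' @param j Marker index (1-based) or marker id.
#' @return A [genotype_vector()] of A1-allele counts.
#' @export
study_genotype <- function(study, j) {
  if (is.character(j)) {
    idx <- match(j, study$bim$SNP)
    if (is.na(idx)) stop("marker id not found: ", j)
    j <- idx
  }
  stopifnot(j >= 1, j <= study$marker_count)
  off <- (j - 1) * study$bytes_per_marker
  bytes <- as.integer(study$bed[off + seq_len(study$bytes_per_marker)])
  # unpack low-order pair first
  pairs <- rbind(bytes %% 4L,
                 (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L,
                 bytes %/% 64L)
  codes <- .BED_DECODE[as.vector(pairs)[seq_len(study$n)] + 1L]
  b <- study$bim[j, ]
  genotype_vector(codes, marker = list(
    id = b$SNP, chromosome = as.character(b$CHR), position = b$BP,
    allele_A1 = b$A1, allele_A2 = b$A2))
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink()]; used to build fixtures and to round-trip
#' generated studies. Genotypes are A1-allele counts with `NA` for
#' missing.
#'
#' @param prefix Output path prefix.
#' @param genotypes `n x m` numeric matrix of codes in `{0, 1, 2, NA}`.
#' @param fam Data frame with columns FID, IID, PAT, MAT, SEX, PHENO; a
#'   default is synthesized from `phenotype` when omitted.
#' @param bim Data frame with columns CHR, SNP, CM, BP, A1, A2; a default
#'   is synthesized when omitted.
#' @param phenotype Optional 0/1 vector used to synthesize `fam`
#'   (coded 1/2 on disk).
#' @return Invisibly, `prefix`.
#' @export
write_plink <- function(prefix, genotypes, fam = NULL, bim = NULL,
                        phenotype = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (is.null(fam)) {
    if (is.null(phenotype)) phenotype <- rep(0, n)
    fam <- data.frame(
      FID = paste0("F", seq_len(n)), IID = paste0("I", seq_len(n)),
      PAT = 0L, MAT = 0L, SEX = 0L,
      PHENO = ifelse(is.na(phenotype), -9L, ifelse(phenotype == 1, 2L, 1L)))
  }
  if (is.null(bim)) {
    bim <- data.frame(CHR = 1L, SNP = paste0("snp", seq_len(m)), CM = 0L,
                      BP = seq_len(m), A1 = "A", A2 = "B")
  }
  stopifnot(nrow(fam) == n, nrow(bim) == m)

  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  encode <- function(x) {
    # A1 count -> 2-bit value: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
    v <- ifelse(is.na(x), 1L, ifelse(x == 2, 0L, ifelse(x == 1, 2L, 3L)))
    pad <- (-length(v)) %% 4
    v <- c(v, rep(3L, pad))   # padding pairs are "0 copies"
    vm <- matrix(v, nrow = 4)
    as.raw(vm[1, ] + 4L * vm[2, ] + 16L * vm[3, ] + 64L * vm[4, ])
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.BED_MAGIC, .BED_SNP_MAJOR), con)
  for (j in seq_len(m)) writeBin(encode(genotypes[, j]), con)
  invisible(prefix)
}

#' Read a whitespace-delimited phenotype/covariate table
#'
#' PLINK-style alternate phenotype / covariate files: a header line with
#' `FID IID` followed by named columns, joined to a study's `.fam` by
#' (FID, IID).
#'
#' @param study A `genotype_study`.
#' @param file Path to the table.
#' @param columns Character vector of column names to extract.
#' @return A numeric matrix with one row per study individual (NA where an
#'   individual has no row in `file`).
#' @export
read_pheno_covar <- function(study, file, columns) {
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("FID", "IID") %in% names(tab))) {
    stop("phenotype/covariate file must have FID and IID columns")
  }
  miss <- setdiff(columns, names(tab))
  if (length(miss)) stop("column(s) not found: ", paste(miss, collapse = ", "))
  key <- paste(study$fam$FID, study$fam$IID)
  idx <- match(key, paste(tab$FID, tab$IID))
  out <- sapply(columns, function(cl) as.numeric(tab[[cl]])[idx])
  out <- matrix(out, nrow = study$n,
                dimnames = list(NULL, columns))
  out
}
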