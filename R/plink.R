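#' Read a PLINK 1 binary fileset
#'
#' Decodes a `.bed`/`.bim`/`.fam` trio in SNP-major mode. Each SNP occupies
#' `ceiling(n/4)` bytes of the `.bed` payload, two bits per individual
#' (low-order bits first): `00` = homozygous allele1 (genotype 2), `10` =
#' heterozygous (1), `11` = homozygous allele2 (0), `01` = missing. The
#' counted allele is the `.bim` allele-1 column; breed labels are taken from
#' the `.fam` family-id column, the de-facto convention for population
#' labels in PLINK filesets.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @return list with `data` (a `geno_matrix`) and `labels` (breed labeling).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop_breedid("read_plink: missing file ", f)
  }
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = "character")
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = c("character", "character", "character",
                                             "integer", "character", "character"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_breedid("read_plink: ", bed, " lacks the PLINK magic bytes 6c 1b")
  }
  if (raw[3] != as.raw(0x01)) {
    stop_breedid("read_plink: only SNP-major .bed files (mode byte 01) are supported")
  }
  bps <- ceiling(n / 4)
  if (length(raw) - 3 != bps * m) {
    stop_breedid("read_plink: .bed payload is ", length(raw) - 3, " bytes but ",
                 m, " SNPs x ", n, " samples require ", bps * m)
  }
  # 256 x 4 lookup: byte value -> allele1 dosage of its four 2-bit fields
  codes <- bitwAnd(outer(0:255, c(0L, 2L, 4L, 6L), bitwShiftR), 3L)
  map <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  lut <- matrix(map[codes + 1L], nrow = 256)
  bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = m)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (slot in 1:4) {
    rows <- seq.int(slot, n, by = 4L)
    if (!length(rows)) next
    byte_rows <- (rows - 1L) %/% 4L + 1L
    geno[rows, ] <- lut[bytes[byte_rows, , drop = FALSE] + 1L, slot]
  }
  variants <- variant_table(bim_df[[1]], bim_df[[4]], bim_df[[5]], bim_df[[6]],
                            snp_id = bim_df[[2]])
  ids <- fam_df[[2]]
  rownames(geno) <- ids
  data <- genotype_matrix(geno, variants, ids)
  labels <- stats::setNames(fam_df[[1]], ids)
  list(data = data, labels = labels)
}

#' Write a PLINK 1 binary fileset
#'
#' Emits a standard SNP-major PLINK 1 trio; the exact inverse of
#' [read_plink()] for the fields the format carries. Fractional (imputed)
#' dosages cannot be represented and are refused.
#'
#' @param data `geno_matrix` with integer genotypes in \{0, 1, 2, NA\}.
#' @param labels breed labeling; written to the `.fam` family-id column.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(data, labels, prefix) {
  geno <- data$geno
  if (nrow(geno) == 0) stop_breedid("write_plink: refusing to write an empty sample set")
  labels <- breed_labeling(labels, data)
  if (any(!is.na(geno) & geno != round(geno))) {
    stop_breedid("write_plink: fractional dosages cannot be encoded; ",
                 "write pre-imputation genotypes")
  }
  n <- nrow(geno)
  m <- ncol(geno)
  # genotype -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(1L, nrow = n, ncol = m)
  code[!is.na(geno) & geno == 2] <- 0L
  code[!is.na(geno) & geno == 1] <- 2L
  code[!is.na(geno) & geno == 0] <- 3L
  bps <- ceiling(n / 4)
  padded <- matrix(0L, nrow = bps * 4L, ncol = m)
  padded[seq_len(n), ] <- code
  shift <- rep(c(1L, 4L, 16L, 64L), bps)
  bytes <- rowsum(padded * shift, group = rep(seq_len(bps), each = 4L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)

  v <- data$variants
  utils::write.table(
    data.frame(v$chrom, v$snp_id, 0L, v$pos, v$allele1, v$allele2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(labels, data$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Import genotypes from a VCF file
#'
#' Reads a VCF (v4.x) and converts biallelic SNP records to the internal
#' genotype model; non-SNP and multiallelic records are skipped with a
#' message. Genotypes count the REF allele on import and should then be
#' normalised with [normalize_snp_ids()] so the counted allele becomes the
#' byte-smaller one.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return list with `data` (a `geno_matrix`), `labels` = NULL (VCF carries
#'   no breed labels), and `n_skipped` records.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_breedid("read_vcf requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")
  }
  if (!any(keep)) stop_breedid("read_vcf: no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # count REF alleles from the GT string, phased or not
  count_ref <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 2L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 0L
    out
  }
  geno <- t(apply(gt, 1, count_ref))
  geno <- t(geno)  # samples x snps
  variants <- variant_table(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                            ref[keep], alt[keep])
  ids <- colnames(gt)
  rownames(geno) <- ids
  list(data = genotype_matrix(geno, variants, ids), labels = NULL,
       n_skipped = n_skipped)
}
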