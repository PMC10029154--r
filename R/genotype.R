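#' Construct a variant table
#'
#' A variant table holds one record per SNP: chromosome, 1-based physical
#' position, the two alleles, and a SNP identifier. Identifiers are
#' normalised to the canonical `Chr:Pos:allele1:allele2` form (alleles in
#' ascending byte order) by [normalize_snp_ids()]; until then `snp_id` may be
#' any label (e.g. an array probe name).
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions (bp).
#' @param allele1 allele whose copies are counted in the genotype matrix.
#' @param allele2 the other allele.
#' @param snp_id SNP identifiers; defaults to `chrom:pos:allele1:allele2`
#'   without reordering (use [normalize_snp_ids()] for the canonical form).
#' @return a `data.frame` with columns `chrom`, `pos`, `allele1`, `allele2`,
#'   `snp_id`.
#' @export
variant_table <- function(chrom, pos, allele1, allele2, snp_id = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  allele1 <- as.character(allele1)
  allele2 <- as.character(allele2)
  n <- max(length(chrom), length(pos), length(allele1), length(allele2))
  lens <- c(length(chrom), length(pos), length(allele1), length(allele2))
  if (any(!lens %in% c(1L, n))) {
    stop_breedid("variant_table: columns must have equal length (or length 1)")
  }
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  allele1 <- rep_len(allele1, n)
  allele2 <- rep_len(allele2, n)
  if (any(!nzchar(allele1)) || any(!nzchar(allele2))) {
    stop_breedid("variant_table: alleles must be non-empty strings")
  }
  if (is.null(snp_id)) {
    snp_id <- paste(chrom, pos, allele1, allele2, sep = ":")
  }
  data.frame(chrom = chrom, pos = pos, allele1 = allele1, allele2 = allele2,
             snp_id = as.character(snp_id), stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' The central genotype container: an individuals-by-SNPs matrix of reference
#' allele counts in \{0, 1, 2, NA\}, where the counted (reference) allele of
#' SNP `j` is `variants$allele1[j]`. After mean imputation entries may be
#' fractional dosages in `[0, 2]`.
#'
#' @param geno numeric matrix, individuals in rows, SNPs in columns.
#' @param variants a variant table (see [variant_table()]) with one row per
#'   column of `geno`.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   rownames of `geno`.
#' @return an object of class `geno_matrix`.
#' @export
genotype_matrix <- function(geno, variants, sample_ids = rownames(geno)) {
  geno <- as.matrix(geno)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample%d", seq_len(nrow(geno)))
  }
  if (nrow(variants) != ncol(geno)) {
    stop_breedid("genotype_matrix: variants rows (", nrow(variants),
                 ") != genotype columns (", ncol(geno), ")")
  }
  if (length(sample_ids) != nrow(geno)) {
    stop_breedid("genotype_matrix: sample_ids length != genotype rows")
  }
  if (anyDuplicated(sample_ids)) {
    stop_breedid("genotype_matrix: duplicated sample ids")
  }
  bad <- !(is.na(geno) | (geno >= 0 & geno <= 2))
  if (any(bad)) {
    stop_breedid("genotype_matrix: genotype entries must be in [0, 2] or NA")
  }
  dimnames(geno) <- list(sample_ids, variants$snp_id)
  structure(list(geno = geno, variants = variants, sample_ids = sample_ids),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " SNPs; ", sum(is.na(x$geno)), " missing entries\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

# Subset a geno_matrix by sample index and/or SNP index, keeping the variant
# table in step.
subset_geno <- function(data, samples = NULL, snps = NULL) {
  geno <- data$geno
  variants <- data$variants
  if (!is.null(samples)) geno <- geno[samples, , drop = FALSE]
  if (!is.null(snps)) {
    geno <- geno[, snps, drop = FALSE]
    variants <- variants[snps, , drop = FALSE]
    rownames(variants) <- NULL
  }
  genotype_matrix(geno, variants, rownames(geno))
}

#' Validate a breed labeling against a genotype matrix
#'
#' A breed labeling is a named character vector mapping every sample id to a
#' breed label, covering each sample exactly once.
#'
#' @param labels named character vector (names are sample ids).
#' @param data optional `geno_matrix` to validate coverage against.
#' @return the labels, as a named character vector.
#' @export
breed_labeling <- function(labels, data = NULL) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stop_breedid("breed_labeling: labels must be named by sample id")
  }
  if (anyDuplicated(names(labels))) {
    stop_breedid("breed_labeling: duplicated sample ids in labels")
  }
  if (!is.null(data)) {
    missing <- setdiff(data$sample_ids, names(labels))
    if (length(missing)) {
      stop_breedid("breed_labeling: no breed label for sample(s) ",
                   paste(utils::head(missing, 5), collapse = ", "))
    }
    labels <- labels[data$sample_ids]
  }
  labels
}

#' Normalise SNP identifiers to `Chr:Pos:allele1:allele2`
#'
#' Rewrites every SNP id to the canonical `Chr:Pos:allele1:allele2` form in
#' which `allele1` and `allele2` are the alleles with the smaller and larger
#' ASCII (byte) code. When applied to a genotype matrix, columns whose
#' counted allele changes under the reordering are recoded `g -> 2 - g` so
#' that counts always refer to the byte-smaller allele.
#'
#' Monomorphic records (`allele1 == allele2`) cannot be ordered and are left
#' unrenamed; they are reported in the `monomorphic` element instead of being
#' silently rewritten.
#'
#' @param x a variant table (`data.frame`) or a `geno_matrix`.
#' @return for a variant table: a list with elements `variants` (normalised
#'   table), `flipped` (logical, `TRUE` where the counted allele changed) and
#'   `monomorphic` (logical). For a `geno_matrix`: the recoded matrix, with
#'   the same list attached as attribute `"normalization"`.
#' @export
normalize_snp_ids <- function(x) {
  UseMethod("normalize_snp_ids")
}

#' @export
normalize_snp_ids.data.frame <- function(x) {
  a1 <- x$allele1
  a2 <- x$allele2
  if (any(!nzchar(a1)) || any(!nzchar(a2))) {
    stop_breedid("normalize_snp_ids: alleles must be non-empty strings")
  }
  mono <- a1 == a2
  # byte-order comparison, independent of locale collation
  flip <- !mono & !ascii_lt(a1, a2)
  new1 <- ifelse(flip, a2, a1)
  new2 <- ifelse(flip, a1, a2)
  out <- x
  out$allele1 <- new1
  out$allele2 <- new2
  out$snp_id <- ifelse(mono, x$snp_id,
                       paste(x$chrom, x$pos, new1, new2, sep = ":"))
  if (any(mono)) {
    warning(sum(mono), " monomorphic record(s) (allele1 == allele2) left unrenamed")
  }
  list(variants = out, flipped = flip, monomorphic = mono)
}

#' @export
normalize_snp_ids.geno_matrix <- function(x) {
  norm <- normalize_snp_ids(x$variants)
  geno <- x$geno
  if (any(norm$flipped)) {
    geno[, norm$flipped] <- 2L - geno[, norm$flipped]
  }
  out <- genotype_matrix(geno, norm$variants, x$sample_ids)
  attr(out, "normalization") <- norm[c("flipped", "monomorphic")]
  out
}

# strict byte-order "less than" for allele strings
ascii_lt <- function(a, b) {
  stopifnot(length(a) == length(b))
  mapply(function(x, y) {
    xb <- utf8ToInt(x); yb <- utf8ToInt(y)
    k <- min(length(xb), length(yb))
    if (k > 0) {
      d <- xb[seq_len(k)] - yb[seq_len(k)]
      nz <- which(d != 0)
      if (length(nz)) return(d[nz[1]] < 0)
    }
    length(xb) < length(yb)
  }, a, b, USE.NAMES = FALSE)
}

#' Harmonise an uploaded genotype matrix against a reference panel
#'
#' Normalises SNP ids on both sides, restricts the upload to the SNPs shared
#' with the reference (matched by normalised id), orders the shared SNPs as
#' in the reference, and recodes genotypes `g -> 2 - g` wherever the upload
#' counted the opposite allele, so that the counted (reference) allele of
#' every retained SNP agrees with the reference panel.
#'
#' Strand-ambiguous markers (A/T and C/G) cannot be distinguished from their
#' reverse-complement under this id scheme; they are matched by id as-is and
#' flagged in the report, never strand-flipped.
#'
#' @param upload `geno_matrix` of the individuals to identify.
#' @param reference `geno_matrix` of the reference panel.
#' @return the harmonised upload (`geno_matrix`), with attribute
#'   `"harmonization"`: a list with `n_common`, `n_upload`, `n_reference`,
#'   `n_flipped`, and `ambiguous` (ids of A/T / C/G markers retained).
#' @export
harmonize_to_reference <- function(upload, reference) {
  up <- normalize_snp_ids(upload)
  ref <- normalize_snp_ids(reference)
  n_flipped <- sum(attr(up, "normalization")$flipped)
  common <- intersect(ref$variants$snp_id, up$variants$snp_id)
  if (length(common) == 0) {
    stop_breedid("harmonize_to_reference: no SNPs shared between upload and ",
                 "reference (upload ", ncol(up$geno), " SNPs, reference ",
                 ncol(ref$geno), " SNPs); check id normalisation and genome build")
  }
  ref_order <- ref$variants$snp_id[ref$variants$snp_id %in% common]
  idx <- match(ref_order, up$variants$snp_id)
  out <- subset_geno(up, snps = idx)
  amb <- with(out$variants,
              (allele1 == "A" & allele2 == "T") | (allele1 == "C" & allele2 == "G"))
  attr(out, "harmonization") <- list(
    n_common = length(common),
    n_upload = ncol(upload$geno),
    n_reference = ncol(reference$geno),
    n_flipped = n_flipped,
    ambiguous = out$variants$snp_id[amb]
  )
  out
}

#' Quality-control filter for a labelled genotype panel
#'
#' Applies, in order: (1) removal of SNPs on sex chromosomes, (2) removal of
#' SNPs with overall minor allele frequency below `maf_min`, (3) removal of
#' breeds represented by fewer than `min_breed_size` individuals.
#'
#' @param data `geno_matrix`.
#' @param labels breed labeling (named character vector).
#' @param maf_min minimum minor allele frequency retained (default 0.01).
#' @param min_breed_size minimum number of individuals per retained breed
#'   (default 10).
#' @param sex_chromosomes chromosome labels treated as sex chromosomes.
#' @return list with `data`, `labels`, and `report` (counts removed at each
#'   step, in application order).
#' @export
qc_filter <- function(data, labels, maf_min = 0.01, min_breed_size = 10,
                      sex_chromosomes = c("X", "Y", "23", "24")) {
  labels <- breed_labeling(labels, data)
  n_snps0 <- ncol(data$geno)

  sex <- data$variants$chrom %in% sex_chromosomes
  if (any(sex)) data <- subset_geno(data, snps = which(!sex))

  p <- colMeans(data$geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  low <- is.na(maf) | maf < maf_min
  if (any(low)) data <- subset_geno(data, snps = which(!low))
  if (ncol(data$geno) == 0) {
    stop_breedid("qc_filter: no SNPs remain after filtering")
  }

  sizes <- table(labels)
  small_breeds <- names(sizes)[sizes < min_breed_size]
  keep_sample <- !(labels %in% small_breeds)
  if (any(!keep_sample)) {
    data <- subset_geno(data, samples = which(keep_sample))
    labels <- labels[keep_sample]
  }
  if (nrow(data$geno) == 0) {
    stop_breedid("qc_filter: no individuals remain after breed-size filter")
  }

  report <- list(
    n_snps_input = n_snps0,
    n_removed_sex_chromosome = sum(sex),
    n_removed_maf = sum(low),
    n_snps_retained = ncol(data$geno),
    breeds_removed = small_breeds,
    n_samples_removed = sum(!keep_sample),
    n_samples_retained = nrow(data$geno)
  )
  list(data = data, labels = labels, report = report)
}

#' Mean-impute missing genotypes
#'
#' Replaces every missing genotype by the per-SNP mean of the observed
#' genotypes (a fractional dosage). Observed values are never altered. When
#' `means` is supplied (e.g. the training-fold means during cross-validation)
#' those values are used instead of the column means of `data`, preventing
#' information flow from test to training folds.
#'
#' @param data `geno_matrix`.
#' @param means optional named numeric vector of per-SNP imputation values.
#' @return the imputed `geno_matrix`.
#' @export
impute_missing <- function(data, means = NULL) {
  geno <- data$geno
  miss <- is.na(geno)
  if (!any(miss)) return(data)
  if (is.null(means)) {
    means <- colMeans(geno, na.rm = TRUE)
    bad <- !is.finite(means)
    if (any(bad)) {
      stop_breedid("impute_missing: SNP(s) with no observed genotypes: ",
                   paste(utils::head(colnames(geno)[bad], 5), collapse = ", "))
    }
  } else {
    means <- means[colnames(geno)]
    if (anyNA(means)) {
      stop_breedid("impute_missing: supplied means do not cover all SNPs")
    }
  }
  idx <- which(miss, arr.ind = TRUE)
  geno[idx] <- means[idx[, 2]]
  genotype_matrix(geno, data$variants, data$sample_ids)
}
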