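test_that("PLINK write/read round-trip is bit-exact", {
  toy <- make_toy_panel(n_breeds = 3, n_snps = 37, n_per_breed = 7,
                        missing_rate = 0.05)
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_plink(toy$data, toy$labels, prefix)
  back <- read_plink(prefix)
  expect_identical(unname(back$data$geno), unname(toy$data$geno))
  expect_identical(back$data$sample_ids, toy$data$sample_ids)
  expect_identical(back$data$variants$pos, toy$data$variants$pos)
  expect_identical(back$data$variants$snp_id, toy$data$variants$snp_id)
  expect_identical(back$data$variants$allele1, toy$data$variants$allele1)
  expect_identical(unname(back$labels), unname(toy$labels))
})

test_that(".bed bytes match the independent bit-packing oracle", {
  # 5 samples: each SNP must occupy ceiling(5/4) = 2 payload bytes
  sep <- make_separable_pair(n_snps = 3, n_per_breed = 3)
  dat <- breedid:::subset_geno(sep$data, samples = 1:5)
  dat$geno[2, 1] <- NA
  dat$geno[4, 2] <- 1L
  prefix <- file.path(withr::local_tempdir(), "five")
  write_plink(dat, sep$labels[1:5], prefix)
  bytes <- readBin(paste0(prefix, ".bed"), "raw", n = 1000)
  expect_length(bytes, 3 + 2 * 3)
  expect_identical(bytes, bed_bytes_oracle(dat$geno))
})

test_that("corrupt magic bytes and dimension mismatches are refused", {
  toy <- make_toy_panel(n_snps = 10, n_per_breed = 3)
  prefix <- file.path(withr::local_tempdir(), "bad")
  write_plink(toy$data, toy$labels, prefix)
  bed <- paste0(prefix, ".bed")
  raw <- readBin(bed, "raw", n = file.size(bed))
  raw[1] <- as.raw(0x00)
  writeBin(raw, bed)
  expect_error(read_plink(prefix), "magic")
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), raw[4:10]), bed)
  expect_error(read_plink(prefix), "payload")
  expect_error(write_plink(breedid:::subset_geno(toy$data, samples = integer(0)),
                           character(0), prefix), "empty")
})

test_that(".bim is 6 whitespace-separated columns with 1-based positions", {
  toy <- make_toy_panel(n_snps = 12, n_per_breed = 3)
  prefix <- file.path(withr::local_tempdir(), "fmt")
  write_plink(toy$data, toy$labels, prefix)
  lines <- readLines(paste0(prefix, ".bim"))
  fields <- strsplit(lines, "[ \t]+")
  expect_true(all(lengths(fields) == 6))
  pos <- as.integer(vapply(fields, `[`, "", 4))
  expect_identical(pos, toy$data$variants$pos)
  expect_true(all(pos >= 1))
})

test_that("SNP ids normalise to Chr:Pos:allele1:allele2 with ASCII-ordered alleles", {
  v <- variant_table(chrom = c("1", "1", "2", "3"),
                     pos = c(12345L, 100L, 555L, 7L),
                     allele1 = c("A", "T", "G", "A"),
                     allele2 = c("G", "C", "C", "T"),
                     snp_id = paste0("probe", 1:4))
  norm <- normalize_snp_ids(v)
  expect_identical(norm$variants$snp_id,
                   c("1:12345:A:G", "1:100:C:T", "2:555:C:G", "3:7:A:T"))
  expect_identical(norm$flipped, c(FALSE, TRUE, TRUE, FALSE))
  # idempotent
  again <- normalize_snp_ids(norm$variants)
  expect_identical(again$variants, norm$variants)
  expect_false(any(again$flipped))
})

test_that("monomorphic records are flagged, not silently renamed", {
  v <- variant_table("1", 5L, "A", "A", snp_id = "mono1")
  expect_warning(norm <- normalize_snp_ids(v), "monomorphic")
  expect_identical(norm$variants$snp_id, "mono1")
  expect_true(norm$monomorphic)
})

test_that("normalising a genotype matrix flips counted alleles g -> 2 - g", {
  v <- variant_table("1", c(10L, 20L), c("A", "T"), c("G", "C"))
  geno <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L), nrow = 3,
                 dimnames = list(paste0("s", 1:3), NULL))
  dat <- genotype_matrix(geno, v)
  norm <- normalize_snp_ids(dat)
  expect_identical(unname(norm$geno[, 1]), c(0L, 1L, 2L))   # A<G: unchanged
  expect_identical(unname(norm$geno[, 2]), c(0L, 2L, 1L))   # T/C swapped
})

test_that("harmonisation restricts to the reference intersection in reference order", {
  toy <- make_toy_panel(n_snps = 50, n_per_breed = 5)
  ref <- toy$data
  keep <- seq(2, 50, by = 5)                # 10 of 50 SNPs, scrambled order
  upload <- breedid:::subset_geno(ref, snps = rev(keep))
  out <- harmonize_to_reference(upload, ref)
  expect_equal(ncol(out$geno), 10)
  expect_identical(colnames(out$geno), colnames(ref$geno)[keep])
  rep <- attr(out, "harmonization")
  expect_equal(rep$n_common, 10)
  # identical upload -> identity
  same <- harmonize_to_reference(ref, ref)
  expect_identical(same$geno, ref$geno)
  # idempotence
  twice <- harmonize_to_reference(out, ref)
  expect_identical(twice$geno, out$geno)
  expect_error(harmonize_to_reference(
    breedid:::subset_geno(ref, snps = 1:5), make_separable_pair(4, 2)$data),
    "no SNPs shared")
})

test_that("harmonisation recodes uploads that count the opposite allele", {
  v_ref <- variant_table("1", c(10L, 20L), c("A", "C"), c("G", "T"))
  ref <- genotype_matrix(matrix(c(2L, 0L, 1L, 1L), 2,
                                dimnames = list(c("r1", "r2"), NULL)), v_ref)
  # same SNPs but the upload counts the byte-larger allele at both
  v_up <- variant_table("1", c(10L, 20L), c("G", "T"), c("A", "C"))
  up <- genotype_matrix(matrix(c(2L, 0L, 1L, 0L), 2,
                               dimnames = list(c("u1", "u2"), NULL)), v_up)
  out <- harmonize_to_reference(up, ref)
  expect_identical(unname(out$geno), matrix(c(0L, 2L, 1L, 2L), 2))
})

test_that("QC removes sex chromosomes, low-MAF SNPs, then small breeds", {
  v <- variant_table(chrom = c("1", "X", "2", "Y", "3"),
                     pos = c(1:5) * 10L,
                     allele1 = rep("A", 5), allele2 = rep("G", 5))
  # SNP3 (chrom 2) gets MAF 0.005 in 100 samples: one heterozygote in 100
  geno <- matrix(1L, nrow = 100, ncol = 5,
                 dimnames = list(paste0("s", 1:100), NULL))
  geno[, 3] <- c(1L, rep(0L, 99))
  labels <- stats::setNames(c(rep("BIG", 91), rep("TINY", 9)), paste0("s", 1:100))
  dat <- genotype_matrix(geno, v)
  out <- qc_filter(dat, labels)
  expect_identical(out$data$variants$chrom, c("1", "3"))
  expect_equal(out$report$n_removed_sex_chromosome, 2)
  expect_equal(out$report$n_removed_maf, 1)
  expect_identical(out$report$breeds_removed, "TINY")
  expect_equal(nrow(out$data$geno), 91)
  expect_false("TINY" %in% out$labels)
  # report counts sum against dimension changes
  expect_equal(out$report$n_snps_input -
                 out$report$n_removed_sex_chromosome - out$report$n_removed_maf,
               out$report$n_snps_retained)
})

test_that("mean imputation fills exactly the missing entries", {
  v <- variant_table("1", c(10L, 20L), c("A", "A"), c("G", "G"))
  geno <- matrix(c(0, 2, NA, 1, 1, 1), nrow = 3,
                 dimnames = list(paste0("s", 1:3), NULL))
  dat <- genotype_matrix(geno, v)
  imp <- impute_missing(dat)
  expect_equal(unname(imp$geno[3, 1]), 1.0)    # mean of {0, 2}
  expect_identical(imp$geno[1:2, 1], dat$geno[1:2, 1])
  expect_identical(imp$geno[, 2], dat$geno[, 2])
  # no missing entries -> identity
  expect_identical(impute_missing(imp)$geno, imp$geno)
  dat$geno[, 2] <- NA
  expect_error(impute_missing(dat), "no observed genotypes")
})

test_that("VCF import recovers genotypes written as VCF text", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t0|1\t0/0",
    "1\t300\t.\tA\tAT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0"), vcf)
  out <- read_vcf(vcf)
  expect_equal(out$n_skipped, 1)               # the indel record
  expect_equal(dim(out$data$geno), c(3L, 2L))
  expect_identical(unname(out$data$geno[, 1]), c(2L, 1L, 0L))
  expect_identical(unname(out$data$geno[, 2]), c(NA_integer_, 1L, 2L))
})
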