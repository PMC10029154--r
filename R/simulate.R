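#' Simulation configuration for multi-breed genotype panels
#'
#' Defines a Balding-Nichols style simulation: each SNP draws an ancestral
#' allele frequency, and each breed's frequency drifts around it with a
#' divergence (drift) parameter `F`; individuals are then drawn in
#' Hardy-Weinberg proportions within breeds.
#'
#' @param n_breeds number of breeds (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param n_per_breed individuals per breed; a single count or one per breed.
#' @param divergence drift parameter `F` in (0, 1); the expected
#'   Weir-Cockerham FST between breeds is approximately `F`.
#' @param ancestral_maf_range interval within (0, 0.5] from which the
#'   ancestral minor allele frequency is drawn uniformly.
#' @param missing_rate probability, in `[0, 1)`, that any single genotype is
#'   set missing (missing completely at random).
#' @param seed integer seed making the whole simulation reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_breeds, n_snps, n_per_breed, divergence,
                       ancestral_maf_range = c(0.05, 0.5),
                       missing_rate = 0, seed = 1L) {
  if (n_breeds < 2) stop_breedid("sim_config: n_breeds must be >= 2")
  if (n_snps < 1) stop_breedid("sim_config: n_snps must be >= 1")
  if (!(length(n_per_breed) %in% c(1L, n_breeds)) || any(n_per_breed < 1)) {
    stop_breedid("sim_config: n_per_breed must be a single count or one per breed, all >= 1")
  }
  if (!is.finite(divergence) || divergence <= 0 || divergence >= 1) {
    stop_breedid("sim_config: divergence must lie strictly in (0, 1)")
  }
  if (length(ancestral_maf_range) != 2 || ancestral_maf_range[1] <= 0 ||
      ancestral_maf_range[2] > 0.5 || diff(ancestral_maf_range) < 0) {
    stop_breedid("sim_config: ancestral_maf_range must be an interval within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_breedid("sim_config: missing_rate must be in [0, 1)")
  }
  structure(list(n_breeds = as.integer(n_breeds), n_snps = as.integer(n_snps),
                 n_per_breed = rep_len(as.integer(n_per_breed), n_breeds),
                 divergence = divergence,
                 ancestral_maf_range = ancestral_maf_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Variant table for simulated SNPs: sequential positions on pig autosomes
# 1-18 with uniform 10 kb spacing (sex chromosomes deliberately absent), and
# a biallelic A/C G/T... pair drawn per SNP with alleles already in byte
# order, so simulated ids are born normalised.
sim_variant_table <- function(n_snps) {
  chrom <- as.character(rep_len(1:18, n_snps)[order(rep_len(1:18, n_snps))])
  chrom <- as.character(sort(rep_len(1:18, n_snps)))
  pos <- integer(n_snps)
  for (c_ in unique(chrom)) {
    k <- which(chrom == c_)
    pos[k] <- seq_along(k) * 10000L
  }
  pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T"), ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), n_snps, replace = TRUE)
  variant_table(chrom, pos, pairs[pick, 1], pairs[pick, 2])
}

#' Simulate breed allele frequencies under a drift model
#'
#' For each SNP an ancestral frequency `p` is drawn uniformly from
#' `ancestral_maf_range` and assigned at random to either allele; each
#' breed's reference-allele frequency is then drawn from the Balding-Nichols
#' Beta distribution with shape parameters `p(1-F)/F` and `(1-p)(1-F)/F`,
#' i.e. mean `p` and variance `F p (1-p)`.
#'
#' @param config a [sim_config()].
#' @return a breeds-by-SNPs matrix of reference-allele frequencies with
#'   breed ids as rownames and SNP ids as colnames; the simulated variant
#'   table is attached as attribute `"variants"`.
#' @export
simulate_breed_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    variants <- sim_variant_table(config$n_snps)
    r <- config$ancestral_maf_range
    p <- stats::runif(config$n_snps, r[1], r[2])
    swap <- stats::runif(config$n_snps) < 0.5
    p[swap] <- 1 - p[swap]
    f <- config$divergence
    shape1 <- p * (1 - f) / f
    shape2 <- (1 - p) * (1 - f) / f
    freq <- matrix(stats::rbeta(config$n_breeds * config$n_snps,
                                rep(shape1, each = config$n_breeds),
                                rep(shape2, each = config$n_breeds)),
                   nrow = config$n_breeds, ncol = config$n_snps)
    dimnames(freq) <- list(paste0("BREED", seq_len(config$n_breeds)),
                           variants$snp_id)
    attr(freq, "variants") <- variants
    attr(freq, "ancestral") <- p
    freq
  })
}

#' Simulate Hardy-Weinberg genotypes from breed frequencies
#'
#' Each individual's genotype at each SNP is Binomial(2, breed frequency);
#' entries are then set missing independently with probability
#' `missing_rate`.
#'
#' @param freqs breeds-by-SNPs frequency matrix as returned by
#'   [simulate_breed_frequencies()] (or any matrix with breed rownames and a
#'   `"variants"` attribute).
#' @param n_per_breed individuals per breed; single count or one per breed,
#'   named by breed if per-breed.
#' @param missing_rate per-entry missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `data` (a `geno_matrix`) and `labels` (breed labeling).
#' @export
simulate_genotypes <- function(freqs, n_per_breed, missing_rate = 0, seed = 1L) {
  variants <- attr(freqs, "variants")
  if (is.null(variants)) {
    variants <- variant_table(rep("1", ncol(freqs)), seq_len(ncol(freqs)),
                              rep("A", ncol(freqs)), rep("G", ncol(freqs)),
                              colnames(freqs))
  }
  breeds <- rownames(freqs)
  n_per_breed <- rep_len(as.integer(n_per_breed), length(breeds))
  if (any(n_per_breed < 1)) stop_breedid("simulate_genotypes: n_per_breed must be >= 1")
  with_seed(seed, {
    rows <- vector("list", length(breeds))
    for (b in seq_along(breeds)) {
      n <- n_per_breed[b]
      g <- matrix(stats::rbinom(n * ncol(freqs), 2L, rep(freqs[b, ], each = n)),
                  nrow = n)
      rows[[b]] <- g
    }
    geno <- do.call(rbind, rows)
    labels <- rep(breeds, n_per_breed)
    ids <- paste0(labels, "_", unlist(lapply(n_per_breed, seq_len)))
    if (missing_rate > 0) {
      geno[stats::runif(length(geno)) < missing_rate] <- NA
    }
    rownames(geno) <- ids
    data <- genotype_matrix(geno, variants, ids)
    list(data = data, labels = stats::setNames(labels, ids))
  })
}

#' Simulate F1 crossbred individuals between two breeds
#'
#' Each genotype is the sum of one allele drawn from each parental breed:
#' Bernoulli(f_a) + Bernoulli(f_b) at every SNP.
#'
#' @param freqs breeds-by-SNPs frequency matrix.
#' @param breed_a,breed_b rownames of the two parental breeds.
#' @param n number of crossbred individuals.
#' @param seed integer seed.
#' @return a `geno_matrix` of `n` F1 individuals.
#' @export
simulate_crossbreds <- function(freqs, breed_a, breed_b, n, seed = 1L) {
  for (b in c(breed_a, breed_b)) {
    if (!b %in% rownames(freqs)) {
      stop_breedid("simulate_crossbreds: breed '", b, "' not present in freqs")
    }
  }
  variants <- attr(freqs, "variants")
  if (is.null(variants)) {
    variants <- variant_table(rep("1", ncol(freqs)), seq_len(ncol(freqs)),
                              rep("A", ncol(freqs)), rep("G", ncol(freqs)),
                              colnames(freqs))
  }
  with_seed(seed, {
    fa <- rep(freqs[breed_a, ], each = n)
    fb <- rep(freqs[breed_b, ], each = n)
    g <- matrix(stats::rbinom(n * ncol(freqs), 1L, fa) +
                  stats::rbinom(n * ncol(freqs), 1L, fb), nrow = n)
    ids <- paste0("F1_", breed_a, "x", breed_b, "_", seq_len(n))
    rownames(g) <- ids
    genotype_matrix(g, variants, ids)
  })
}

#' Spike breed-informative SNPs into a frequency matrix
#'
#' Pushes the frequencies of the chosen SNPs toward opposite extremes
#' between the target breeds and all other breeds: target-breed frequencies
#' are shifted by `+delta`, the rest by `-delta`, and the result is clipped
#' to `[0, 1]`. Used to plant ground-truth informative markers for
#' selector-recovery experiments. The input matrix is not modified.
#'
#' @param freqs breeds-by-SNPs frequency matrix.
#' @param snp_indices column indices (or SNP ids) of the SNPs to spike.
#' @param target_breeds breed rownames shifted upward.
#' @param delta frequency shift in `[0, 1]`; `delta = 1` drives the spiked
#'   SNPs to fixed differences.
#' @return a new frequency matrix with the same dimnames and attributes.
#' @export
spike_informative_snps <- function(freqs, snp_indices, target_breeds, delta) {
  if (length(snp_indices) == 0) {
    stop_breedid("spike_informative_snps: empty SNP index set")
  }
  if (is.character(snp_indices)) {
    snp_indices <- match(snp_indices, colnames(freqs))
  }
  if (anyNA(snp_indices) || any(snp_indices < 1) || any(snp_indices > ncol(freqs))) {
    stop_breedid("spike_informative_snps: invalid SNP indices")
  }
  if (!all(target_breeds %in% rownames(freqs))) {
    stop_breedid("spike_informative_snps: unknown target breed(s)")
  }
  out <- freqs
  up <- rownames(freqs) %in% target_breeds
  out[up, snp_indices] <- pmin(1, out[up, snp_indices] + delta)
  out[!up, snp_indices] <- pmax(0, out[!up, snp_indices] - delta)
  out
}
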