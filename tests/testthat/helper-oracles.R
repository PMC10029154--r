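# Independent oracles used to cross-check the package implementations.
# These are written as literal, loop-based transcriptions so they share no
# code path with the vectorised implementations they check.

# naive double-loop average Euclidean distance over breed pairs
aed_oracle <- function(freqs) {
  t_breeds <- nrow(freqs)
  out <- numeric(ncol(freqs))
  for (s in seq_len(ncol(freqs))) {
    acc <- 0
    for (i in seq_len(t_breeds - 1)) {
      for (j in (i + 1):t_breeds) {
        acc <- acc + (freqs[i, s] - freqs[j, s])^2
      }
    }
    out[s] <- sqrt(acc) / choose(t_breeds, 2)
  }
  out
}

# textbook Weir & Cockerham (1984) a/b/c variance components for one SNP,
# from per-population genotype vectors (0/1/2 allele1 counts, NA = missing)
wc_fst_oracle <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    g <- geno_by_pop[[i]]
    g <- g[!is.na(g)]
    n[i] <- length(g)
    p[i] <- sum(g) / (2 * length(g))
    h[i] <- mean(g == 1)
  }
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  a / (a + b + c_)
}

# bit-level PLINK .bed writer: packs genotypes two bits at a time with
# explicit shifts, independent of the vectorised writer in the package
bed_bytes_oracle <- function(geno) {
  n <- nrow(geno)
  out <- raw(0)
  for (s in seq_len(ncol(geno))) {
    for (start in seq(1, n, by = 4)) {
      byte <- 0L
      for (slot in 0:3) {
        i <- start + slot
        code <- if (i > n) 0L else {
          g <- geno[i, s]
          if (is.na(g)) 1L else if (g == 2) 0L else if (g == 1) 2L else 3L
        }
        byte <- byte + bitwShiftL(code, 2L * slot)
      }
      out <- c(out, as.raw(byte))
    }
  }
  c(as.raw(c(0x6c, 0x1b, 0x01)), out)
}

# small labelled genotype panel used across tests
make_toy_panel <- function(n_breeds = 3, n_snps = 50, n_per_breed = 10,
                           divergence = 0.2, missing_rate = 0, seed = 42) {
  cfg <- sim_config(n_breeds, n_snps, n_per_breed, divergence,
                    missing_rate = missing_rate, seed = seed)
  fr <- simulate_breed_frequencies(cfg)
  c(simulate_genotypes(fr, n_per_breed, missing_rate, seed = seed + 1),
    list(freqs = fr))
}

# two breeds fixed for opposite alleles at every SNP: perfectly separable
make_separable_pair <- function(n_snps = 100, n_per_breed = 10) {
  variants <- variant_table(rep("1", n_snps), seq_len(n_snps) * 100L,
                            rep("A", n_snps), rep("G", n_snps))
  geno <- rbind(matrix(2L, n_per_breed, n_snps), matrix(0L, n_per_breed, n_snps))
  ids <- c(paste0("P1_", seq_len(n_per_breed)), paste0("P2_", seq_len(n_per_breed)))
  rownames(geno) <- ids
  list(data = genotype_matrix(geno, variants, ids),
       labels = stats::setNames(rep(c("POP1", "POP2"), each = n_per_breed), ids))
}
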