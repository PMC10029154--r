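#' Per-breed reference-allele frequencies
#'
#' Computes the breeds-by-SNPs matrix of reference-allele frequencies:
#' entry (b, s) is the sum of reference-allele counts in breed b at SNP s
#' divided by twice the number of observed genotypes; missing genotypes are
#' excluded from both numerator and denominator.
#'
#' @param data `geno_matrix`.
#' @param labels breed labeling.
#' @return breeds x SNPs frequency matrix (breed rownames, SNP id colnames)
#'   with the variant table attached as attribute `"variants"`.
#' @export
breed_frequencies <- function(data, labels) {
  labels <- breed_labeling(labels, data)
  geno <- data$geno
  grp <- factor(labels, levels = sort(unique(labels)))
  obs <- !is.na(geno)
  g0 <- geno
  g0[!obs] <- 0
  counts <- rowsum(g0, grp)                 # allele counts per breed
  n_obs <- rowsum(obs + 0, grp)             # observed genotypes per breed
  if (any(n_obs == 0)) {
    bad <- which(n_obs == 0, arr.ind = TRUE)[1, ]
    stop_breedid("breed_frequencies: breed '", levels(grp)[bad[1]],
                 "' has no observed genotypes at SNP ",
                 colnames(geno)[bad[2]], "; impute or filter first")
  }
  freq <- counts / (2 * n_obs)
  attr(freq, "variants") <- data$variants
  freq
}

# wrap per-SNP scores with the metadata build_panel needs for tie-breaking
selector_scores <- function(selector, score, variants) {
  structure(
    data.frame(snp_id = variants$snp_id, chrom = variants$chrom,
               pos = variants$pos, score = score, stringsAsFactors = FALSE),
    selector = selector, class = c("selector_scores", "data.frame"))
}

#' @export
print.selector_scores <- function(x, ...) {
  cat("<selector_scores> ", attr(x, "selector"), ": ", nrow(x), " SNPs, ",
      sum(is.na(x$score)), " missing scores\n", sep = "")
  invisible(x)
}

#' Average Euclidean distance (AED) of breed allele frequencies
#'
#' For each SNP with breed frequencies f_1..f_T the statistic is
#' \deqn{AED = \frac{1}{C(T,2)} \sqrt{\sum_{i<j} (f_i - f_j)^2},}
#' the root of the summed squared pairwise frequency differences divided by
#' the number of breed pairs. It is zero iff all breeds share the frequency.
#'
#' @param freqs breeds x SNPs frequency matrix (>= 2 breeds).
#' @return a `selector_scores` object (selector `"AED"`).
#' @export
score_aed <- function(freqs) {
  t_breeds <- nrow(freqs)
  if (is.null(t_breeds) || t_breeds < 2) {
    stop_breedid("score_aed: at least two breeds required")
  }
  # sum_{i<j} (f_i - f_j)^2 = T * sum f_i^2 - (sum f_i)^2
  ss <- colSums(freqs^2)
  s <- colSums(freqs)
  pairsum <- pmax(0, t_breeds * ss - s^2)
  score <- sqrt(pairsum) / choose(t_breeds, 2)
  selector_scores("AED", unname(score), variants_of(freqs))
}

variants_of <- function(freqs) {
  v <- attr(freqs, "variants")
  if (is.null(v)) {
    v <- variant_table(rep("1", ncol(freqs)), seq_len(ncol(freqs)),
                       rep("A", ncol(freqs)), rep("G", ncol(freqs)),
                       colnames(freqs) %||% paste0("snp", seq_len(ncol(freqs))))
  }
  v
}

#' Per-SNP Weir-Cockerham F_ST
#'
#' The multi-population Weir & Cockerham (1984) estimator
#' \eqn{\hat\theta = a / (a + b + c)} computed per SNP from the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components, using observed genotype and
#' heterozygote counts per breed. The estimate can be slightly negative when
#' there is no differentiation; SNPs whose denominator is undefined (e.g. a
#' breed with no observed genotypes, or a monomorphic SNP) get a missing
#' score.
#'
#' @param data `geno_matrix`.
#' @param labels breed labeling (>= 2 breeds).
#' @return a `selector_scores` object (selector `"FST"`).
#' @export
score_fst <- function(data, labels) {
  labels <- breed_labeling(labels, data)
  breeds <- sort(unique(labels))
  r <- length(breeds)
  if (r < 2) stop_breedid("score_fst: at least two breeds required")
  geno <- data$geno
  grp <- factor(labels, levels = breeds)
  obs <- !is.na(geno)
  g0 <- geno
  g0[!obs] <- 0
  n_mat <- rowsum(obs + 0, grp)             # r x m sample sizes (individuals)
  count <- rowsum(g0, grp)                  # allele1 counts
  het <- rowsum((geno == 1 & obs) + 0, grp) # heterozygote counts

  any_empty <- colSums(n_mat == 0) > 0
  n_mat_safe <- pmax(n_mat, 1e-300)
  p_mat <- count / (2 * n_mat_safe)
  h_mat <- het / n_mat_safe

  nbar <- colMeans(n_mat)
  sum_n <- colSums(n_mat)
  nc <- (sum_n - colSums(n_mat^2) / sum_n) / (r - 1)
  pbar <- colSums(n_mat * p_mat) / sum_n
  s2 <- colSums(n_mat * sweep(p_mat, 2L, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_mat * h_mat) / sum_n

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_comp <- hbar / 2
  denom <- a + b + c_comp
  theta <- a / denom
  theta[!is.finite(theta) | abs(denom) < 1e-12 | any_empty] <- NA_real_
  selector_scores("FST", unname(theta), data$variants)
}

#' PCA eigenvector loadings of the breed-frequency matrix
#'
#' Principal component analysis of the breeds-by-SNPs frequency matrix (SNP
#' columns mean-centred, unscaled). The score of a SNP is the sum over the
#' first `min(n_components, T - 1)` principal components of the squared
#' eigenvector (rotation) entry for that SNP. With orthonormal eigenvectors
#' the scores over all SNPs sum to the number of components used.
#'
#' @param freqs breeds x SNPs frequency matrix (>= 2 breeds).
#' @param n_components number of leading components (default 10).
#' @return a `selector_scores` object (selector `"PCA"`).
#' @export
score_pca_loading <- function(freqs, n_components = 10) {
  t_breeds <- nrow(freqs)
  if (is.null(t_breeds) || t_breeds < 2) {
    stop_breedid("score_pca_loading: at least two breeds required")
  }
  centred <- sweep(freqs, 2L, colMeans(freqs))
  if (all(abs(centred) < 1e-12)) {
    warning("score_pca_loading: all SNP columns constant across breeds; all scores 0")
    return(selector_scores("PCA", rep(0, ncol(freqs)), variants_of(freqs)))
  }
  pc <- stats::prcomp(freqs, center = TRUE, scale. = FALSE)
  k <- min(n_components, t_breeds - 1L, ncol(pc$rotation))
  if (k < n_components) {
    message("score_pca_loading: using ", k, " components (limited by breed count)")
  }
  score <- rowSums(pc$rotation[, seq_len(k), drop = FALSE]^2)
  out <- selector_scores("PCA", unname(score), variants_of(freqs))
  attr(out, "n_components_used") <- k
  out
}

#' PLSR regression-coefficient scores
#'
#' Fits a partial least squares regression of the one-hot breed indicator
#' matrix on the genotype dosages ([plsr_fit()]) and scores each SNP by the
#' sum over breeds of its squared regression coefficients. Genotypes are
#' mean-imputed before fitting; dosages feed the regression unstandardised.
#'
#' @param data `geno_matrix`.
#' @param labels breed labeling (>= 2 breeds).
#' @param n_components latent components, capped at
#'   `min(n_components, n_samples - 1, n_SNPs)` (default 150).
#' @return a `selector_scores` object (selector `"PLSR"`).
#' @export
score_plsr <- function(data, labels, n_components = 150) {
  labels <- breed_labeling(labels, data)
  if (length(unique(labels)) < 2) {
    stop_breedid("score_plsr: at least two breeds required")
  }
  x <- impute_missing(data)$geno
  y <- one_hot(labels)
  fit <- plsr_fit(x, y, n_components)
  score <- rowSums(fit$coefficients^2)
  selector_scores("PLSR", unname(score), data$variants)
}

#' Build a fixed-density marker panel from selector scores
#'
#' Retains the `density` top-scoring SNPs in descending score order. Ties
#' are broken by ascending (chromosome, position) and SNPs with missing
#' scores rank last, so the panel is reproducible across runs.
#'
#' @param scores a `selector_scores` object.
#' @param density number of SNPs to retain (>= 1).
#' @return an object of class `breedid_panel`: list with `selector`,
#'   `density`, `snp_ids` (rank order) and the ranked `scores`.
#' @export
build_panel <- function(scores, density) {
  stopifnot(inherits(scores, "selector_scores"))
  if (density < 1) stop_breedid("build_panel: density must be >= 1")
  if (density > nrow(scores)) {
    warning("build_panel: density ", density, " exceeds the ", nrow(scores),
            " available SNPs; returning all SNPs")
    density <- nrow(scores)
  }
  ord <- order(is.na(scores$score), -ifelse(is.na(scores$score), 0, scores$score),
               chrom_sort_key(scores$chrom), scores$pos)
  top <- ord[seq_len(density)]
  structure(list(selector = attr(scores, "selector"), density = as.integer(density),
                 snp_ids = scores$snp_id[top], scores = scores$score[top]),
            class = "breedid_panel")
}

#' @export
print.breedid_panel <- function(x, ...) {
  cat("<breedid_panel> ", x$density, " SNPs selected by ", x$selector, "\n", sep = "")
  invisible(x)
}
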