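#' Configuration for the breed-identification workflow
#'
#' @param n_select number of informative SNPs to select when enough common
#'   SNPs are available (default 5000). Selection is skipped when the
#'   upload/reference intersection is smaller than `n_select`.
#' @param selector marker selector (default `"PLSR"`).
#' @param classifier classifier (default `"PLSDA"`; the only
#'   probability-capable choice, required when `threshold` is not `NA`).
#' @param threshold unknown-rejection probability threshold in `[0, 1]`, or
#'   `NA` to disable rejection (default 0.02).
#' @param min_common_floor minimum common-SNP count below which a prominent
#'   reliability warning is raised (default 200).
#' @return an object of class `identification_config`.
#' @export
identification_config <- function(n_select = 5000L, selector = "PLSR",
                                  classifier = "PLSDA", threshold = 0.02,
                                  min_common_floor = 200L) {
  if (n_select < 1) stop_breedid("identification_config: n_select must be >= 1")
  if (!is.na(threshold) && (threshold < 0 || threshold > 1)) {
    stop_breedid("identification_config: threshold must be in [0, 1] or NA")
  }
  structure(list(n_select = as.integer(n_select),
                 selector = match.arg(toupper(selector),
                                      c("AED", "FST", "PCA", "PLSR")),
                 classifier = toupper(classifier), threshold = threshold,
                 min_common_floor = as.integer(min_common_floor)),
            class = "identification_config")
}

#' Identify the breeds of uploaded individuals against a reference panel
#'
#' The full identification pipeline: SNP ids of upload and reference are
#' normalised, the upload restricted to the SNPs shared with the reference
#' and recoded to the reference alleles; if the number of common SNPs is at
#' least `n_select`, the selector (PLSR by default) is run on the reference
#' restricted to the common SNPs and the top `n_select` markers retained,
#' otherwise selection is skipped and all common SNPs are used; the
#' classifier (PLS-DA) is then trained on the reference panel and each
#' uploaded individual assigned the breed with the highest softmax
#' probability, with assignments below the rejection threshold set to
#' "unknown".
#'
#' @param upload `geno_matrix` of individuals to identify.
#' @param reference `geno_matrix` of the labelled reference panel (already
#'   quality-controlled).
#' @param ref_labels breed labeling of the reference individuals.
#' @param config an [identification_config()].
#' @param seed integer seed (random forest only; the default pipeline is
#'   deterministic).
#' @return a `prediction_result` with attribute `"report"`: list with
#'   `n_common`, `selection_skipped`, `panel_size`, `selector`,
#'   `classifier`, `threshold`.
#' @export
identify_breeds <- function(upload, reference, ref_labels,
                            config = identification_config(), seed = 1L) {
  stopifnot(inherits(config, "identification_config"))
  ref_labels <- breed_labeling(ref_labels, reference)
  upload_h <- harmonize_to_reference(upload, reference)
  n_common <- ncol(upload_h$geno)
  if (n_common < config$min_common_floor) {
    warning("identify_breeds: only ", n_common, " SNPs shared with the ",
            "reference (floor ", config$min_common_floor,
            "); assignments may be unreliable")
  }
  reference <- normalize_snp_ids(reference)
  ref_common <- subset_geno(reference,
                            snps = match(colnames(upload_h$geno),
                                         colnames(reference$geno)))
  skip <- n_common < config$n_select
  if (!skip) {
    ref_imp <- impute_missing(ref_common)
    scores <- compute_selector_scores(ref_imp, ref_labels, config$selector, NULL)
    panel <- build_panel(scores, config$n_select)
    panel_ids <- panel$snp_ids
  } else {
    panel_ids <- colnames(upload_h$geno)
  }
  ref_panel <- subset_geno(ref_common,
                           snps = match(panel_ids, colnames(ref_common$geno)))
  model <- fit_classifier(classifier_spec(config$classifier), ref_panel,
                          ref_labels, seed = seed)
  up_panel <- subset_geno(upload_h,
                          snps = match(panel_ids, colnames(upload_h$geno)))
  results <- predict(model, up_panel)
  results <- apply_unknown_threshold(results, config$threshold)
  attr(results, "report") <- list(
    n_common = n_common, selection_skipped = skip,
    panel_size = length(panel_ids), selector = config$selector,
    classifier = config$classifier, threshold = config$threshold)
  results
}

#' Design a breed-informative SNP panel for chosen breeds
#'
#' Selects the markers that best discriminate the requested breeds and
#' evaluates the panel by five-fold cross-validation. With multiple target
#' breeds the selector runs on the reference individuals of those breeds
#' only; with a single target breed a two-class problem is posed (the
#' target versus all other reference breeds pooled) so that markers
#' distinguishing that breed from the rest of the reference are selected.
#'
#' @param reference `geno_matrix` reference panel.
#' @param ref_labels breed labeling.
#' @param target_breeds one or more breed labels present in the reference.
#' @param density panel size (>= 1).
#' @param selector marker selector (default `"PLSR"`).
#' @param classifier [classifier_spec()] used in the evaluation CV (default
#'   PLS-DA).
#' @param seed integer seed for the CV fold shuffle.
#' @return list with `panel` (a `breedid_panel`) and `cv` (a `cv_report`
#'   from one round of five-fold CV on the relevant individuals).
#' @export
design_panel <- function(reference, ref_labels, target_breeds, density,
                         selector = "PLSR",
                         classifier = classifier_spec("PLSDA"), seed = 1L) {
  ref_labels <- breed_labeling(ref_labels, reference)
  available <- sort(unique(ref_labels))
  unknown <- setdiff(target_breeds, available)
  if (length(unknown)) {
    stop_breedid("design_panel: unknown breed(s) ",
                 paste(unknown, collapse = ", "), "; available: ",
                 paste(available, collapse = ", "))
  }
  if (density < 1) stop_breedid("design_panel: density must be >= 1")
  selector <- match.arg(toupper(selector), c("AED", "FST", "PCA", "PLSR"))
  if (length(target_breeds) >= 2) {
    keep <- ref_labels %in% target_breeds
    data <- subset_geno(reference, samples = which(keep))
    labels <- ref_labels[keep]
  } else {
    data <- reference
    labels <- stats::setNames(
      ifelse(ref_labels == target_breeds, target_breeds, "OTHER"),
      names(ref_labels))
  }
  data <- impute_missing(data)
  scores <- compute_selector_scores(data, labels, selector, NULL)
  panel <- build_panel(scores, min(density, ncol(data$geno)))
  snp_idx <- match(panel$snp_ids, colnames(data$geno))
  cv <- repeated_cv(subset_geno(data, snps = snp_idx), labels,
                    selector = selector, density = panel$density,
                    classifier = classifier, n_repeats = 1L, n_folds = 5L,
                    seed = seed)
  list(panel = panel, cv = cv)
}

#' Merge labelled genotype datasets into a reference panel
#'
#' Normalises SNP ids in every dataset, restricts all of them to the SNPs
#' common to every dataset (matched by normalised id and harmonised to the
#' allele orientation of the first dataset), stacks the individuals, and
#' applies the standard QC filters.
#'
#' @param datasets list of `list(data = geno_matrix, labels = labeling)`.
#' @param maf_min,min_breed_size,sex_chromosomes passed to [qc_filter()].
#' @return list with `data`, `labels`, and `report` (merge and QC counts).
#' @export
build_reference <- function(datasets, maf_min = 0.01, min_breed_size = 10,
                            sex_chromosomes = c("X", "Y", "23", "24")) {
  if (length(datasets) < 1) stop_breedid("build_reference: at least one dataset required")
  first <- normalize_snp_ids(datasets[[1]]$data)
  harmonized <- vector("list", length(datasets))
  harmonized[[1]] <- first
  if (length(datasets) > 1) {
    for (i in seq_along(datasets)[-1]) {
      harmonized[[i]] <- harmonize_to_reference(datasets[[i]]$data, first)
    }
    common <- Reduce(intersect, lapply(harmonized, function(d) colnames(d$geno)))
    if (length(common) == 0) {
      stop_breedid("build_reference: no SNPs shared by all datasets")
    }
    common <- colnames(first$geno)[colnames(first$geno) %in% common]
    harmonized <- lapply(harmonized, function(d) {
      subset_geno(d, snps = match(common, colnames(d$geno)))
    })
  }
  geno <- do.call(rbind, lapply(harmonized, function(d) d$geno))
  merged <- genotype_matrix(geno, harmonized[[1]]$variants, rownames(geno))
  labels <- do.call(c, lapply(datasets, function(d) breed_labeling(d$labels)))
  qc <- qc_filter(merged, labels, maf_min = maf_min,
                  min_breed_size = min_breed_size,
                  sex_chromosomes = sex_chromosomes)
  qc$report$n_datasets <- length(datasets)
  qc$report$n_common_snps <- ncol(merged$geno)
  qc
}
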