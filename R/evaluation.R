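#' Stratified fold assignment
#'
#' Assigns individuals to `n_folds` cross-validation folds so that each
#' breed's individuals are spread as evenly as possible: within every breed
#' the per-fold counts differ by at most one. Breeds with fewer individuals
#' than folds trigger a warning (some folds will lack that breed) but their
#' individuals are still assigned.
#'
#' @param labels breed labeling (named character vector).
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return integer vector of fold indices (1..n_folds), named by sample id.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  if (n_folds < 2) stop_breedid("stratified_folds: n_folds must be >= 2")
  labels <- breed_labeling(labels)
  small <- names(which(table(labels) < n_folds))
  if (length(small)) {
    warning("stratified_folds: breed(s) with fewer individuals than folds: ",
            paste(small, collapse = ", "))
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    names(fold) <- names(labels)
    for (b in sort(unique(labels))) {
      idx <- which(labels == b)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(n_folds, 1L)
      fold[idx] <- (start - 1L + seq_along(idx) - 1L) %% n_folds + 1L
    }
    fold
  })
}

#' Repeated stratified cross-validation of a selector/classifier pipeline
#'
#' Runs `n_repeats` rounds of stratified `n_folds`-fold cross-validation.
#' Within every fold the selector statistic is computed on the training
#' portion only, the top-`density` panel built, the classifier trained on
#' the training individuals, and the held-out individuals predicted; no
#' information from the held-out fold reaches panel selection or model
#' fitting (test-fold missing genotypes are completed with training-fold
#' means). For PLS-DA the argmax label is used (no unknown-rejection).
#'
#' Several densities may be evaluated at once; the per-fold selector scores
#' are computed a single time and the panel/classifier stage repeated per
#' density.
#'
#' @param data `geno_matrix`.
#' @param labels breed labeling.
#' @param selector `"AED"`, `"FST"`, `"PCA"` or `"PLSR"`.
#' @param density panel density (or vector of densities).
#' @param classifier a [classifier_spec()].
#' @param n_repeats repeats (default 5).
#' @param n_folds folds (default 5).
#' @param seed integer seed; repeat `r` shuffles folds with `seed + r`.
#' @param selector_components components for the PCA (10) / PLSR (150)
#'   selectors; `NULL` keeps those defaults.
#' @param keep_panels record every fold's selected panel in the report
#'   (element `panels`), e.g. to audit that held-out information never
#'   enters selection.
#' @return an object of class `cv_report`: list with `fold_accuracies`
#'   (data.frame: repeat, fold, density, accuracy), `mean_accuracy` (named
#'   by density), `per_breed_accuracy`, and `confusion` (table at the first
#'   density).
#' @export
repeated_cv <- function(data, labels, selector, density, classifier,
                        n_repeats = 5L, n_folds = 5L, seed = 1L,
                        selector_components = NULL, keep_panels = FALSE) {
  labels <- breed_labeling(labels, data)
  selector <- match.arg(toupper(selector), c("AED", "FST", "PCA", "PLSR"))
  densities <- sort(unique(as.integer(density)))
  rows <- list()
  correct_by_breed <- stats::setNames(numeric(length(unique(labels))),
                                      sort(unique(labels)))
  total_by_breed <- correct_by_breed
  confusion <- NULL
  panels <- if (keep_panels) list() else NULL
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(labels, n_folds, seed = seed + r)
    for (f in seq_len(n_folds)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      train <- subset_geno(data, samples = train_idx)
      test <- subset_geno(data, samples = test_idx)
      train_lab <- labels[train_idx]
      test_lab <- labels[test_idx]
      train <- impute_missing(train)
      scores <- compute_selector_scores(train, train_lab, selector,
                                        selector_components)
      for (d in densities) {
        dd <- d
        if (dd > ncol(train$geno)) {
          warning("repeated_cv: density ", dd, " exceeds available SNPs; truncated")
          dd <- ncol(train$geno)
        }
        panel <- build_panel(scores, dd)
        if (keep_panels) {
          panels[[paste(r, f, dd, sep = ":")]] <- panel$snp_ids
        }
        snp_idx <- match(panel$snp_ids, colnames(data$geno))
        model <- fit_classifier(classifier, subset_geno(train, snps = snp_idx),
                                train_lab, seed = seed + r)
        pred <- predict(model, subset_geno(test, snps = snp_idx))
        acc <- mean(pred$predicted_breed == test_lab)
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, fold = f, density = dd, accuracy = acc)
        if (d == densities[1]) {
          hit <- pred$predicted_breed == test_lab
          agg <- tapply(hit, test_lab, sum)
          correct_by_breed[names(agg)] <- correct_by_breed[names(agg)] + agg
          tot <- table(test_lab)
          total_by_breed[names(tot)] <- total_by_breed[names(tot)] + tot
          tab <- table(truth = test_lab, predicted = pred$predicted_breed)
          confusion <- if (is.null(confusion)) tab else add_tables(confusion, tab)
        }
      }
    }
  }
  fold_acc <- do.call(rbind, rows)
  mean_acc <- c(tapply(fold_acc$accuracy, fold_acc$density, mean))
  structure(list(
    n_repeats = n_repeats, n_folds = n_folds, selector = selector,
    classifier = classifier$name, densities = densities,
    fold_accuracies = fold_acc,
    mean_accuracy = mean_acc,
    per_breed_accuracy = correct_by_breed / pmax(total_by_breed, 1),
    confusion = confusion, panels = panels), class = "cv_report")
}

compute_selector_scores <- function(train, train_lab, selector, components) {
  switch(selector,
    AED = score_aed(breed_frequencies(train, train_lab)),
    FST = score_fst(train, train_lab),
    PCA = score_pca_loading(breed_frequencies(train, train_lab),
                            n_components = components %||% 10),
    PLSR = score_plsr(train, train_lab, n_components = components %||% 150))
}

add_tables <- function(a, b) {
  rows <- union(rownames(a), rownames(b))
  cols <- union(colnames(a), colnames(b))
  out <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  out[rownames(a), colnames(a)] <- out[rownames(a), colnames(a)] + a
  out[rownames(b), colnames(b)] <- out[rownames(b), colnames(b)] + b
  as.table(out)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$selector, " selector + ", x$classifier, ", ",
      x$n_repeats, "x", x$n_folds, "-fold CV\n", sep = "")
  for (d in names(x$mean_accuracy)) {
    cat(sprintf("  density %s: mean accuracy %.4f\n", d, x$mean_accuracy[[d]]))
  }
  invisible(x)
}

#' Per-category accuracy for pure, unknown-breed and crossbred individuals
#'
#' Pure individuals are correct when `final_label` equals their true breed;
#' unknown-breed and crossbred individuals are correct when their
#' `final_label` is `"unknown"` (an "unknown" call is the desired outcome
#' for animals whose breed is absent from the reference). Categories with no
#' individuals are reported as `NA` rather than zero.
#'
#' @param results `prediction_result` (after thresholding).
#' @param truth named vector: sample id -> true breed, or
#'   `"unknown-expected"` for individuals outside the reference breeds.
#' @param categories named vector: sample id -> `"pure"`, `"unknown_breed"`
#'   or `"crossbred"`.
#' @return named numeric vector with elements `pure`, `unknown_breed`,
#'   `crossbred`.
#' @export
category_accuracy <- function(results, truth, categories) {
  ids <- results$sample_id
  if (!all(ids %in% names(truth)) || !all(ids %in% names(categories))) {
    stop_breedid("category_accuracy: every predicted sample needs a truth ",
                 "and category entry")
  }
  truth <- truth[ids]
  categories <- categories[ids]
  out <- c(pure = NA_real_, unknown_breed = NA_real_, crossbred = NA_real_)
  pure <- categories == "pure"
  if (any(pure)) out["pure"] <- mean(results$final_label[pure] == truth[pure])
  for (cat_ in c("unknown_breed", "crossbred")) {
    sel <- categories == cat_
    if (any(sel)) out[cat_] <- mean(results$final_label[sel] == "unknown")
  }
  out
}

#' Sweep the unknown-rejection threshold
#'
#' Re-applies [apply_unknown_threshold()] at every threshold of the grid and
#' records per-category accuracies, tracing the trade-off between pure-breed
#' accuracy (non-increasing in the threshold) and unknown/crossbred
#' detection (non-decreasing). The default grid is 0.010 to 0.030 in steps
#' of 0.001 (21 values).
#'
#' @param results `prediction_result` with probabilities.
#' @param truth,categories as in [category_accuracy()].
#' @param thresholds strictly increasing numeric grid.
#' @return a `data.frame` (class `threshold_sweep`) with columns
#'   `threshold`, `pure`, `unknown_breed`, `crossbred`.
#' @export
threshold_sweep <- function(results, truth, categories,
                            thresholds = seq(0.01, 0.03, by = 0.001)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_breedid("threshold_sweep: thresholds must be strictly increasing")
  }
  rows <- lapply(thresholds, function(th) {
    acc <- category_accuracy(apply_unknown_threshold(results, th),
                             truth, categories)
    data.frame(threshold = th, pure = acc["pure"],
               unknown_breed = acc["unknown_breed"],
               crossbred = acc["crossbred"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", "data.frame")
  out
}
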