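#' Specify a breed classifier
#'
#' Supported classifiers and their default parameters:
#' \describe{
#'   \item{KNN}{k-nearest neighbours on Euclidean genotype distance;
#'     `k = 5`. Ties among equally frequent neighbour labels go to the label
#'     of the nearest neighbour among the tied classes.}
#'   \item{NSC}{nearest shrunken centroids; shrinkage `threshold = 30`.}
#'   \item{PLSDA}{partial least squares discriminant analysis with softmax
#'     class probabilities; `ncomp = 150` (capped at
#'     `min(ncomp, n - 1, panel size)`).}
#'   \item{RF}{random forest; `ntree = 500`, `mtry = floor(sqrt(p))`.}
#'   \item{SVMp}{support vector machine, polynomial kernel; `degree = 3`,
#'     `gamma = 1/p`, `cost = 1`, features standardised.}
#'   \item{SVMr}{support vector machine, Gaussian radial kernel;
#'     `gamma = 1/p`, `cost = 1`, features standardised.}
#' }
#' Only PLS-DA produces class probabilities (softmax over its raw per-class
#' predictions); the other classifiers return hard labels and cannot drive
#' unknown-breed rejection.
#'
#' @param name one of `"KNN"`, `"NSC"`, `"PLSDA"`, `"RF"`, `"SVMp"`,
#'   `"SVMr"`.
#' @param ... parameter overrides (`k`, `threshold`, `ncomp`, `ntree`,
#'   `mtry`, `degree`, `gamma`, `cost` as applicable).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, ...) {
  name <- as.character(name)
  defaults <- switch(name,
    KNN   = list(k = 5L),
    NSC   = list(threshold = 30),
    PLSDA = list(ncomp = 150L),
    RF    = list(ntree = 500L, mtry = NULL),
    SVMp  = list(degree = 3L, gamma = NULL, cost = 1),
    SVMr  = list(gamma = NULL, cost = 1),
    stop_breedid("classifier_spec: unsupported classifier '", name,
                 "'; choose one of KNN, NSC, PLSDA, RF, SVMp, SVMr")
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop_breedid("classifier_spec: unknown parameter(s) for ", name, ": ",
                 paste(unknown, collapse = ", "))
  }
  defaults[names(override)] <- override
  structure(list(name = name, parameters = defaults), class = "classifier_spec")
}

#' Train a breed classifier on a genotype panel
#'
#' Fits the classifier named in `spec` on the supplied genotypes (typically
#' already restricted to a marker panel). Missing genotypes are mean-imputed
#' from the training data; the imputation means are stored so test data can
#' be completed identically.
#'
#' @param spec a [classifier_spec()].
#' @param data training `geno_matrix`.
#' @param labels breed labeling (>= 2 breeds).
#' @param seed integer seed (used by the random forest; the other
#'   classifiers are deterministic).
#' @return an object of class `breedid_model`.
#' @export
fit_classifier <- function(spec, data, labels, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- breed_labeling(labels, data)
  breeds <- sort(unique(labels))
  if (length(breeds) < 2) stop_breedid("fit_classifier: at least two breeds required")
  if (any(table(labels) < 2)) {
    warning("fit_classifier: breed(s) with a single training individual")
  }
  data <- impute_missing(data)
  x <- data$geno
  x_means <- colMeans(x)
  p <- ncol(x)
  prm <- spec$parameters
  fit <- switch(spec$name,
    KNN = list(x = x, y = labels, k = as.integer(prm$k)),
    NSC = fit_nsc(x, labels, prm$threshold),
    PLSDA = plsr_fit(x, one_hot(labels), prm$ncomp),
    RF = with_seed(seed, randomForest::randomForest(
      x = x, y = factor(labels, levels = breeds),
      ntree = prm$ntree, mtry = prm$mtry %||% max(1L, floor(sqrt(p))))),
    SVMp = fit_svm(x, labels, breeds, kernel = "polynomial",
                   degree = prm$degree, gamma = prm$gamma %||% 1 / p,
                   cost = prm$cost),
    SVMr = fit_svm(x, labels, breeds, kernel = "radial",
                   gamma = prm$gamma %||% 1 / p, cost = prm$cost)
  )
  structure(list(spec = spec, breed_ids = breeds,
                 panel = data$variants$snp_id, x_means = x_means, fit = fit),
            class = "breedid_model")
}

#' @export
print.breedid_model <- function(x, ...) {
  cat("<breedid_model> ", x$spec$name, " over ", length(x$breed_ids),
      " breeds, ", length(x$panel), " SNPs\n", sep = "")
  invisible(x)
}

# Nearest shrunken centroids (Tibshirani et al. 2002): breed centroids are
# standardised by the pooled within-breed SD (plus the usual positive offset
# s0 = median(s)), shrunk componentwise toward the overall centroid by soft
# thresholding, and test individuals are assigned to the nearest shrunken
# centroid under the standardised discriminant with class-prior correction.
fit_nsc <- function(x, labels, threshold) {
  breeds <- sort(unique(labels))
  grp <- factor(labels, levels = breeds)
  n <- nrow(x)
  k <- length(breeds)
  n_k <- as.vector(table(grp))
  centroids <- rowsum(x, grp) / n_k
  overall <- colMeans(x)
  within_ss <- colSums((x - centroids[as.integer(grp), , drop = FALSE])^2)
  s <- sqrt(within_ss / (n - k))
  # positive offset guarding against zero within-breed variance
  s0 <- stats::median(s)
  if (s0 <= 0) s0 <- max(mean(s), 1e-6)
  m_k <- sqrt(pmax(0, 1 / n_k - 1 / n))
  denom <- outer(m_k, s + s0)
  d <- (centroids - matrix(overall, k, ncol(x), byrow = TRUE)) / denom
  d_shrunk <- sign(d) * pmax(abs(d) - threshold, 0)
  shrunk <- matrix(overall, k, ncol(x), byrow = TRUE) + denom * d_shrunk
  if (all(abs(d_shrunk) < 1e-12)) {
    warning("fit_nsc: shrinkage collapsed all centroids to the overall ",
            "centroid; predictions are degenerate")
  }
  list(centroids = shrunk, s = s + s0, prior = n_k / n, breeds = breeds)
}

predict_nsc <- function(fit, x) {
  disc <- sapply(seq_along(fit$breeds), function(k) {
    rowSums(sweep(x, 2L, fit$centroids[k, ])^2 / rep(fit$s^2, each = nrow(x))) -
      2 * log(fit$prior[k])
  })
  disc <- matrix(disc, nrow = nrow(x))
  fit$breeds[apply(disc, 1L, which.min)]
}

# SVMs: features standardised with training mean/SD (zero-variance features
# left centred), multi-class handled one-vs-one by e1071.
fit_svm <- function(x, labels, breeds, kernel, cost, gamma, degree = 3L) {
  centre <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  scl <- ifelse(sdev > 0, sdev, 1)
  xs <- sweep(sweep(x, 2L, centre), 2L, scl, "/")
  args <- list(x = xs, y = factor(labels, levels = breeds), kernel = kernel,
               gamma = gamma, cost = cost, scale = FALSE)
  if (kernel == "polynomial") args$degree <- degree
  list(model = do.call(e1071::svm, args), centre = centre, scale = scl)
}

knn_predict <- function(fit, x) {
  train <- fit$x
  k <- min(fit$k, nrow(train))
  d2 <- outer(rowSums(x^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(x)), rowSums(train^2)) - 2 * tcrossprod(x, train)
  apply_one <- function(row_d) {
    ord <- order(row_d)
    nn <- ord[seq_len(k)]
    votes <- table(fit$y[nn])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) return(winners)
    # tie: label of the nearest neighbour among the tied classes
    for (i in nn) if (fit$y[i] %in% winners) return(fit$y[[i]])
  }
  vapply(seq_len(nrow(x)), function(i) apply_one(d2[i, ]), character(1))
}

# raw per-breed PLSR predictions for the one-hot response
plsda_raw_scores <- function(model, x) {
  stats::predict(model$fit, x)
}

check_panel_match <- function(model, data) {
  if (!identical(colnames(data$geno), model$panel)) {
    if (all(model$panel %in% colnames(data$geno))) {
      return(subset_geno(data, snps = match(model$panel, colnames(data$geno))))
    }
    stop_breedid("predict: test SNPs do not match the model's panel; ",
                 "harmonize the upload to the reference and subset to the panel")
  }
  data
}

#' Predict breed labels for test individuals
#'
#' Produces one prediction per test individual. For PLS-DA the per-breed
#' softmax probabilities are attached (attribute `"probabilities"`) and
#' `max_probability` is filled; the other classifiers return hard labels
#' only. `final_label` equals `predicted_breed` until
#' [apply_unknown_threshold()] is applied.
#'
#' @param object a fitted `breedid_model`.
#' @param data test `geno_matrix` whose SNPs match the model's panel (a
#'   superset is subset automatically).
#' @param ... unused.
#' @return a `data.frame` (class `prediction_result`) with columns
#'   `sample_id`, `predicted_breed`, `max_probability`, `final_label`.
#' @export
predict.breedid_model <- function(object, data, ...) {
  data <- check_panel_match(object, data)
  data <- impute_missing(data, means = object$x_means)
  x <- data$geno
  prob <- NULL
  pred <- switch(object$spec$name,
    KNN = knn_predict(object$fit, x),
    NSC = predict_nsc(object$fit, x),
    PLSDA = {
      prob <- softmax_rows(plsda_raw_scores(object, x))
      colnames(prob) <- object$breed_ids
      object$breed_ids[max.col(prob, ties.method = "first")]
    },
    RF = as.character(stats::predict(object$fit, x)),
    SVMp = ,
    SVMr = {
      xs <- sweep(sweep(x, 2L, object$fit$centre), 2L, object$fit$scale, "/")
      as.character(stats::predict(object$fit$model, xs))
    }
  )
  res <- data.frame(sample_id = data$sample_ids, predicted_breed = pred,
                    max_probability = if (is.null(prob)) NA_real_ else
                      unname(apply(prob, 1L, max)),
                    final_label = pred, stringsAsFactors = FALSE)
  class(res) <- c("prediction_result", "data.frame")
  if (!is.null(prob)) {
    rownames(prob) <- data$sample_ids
    attr(res, "probabilities") <- prob
  }
  res
}

#' PLS-DA softmax breed probabilities
#'
#' Maps the raw PLSR predictions of the one-hot breed responses through the
#' softmax function, `p_b = exp(s_b) / sum_c exp(s_c)`, giving a full
#' probability distribution over the training breeds for every test
#' individual.
#'
#' @param model a fitted `breedid_model` with spec name `"PLSDA"`.
#' @param data test `geno_matrix`.
#' @return a `prediction_result` with the breeds-by-individual probability
#'   matrix in attribute `"probabilities"`.
#' @export
plsda_probabilities <- function(model, data) {
  stopifnot(inherits(model, "breedid_model"))
  if (model$spec$name != "PLSDA") {
    stop_breedid("plsda_probabilities: model is ", model$spec$name,
                 ", not PLSDA")
  }
  predict(model, data)
}

#' Reject low-confidence assignments as "unknown"
#'
#' Sets `final_label` to `"unknown"` for every individual whose highest
#' breed probability falls strictly below `threshold`. A threshold of `NA`
#' disables rejection entirely. Raising the threshold can only convert
#' assignments to "unknown", never the reverse.
#'
#' @param results a `prediction_result` with probabilities present.
#' @param threshold value in `[0, 1]`, or `NA` to disable rejection.
#' @return the updated `prediction_result`.
#' @export
apply_unknown_threshold <- function(results, threshold) {
  if (length(threshold) != 1) stop_breedid("apply_unknown_threshold: single threshold expected")
  if (is.na(threshold)) {
    results$final_label <- results$predicted_breed
    return(results)
  }
  if (threshold < 0 || threshold > 1) {
    stop_breedid("apply_unknown_threshold: threshold must be in [0, 1] or NA")
  }
  if (anyNA(results$max_probability)) {
    stop_breedid("apply_unknown_threshold: results carry no probabilities ",
                 "(only PLS-DA produces them)")
  }
  results$final_label <- ifelse(results$max_probability < threshold,
                                "unknown", results$predicted_breed)
  results
}
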