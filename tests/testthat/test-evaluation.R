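test_that("stratified folds split every breed evenly and partition the samples", {
  labels <- stats::setNames(rep(c("A", "B", "C"), each = 10),
                            paste0("s", 1:30))
  fold <- stratified_folds(labels, 5, seed = 3)
  expect_setequal(names(fold), names(labels))
  for (b in c("A", "B", "C")) {
    counts <- table(factor(fold[labels == b], levels = 1:5))
    expect_true(all(counts == 2))
  }
  # deterministic given seed, different across seeds
  expect_identical(fold, stratified_folds(labels, 5, seed = 3))
  expect_false(identical(fold, stratified_folds(labels, 5, seed = 4)))
  # tiny breed: warning, individuals still assigned one per fold
  labels2 <- c(labels, stats::setNames(rep("D", 3), paste0("t", 1:3)))
  expect_warning(fold2 <- stratified_folds(labels2, 5, seed = 1), "fewer")
  expect_equal(sum(labels2[names(fold2)] == "D"), 3)
  expect_true(all(table(fold2[labels2[names(fold2)] == "D"]) == 1))
  expect_error(stratified_folds(labels, 1), "n_folds")
})

test_that("repeated CV yields repeats x folds accuracies and aces separable data", {
  sep <- make_separable_pair(n_snps = 50, n_per_breed = 10)
  rep_cv <- repeated_cv(sep$data, sep$labels, selector = "AED", density = 20,
                        classifier = classifier_spec("PLSDA", ncomp = 5),
                        n_repeats = 5, n_folds = 5, seed = 10)
  expect_equal(nrow(rep_cv$fold_accuracies), 25)
  expect_equal(unname(rep_cv$mean_accuracy), 1)
  expect_true(all(rep_cv$per_breed_accuracy == 1))
  # reproducible under the same seed
  rep_cv2 <- repeated_cv(sep$data, sep$labels, selector = "AED", density = 20,
                         classifier = classifier_spec("PLSDA", ncomp = 5),
                         n_repeats = 5, n_folds = 5, seed = 10)
  expect_identical(rep_cv$fold_accuracies, rep_cv2$fold_accuracies)
})

test_that("label-permuted data scores at chance level", {
  toy <- make_toy_panel(n_breeds = 10, n_snps = 200, n_per_breed = 10,
                        divergence = 0.15, seed = 50)
  set.seed(60)
  perm <- stats::setNames(sample(toy$labels), names(toy$labels))
  rep_cv <- repeated_cv(toy$data, perm, selector = "AED", density = 100,
                        classifier = classifier_spec("KNN"),
                        n_repeats = 2, n_folds = 5, seed = 61)
  expect_lt(unname(rep_cv$mean_accuracy), 0.2)   # chance is 0.1
})

test_that("selector scoring inside CV cannot see the held-out fold", {
  # Breed-informative signal everywhere except one SNP whose informativeness
  # is planted only among one fold's individuals: that SNP must never be
  # selected by the folds that hold those individuals out.
  labels <- stats::setNames(rep(c("A", "B"), each = 20), paste0("s", 1:40))
  fold <- stratified_folds(labels, 2, seed = 5)
  n_snps <- 12
  set.seed(6)
  geno <- matrix(0L, 40, n_snps)
  geno[labels == "B", 1:10] <- 2L                   # globally informative
  # SNP 11/12: informative ONLY within fold 1 / fold 2 respectively
  for (f in 1:2) {
    snp <- 10 + f
    in_fold <- fold == f
    geno[in_fold & labels == "B", snp] <- 2L
    geno[!in_fold, snp] <- 1L                       # useless outside the fold
  }
  rownames(geno) <- names(labels)
  dat <- genotype_matrix(geno, variant_table("1", (1:n_snps) * 100L, "A", "G"))
  rep_cv <- repeated_cv(dat, labels, selector = "AED", density = 5,
                        classifier = classifier_spec("KNN"),
                        n_repeats = 1, n_folds = 2, seed = 5,
                        keep_panels = TRUE)
  snp_ids <- dat$variants$snp_id
  # fold f tests on fold==f individuals, trains on the rest: the SNP whose
  # signal lives only in fold f must be absent from fold f's panel
  expect_false(snp_ids[11] %in% rep_cv$panels[["1:1:5"]])
  expect_false(snp_ids[12] %in% rep_cv$panels[["1:2:5"]])
})

test_that("category accuracies follow the unknown-is-correct convention", {
  res <- data.frame(
    sample_id = c("p1", "p2", "u1", "c1"),
    predicted_breed = c("X", "Y", "X", "X"),
    max_probability = c(0.5, 0.5, 0.01, 0.01),
    final_label = c("X", "X", "unknown", "X"),
    stringsAsFactors = FALSE)
  class(res) <- c("prediction_result", "data.frame")
  truth <- c(p1 = "X", p2 = "Y", u1 = "unknown-expected", c1 = "unknown-expected")
  cats <- c(p1 = "pure", p2 = "pure", u1 = "unknown_breed", c1 = "crossbred")
  acc <- category_accuracy(res, truth, cats)
  expect_equal(unname(acc["pure"]), 0.5)
  expect_equal(unname(acc["unknown_breed"]), 1)
  # crossbred assigned a parental label counts as incorrect
  expect_equal(unname(acc["crossbred"]), 0)
  # empty category reported as NA, not zero
  acc2 <- category_accuracy(res[1:3, ], truth, cats)
  expect_true(is.na(acc2["crossbred"]))
  expect_error(category_accuracy(res, truth[1:2], cats), "truth")
})

test_that("threshold sweep uses the 21-value default grid and is monotone", {
  set.seed(30)
  n <- 60
  res <- data.frame(
    sample_id = paste0("s", 1:n),
    predicted_breed = rep("X", n),
    max_probability = runif(n, 0.005, 0.035),
    final_label = rep("X", n),
    stringsAsFactors = FALSE)
  class(res) <- c("prediction_result", "data.frame")
  truth <- stats::setNames(
    c(rep("X", 30), rep("unknown-expected", 30)), res$sample_id)
  cats <- stats::setNames(
    c(rep("pure", 30), rep("unknown_breed", 15), rep("crossbred", 15)),
    res$sample_id)
  sw <- threshold_sweep(res, truth, cats)
  expect_equal(nrow(sw), 21)
  expect_equal(sw$threshold, seq(0.010, 0.030, by = 0.001))
  expect_true(all(diff(sw$pure) <= 1e-12))
  expect_true(all(diff(sw$unknown_breed) >= -1e-12))
  expect_true(all(diff(sw$crossbred) >= -1e-12))
  # threshold 0 rejects nothing
  sw0 <- threshold_sweep(res, truth, cats, thresholds = c(0, 0.5))
  expect_equal(sw0$unknown_breed[1], 0)
  expect_error(threshold_sweep(res, truth, cats, thresholds = c(0.3, 0.1)),
               "increasing")
})

test_that("accuracy does not degrade with panel density on simulated breeds", {
  toy <- make_toy_panel(n_breeds = 6, n_snps = 800, n_per_breed = 12,
                        divergence = 0.05, seed = 70)
  rep_cv <- repeated_cv(toy$data, toy$labels, selector = "AED",
                        density = c(50, 400),
                        classifier = classifier_spec("PLSDA", ncomp = 30),
                        n_repeats = 2, n_folds = 5, seed = 71)
  expect_lte(rep_cv$mean_accuracy[["50"]], rep_cv$mean_accuracy[["400"]] + 0.02)
})
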