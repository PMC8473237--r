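test_that("metrics follow their defining arithmetic", {
  m <- compute_metrics(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$balanced_accuracy, 0.85)
  p <- compute_metrics(10, 0, 10, 0)
  expect_equal(c(p$sensitivity, p$specificity, p$balanced_accuracy),
               c(1, 1, 1))
  expect_warning(compute_metrics(0, 0, 5, 1), "sensitivity undefined")
  expect_error(compute_metrics(0, 0, 0, 0), "all-zero")
  # balanced accuracy is the exact mean of the published sens/spec pair
  expect_equal((0.9272 + 0.9494) / 2, 0.9383, tolerance = 5e-5)
})

test_that("rank-based AUC handles order, ties and randomness", {
  expect_equal(roc_auc(1:10, rep(c("HC", "MCI"), each = 5)), 1)
  expect_equal(roc_auc(rep(0, 10), rep(c("HC", "MCI"), each = 5)), 0.5)
  set.seed(11)
  sc <- rnorm(1000)
  lb <- sample(rep(c("HC", "MCI"), 500))
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep("MCI", 5)), "both classes")
})

test_that("rank AUC agrees with pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- rnorm(200)
  lb <- ifelse(sc + rnorm(200) > 0, "MCI", "HC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lb, c("HC", "MCI")), predictor = sc, quiet = TRUE,
    direction = "<")))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-12)
})

test_that("MCR splits are stratified, seeded and sized as configured", {
  set.seed(20)
  n <- 120
  x <- rbind(matrix(rnorm(n * 4), ncol = 4),
             matrix(rnorm(n * 4, mean = 3), ncol = 4))
  fd <- make_features(x, rep(c("HC", "MCI"), each = n),
                      rep(sprintf("s%02d", 1:24), each = 10))
  r1 <- mcr_evaluate(fd, scheme = split_scheme("MCR", n_repeats = 5,
                                               seed = 99))
  r2 <- mcr_evaluate(fd, scheme = split_scheme("MCR", n_repeats = 5,
                                               seed = 99))
  expect_identical(r1$accuracy, r2$accuracy)
  # well-separated classes -> perfect accuracy
  expect_equal(r1$mean_accuracy, 1)
  expect_equal(r1$balanced_accuracy, 1)
  # test fraction 0.05 of 120 per class -> 6 per class, 12 total per repeat
  expect_equal(unname(sum(r1$confusion)), 5L * 12L)
})

test_that("balanced accuracy identity holds on every evaluation", {
  coh <- tiny_coh()
  part <- partition_rois(connectivity_stats(coh), pair_deltas(coh))
  fd <- build_feature_dataset(tiny_cohort(), part, "hyper")
  for (clf in list(classifier_spec("knn"), classifier_spec("lda"),
                   classifier_spec("svm"))) {
    ev <- mcr_evaluate(fd, clf, split_scheme("MCR", n_repeats = 3, seed = 1))
    expect_equal(ev$balanced_accuracy,
                 (ev$mean_sensitivity + ev$mean_specificity) / 2,
                 tolerance = 1e-12)
    expect_true(all(c(ev$mean_sensitivity, ev$mean_specificity,
                      ev$auc) >= 0))
    expect_true(all(c(ev$mean_sensitivity, ev$mean_specificity,
                      ev$auc) <= 1))
  }
})

test_that("shuffled labels give chance-level MCR accuracy", {
  set.seed(30)
  x <- matrix(rnorm(240 * 5), ncol = 5)
  lb <- sample(rep(c("HC", "MCI"), each = 120))
  fd <- make_features(x, lb, rep(sprintf("s%02d", 1:24), each = 10))
  ev <- mcr_evaluate(fd, scheme = split_scheme("MCR", n_repeats = 20,
                                               seed = 7))
  n_pred <- sum(ev$confusion)
  ci <- 1.96 * sqrt(0.25 / n_pred)
  expect_lt(abs(ev$mean_accuracy - 0.5), ci + 0.05)
})

test_that("subject-wise LOO never leaks held-out subjects and pairs folds", {
  # features encode subject identity; class signal present
  set.seed(31)
  subj <- rep(sprintf("%s%02d", rep(c("h", "m"), each = 6), 1:6), each = 5)
  cls <- rep(c("HC", "MCI"), each = 30)
  x <- matrix(rnorm(60 * 3), ncol = 3) + ifelse(cls == "MCI", 5, 0)
  fd <- make_features(x, cls, subj)
  ev <- loo_evaluate(fd, classifier_spec("svm"))
  expect_equal(length(ev$accuracy), 6L)  # one fold per subject pair
  expect_equal(ev$mean_accuracy, 1)
  expect_equal(ev$subject_accuracy, 1)
  # identical-within-class features with 2 subjects/class -> perfect
  x2 <- rbind(matrix(1, 10, 2), matrix(5, 10, 2)) +
    matrix(rnorm(40, sd = 1e-6), ncol = 2)
  fd2 <- make_features(x2, rep(c("HC", "MCI"), each = 10),
                       rep(c("a", "b", "c", "d"), each = 5))
  expect_equal(loo_evaluate(fd2, classifier_spec("knn"))$mean_accuracy, 1)
  # unbalanced subject counts are rejected
  fd3 <- make_features(x2[1:15, ], c(rep("HC", 10), rep("MCI", 5)),
                       rep(c("a", "b", "c"), each = 5))
  expect_error(loo_evaluate(fd3), "equal subject counts")
})

test_that("subject random effects open an MCR-over-LOO optimism gap", {
  # class-uninformative features dominated by subject fingerprints:
  # MCR (same subject on both sides) looks far better than honest LOO
  set.seed(32)
  n_subj <- 8; n_ep <- 8
  subj <- rep(sprintf("%s%02d", rep(c("h", "m"), each = n_subj),
                      1:n_subj), each = n_ep)
  cls <- rep(c("HC", "MCI"), each = n_subj * n_ep)
  subj_eff <- matrix(rnorm(2 * n_subj * 4, sd = 2), ncol = 4)
  x <- subj_eff[rep(seq_len(2 * n_subj), each = n_ep), ] +
    0.3 * matrix(rnorm(2 * n_subj * n_ep * 4), ncol = 4) +
    ifelse(cls == "MCI", 0.4, 0)
  fd <- make_features(x, cls, subj)
  mcr <- mcr_evaluate(fd, classifier_spec("knn"),
                      split_scheme("MCR", n_repeats = 10,
                                   test_fraction = 0.1, seed = 3))
  loo <- loo_evaluate(fd, classifier_spec("knn"))
  expect_gt(mcr$mean_accuracy, loo$mean_accuracy)
})

test_that("classifier specification validates its contract", {
  expect_error(classifier_spec("knn", k = 4), "odd")
  expect_s3_class(classifier_spec("svm", kernel = "poly2"),
                  "megcoh_classifier")
  expect_error(split_scheme("MCR", test_fraction = 0), "test_fraction")
})
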