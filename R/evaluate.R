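# Dual cross-validation evaluation: Monte-Carlo repeated random splits
# (observation-level, stratified per class) versus subject-wise
# leave-one-out, over k-NN, LDA and SVM. The contrast between the two
# protocols quantifies the optimism introduced when epochs of one subject
# appear in both training and test sets.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(code)
}

#' Classifier specification
#'
#' @param family "knn", "lda" or "svm".
#' @param k Neighbour count for k-NN (odd; default 3).
#' @param kernel SVM kernel: "rbf" (Euclidean radial basis, the
#'   leave-one-out default), "poly2" (2nd-order polynomial) or "linear".
#' @param cost SVM regularisation constant (default 1).
#' @param standardize Z-score features using training-set statistics
#'   before distance-based classifiers (default TRUE).
#' @return List of class `megcoh_classifier`.
#' @export
classifier_spec <- function(family = c("knn", "lda", "svm"), k = 3L,
                            kernel = c("rbf", "poly2", "linear"),
                            cost = 1, standardize = TRUE) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  if (family == "knn" && k %% 2L == 0L) {
    stop("k must be odd for binary k-NN (no prediction ties)")
  }
  structure(list(family = family, k = as.integer(k), kernel = kernel,
                 cost = cost, standardize = standardize),
            class = "megcoh_classifier")
}

# Fit on (x_train, y_train), return predicted labels and MCI scores for
# x_test. y levels are fixed to c("HC", "MCI") with MCI the positive
# class.
fit_predict <- function(clf, x_train, y_train, x_test) {
  y_train <- factor(y_train, levels = c("HC", "MCI"))
  if (clf$standardize) {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    x_train <- sweep(sweep(x_train, 2L, mu, "-"), 2L, sdv, "/")
    x_test <- sweep(sweep(x_test, 2L, mu, "-"), 2L, sdv, "/")
  }
  if (clf$family == "knn") {
    pr <- class::knn(x_train, x_test, y_train, k = clf$k, prob = TRUE)
    p_win <- attr(pr, "prob")
    score <- ifelse(pr == "MCI", p_win, 1 - p_win)
    list(pred = as.character(pr), score = score)
  } else if (clf$family == "lda") {
    fit <- MASS::lda(x_train, grouping = y_train)
    pr <- stats::predict(fit, x_test)
    list(pred = as.character(pr$class), score = pr$posterior[, "MCI"])
  } else {
    args <- list(x = x_train, y = y_train, cost = clf$cost, scale = FALSE)
    args <- c(args, switch(clf$kernel,
                           rbf = list(kernel = "radial"),
                           poly2 = list(kernel = "polynomial", degree = 2L),
                           linear = list(kernel = "linear")))
    fit <- do.call(e1071::svm, args)
    pr <- stats::predict(fit, x_test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- if (grepl("^MCI", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
    list(pred = as.character(pr), score = score)
  }
}

#' Classification metrics from a 2x2 confusion
#'
#' Sensitivity = TP / (TP + FN) with MCI positive, specificity =
#' TN / (TN + FP), balanced accuracy = their arithmetic mean. A zero
#' denominator yields NA with a warning rather than an error.
#'
#' @param tp,fn,tn,fp Nonnegative counts.
#' @return List: sensitivity, specificity, balanced_accuracy, accuracy.
#' @export
compute_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  total <- tp + fn + tn + fp
  if (total == 0) stop("all-zero confusion matrix")
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive-class observations: sensitivity undefined")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative-class observations: specificity undefined")
    NA_real_
  }
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)),
       accuracy = (tp + tn) / total)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney U normalisation with midrank tie handling: the
#' probability that a random MCI score exceeds a random HC score (ties
#' count one half).
#'
#' @param scores Numeric classifier scores (larger = more MCI-like).
#' @param labels Class labels containing both "HC" and "MCI".
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "MCI"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluation split scheme
#'
#' @param kind "MCR" (Monte-Carlo repeated observation-level splits) or
#'   "LOO" (subject-wise leave-one-out).
#' @param n_repeats MCR repeat count (default 20).
#' @param test_fraction MCR held-out fraction per class (default 0.05).
#' @param seed Seed for the MCR split draws.
#' @return List of class `megcoh_scheme`.
#' @export
split_scheme <- function(kind = c("MCR", "LOO"), n_repeats = 20L,
                         test_fraction = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(test_fraction > 0, test_fraction < 1, n_repeats >= 1L)
  structure(list(kind = kind, n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "megcoh_scheme")
}

eval_result <- function(accuracy, sens, spec, auc, confusion, config) {
  ms <- mean(sens, na.rm = TRUE)
  mp <- mean(spec, na.rm = TRUE)
  structure(list(accuracy = accuracy,
                 mean_accuracy = mean(accuracy),
                 mean_sensitivity = ms, mean_specificity = mp,
                 balanced_accuracy = (ms + mp) / 2,
                 auc = mean(auc, na.rm = TRUE),
                 confusion = confusion, config = config),
            class = "megcoh_eval")
}

#' @export
print.megcoh_eval <- function(x, ...) {
  cat(sprintf(paste0("%s evaluation (%s): mean accuracy %.4f, ",
                     "sens %.4f, spec %.4f, balanced %.4f, AUC %.4f\n"),
              x$config$scheme, x$config$classifier, x$mean_accuracy,
              x$mean_sensitivity, x$mean_specificity, x$balanced_accuracy,
              x$auc))
  invisible(x)
}

#' Monte-Carlo repeated-split evaluation
#'
#' Per repeat, a stratified observation-level split holds out
#' `test_fraction` of each class (342 train / 18 test per class at the
#' reference scale), the classifier is fit on the training rows and
#' scored on the held-out rows; metrics are averaged over repeats.
#' Epochs of one subject may appear on both sides of the split -- that is
#' the point of contrast with [loo_evaluate()].
#'
#' @param features A `megcoh_features` dataset.
#' @param clf [classifier_spec()] (default 3-NN, the MCR protocol
#'   default).
#' @param scheme [split_scheme()] of kind "MCR".
#' @return A `megcoh_eval` result.
#' @export
mcr_evaluate <- function(features, clf = classifier_spec("knn", k = 3L),
                         scheme = split_scheme("MCR")) {
  if (scheme$kind != "MCR") stop("scheme$kind must be 'MCR'")
  y <- features$class_label
  classes <- c("HC", "MCI")
  if (any(table(factor(y, classes)) < 2L)) {
    stop("need at least 2 observations per class")
  }
  with_local_seed(scheme$seed, {
    acc <- sens <- spec <- auc <- numeric(scheme$n_repeats)
    conf <- c(tp = 0, fn = 0, tn = 0, fp = 0)
    for (r in seq_len(scheme$n_repeats)) {
      test_idx <- unlist(lapply(classes, function(cl) {
        idx <- which(y == cl)
        n_test <- max(1L, round(length(idx) * scheme$test_fraction))
        sample(idx, n_test)
      }))
      res <- fit_predict(clf, features$x[-test_idx, , drop = FALSE],
                         y[-test_idx],
                         features$x[test_idx, , drop = FALSE])
      truth <- y[test_idx]
      tp <- sum(res$pred == "MCI" & truth == "MCI")
      fn <- sum(res$pred == "HC" & truth == "MCI")
      tn <- sum(res$pred == "HC" & truth == "HC")
      fp <- sum(res$pred == "MCI" & truth == "HC")
      m <- compute_metrics(tp, fn, tn, fp)
      acc[r] <- m$accuracy; sens[r] <- m$sensitivity
      spec[r] <- m$specificity
      auc[r] <- roc_auc(res$score, truth)
      conf <- conf + c(tp = tp, fn = fn, tn = tn, fp = fp)
    }
    eval_result(acc, sens, spec, auc, conf,
                list(scheme = "MCR", classifier = clf$family,
                     n_repeats = scheme$n_repeats,
                     test_fraction = scheme$test_fraction,
                     seed = scheme$seed, clf = unclass(clf)))
  })
}

#' Subject-wise leave-one-out evaluation
#'
#' Fold f holds out subject f of EACH class (all of their epochs); no
#' observation of a held-out subject appears in training, eliminating
#' subject leakage. Requires equal subject counts per class (20 folds at
#' the reference scale). Epoch-level accuracy is averaged over folds; a
#' subject-level majority-vote accuracy is also reported.
#'
#' @param features A `megcoh_features` dataset.
#' @param clf [classifier_spec()] (default SVM with RBF kernel, the LOO
#'   protocol default).
#' @return A `megcoh_eval` result with an extra `subject_accuracy` field.
#' @export
loo_evaluate <- function(features,
                         clf = classifier_spec("svm", kernel = "rbf")) {
  y <- features$class_label
  subj <- features$subject_id
  hc_subj <- unique(subj[y == "HC"])
  mci_subj <- unique(subj[y == "MCI"])
  if (length(intersect(hc_subj, mci_subj)) > 0L) {
    stop("a subject appears in both classes")
  }
  if (length(hc_subj) != length(mci_subj)) {
    stop("subject-paired LOO requires equal subject counts per class")
  }
  if (length(hc_subj) < 2L) stop("need at least 2 subjects per class")
  nf <- length(hc_subj)
  acc <- sens <- spec <- auc <- numeric(nf)
  conf <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  vote_correct <- logical(0)
  for (f in seq_len(nf)) {
    held <- c(hc_subj[f], mci_subj[f])
    test_idx <- which(subj %in% held)
    stopifnot(length(intersect(subj[-test_idx], held)) == 0L)
    res <- fit_predict(clf, features$x[-test_idx, , drop = FALSE],
                       y[-test_idx],
                       features$x[test_idx, , drop = FALSE])
    truth <- y[test_idx]
    tp <- sum(res$pred == "MCI" & truth == "MCI")
    fn <- sum(res$pred == "HC" & truth == "MCI")
    tn <- sum(res$pred == "HC" & truth == "HC")
    fp <- sum(res$pred == "MCI" & truth == "HC")
    m <- compute_metrics(tp, fn, tn, fp)
    acc[f] <- m$accuracy; sens[f] <- m$sensitivity
    spec[f] <- m$specificity
    auc[f] <- roc_auc(res$score, truth)
    conf <- conf + c(tp = tp, fn = fn, tn = tn, fp = fp)
    for (s in held) {
      sel <- subj[test_idx] == s
      maj <- names(sort(table(res$pred[sel]), decreasing = TRUE))[1L]
      vote_correct <- c(vote_correct, maj == unique(truth[sel]))
    }
  }
  out <- eval_result(acc, sens, spec, auc, conf,
                     list(scheme = "LOO", classifier = clf$family,
                          n_folds = nf, clf = unclass(clf)))
  out$subject_accuracy <- mean(vote_correct)
  out
}
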