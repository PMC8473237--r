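# End-to-end orchestration: generate -> connectivity -> partition ->
# features -> classification -> per-dimension screening, with every
# artifact written to an output directory and a manifest echoing the
# configuration. One master seed spawns per-stage child seeds so each
# stage is individually reproducible.

#' Pipeline configuration
#'
#' Bundles every module's parameter block under a single seed.
#'
#' @param synth [synth_params()] for the synthetic cohort (its `seed` is
#'   overridden by the derived generation child seed).
#' @param conn_epoch_len Connectivity epoch length in seconds (default 1).
#' @param band Broadband coherence range (Hz).
#' @param est [est_params()] spectral estimation settings.
#' @param feature_epoch_len Feature epoch length in seconds (default 10).
#' @param preproc [preprocess_params()] for the feature pipeline.
#' @param aggregation ROI-group feature aggregation ("mean" or "concat").
#' @param groups ROI groups to evaluate.
#' @param clf_mcr,clf_loo [classifier_spec()] per protocol (defaults:
#'   3-NN for MCR, RBF-kernel SVM for LOO).
#' @param n_repeats MCR repeat count.
#' @param test_fraction MCR held-out fraction per class.
#' @param alpha Screening significance level.
#' @param balance Enforce the 5-vs-5 ROI partition.
#' @param seed Master seed.
#' @return List of class `megcoh_config`.
#' @export
pipeline_config <- function(synth = synth_params(),
                            conn_epoch_len = 1, band = c(0.5, 80),
                            est = est_params(),
                            feature_epoch_len = 10,
                            preproc = preprocess_params(),
                            aggregation = c("mean", "concat"),
                            groups = c("hyper", "hypo", "all"),
                            clf_mcr = classifier_spec("knn", k = 3L),
                            clf_loo = classifier_spec("svm", kernel = "rbf"),
                            n_repeats = 20L, test_fraction = 0.05,
                            alpha = 0.05, balance = TRUE, seed = 1L) {
  aggregation <- match.arg(aggregation)
  groups <- match.arg(groups, several.ok = TRUE)
  structure(list(synth = synth, conn_epoch_len = conn_epoch_len,
                 band = band, est = est,
                 feature_epoch_len = feature_epoch_len, preproc = preproc,
                 aggregation = aggregation, groups = groups,
                 clf_mcr = clf_mcr, clf_loo = clf_loo,
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, alpha = alpha,
                 balance = balance, seed = as.integer(seed)),
            class = "megcoh_config")
}

#' Run the full pipeline
#'
#' Executes all stages in order -- cohort generation, epoch-wise pairwise
#' coherence, degree statistics and ROI partition, wavelet feature
#' extraction per ROI group, MCR and LOO evaluation, and the
#' per-dimension statistical screen -- optionally writing each artifact
#' under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; NULL skips writing files.
#' @param verbose Log stage boundaries with row/epoch counts.
#' @return List of class `megcoh_bundle`: `cohort`, `coh`, `stats_table`,
#'   `deltas`, `partition`, `hemi_tests`, `features` (per group),
#'   `evals` (per group x scheme), `screen`, `counts`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- vapply(1:4, function(k) child_seed(config$seed, 1000L + k), 1L)

  synth <- config$synth
  synth$seed <- seeds[1L]
  cohort <- generate_cohort(synth)
  n_subj <- length(cohort$subjects)
  say("generate: %d subjects, %d ROIs, %d samples each", n_subj,
      length(cohort$roi_labels), ncol(cohort$subjects[[1]]$data))

  coh <- cohort_coherence(cohort, config$conn_epoch_len, config$band,
                          config$est)
  epochs_per_class <- sum(coh$class_label == "HC")
  say("connect: %d unique ROI pairs, %d epochs per class, %d MS-COH evaluations",
      nrow(coh$pairs), epochs_per_class, coh$n_coherence_evals)
  stats_table <- connectivity_stats(coh)
  deltas <- pair_deltas(coh)
  partition <- partition_rois(stats_table, deltas, balance = config$balance)
  hemi <- list(HC = hemispheric_group_tests(coh, "HC", config$alpha),
               MCI = hemispheric_group_tests(coh, "MCI", config$alpha))
  say("partition: hyper = {%s}", paste(partition$hyper, collapse = ", "))

  features <- list(); evals <- list()
  for (g in config$groups) {
    fd <- build_feature_dataset(cohort, partition, group = g,
                                aggregation = config$aggregation,
                                epoch_len = config$feature_epoch_len,
                                params = config$preproc)
    features[[g]] <- fd
    say("features[%s]: %d observations x %d dims (%d per class)", g,
        nrow(fd$x), ncol(fd$x), sum(fd$class_label == "HC"))
    evals[[paste0(g, "_MCR")]] <- mcr_evaluate(
      fd, config$clf_mcr,
      split_scheme("MCR", n_repeats = config$n_repeats,
                   test_fraction = config$test_fraction, seed = seeds[2L]))
    evals[[paste0(g, "_LOO")]] <- loo_evaluate(fd, config$clf_loo)
    say("classify[%s]: MCR balanced %.4f, LOO balanced %.4f", g,
        evals[[paste0(g, "_MCR")]]$balanced_accuracy,
        evals[[paste0(g, "_LOO")]]$balanced_accuracy)
  }

  screen <- NULL
  if ("hyper" %in% names(features)) {
    fd <- features$hyper
    screen <- per_dimension_screen(fd$x[fd$class_label == "HC", , drop = FALSE],
                                   fd$x[fd$class_label == "MCI", , drop = FALSE],
                                   alpha = config$alpha,
                                   labels = colnames(fd$x))
    say("screen: %d of %d dimensions jointly significant",
        sum(screen$joint_significant), nrow(screen))
  }

  counts <- list(
    n_subjects = n_subj,
    n_roi_pairs = nrow(coh$pairs),
    n_inter_pairs = sum(coh$pairs$hemi == "inter"),
    n_intra_pairs = sum(coh$pairs$hemi == "intra"),
    epochs_per_class_per_roi = epochs_per_class,
    n_coherence_evals = coh$n_coherence_evals,
    n_feature_dims = ncol(features[[1L]]$x),
    feature_epochs_per_subject =
      sum(features[[1L]]$subject_id == features[[1L]]$subject_id[1L]),
    observations_per_class = sum(features[[1L]]$class_label == "HC")
  )

  bundle <- structure(list(cohort = cohort, coh = coh,
                           stats_table = stats_table, deltas = deltas,
                           partition = partition, hemi_tests = hemi,
                           features = features, evals = evals,
                           screen = screen, counts = counts,
                           config = config),
                      class = "megcoh_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Serialize the report bundle (plain-text artifacts + manifest).
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  write_cohort_h5(bundle$cohort, file.path(out_dir, "cohort.h5"))
  w(bundle$stats_table, "connectivity_stats.csv")
  w(bundle$deltas, "pair_deltas.csv")
  jsonlite::write_json(list(hyper = bundle$partition$hyper,
                            hypo = bundle$partition$hypo,
                            candidates = bundle$partition$candidates),
                       file.path(out_dir, "partition.json"))
  for (g in names(bundle$features)) {
    fd <- bundle$features[[g]]
    w(cbind(data.frame(subject_id = fd$subject_id,
                       class = fd$class_label, epoch = fd$epoch),
            as.data.frame(fd$x)),
      sprintf("features_%s.csv", g))
  }
  for (nm in names(bundle$evals)) {
    ev <- bundle$evals[[nm]]
    jsonlite::write_json(list(mean_accuracy = ev$mean_accuracy,
                              mean_sensitivity = ev$mean_sensitivity,
                              mean_specificity = ev$mean_specificity,
                              balanced_accuracy = ev$balanced_accuracy,
                              auc = ev$auc,
                              confusion = as.list(ev$confusion),
                              config = ev$config),
                         file.path(out_dir, sprintf("eval_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$screen)) w(bundle$screen, "feature_screen.csv")
  manifest <- list(seed = bundle$config$seed,
                   counts = bundle$counts,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("megcoh")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
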