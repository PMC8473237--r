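# Cohort-level connectivity analysis: degree-of-connectivity statistics,
# pair-wise class deltas, and the hyper/hypo ROI partition.

#' Epoch-wise pairwise coherence for a whole cohort
#'
#' Runs [pairwise_matrix()] on every 1-s (by default) epoch of every
#' subject and collects the 45 unique pair values in long-matrix form.
#' This is the single expensive pass every downstream connectivity
#' statistic reads from.
#'
#' @param cohort A `megcoh_cohort`.
#' @param epoch_len Epoch length in seconds.
#' @param band Broadband summary range in Hz.
#' @param params [est_params()] object.
#' @return List of class `megcoh_cohort_coh`: `pair_values` (total epochs
#'   x 45 matrix, columns named "A-B"), `subject_id`, `class_label`,
#'   `epoch` (parallel vectors), `pairs` (the [roi_pairs()] table),
#'   `roi_labels`, `n_coherence_evals` (epochs x 45).
#' @export
cohort_coherence <- function(cohort, epoch_len = 1, band = c(0.5, 80),
                             params = est_params()) {
  labels <- cohort$roi_labels
  prs <- roi_pairs(labels)
  res <- vector("list", length(cohort$subjects))
  meta <- vector("list", length(cohort$subjects))
  iu <- cbind(match(prs$roi_a, labels), match(prs$roi_b, labels))
  for (si in seq_along(cohort$subjects)) {
    subj <- cohort$subjects[[si]]
    eps <- epoch_signal(subj, epoch_len)
    vals <- matrix(NA_real_, nrow = length(eps), ncol = nrow(prs))
    for (e in seq_along(eps)) {
      m <- pairwise_matrix(eps[[e]], subj$fs, band, params, labels)$matrix
      vals[e, ] <- m[iu]
    }
    res[[si]] <- vals
    meta[[si]] <- data.frame(subject_id = subj$subject_id,
                             class_label = subj$class_label,
                             epoch = seq_along(eps),
                             stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  pv <- do.call(rbind, res)
  colnames(pv) <- prs$pair
  structure(list(pair_values = pv, subject_id = meta$subject_id,
                 class_label = meta$class_label, epoch = meta$epoch,
                 pairs = prs, roi_labels = labels,
                 n_coherence_evals = nrow(pv) * ncol(pv)),
            class = "megcoh_cohort_coh")
}

# epoch-level degree series for every ROI: total-epochs x 10 matrix.
degree_series <- function(coh) {
  labels <- coh$roi_labels
  deg <- matrix(0, nrow = nrow(coh$pair_values), ncol = length(labels),
                dimnames = list(NULL, labels))
  for (k in seq_len(nrow(coh$pairs))) {
    deg[, coh$pairs$roi_a[k]] <- deg[, coh$pairs$roi_a[k]] + coh$pair_values[, k]
    deg[, coh$pairs$roi_b[k]] <- deg[, coh$pairs$roi_b[k]] + coh$pair_values[, k]
  }
  deg
}

#' Degree-of-connectivity statistics per ROI and class
#'
#' Mean, max, min and SD of the epoch-level degree of connectivity (sum of
#' an ROI's nine pairwise broadband coherences), pooled over all subjects'
#' epochs within each class -- 3600 values per (ROI, class) at the
#' reference scale of 20 subjects x 180 epochs.
#'
#' @param coh A `megcoh_cohort_coh` from [cohort_coherence()], or a
#'   `megcoh_cohort` (in which case the coherence pass is run first).
#' @param ... Passed to [cohort_coherence()] when `coh` is a cohort.
#' @return data.frame with columns roi, class_label, n_epochs, mean, max,
#'   min, sd.
#' @export
connectivity_stats <- function(coh, ...) {
  if (inherits(coh, "megcoh_cohort")) coh <- cohort_coherence(coh, ...)
  classes <- unique(coh$class_label)
  if (length(classes) < 1L) stop("empty cohort")
  deg <- degree_series(coh)
  out <- expand.grid(roi = coh$roi_labels, class_label = classes,
                     stringsAsFactors = FALSE)
  stats_f <- function(v) c(n_epochs = length(v), mean = mean(v),
                           max = max(v), min = min(v),
                           sd = if (length(v) < 2L) 0 else stats::sd(v))
  st <- t(mapply(function(r, cl) stats_f(deg[coh$class_label == cl, r]),
                 out$roi, out$class_label))
  cbind(out, as.data.frame(st))
}

#' Per-pair mean-coherence class deltas (MCI - HC)
#'
#' @param coh A `megcoh_cohort_coh`.
#' @return data.frame: roi_a, roi_b, pair, hemi, mean_hc, mean_mci, delta.
#' @export
pair_deltas <- function(coh) {
  hc <- coh$class_label == "HC"
  mci <- coh$class_label == "MCI"
  if (!any(hc) || !any(mci)) stop("both classes required for pair deltas")
  d <- coh$pairs
  d$mean_hc <- colMeans(coh$pair_values[hc, , drop = FALSE])
  d$mean_mci <- colMeans(coh$pair_values[mci, , drop = FALSE])
  d$delta <- d$mean_mci - d$mean_hc
  d
}

#' Partition ROIs into hyper- and hypo-connected groups
#'
#' Every ROI participating in at least one pair whose mean coherence
#' increases in MCI is a hyper-connectivity candidate. With `balance =
#' TRUE` the candidate set is adjusted to exactly 5 ROIs (demoting
#' candidates with the lowest degree-of-connectivity delta, or promoting
#' non-candidates with the highest), mirroring the balanced 5-vs-5 group
#' design used for classification.
#'
#' @param stats_table Output of [connectivity_stats()] covering both
#'   classes.
#' @param deltas Output of [pair_deltas()].
#' @param balance Enforce |hyper| = 5 (default TRUE).
#' @param override Optional character vector: an explicit hyper set that
#'   bypasses the rule entirely.
#' @return List of class `megcoh_partition`: `hyper`, `hypo` (character
#'   vectors), `candidates` (pre-balance hyper candidates), `evidence`
#'   (the 45-row deltas table), `degree_delta` (named per-ROI MCI-HC mean
#'   degree difference).
#' @export
partition_rois <- function(stats_table, deltas, balance = TRUE,
                           override = NULL) {
  labels <- unique(stats_table$roi)
  if (!setequal(labels, unique(c(deltas$roi_a, deltas$roi_b)))) {
    stop("ROI sets of stats table and pair deltas differ")
  }
  mh <- stats_table$mean[stats_table$class_label == "HC"]
  names(mh) <- stats_table$roi[stats_table$class_label == "HC"]
  mm <- stats_table$mean[stats_table$class_label == "MCI"]
  names(mm) <- stats_table$roi[stats_table$class_label == "MCI"]
  deg_delta <- mm[labels] - mh[labels]
  names(deg_delta) <- labels

  if (!is.null(override)) {
    if (!all(override %in% labels)) stop("override contains unknown ROIs")
    hyper <- override
  } else {
    up <- deltas$delta > 0
    cand <- unique(c(deltas$roi_a[up], deltas$roi_b[up]))
    hyper <- cand
    if (balance) {
      target <- length(labels) %/% 2L
      if (length(hyper) > target) {
        # demote candidates with the lowest degree delta
        hyper <- hyper[order(deg_delta[hyper], decreasing = TRUE)][seq_len(target)]
      } else if (length(hyper) < target) {
        pool <- setdiff(labels, hyper)
        add <- pool[order(deg_delta[pool], decreasing = TRUE)]
        hyper <- c(hyper, add[seq_len(target - length(hyper))])
      }
    }
  }
  cand <- if (is.null(override)) {
    unique(c(deltas$roi_a[deltas$delta > 0], deltas$roi_b[deltas$delta > 0]))
  } else override
  structure(list(hyper = sort(hyper),
                 hypo = sort(setdiff(labels, hyper)),
                 candidates = sort(cand),
                 evidence = deltas,
                 degree_delta = deg_delta),
            class = "megcoh_partition")
}

#' @export
print.megcoh_partition <- function(x, ...) {
  cat("hyper-COH:", paste(x$hyper, collapse = ", "), "\n")
  cat("hypo-COH: ", paste(x$hypo, collapse = ", "), "\n")
  invisible(x)
}

#' Inter-/intra-hemispheric pairwise degree comparisons
#'
#' For every ROI pair, a two-sample t-test (pooled variance) compares the
#' two ROIs' epoch-level degree-of-connectivity sets within a class, and
#' pairs are labeled inter- or intra-hemispheric (25 / 20 for the
#' canonical layout). The fraction of significant pairs per group
#' summarises how strongly regional connectivity profiles differ.
#'
#' @param coh A `megcoh_cohort_coh`.
#' @param class_label Class whose epochs are tested ("HC" or "MCI").
#' @param alpha Significance level (default 0.05).
#' @return List: `table` (per-pair data.frame with hemi label, t statistic
#'   and p), `frac_significant` (named vector for inter and intra),
#'   `alpha`.
#' @export
hemispheric_group_tests <- function(coh, class_label = "HC", alpha = 0.05) {
  keep <- coh$class_label == class_label
  if (!any(keep)) stop("no epochs for class ", class_label)
  deg <- degree_series(coh)[keep, , drop = FALSE]
  prs <- coh$pairs
  res <- lapply(seq_len(nrow(prs)), function(k) {
    tt <- two_sample_t(deg[, prs$roi_a[k]], deg[, prs$roi_b[k]],
                       label = prs$pair[k])
    data.frame(pair = prs$pair[k], hemi = prs$hemi[k],
               statistic = tt$statistic, p = tt$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  frac <- vapply(c(inter = "inter", intra = "intra"), function(h) {
    sel <- tab$hemi == h
    if (!any(sel)) return(NA_real_)
    mean(tab$p[sel] < alpha)
  }, numeric(1))
  list(table = tab, frac_significant = frac, alpha = alpha)
}
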