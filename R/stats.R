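# Statistical screening: two-sample t, Kruskal-Wallis, Anderson-Darling
# normality, Holm-Bonferroni step-down correction, and the per-dimension
# feature screen. The location tests wrap the base-R implementations; the
# Anderson-Darling test (normal family, estimated parameters) comes from
# the nortest package.

pvalue_record <- function(label, test, statistic, p, alpha = 0.05,
                          p_corrected = NA_real_) {
  structure(list(label = label, test = test, statistic = unname(statistic),
                 p = unname(p), p_corrected = p_corrected, alpha = alpha),
            class = "megcoh_pvalue")
}

#' Two-sample t-test (pooled-variance Student form)
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param label Optional label carried into the record.
#' @param var_equal Pooled-variance Student form when TRUE (default);
#'   Welch otherwise.
#' @param alpha Significance level.
#' @return A p-value record (list): label, test, statistic, p,
#'   p_corrected (NA), alpha.
#' @export
two_sample_t <- function(sample_a, sample_b, label = NA_character_,
                         var_equal = TRUE, alpha = 0.05) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs n >= 2")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(pvalue_record(label, "t", 0, 1, alpha))
    }
    stop("zero variance in both samples with unequal means: t undefined")
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
  pvalue_record(label, "t", tt$statistic, tt$p.value, alpha)
}

#' Kruskal-Wallis rank test for two samples
#'
#' Rank-based location test with tie correction and chi-square
#' approximation; does not assume normality.
#'
#' @inheritParams two_sample_t
#' @return A p-value record.
#' @export
kruskal_wallis <- function(sample_a, sample_b, label = NA_character_,
                           alpha = 0.05) {
  if (length(unique(c(sample_a, sample_b))) == 1L) {
    stop("all values tied across both samples: Kruskal-Wallis undefined")
  }
  kt <- stats::kruskal.test(list(sample_a, sample_b))
  pvalue_record(label, "kruskal_wallis", kt$statistic, kt$p.value, alpha)
}

#' Anderson-Darling normality test
#'
#' A-squared statistic against the normal family with estimated mean and
#' SD (composite null), as used to screen coherence sets before t-testing.
#'
#' @param sample Numeric vector, n >= 8.
#' @param label Optional label.
#' @param alpha Significance level for the `reject` decision.
#' @return A p-value record with an additional `reject` flag.
#' @export
anderson_darling <- function(sample, label = NA_character_, alpha = 0.05) {
  if (length(sample) < 8L) stop("Anderson-Darling test requires n >= 8")
  if (stats::sd(sample) == 0) stop("constant sample: normality test undefined")
  at <- nortest::ad.test(sample)
  rec <- pvalue_record(label, "anderson_darling", at$statistic, at$p.value,
                       alpha)
  rec$reject <- rec$p < alpha
  rec
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusted p-values in the original input order:
#' sort ascending, set adjusted (i) = max over j <= i of
#' min(1, (m - j + 1) p_(j)), then un-sort. Uniformly dominates Bonferroni
#' while controlling family-wise error.
#'
#' @param pvals Numeric vector of raw p-values in \[0,1\].
#' @return Numeric vector of adjusted p-values, same order as input.
#' @export
holm_bonferroni <- function(pvals) {
  if (length(pvals) < 1L) stop("need at least one p-value")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Per-dimension two-test screen of class feature differences
#'
#' For each feature dimension, both the pooled t-test and the
#' Kruskal-Wallis test compare HC vs MCI observations; Holm correction is
#' applied within each test family across the screened dimensions, and the
#' joint mask marks dimensions significant under BOTH tests (on corrected
#' p-values when `correct_within` covers them).
#'
#' @param features_hc,features_mci Observation x dimension matrices with
#'   matching dimensionality.
#' @param alpha Significance level (default 0.05).
#' @param labels Optional dimension labels (e.g. band names).
#' @param correct_within "all" corrects across every dimension;
#'   "significant" restricts the Holm family to dimensions whose raw p is
#'   below alpha in that test (the reported-table convention, where only
#'   the screened bands enter the correction).
#' @return data.frame: label, t_p, t_p_corrected, kw_p, kw_p_corrected,
#'   joint_significant.
#' @export
per_dimension_screen <- function(features_hc, features_mci, alpha = 0.05,
                                 labels = NULL,
                                 correct_within = c("all", "significant")) {
  correct_within <- match.arg(correct_within)
  features_hc <- as.matrix(features_hc)
  features_mci <- as.matrix(features_mci)
  if (ncol(features_hc) != ncol(features_mci)) {
    stop("feature dimensionality mismatch between classes")
  }
  d <- ncol(features_hc)
  if (is.null(labels)) labels <- colnames(features_hc)
  if (is.null(labels)) labels <- paste0("dim", seq_len(d))
  t_p <- vapply(seq_len(d), function(j) {
    two_sample_t(features_hc[, j], features_mci[, j])$p
  }, numeric(1))
  kw_p <- vapply(seq_len(d), function(j) {
    kruskal_wallis(features_hc[, j], features_mci[, j])$p
  }, numeric(1))
  correct <- function(p) {
    adj <- rep(NA_real_, length(p))
    fam <- if (correct_within == "all") seq_along(p) else which(p < alpha)
    if (length(fam)) adj[fam] <- holm_bonferroni(p[fam])
    adj
  }
  t_adj <- correct(t_p)
  kw_adj <- correct(kw_p)
  sig <- function(raw, adj) ifelse(is.na(adj), raw < alpha, adj < alpha)
  data.frame(label = labels, t_p = t_p, t_p_corrected = t_adj,
             kw_p = kw_p, kw_p_corrected = kw_adj,
             joint_significant = sig(t_p, t_adj) & sig(kw_p, kw_adj),
             stringsAsFactors = FALSE)
}
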