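#' megcoh: MEG coherence connectivity and wavelet neuromarkers for MCI
#'
#' Source-space MEG pipeline for MCI-vs-HC discrimination: epoch-wise
#' magnitude-squared coherence over ten cortical ROIs, hyper-/hypo-
#' connectivity partitioning, wavelet-packet approximate-derivative SD
#' neuromarkers, dual cross-validation (Monte-Carlo splits vs subject-wise
#' leave-one-out), and Holm-Bonferroni-corrected screening; includes a
#' synthetic cohort generator with planted class effects.
#'
#' @keywords internal
"_PACKAGE"

# The six jointly significant screening bands must correspond to actual
# WPD nodes of the level-3 tree at 200 Hz; asserted once at load.
screen_bands <- c("L2_25-50Hz", "L3_37.5-50Hz", "L2_50-75Hz",
                  "L3_50-62.5Hz", "L3_62.5-75Hz", "L2_75-100Hz")

.onLoad <- function(libname, pkgname) {
  labels <- wpd_band_table(fs = 200, max_level = 3L)$label
  missing <- setdiff(screen_bands, labels)
  if (length(missing) > 0L) {
    stop("internal error: screening bands not in the WPD tree: ",
         paste(missing, collapse = ", "))
  }
  invisible()
}
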