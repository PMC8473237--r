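#' Canonical cortical ROI labels
#'
#' The ten source-space regions of interest used throughout the pipeline:
#' frontal, temporal, central, parietal and occipital lobes of the left and
#' right hemispheres. All data arrays and coherence matrices follow this
#' order.
#'
#' @return Character vector of length 10: LF, RF, LT, RT, LC, RC, LP, RP,
#'   LO, RO.
#' @export
roi_labels <- function() {
  c("LF", "RF", "LT", "RT", "LC", "RC", "LP", "RP", "LO", "RO")
}

#' Hemisphere of an ROI label
#'
#' @param roi Character vector of ROI labels; the first character must be
#'   "L" or "R".
#' @return Character vector of "L"/"R".
#' @export
roi_hemisphere <- function(roi) {
  h <- substr(roi, 1L, 1L)
  if (!all(h %in% c("L", "R"))) {
    stop("ROI labels must start with 'L' or 'R': ",
         paste(roi[!h %in% c("L", "R")], collapse = ", "))
  }
  h
}

#' All unique unordered ROI pairs
#'
#' For ten ROIs this yields the 45 unique combinations used for pairwise
#' connectivity, each labeled inter- or intra-hemispheric (25 inter, 20
#' intra for the canonical 5 + 5 layout).
#'
#' @param labels ROI labels (default [roi_labels()]).
#' @return data.frame with columns `roi_a`, `roi_b`, `pair` ("A-B"), and
#'   `hemi` ("inter" or "intra").
#' @export
roi_pairs <- function(labels = roi_labels()) {
  idx <- utils::combn(length(labels), 2L)
  a <- labels[idx[1L, ]]
  b <- labels[idx[2L, ]]
  data.frame(
    roi_a = a,
    roi_b = b,
    pair = paste(a, b, sep = "-"),
    hemi = ifelse(roi_hemisphere(a) == roi_hemisphere(b), "intra", "inter"),
    stringsAsFactors = FALSE
  )
}

# Validate a full 10-label (or general) ROI set: unique, balanced L/R.
validate_roi_labels <- function(labels) {
  if (anyDuplicated(labels)) stop("duplicate ROI labels")
  h <- roi_hemisphere(labels)
  if (length(labels) == 10L && (sum(h == "L") != 5L || sum(h == "R") != 5L)) {
    stop("expected 5 ROIs per hemisphere, got ",
         sum(h == "L"), " L / ", sum(h == "R"), " R")
  }
  invisible(labels)
}

# Normalise an unordered pair string "A-B" so that ROI order follows
# `labels`; used when matching user-supplied pair lists.
canonical_pair <- function(roi_a, roi_b, labels = roi_labels()) {
  ia <- match(roi_a, labels)
  ib <- match(roi_b, labels)
  if (anyNA(ia) || anyNA(ib)) stop("unknown ROI label in pair")
  swap <- ia > ib
  a <- ifelse(swap, roi_b, roi_a)
  b <- ifelse(swap, roi_a, roi_b)
  paste(a, b, sep = "-")
}
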