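# Wavelet-packet neuromarkers.
#
# Each 10-s epoch is band-pass filtered (0.1-100 Hz Butterworth, zero
# phase), decomposed with a level-3 Daubechies-4 wavelet packet tree, and
# summarised by the sample SD of the first difference ("approximate
# derivative") of each node's coefficients: 2 + 4 + 8 = 14 features per
# ROI per epoch, ordered frequency-ascending within each level.
#
# No wavelet transform is available in the installed R stack, so the
# filter-bank decomposition is implemented here: Daubechies-4 analysis
# filters, half-sample symmetric boundary extension (periodic extension
# available for exact energy conservation), dyadic downsampling, and
# frequency-ordered (Gray-code) node layout.

# Daubechies-4 analysis filters (orthonormal; 8 taps).
db4_dec_lo <- c(-0.01059740178506903, 0.0328830116668852,
                0.03084138183556076, -0.18703481171909309,
                -0.02798376941685985, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.02798376941685985,
                0.18703481171909309, 0.03084138183556076,
                -0.0328830116668852, -0.01059740178506903)

# One analysis step: filter + downsample by 2.
# symmetric: half-sample symmetric extension by (flen-1) on each side,
# full convolution, phase offset flen; output length floor((n+flen-1)/2).
# periodic: circular convolution; output length n/2 (n must be even).
dwt_step <- function(x, filt, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  flen <- length(filt)
  n <- length(x)
  if (n < 2L) stop("signal too short for a decomposition step")
  if (mode == "symmetric") {
    ext <- c(rev(x[seq_len(flen - 1L)]), x, rev(x)[seq_len(flen - 1L)])
    full <- stats::convolve(ext, rev(filt), type = "open")
    outlen <- (n + flen - 1L) %/% 2L
    full[seq(flen + 1L, by = 2L, length.out = outlen)]
  } else {
    if (n %% 2L != 0L) stop("periodic mode requires even length")
    idx <- outer(seq(2L, n, by = 2L), seq_len(flen) - 1L, `-`) %% n + 1L
    drop(matrix(x[idx], ncol = flen) %*% filt)
  }
}

# Frequency-ordered node paths at a level ("a" = lowpass child, "d" =
# highpass): children keep (a, d) order under even-indexed parents and
# swap under odd-indexed ones (binary-reflected Gray code).
wpd_freq_paths <- function(level) {
  paths <- ""
  for (l in seq_len(level)) {
    nxt <- character(2L * length(paths))
    for (i in seq_along(paths)) {
      ch <- if ((i - 1L) %% 2L == 0L) c("a", "d") else c("d", "a")
      nxt[2L * i - 1L] <- paste0(paths[i], ch[1L])
      nxt[2L * i] <- paste0(paths[i], ch[2L])
    }
    paths <- nxt
  }
  paths
}

#' Nominal WPD node bands
#'
#' Frequency-ascending nominal bands of all nodes of levels 1..max_level:
#' level L tiles \[0, fs/2\] into 2^L equal bands.
#'
#' @param fs Sampling rate (Hz).
#' @param max_level Deepest level (default 3).
#' @return data.frame: level, index (frequency position within level,
#'   1-based), band_lo, band_hi, label (e.g. "L3_37.5-50Hz").
#' @export
wpd_band_table <- function(fs = 200, max_level = 3L) {
  do.call(rbind, lapply(seq_len(max_level), function(l) {
    width <- fs / 2 / 2^l
    k <- seq_len(2^l)
    data.frame(level = l, index = k,
               band_lo = (k - 1) * width, band_hi = k * width,
               label = sprintf("L%d_%g-%gHz", l, (k - 1) * width, k * width),
               stringsAsFactors = FALSE)
  }))
}

#' Wavelet packet decomposition (Daubechies 4, level 3)
#'
#' Returns ALL nodes of levels 1, 2 and 3 (2 + 4 + 8 = 14) in
#' frequency-ascending order within each level, each labeled with its
#' nominal band on the 0 to fs/2 axis.
#'
#' @param x Numeric signal (length >= 2^max_level).
#' @param fs Sampling rate (Hz), used only for band labels.
#' @param max_level Decomposition depth (default 3).
#' @param mode Boundary extension: "symmetric" (default) or "periodic"
#'   (exact Parseval energy conservation; even lengths only).
#' @return List of nodes; each node is a list with `level`, `index`,
#'   `path`, `band` (c(lo, hi) Hz), `label`, `coefficients`.
#' @export
wpd_decompose <- function(x, fs = 200, max_level = 3L,
                          mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  if (length(x) < 2^max_level) stop("signal shorter than 2^max_level samples")
  bands <- wpd_band_table(fs, max_level)
  nodes <- list()
  level_nodes <- list(x)      # frequency-ordered nodes of current level
  for (l in seq_len(max_level)) {
    nxt <- vector("list", 2L * length(level_nodes))
    for (i in seq_along(level_nodes)) {
      lo <- dwt_step(level_nodes[[i]], db4_dec_lo, mode)
      hi <- dwt_step(level_nodes[[i]], db4_dec_hi, mode)
      if ((i - 1L) %% 2L == 0L) {
        nxt[[2L * i - 1L]] <- lo; nxt[[2L * i]] <- hi
      } else {
        nxt[[2L * i - 1L]] <- hi; nxt[[2L * i]] <- lo
      }
    }
    level_nodes <- nxt
    paths <- wpd_freq_paths(l)
    for (i in seq_along(level_nodes)) {
      b <- bands[bands$level == l & bands$index == i, ]
      nodes[[length(nodes) + 1L]] <-
        list(level = l, index = i, path = paths[i],
             band = c(b$band_lo, b$band_hi), label = b$label,
             coefficients = level_nodes[[i]])
    }
  }
  nodes
}

#' Approximate derivative of a coefficient sequence
#'
#' First differences between adjacent elements: out\[i\] = x\[i+1\] - x\[i\].
#'
#' @param coeffs Numeric vector, length >= 2.
#' @return Numeric vector of length length(coeffs) - 1.
#' @export
approx_derivative <- function(coeffs) {
  if (length(coeffs) < 2L) stop("need at least 2 coefficients")
  diff(coeffs)
}

#' Preprocessing parameters for the feature pipeline
#'
#' @param target_fs Working sampling rate (Hz, default 200).
#' @param band Band-pass range in Hz (default 0.1--100; the upper edge is
#'   clamped to 0.995 x Nyquist for a realizable filter).
#' @param filter_order Butterworth order (default 4; applied forward and
#'   backward, so the effective order doubles).
#' @return List of class `megcoh_preproc_params`.
#' @export
preprocess_params <- function(target_fs = 200, band = c(0.1, 100),
                              filter_order = 4L) {
  stopifnot(target_fs > 0, filter_order >= 1L, band[1] < band[2])
  structure(list(target_fs = target_fs, band = band,
                 filter_order = as.integer(filter_order)),
            class = "megcoh_preproc_params")
}

#' Preprocess one epoch channel
#'
#' Anti-alias decimation to the target rate (when the input rate is
#' higher; the ratio must be an integer), then zero-phase Butterworth
#' band-pass with the upper edge clamped below Nyquist.
#'
#' @param x Numeric signal.
#' @param in_fs Input sampling rate (Hz), >= target rate.
#' @param params [preprocess_params()] object.
#' @return Filtered signal at `params$target_fs`.
#' @export
preprocess <- function(x, in_fs, params = preprocess_params()) {
  tfs <- params$target_fs
  if (in_fs < tfs) stop("input rate below target rate")
  if (length(x) < 3L * params$filter_order) {
    stop("epoch too short for filter warm-up")
  }
  if (in_fs > tfs) {
    q <- in_fs / tfs
    if (abs(q - round(q)) > 1e-8) {
      stop("in_fs must be an integer multiple of the target rate")
    }
    x <- as.numeric(signal::decimate(x, as.integer(round(q)), ftype = "iir"))
  }
  x <- x - mean(x)   # remove DC before the high-pass side sees it
  nyq <- tfs / 2
  lo <- params$band[1] / nyq
  hi <- min(params$band[2], 0.995 * nyq) / nyq
  bf <- signal::butter(params$filter_order, c(lo, hi), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Segment a recording into feature epochs
#'
#' @inheritParams epoch_signal
#' @param epoch_len Epoch length in seconds (default 10, giving 18 epochs
#'   from a 180-s recording).
#' @return List of channel x samples matrices.
#' @export
segment_for_features <- function(recording, epoch_len = 10) {
  epoch_signal(recording, epoch_len)
}

#' Wavelet feature vector of one preprocessed epoch channel
#'
#' SD (sample, n-1 denominator) of the approximate derivative of each WPD
#' node's coefficients; 14 values ordered level 1, 2, 3, each level
#' frequency-ascending.
#'
#' @param x Preprocessed signal at `fs`.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector of length 14 (names from
#'   [wpd_band_table()] labels).
#' @export
extract_features <- function(x, fs = 200) {
  nodes <- wpd_decompose(x, fs = fs, max_level = 3L)
  vals <- vapply(nodes, function(nd) {
    stats::sd(approx_derivative(nd$coefficients))
  }, numeric(1))
  names(vals) <- vapply(nodes, `[[`, "", "label")
  vals
}

#' Build the observation-level feature dataset for an ROI group
#'
#' One observation per (subject, 10-s epoch): each ROI channel of the
#' selected group is preprocessed and reduced to its 14 wavelet features,
#' then the group's ROI vectors are combined by `aggregation` ("mean":
#' 14-dim observations, the replication default; "concat": 14 x group
#' size).
#'
#' @param cohort A `megcoh_cohort`.
#' @param partition A `megcoh_partition` (required unless group = "all").
#' @param group "hyper", "hypo" or "all".
#' @param aggregation "mean" or "concat".
#' @param epoch_len Feature epoch length in seconds (default 10).
#' @param params [preprocess_params()] object.
#' @return Object of class `megcoh_features`: `x` (observations x dims
#'   matrix), `subject_id`, `class_label`, `epoch`, `group`, `rois`.
#' @export
build_feature_dataset <- function(cohort, partition = NULL,
                                  group = c("hyper", "hypo", "all"),
                                  aggregation = c("mean", "concat"),
                                  epoch_len = 10,
                                  params = preprocess_params()) {
  group <- match.arg(group)
  aggregation <- match.arg(aggregation)
  rois <- switch(group,
                 all = cohort$roi_labels,
                 hyper = partition$hyper,
                 hypo = partition$hypo)
  if (is.null(rois) || length(rois) == 0L) {
    stop("empty ROI group; supply a partition for group = 'hyper'/'hypo'")
  }
  rows <- list(); meta <- list()
  for (subj in cohort$subjects) {
    eps <- segment_for_features(subj, epoch_len)
    for (e in seq_along(eps)) {
      fv <- lapply(rois, function(r) {
        extract_features(preprocess(eps[[e]][r, ], subj$fs, params),
                         fs = params$target_fs)
      })
      obs <- if (aggregation == "mean") {
        Reduce(`+`, fv) / length(fv)
      } else {
        v <- unlist(fv)
        names(v) <- paste(rep(rois, each = length(fv[[1]])),
                          names(fv[[1]]), sep = ".")
        v
      }
      rows[[length(rows) + 1L]] <- obs
      meta[[length(meta) + 1L]] <-
        data.frame(subject_id = subj$subject_id,
                   class_label = subj$class_label, epoch = e,
                   stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  structure(list(x = do.call(rbind, rows), subject_id = meta$subject_id,
                 class_label = meta$class_label, epoch = meta$epoch,
                 group = group, rois = rois),
            class = "megcoh_features")
}

#' @export
print.megcoh_features <- function(x, ...) {
  cat("megcoh features: ", nrow(x$x), " observations x ", ncol(x$x),
      " dims (group = ", x$group, ": ", paste(x$rois, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Train-only PCA reduction
#'
#' Centering and principal axes are estimated from the training rows ONLY
#' and applied to both sets, avoiding test-set leakage; components are
#' ordered by decreasing explained variance.
#'
#' @param train,test Observation x dimension matrices (test may be NULL).
#' @param k Number of components to keep, 1 <= k <= ncol(train).
#' @return List: `train`, `test` (projected matrices with k columns),
#'   `rotation`, `center`, `explained_variance_ratio`.
#' @export
pca_reduce <- function(train, test = NULL, k) {
  train <- as.matrix(train)
  if (k < 1L || k > ncol(train)) stop("k must be in 1..ncol(train)")
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  r <- ncol(pc$rotation)
  if (k > r) {
    warning("k exceeds the rank of the training data; trailing components ",
            "have zero variance")
  }
  rot <- matrix(0, nrow = ncol(train), ncol = k)
  rot[, seq_len(min(k, r))] <- pc$rotation[, seq_len(min(k, r))]
  project <- function(m) {
    sweep(as.matrix(m), 2L, pc$center, "-") %*% rot
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(train = project(train),
       test = if (!is.null(test)) project(test),
       rotation = rot, center = pc$center,
       explained_variance_ratio = evr[seq_len(min(k, r))])
}
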