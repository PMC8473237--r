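# Magnitude-squared spectral coherence connectivity.
#
# C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f)), with P_xy the cross-spectral
# density of jointly stationary x, y. Within a single segment |C_xy| is
# identically 1, so the estimator must average: Welch's method with Hann
# sub-segments at 50% overlap is used (0.5 s sub-segments by default, i.e.
# 3 averaged segments per 1 s epoch and a 2 Hz frequency grid at 200 Hz).

#' Spectral estimation parameters for Welch coherence
#'
#' @param seg_len_sec Sub-segment length in seconds (default 0.5).
#' @param overlap Fractional overlap between consecutive sub-segments
#'   (default 0.5).
#' @param window Window function; only "hann" (periodic) is provided.
#' @return List of class `megcoh_est_params`.
#' @export
est_params <- function(seg_len_sec = 0.5, overlap = 0.5, window = "hann") {
  stopifnot(seg_len_sec > 0, overlap >= 0, overlap < 1)
  window <- match.arg(window, "hann")
  structure(list(seg_len_sec = seg_len_sec, overlap = overlap,
                 window = window),
            class = "megcoh_est_params")
}

hann_window <- function(n) {
  # periodic Hann, matching the convention of standard Welch implementations
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

# Segment start indices (1-based) for Welch averaging.
welch_starts <- function(n, nper, noverlap) {
  step <- nper - noverlap
  if (n < nper) stop("signal shorter than one Welch sub-segment")
  seq(1L, n - nper + 1L, by = step)
}

# One-sided windowed FFTs of every Welch sub-segment of every row of `x`
# (channels x samples). Returns (nfreq x nseg x nchan) complex array;
# each sub-segment is mean-detrended before windowing.
welch_ffts <- function(x, nper, noverlap) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  starts <- welch_starts(ncol(x), nper, noverlap)
  win <- hann_window(nper)
  nfreq <- nper %/% 2L + 1L
  segs <- matrix(0, nrow = nper, ncol = length(starts) * nrow(x))
  k <- 0L
  for (ch in seq_len(nrow(x))) {
    for (s in starts) {
      k <- k + 1L
      seg <- x[ch, s:(s + nper - 1L)]
      segs[, k] <- (seg - mean(seg)) * win
    }
  }
  ff <- stats::mvfft(segs)[seq_len(nfreq), , drop = FALSE]
  array(ff, dim = c(nfreq, length(starts), nrow(x)))
}

#' Magnitude-squared coherence between two signals
#'
#' Welch-averaged estimate of \eqn{C_{xy}(f) = |P_{xy}(f)|^2 /
#' (P_{xx}(f) P_{yy}(f))} using Hann-windowed, mean-detrended,
#' 50\%-overlapping sub-segments.
#'
#' @param x,y Numeric vectors of equal length.
#' @param fs Sampling rate (Hz).
#' @param params [est_params()] object.
#' @return List of class `megcoh_coherence`: `freqs` (Hz), `values` in
#'   \[0,1\], `n_segments`, and `undefined` (TRUE when either input has
#'   zero variance, in which case `values` are NA rather than propagating
#'   0/0).
#' @export
ms_coherence <- function(x, y, fs, params = est_params()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  nper <- as.integer(round(fs * params$seg_len_sec))
  noverlap <- as.integer(round(nper * params$overlap))
  if (length(x) < nper) {
    stop("inputs must span at least one sub-segment (", nper, " samples)")
  }
  freqs <- (seq_len(nper %/% 2L + 1L) - 1L) * fs / nper
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(list(freqs = freqs,
                          values = rep(NA_real_, length(freqs)),
                          n_segments = NA_integer_, undefined = TRUE),
                     class = "megcoh_coherence"))
  }
  ff <- welch_ffts(rbind(x, y), nper, noverlap)
  X <- ff[, , 1L, drop = FALSE]; dim(X) <- dim(ff)[1:2]
  Y <- ff[, , 2L, drop = FALSE]; dim(Y) <- dim(ff)[1:2]
  pxx <- rowMeans(Re(X * Conj(X)))
  pyy <- rowMeans(Re(Y * Conj(Y)))
  pxy <- rowMeans(X * Conj(Y))
  vals <- Mod(pxy)^2 / (pxx * pyy)
  vals[pxx == 0 | pyy == 0] <- 0
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(freqs = freqs, values = vals, n_segments = dim(ff)[2L],
                 undefined = FALSE),
            class = "megcoh_coherence")
}

#' Broadband summary of a coherence spectrum
#'
#' Arithmetic mean of the coherence values over frequency bins falling in
#' `band` (edges inclusive); the default 0.5--80 Hz broadband summary is
#' the pipeline's functional-connectivity scalar.
#'
#' @param spec A `megcoh_coherence` object (or list with `freqs`,
#'   `values`).
#' @param band c(lo, hi) in Hz.
#' @return Scalar in \[0,1\].
#' @export
broadband_coherence <- function(spec, band = c(0.5, 80)) {
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(sel)) stop("band [", band[1], ", ", band[2],
                      "] Hz contains no frequency bins")
  mean(spec$values[sel])
}

#' Split a recording into non-overlapping epochs
#'
#' @param recording A `megcoh_subject` (or any list with `data` matrix and
#'   `fs`).
#' @param epoch_len Epoch length in seconds (default 1).
#' @return List of channel x (fs * epoch_len) matrices; a trailing partial
#'   epoch is discarded.
#' @export
epoch_signal <- function(recording, epoch_len = 1) {
  nper <- round(recording$fs * epoch_len)
  if (abs(recording$fs * epoch_len - nper) > 1e-8) {
    stop("fs * epoch_len must be an integer sample count")
  }
  nper <- as.integer(nper)
  n <- ncol(recording$data)
  if (n < nper) stop("epoch longer than recording")
  n_epochs <- n %/% nper
  lapply(seq_len(n_epochs), function(e) {
    recording$data[, ((e - 1L) * nper + 1L):(e * nper), drop = FALSE]
  })
}

#' Pairwise broadband coherence matrix for one epoch
#'
#' Computes the 45 unique pairwise MS-coherences among the 10 ROI channels
#' (channel FFTs are computed once and shared across pairs), reduces each
#' to its broadband summary, and mirrors into a symmetric matrix with unit
#' diagonal.
#'
#' @param epoch Channels x samples matrix (rows in canonical ROI order).
#' @param fs Sampling rate (Hz).
#' @param band Broadband summary range, c(lo, hi) Hz.
#' @param params [est_params()] object.
#' @param roi_labels Row labels (default [roi_labels()]).
#' @return List of class `megcoh_cohmat`: `matrix` (10 x 10 symmetric,
#'   diag 1), `roi_labels`.
#' @export
pairwise_matrix <- function(epoch, fs, band = c(0.5, 80),
                            params = est_params(),
                            roi_labels = megcoh::roi_labels()) {
  if (nrow(epoch) != length(roi_labels)) {
    stop("epoch must have one row per ROI label")
  }
  nper <- as.integer(round(fs * params$seg_len_sec))
  noverlap <- as.integer(round(nper * params$overlap))
  ff <- welch_ffts(epoch, nper, noverlap)
  nfreq <- dim(ff)[1L]
  freqs <- (seq_len(nfreq) - 1L) * fs / nper
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("empty broadband range")
  nch <- dim(ff)[3L]
  auto <- vapply(seq_len(nch),
                 function(i) rowMeans(Re(ff[, , i] * Conj(ff[, , i]))),
                 numeric(nfreq))
  m <- diag(1, nch)
  dimnames(m) <- list(roi_labels, roi_labels)
  for (i in seq_len(nch - 1L)) {
    fi <- Conj(ff[, , i])
    for (j in (i + 1L):nch) {
      pxy <- rowMeans(fi * ff[, , j])
      cxy <- Mod(pxy)^2 / (auto[, i] * auto[, j])
      cxy[auto[, i] == 0 | auto[, j] == 0] <- 0
      cxy <- pmin(pmax(cxy, 0), 1)
      m[i, j] <- m[j, i] <- mean(cxy[sel])
    }
  }
  structure(list(matrix = m, roi_labels = roi_labels),
            class = "megcoh_cohmat")
}

#' Degree of connectivity of one ROI in a coherence matrix
#'
#' Sum of the nine off-diagonal broadband coherences of the ROI's row;
#' lies in \[0, 9\] for ten ROIs.
#'
#' @param mat A `megcoh_cohmat` (or plain symmetric matrix with ROI
#'   dimnames).
#' @param roi ROI label.
#' @return Scalar degree of connectivity.
#' @export
degree_of_connectivity <- function(mat, roi) {
  m <- if (inherits(mat, "megcoh_cohmat")) mat$matrix else mat
  if (!roi %in% rownames(m)) stop("unknown ROI: ", roi)
  sum(m[roi, ]) - m[roi, roi]
}
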