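# Synthetic MEG-like cohort generator.
#
# Channels are synthesised directly from a target coherency structure:
# within each canonical frequency band (delta/theta/alpha/beta/gamma),
# every frequency bin's 10-channel coefficient vector is D %*% sqrtm(G)
# %*% z with z iid complex Gaussian, G the 10 x 10 matrix of pairwise
# coherency magnitudes (unit diagonal) and D a diagonal channel gain.
# The cross-spectral matrix of such data equals D G D, so the planted
# magnitude-squared coherence of a pair is exactly the square of its G
# entry -- the class effects enter the estimator at first order, while
# diagonal gains (subject band gains, the MCI spectral effect) change
# spectra without touching coherence.

#' Canonical frequency bands used by the synthetic generator
#'
#' @return Named list of c(lo, hi) Hz ranges for delta, theta, alpha,
#'   beta, gamma.
#' @export
canonical_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 80))
}

#' Parameters of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: 20 subjects per
#' class, 10 ROI channels at 200 Hz for 180 s, increased MCI coupling on
#' the LF-LT, RT-RC and LP-LO pairs and decreased coupling elsewhere, and
#' a class power difference confined to 25--100 Hz in the ROIs that are
#' members of the hyper-coupled pairs.
#'
#' Coupling parameters are coherency magnitudes: a pair with coupling c
#' has planted magnitude-squared coherence c^2 at the source level (the
#' Welch estimator adds its own positive bias on top).
#'
#' @param n_subjects_per_class Subjects per class (HC and MCI).
#' @param fs Sampling rate in Hz. 200 is the native rate; 1000 exercises
#'   the down-sampling path of the feature pipeline.
#' @param duration Recording length per subject in seconds.
#' @param roi_labels Ten ROI labels, 5 per hemisphere (prefix L/R).
#' @param hyper_pairs Character vector of "A-B" ROI pairs whose coupling
#'   is increased in MCI.
#' @param coupling_base Baseline pairwise coherency magnitude in \[0,1\].
#' @param coupling_delta_hyper Coupling increase applied to `hyper_pairs`
#'   in MCI subjects.
#' @param coupling_delta_hypo Coupling decrease applied to all other
#'   pairs in MCI subjects.
#' @param spectral_effect_band Hz range whose power differs by class.
#' @param spectral_effect_size Relative power change (0.3 = +30\% power
#'   in MCI) applied within `spectral_effect_band` to the ROIs
#'   participating in `hyper_pairs`.
#' @param subject_sd Between-subject SD of the per-pair coupling
#'   perturbation (coherency units).
#' @param band_gain_sd Between-subject SD of the log band-power gain; the
#'   per-subject spectral fingerprint this creates is what makes
#'   subject-wise leave-one-out evaluation harder than pooled-epoch
#'   splitting.
#' @param noise_sd Independent per-channel broadband sensor-noise SD
#'   (channels carry unit variance per band before noise).
#' @param seed Integer seed; generation is a pure function of
#'   (params, seed).
#' @return Object of class `megcoh_synth_params` (a validated list).
#' @export
synth_params <- function(n_subjects_per_class = 20L,
                         fs = 200,
                         duration = 180,
                         roi_labels = megcoh::roi_labels(),
                         hyper_pairs = c("LF-LT", "RT-RC", "LP-LO"),
                         coupling_base = 0.4,
                         coupling_delta_hyper = 0.04,
                         coupling_delta_hypo = 0.04,
                         spectral_effect_band = c(25, 100),
                         spectral_effect_size = 0.3,
                         subject_sd = 0.008,
                         band_gain_sd = 0.15,
                         noise_sd = 0.5,
                         seed = 1L) {
  p <- list(
    n_subjects_per_class = as.integer(n_subjects_per_class), fs = fs,
    duration = duration, roi_labels = roi_labels, hyper_pairs = hyper_pairs,
    coupling_base = coupling_base,
    coupling_delta_hyper = coupling_delta_hyper,
    coupling_delta_hypo = coupling_delta_hypo,
    spectral_effect_band = spectral_effect_band,
    spectral_effect_size = spectral_effect_size,
    subject_sd = subject_sd, band_gain_sd = band_gain_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(p) <- "megcoh_synth_params"
  validate_synth_params(p)
}

validate_synth_params <- function(p) {
  stopifnot(p$n_subjects_per_class >= 1L, p$fs > 0, p$duration > 0)
  if (length(p$roi_labels) != 10L) stop("exactly 10 ROI labels required")
  validate_roi_labels(p$roi_labels)
  n <- p$fs * p$duration
  if (abs(n - round(n)) > 1e-8) stop("duration * fs must be an integer sample count")
  if (p$coupling_base < 0 || p$coupling_base > 1) {
    stop("coupling_base must lie in [0,1]")
  }
  if (p$coupling_base + p$coupling_delta_hyper > 1 ||
      p$coupling_base - p$coupling_delta_hypo < 0) {
    stop("coupling_base with class deltas must remain in [0,1]")
  }
  prs <- roi_pairs(p$roi_labels)
  if (!all(p$hyper_pairs %in% prs$pair)) {
    stop("hyper_pairs must be canonical 'A-B' pairs: ",
         paste(setdiff(p$hyper_pairs, prs$pair), collapse = ", "))
  }
  invisible(p)
}

# Deterministic child seed below 2^31 (minimal standard LCG step).
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(k)) %% 2147483647)
}

# Hermitian-symmetric inverse FFT: real signal of length n from one-sided
# complex coefficients `coef` placed at (0-based) bin indices `bins`
# (DC and Nyquist excluded by construction).
real_from_spectrum <- function(coef, bins, n) {
  z <- complex(length.out = n)
  z[bins + 1L] <- coef
  z[n - bins + 1L] <- Conj(coef)
  Re(stats::fft(z, inverse = TRUE)) / n
}

# Per-band frequency bins (0-based, excluding DC and Nyquist).
band_bins <- function(band, fs, n) {
  f <- (seq_len(n) - 1) * fs / n
  half <- floor((n - 1) / 2)
  which(f >= band[1] & f <= band[2] & seq_along(f) <= half + 1 &
          seq_along(f) >= 2) - 1L
}

# Hermitian square root of a coherency-magnitude matrix, with eigenvalue
# clipping so near-singular targets (e.g. coupling ~ 1) stay usable.
coherency_sqrt <- function(G) {
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-8)
  eg$vectors %*% (sqrt(vals) * t(eg$vectors))
}

#' Generate one synthetic subject recording
#'
#' Builds the subject's pairwise coherency target (class deltas on the
#' planted pairs plus per-pair subject perturbation, clamped into
#' \[0, 1\]), draws every band's frequency-bin coefficients through the
#' matrix square root of that target, applies the subject band gains and
#' the MCI spectral effect as diagonal channel gains, and adds
#' independent sensor noise.
#'
#' @param class_label "HC" or "MCI".
#' @param params A [synth_params()] object.
#' @param seed Integer seed for this subject.
#' @param subject_id Optional identifier (defaults to class + seed).
#' @return Object of class `megcoh_subject`: list with `subject_id`,
#'   `class_label`, `fs`, and `data` (10 x n matrix, rows in canonical
#'   ROI order).
#' @export
generate_subject <- function(class_label, params, seed,
                             subject_id = paste0(class_label, "_", seed)) {
  if (!class_label %in% c("HC", "MCI")) {
    stop("class_label must be 'HC' or 'MCI', got: ", class_label)
  }
  validate_synth_params(params)
  n <- as.integer(round(params$fs * params$duration))
  labels <- params$roi_labels
  nch <- length(labels)
  prs <- roi_pairs(labels)
  npair <- nrow(prs)
  bands <- canonical_bands()

  # class-level pair couplings (coherency magnitudes)
  cpl <- rep(params$coupling_base, npair)
  is_hyper <- prs$pair %in% params$hyper_pairs
  if (class_label == "MCI") {
    cpl <- cpl + ifelse(is_hyper, params$coupling_delta_hyper,
                        -params$coupling_delta_hypo)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  # subject random effects: per-pair coupling perturbation + band gains
  cpl <- cpl + stats::rnorm(npair, sd = params$subject_sd)
  n_clamped <- sum(cpl < 0 | cpl > 1)
  if (n_clamped > 0L) {
    warning(sprintf("subject %s: %d pair coupling(s) clamped into [0,1]",
                    subject_id, n_clamped),
            call. = FALSE)
    cpl <- pmin(pmax(cpl, 0), 1)
  }
  band_gain <- exp(stats::rnorm(length(bands), sd = params$band_gain_sd))

  G <- diag(1, nch)
  ia <- match(prs$roi_a, labels); ib <- match(prs$roi_b, labels)
  G[cbind(ia, ib)] <- cpl
  G[cbind(ib, ia)] <- cpl
  Gh <- coherency_sqrt(G)

  effect_rois <- unique(unlist(strsplit(params$hyper_pairs, "-", fixed = TRUE)))
  effect_gain <- if (class_label == "MCI") sqrt(1 + params$spectral_effect_size) else 1
  eband <- params$spectral_effect_band

  data <- matrix(0, nrow = nch, ncol = n, dimnames = list(labels, NULL))
  for (bi in seq_along(bands)) {
    bins <- band_bins(bands[[bi]], params$fs, n)
    nb <- length(bins)
    if (nb == 0L) next
    amp <- n / (2 * sqrt(nb))          # unit-variance time series per channel
    z <- matrix(complex(real = stats::rnorm(nb * nch),
                        imaginary = stats::rnorm(nb * nch)),
                nrow = nb)
    chan <- z %*% Gh                   # cross-spectral structure = G
    gains <- rep(amp * band_gain[bi], nch)
    f_bins <- bins * params$fs / n
    in_eff <- f_bins >= eband[1] & f_bins <= eband[2]
    if (effect_gain != 1 && any(in_eff)) {
      eff_ch <- labels %in% effect_rois
      chan[in_eff, eff_ch] <- chan[in_eff, eff_ch] * effect_gain
    }
    chan <- sweep(chan, 2L, gains, "*")
    for (ri in seq_len(nch)) {
      data[ri, ] <- data[ri, ] + real_from_spectrum(chan[, ri], bins, n)
    }
  }
  if (params$noise_sd > 0) {
    data <- data + matrix(stats::rnorm(length(data), sd = params$noise_sd),
                          nrow = nrow(data))
  }
  structure(list(subject_id = subject_id, class_label = class_label,
                 fs = params$fs, data = data),
            class = "megcoh_subject")
}

#' Generate a synthetic cohort
#'
#' @param params A [synth_params()] object; `params$seed` drives all
#'   randomness (per-subject child seeds are derived deterministically).
#' @return Object of class `megcoh_cohort`: list with `subjects` (list of
#'   [generate_subject()] outputs, HC first), `params`, `roi_labels`.
#' @export
generate_cohort <- function(params = synth_params()) {
  validate_synth_params(params)
  subjects <- vector("list", 2L * params$n_subjects_per_class)
  k <- 0L
  for (cls in c("HC", "MCI")) {
    for (i in seq_len(params$n_subjects_per_class)) {
      k <- k + 1L
      subjects[[k]] <- generate_subject(
        cls, params, seed = child_seed(params$seed, k),
        subject_id = sprintf("%s_%02d", cls, i)
      )
    }
  }
  structure(list(subjects = subjects, params = params,
                 roi_labels = params$roi_labels),
            class = "megcoh_cohort")
}

#' @export
print.megcoh_cohort <- function(x, ...) {
  cls <- vapply(x$subjects, `[[`, "", "class_label")
  ns <- vapply(x$subjects, function(s) ncol(s$data), 0)
  cat("megcoh synthetic cohort: ", length(x$subjects), " subjects (",
      sum(cls == "HC"), " HC / ", sum(cls == "MCI"), " MCI), ",
      length(x$roi_labels), " ROIs, ", unique(ns)[1], " samples @ ",
      x$subjects[[1]]$fs, " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.megcoh_subject <- function(x, ...) {
  cat("megcoh subject ", x$subject_id, " (", x$class_label, "): ",
      nrow(x$data), " ROIs x ", ncol(x$data), " samples @ ", x$fs, " Hz\n",
      sep = "")
  invisible(x)
}
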