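# Shared fixtures and independent oracles for the test suite.

# Memoized small cohorts so expensive generation runs once per session.
.megcoh_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .megcoh_cache)) {
    assign(key, force(expr), envir = .megcoh_cache)
  }
  get(key, envir = .megcoh_cache)
}

tiny_cohort <- function(seed = 1L, n = 4L, duration = 30) {
  cached(sprintf("cohort_%d_%d_%g", seed, n, duration), {
    suppressWarnings(generate_cohort(
      synth_params(n_subjects_per_class = n, duration = duration,
                   seed = seed)))
  })
}

tiny_coh <- function(seed = 1L, n = 4L, duration = 30) {
  cached(sprintf("coh_%d_%d_%g", seed, n, duration), {
    cohort_coherence(tiny_cohort(seed, n, duration))
  })
}

# Hand-built feature dataset (for classifier tests that need controlled
# geometry rather than a full synthetic cohort).
make_features <- function(x, class_label, subject_id,
                          epoch = stats::ave(seq_along(class_label),
                                             subject_id, FUN = seq_along)) {
  structure(list(x = as.matrix(x), subject_id = subject_id,
                 class_label = class_label, epoch = epoch,
                 group = "all", rois = "synthetic"),
            class = "megcoh_features")
}

# --- independent oracles -------------------------------------------------

# Direct evaluation of magnitude-squared coherence: explicit per-segment
# FFT periodograms averaged over the same Hann/overlap segment layout,
# written without any package helper.
oracle_coherence <- function(x, y, fs, seg_len_sec = 0.5, overlap = 0.5) {
  nper <- round(fs * seg_len_sec)
  step <- nper - round(nper * overlap)
  win <- 0.5 * (1 - cos(2 * pi * (0:(nper - 1)) / nper))
  starts <- seq(1, length(x) - nper + 1, by = step)
  nf <- nper %/% 2 + 1
  sxx <- syy <- rep(0, nf)
  sxy <- rep(0 + 0i, nf)
  for (s in starts) {
    xs <- x[s:(s + nper - 1)]; ys <- y[s:(s + nper - 1)]
    X <- stats::fft((xs - mean(xs)) * win)[1:nf]
    Y <- stats::fft((ys - mean(ys)) * win)[1:nf]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  list(freqs = (0:(nf - 1)) * fs / nper,
       values = Mod(sxy / length(starts))^2 /
         ((sxx / length(starts)) * (syy / length(starts))))
}

# Brute-force Holm step-down: walk the sorted p-values, rejecting while
# p_(j) <= alpha/(m - j + 1); the adjusted value of p_(j) is the smallest
# alpha at which it is still rejected, accumulated as a running maximum.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  run <- 0
  for (j in seq_len(m)) {
    run <- max(run, min(1, (m - j + 1) * p[ord[j]]))
    adj_sorted[j] <- run
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}
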