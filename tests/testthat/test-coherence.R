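test_that("self-coherence is 1 and values stay in [0,1]", {
  set.seed(1)
  x <- rnorm(400)
  co <- ms_coherence(x, x, 200)
  expect_true(all(abs(co$values - 1) < 1e-9))
  co2 <- ms_coherence(x, rnorm(400), 200)
  expect_true(all(co2$values >= 0 & co2$values <= 1))
  expect_equal(co2$freqs, seq(0, 100, by = 2))
})

test_that("coherence matches an independent Welch reference to 1e-10", {
  # frozen reference computed with scipy.signal.coherence (hann, nperseg
  # 100, noverlap 50) on a shared 20 Hz tone in noise
  a <- scan(test_path("fixtures", "coh_a.txt"), quiet = TRUE)
  b <- scan(test_path("fixtures", "coh_b.txt"), quiet = TRUE)
  ref <- scan(test_path("fixtures", "coh_C.txt"), quiet = TRUE)
  co <- ms_coherence(a, b, 200)
  expect_lt(max(abs(co$values - ref)), 1e-10)
  expect_gt(co$values[co$freqs == 20], 0.99)
})

test_that("coherence equals the brute-force periodogram oracle", {
  set.seed(7)
  for (rep in 1:3) {
    x <- rnorm(200)
    y <- 0.5 * x + rnorm(200)
    mine <- ms_coherence(x, y, 200)
    ora <- oracle_coherence(x, y, 200)
    expect_lt(max(abs(mine$values - ora$values)), 1e-10)
    expect_equal(mine$freqs, ora$freqs)
  }
})

test_that("coherence of a delayed shared tone is high and delay-invariant", {
  n <- 1000; fs <- 200
  tone <- sin(2 * pi * 20 * (0:(n - 1)) / fs)
  set.seed(3)
  x <- tone + 0.2 * rnorm(n)
  vals <- sapply(c(0, 3, 11), function(d) {
    y <- c(tail(tone, d), head(tone, n - d)) + 0.2 * rnorm(n)
    co <- ms_coherence(x, y, fs)
    co$values[co$freqs == 20]
  })
  expect_true(all(vals > 0.9))
  expect_lt(diff(range(vals)), 0.05)
})

test_that("independent white noise sits near the 1/L bias floor", {
  # 3 averaged segments per 1-s epoch -> floor ~ 1/3; Monte-Carlo mean
  set.seed(42)
  floors <- replicate(300, {
    co <- ms_coherence(rnorm(200), rnorm(200), 200)
    mean(co$values)
  })
  expect_lt(abs(mean(floors) - 1 / 3), 1 / 3 * 0.2)
})

test_that("zero-variance input is flagged undefined, not NaN", {
  co <- ms_coherence(rep(1, 200), rnorm(200), 200)
  expect_true(co$undefined)
  expect_true(all(is.na(co$values)))
})

test_that("epoching follows floor(duration/epoch_len)", {
  rec <- list(fs = 200, data = matrix(rnorm(10 * 36000), nrow = 10))
  expect_length(epoch_signal(rec, 1), 180L)
  rec2 <- list(fs = 200, data = matrix(rnorm(2 * 1100), nrow = 2))
  eps <- epoch_signal(rec2, 1)
  expect_length(eps, 5L)   # 100 trailing samples dropped
  expect_equal(ncol(eps[[1]]), 200L)
  rec3 <- list(fs = 200, data = matrix(rnorm(2000), nrow = 1))
  expect_length(epoch_signal(rec3, 10), 1L)
  expect_error(epoch_signal(rec3, 11), "longer than recording")
})

test_that("broadband summary averages the in-band bins", {
  spec <- list(freqs = seq(0, 100, by = 2), values = rep(0.6, 51))
  expect_equal(broadband_coherence(spec, c(0.5, 80)), 0.6)
  # single-bin band returns that bin
  spec$values[11] <- 0.123   # 20 Hz
  expect_equal(broadband_coherence(spec, c(20, 20)), 0.123)
  # linear ramp: mean over the selected grid
  ramp <- list(freqs = seq(0, 100, by = 2), values = seq(0, 1, length.out = 51))
  sel <- ramp$freqs >= 0.5 & ramp$freqs <= 80
  expect_equal(broadband_coherence(ramp, c(0.5, 80)), mean(ramp$values[sel]))
  expect_error(broadband_coherence(spec, c(98.5, 99.5)), "no frequency bins")
})

test_that("pairwise matrix is symmetric, unit-diagonal and in range", {
  set.seed(5)
  epoch <- matrix(rnorm(10 * 200), nrow = 10)
  m <- pairwise_matrix(epoch, 200)$matrix
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 10))
  expect_true(all(m >= 0 & m <= 1))
  # identical rows -> all ones
  same <- matrix(rep(rnorm(200), each = 10), nrow = 10, byrow = FALSE)
  same <- matrix(rep(rnorm(200), 10), nrow = 10, byrow = TRUE)
  m1 <- pairwise_matrix(same, 200)$matrix
  expect_true(all(abs(m1 - 1) < 1e-9))
})

test_that("pairwise matrix agrees with per-pair ms_coherence calls", {
  set.seed(6)
  epoch <- matrix(rnorm(10 * 200), nrow = 10)
  m <- pairwise_matrix(epoch, 200)$matrix
  for (pr in list(c(1, 2), c(3, 9), c(5, 10))) {
    co <- ms_coherence(epoch[pr[1], ], epoch[pr[2], ], 200)
    expect_equal(m[pr[1], pr[2]], broadband_coherence(co), tolerance = 1e-12)
  }
})

test_that("degree of connectivity sums the nine off-diagonal entries", {
  ones <- matrix(1, 10, 10, dimnames = list(roi_labels(), roi_labels()))
  expect_equal(degree_of_connectivity(ones, "LF"), 9)
  eye <- diag(10); dimnames(eye) <- dimnames(ones)
  expect_equal(degree_of_connectivity(eye, "RT"), 0)
  m <- matrix(0.3, 10, 10, dimnames = dimnames(ones)); diag(m) <- 1
  expect_equal(degree_of_connectivity(m, "LO"), 2.7)
  expect_error(degree_of_connectivity(m, "XX"), "unknown ROI")
})
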