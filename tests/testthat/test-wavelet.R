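test_that("WPD coefficients match the reference transform on a fixture", {
  # coefficients frozen from PyWavelets (db4, mode="symmetric",
  # frequency-ordered nodes) on a 64-sample Gaussian fixture
  x <- scan(test_path("fixtures", "wpd_x.txt"), quiet = TRUE)
  oracle <- jsonlite::read_json(test_path("fixtures", "wpd_oracle.json"),
                                simplifyVector = TRUE)
  nodes <- wpd_decompose(x, fs = 200, max_level = 3)
  expect_length(nodes, 14L)
  for (nd in nodes) {
    key <- paste0("L", nd$level, "_", nd$path)
    expect_true(key %in% names(oracle))
    expect_lt(max(abs(nd$coefficients - oracle[[key]])), 1e-12)
  }
  ref_feats <- c(1.014423458817305, 1.31518409094551, 0.882213109891534,
                 1.306139644888515, 1.254614232577173, 1.282568676721245,
                 0.861335308993846, 0.880674692821077, 1.397744273691449,
                 0.623189024382096, 1.054652331663678, 1.107654059268023,
                 0.816531056288004, 1.350808541352521)
  expect_equal(unname(extract_features(x, fs = 200)), ref_feats,
               tolerance = 1e-12)
})

test_that("node bands tile 0-100 Hz in frequency order", {
  tab <- wpd_band_table(200, 3)
  expect_equal(nrow(tab), 14L)
  expect_equal(tab$band_hi[tab$level == 1], c(50, 100))
  expect_equal(tab$band_lo[tab$level == 2], c(0, 25, 50, 75))
  expect_equal(tab$band_hi[tab$level == 3], seq(12.5, 100, by = 12.5))
  expect_true("L3_37.5-50Hz" %in% tab$label)
  # each level tiles the full half-band contiguously
  for (l in 1:3) {
    sub <- tab[tab$level == l, ]
    expect_equal(sub$band_lo[-1], sub$band_hi[-nrow(sub)])
  }
})

test_that("periodic-mode decomposition conserves energy per level", {
  set.seed(10)
  x <- rnorm(256)
  nodes <- wpd_decompose(x, fs = 200, mode = "periodic")
  for (l in 1:3) {
    e <- sum(vapply(nodes[vapply(nodes, `[[`, 0, "level") == l],
                    function(nd) sum(nd$coefficients^2), numeric(1)))
    expect_equal(e, sum(x^2), tolerance = 1e-6)
  }
})

test_that("approximate derivative is the first difference", {
  expect_equal(approx_derivative(c(1, 3, 6)), c(2, 3))
  expect_equal(approx_derivative(rep(5, 10)), rep(0, 9))
  expect_equal(approx_derivative(seq(0, 2, by = 0.5)), rep(0.5, 4))
  expect_error(approx_derivative(1), "at least 2")
})

test_that("features are non-negative, 14-dim, zero for silence, linear", {
  z <- extract_features(rep(0, 2000))
  expect_length(z, 14L)
  expect_true(all(z == 0))
  set.seed(2)
  x <- rnorm(2000)
  f1 <- extract_features(x)
  expect_true(all(f1 > 0))
  f3 <- extract_features(3.5 * x)
  expect_equal(f3, 3.5 * f1, tolerance = 1e-9)
})

test_that("a 40 Hz tone dominates the matching nodes of each level", {
  tone <- sin(2 * pi * 40 * (0:1999) / 200)
  f <- extract_features(tone)
  l2 <- f[grep("^L2_", names(f))]
  expect_equal(names(which.max(l2)), "L2_25-50Hz")
  l3 <- f[grep("^L3_", names(f))]
  expect_equal(names(which.max(l3)), "L3_37.5-50Hz")
})

test_that("preprocessing removes out-of-band content", {
  # 150 Hz tone sampled at 1000 Hz is eliminated by anti-alias decimation
  t <- (1:10000) / 1000
  tone <- sin(2 * pi * 150 * t)
  y <- preprocess(tone, 1000)
  expect_length(y, 2000L)
  expect_lt(stats::sd(y) / stats::sd(tone), 0.1)  # > 20 dB attenuation
  # DC offset removed by the 0.1 Hz high-pass side
  set.seed(4)
  d <- preprocess(rnorm(2000) + 10, 200)
  expect_lt(abs(mean(d)), 0.1)
  expect_error(preprocess(rnorm(100), 100), "below target")
  expect_error(preprocess(rnorm(5), 200), "warm-up")
  expect_error(preprocess(rnorm(1000), 300), "integer multiple")
})

test_that("feature segmentation yields 18 ten-second epochs at 180 s", {
  rec <- list(fs = 200, data = matrix(rnorm(36000), nrow = 1))
  expect_length(segment_for_features(rec), 18L)
  rec2 <- list(fs = 200, data = matrix(rnorm(5000), nrow = 1))
  expect_length(segment_for_features(rec2), 2L)  # 25 s -> 2, remainder dropped
})

test_that("feature datasets have the right shape and metadata", {
  cohort <- tiny_cohort()
  coh <- tiny_coh()
  part <- partition_rois(connectivity_stats(coh), pair_deltas(coh))
  fd <- build_feature_dataset(cohort, part, "hyper", "mean")
  expect_equal(ncol(fd$x), 14L)
  expect_equal(nrow(fd$x), 8L * 3L)   # 8 subjects x 3 ten-second epochs
  expect_equal(sum(fd$class_label == "HC"), 12L)
  fc <- build_feature_dataset(cohort, part, "hyper", "concat")
  expect_equal(ncol(fc$x), 70L)       # 5 ROIs x 14
  fa <- build_feature_dataset(cohort, group = "all")
  expect_length(fa$rois, 10L)
})

test_that("PCA axes come from training rows only", {
  set.seed(8)
  train <- matrix(rnorm(200), ncol = 4)
  test <- matrix(rnorm(40), ncol = 4)
  a <- pca_reduce(train, test, k = 2)
  b <- pca_reduce(train, test + 100, k = 2)   # test rows must not matter
  expect_equal(a$rotation, b$rotation)
  expect_equal(a$train, b$train)
})

test_that("PCA recovers planted low-rank structure", {
  set.seed(9)
  n <- 300
  factors <- matrix(rnorm(n * 2), ncol = 2)
  load <- matrix(rnorm(2 * 10), nrow = 2)
  x <- factors %*% load + 0.05 * matrix(rnorm(n * 10), ncol = 10)
  r <- pca_reduce(x, k = 2)
  expect_gt(sum(r$explained_variance_ratio), 0.95)
  # rank-1 data: a single component explains everything
  x1 <- matrix(rnorm(n), ncol = 1) %*% t(rnorm(6))
  r1 <- pca_reduce(x1, k = 1)
  expect_equal(sum(r1$explained_variance_ratio), 1, tolerance = 1e-9)
  # full-k projection is a lossless rotation
  rf <- pca_reduce(x, x, k = 10)
  d0 <- as.matrix(dist(x))
  d1 <- as.matrix(dist(rf$test))
  expect_equal(d0, d1, tolerance = 1e-9)
  expect_error(pca_reduce(x, k = 11), "k must be")
})
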