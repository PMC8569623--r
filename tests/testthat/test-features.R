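test_that("windowing tiles the signal with the expected starts", {
  set.seed(71)
  x <- matrix(rnorm(3 * 1000), 3, 1000)
  w <- window_signal(x, 200, 100)
  expect_length(w, 9)
  expect_equal(sapply(w, attr, "t0"), seq(0, 800, 100))
  w1 <- window_signal(x, 1000, 100)
  expect_length(w1, 1)
  expect_equal(unclass(w1[[1]]), x, ignore_attr = TRUE)
  # non-overlapping windows concatenate back to the leading samples
  wnl <- window_signal(x, 300, 300)
  expect_equal(do.call(cbind, lapply(wnl, unclass)),
               x[, 1:900], ignore_attr = TRUE)
  expect_error(window_signal(x, 2000, 100), "exceeds")
})

test_that("time and spectral features match brute-force oracles", {
  expect_equal(mean_absolute_value(rep(-3.2, 10)), 3.2)
  expect_equal(mean_absolute_value(c(1, -1, 2, -2)), 1.5)
  set.seed(73)
  for (i in 1:5) {
    x <- rnorm(1000)
    # elementwise loop oracles
    mav <- 0; for (v in x) mav <- mav + abs(v)
    expect_equal(mean_absolute_value(x), mav / 1000, tolerance = 1e-12)
    ps <- power_spectrum(x, 1000)
    expect_equal(sum(ps$P), mean(x^2), tolerance = 1e-6)  # Parseval
    # median frequency: exhaustive cumulative scan
    acc <- 0; j <- 0
    repeat {
      j <- j + 1
      acc <- acc + ps$P[j]
      if (acc >= sum(ps$P) / 2) break
    }
    expect_identical(median_frequency(ps$P, ps$freqs), ps$freqs[j])
    mnp <- 0; for (v in ps$P) mnp <- mnp + v
    expect_equal(mean_power(ps$P), mnp / length(ps$P), tolerance = 1e-12)
  }
})

test_that("the periodogram concentrates a bin-aligned sine in one bin", {
  fs <- 1000; K <- 500
  t <- (0:(K - 1)) / fs
  x <- sin(2 * pi * 40 * t)  # exactly bin 40 Hz at df = 2 Hz
  ps <- power_spectrum(x, fs)
  expect_gte(ps$P[which.min(abs(ps$freqs - 40))] / sum(ps$P), 0.99)
  z <- power_spectrum(numeric(64), fs)
  expect_true(all(z$P == 0))
})

test_that("the frequency ratio follows the band power ratio", {
  freqs <- 0:100
  P <- rep(1, 101)
  expect_equal(frequency_ratio(P, freqs, 10, 19, 60, 69), 1)
  P2 <- c(rep(1, 50), rep(0, 51))
  expect_warning(fr <- frequency_ratio(P2, freqs, 0, 40, 60, 100), "Inf")
  expect_identical(fr, Inf)
  # two tones, one per band: FR ~ a^2 / b^2
  fs <- 1000; t <- (0:999) / fs
  a <- 1.5; b <- 0.7
  x <- a * sin(2 * pi * 30 * t) + b * sin(2 * pi * 200 * t)
  ps <- power_spectrum(x, fs)
  fr <- frequency_ratio(ps$P, ps$freqs, 20, 45, 95, 450)
  expect_lt(abs(fr - a^2 / b^2) / (a^2 / b^2), 0.05)
})

test_that("median frequency handles flat and point-mass spectra", {
  M <- 11
  expect_equal(median_frequency(rep(2, M), 0:(M - 1)), ceiling(M / 2) - 1)
  P <- numeric(8); P[4] <- 5
  expect_equal(median_frequency(P, seq(0, 70, 10)), 30)
  expect_error(median_frequency(numeric(8), seq(0, 70, 10)), "all-zero")
  expect_equal(mean_power(rep(3, 7)), 3)
  expect_equal(mean_power(c(5, rep(0, 9))), 0.5)
})

test_that("feature scale equivariances hold", {
  set.seed(79)
  x <- rnorm(512)
  a <- 2.83
  ps1 <- power_spectrum(x, 1000)
  ps2 <- power_spectrum(a * x, 1000)
  expect_equal(mean_absolute_value(a * x), a * mean_absolute_value(x),
               tolerance = 1e-9)
  expect_equal(median_frequency(ps2$P, ps2$freqs),
               median_frequency(ps1$P, ps1$freqs), tolerance = 1e-9)
  expect_equal(frequency_ratio(ps2$P, ps2$freqs, 20, 45, 95, 450),
               frequency_ratio(ps1$P, ps1$freqs, 20, 45, 95, 450),
               tolerance = 1e-9)
  expect_equal(mean_power(ps2$P), a^2 * mean_power(ps1$P), tolerance = 1e-9)
})

test_that("feature images compose the four standalone features per channel", {
  set.seed(83)
  x <- matrix(rnorm(4 * 200), 4, 200)
  w <- window_signal(x, 200, 200)[[1]]
  img <- build_feature_image(w, fs = 1000)
  expect_equal(dim(img), c(4, 4))
  for (c in 1:4) {
    ps <- power_spectrum(x[c, ], 1000)
    expect_equal(unname(img["MAV", c]), mean_absolute_value(x[c, ]))
    expect_equal(unname(img["FR", c]),
                 frequency_ratio(ps$P, ps$freqs, 20, 45, 95, 450))
    expect_equal(unname(img["MDF", c]), median_frequency(ps$P, ps$freqs))
    expect_equal(unname(img["MNP", c]), mean_power(ps$P))
  }
  expect_true(all(img["MDF", ] >= 0 & img["MDF", ] <= 500))
  # determinism and constant-signal MAV row
  expect_identical(img, build_feature_image(w, fs = 1000))
  const <- matrix(c(rep(-1.5, 100), rep(2, 100)), 2, 100, byrow = TRUE)
  img2 <- suppressWarnings(build_feature_image(const, fs = 1000))
  expect_equal(unname(img2["MAV", ]), c(1.5, 2))
})

test_that("patch decomposition partitions and reassembles exactly", {
  set.seed(89)
  img <- matrix(rnorm(8 * 200), 8, 200)
  p1 <- decompose_patches(img, 1)
  expect_identical(p1[[1]], img)
  p4 <- decompose_patches(img, 4)
  expect_length(p4, 4)
  expect_true(all(sapply(p4, dim)[2, ] == 50))
  expect_identical(do.call(cbind, p4), img)
  expect_error(decompose_patches(img, 3), "divisible")
})

test_that("mutual-information ranking orders informative features last", {
  set.seed(97)
  n <- 2000
  labels <- sample(0:3, n, replace = TRUE)
  deterministic <- labels * 1.0              # 1-to-1 encoding of the label
  noise <- runif(n)                          # independent of labels
  informative <- labels + rnorm(n, 0, 0.3)
  feats <- cbind(noise, informative, deterministic)
  r <- rank_features_mutual_information(feats, labels)
  expect_equal(r$elimination_order[3], 3)    # deterministic column survives
  expect_equal(r$elimination_order[1], 1)    # noise column goes first
  expect_lte(r$mi[1], 0.05)
  expect_gt(r$mi[3], 1.9)                    # ~2 bits for 4 balanced classes
  # two identical informative columns + noise: noise eliminated first
  feats2 <- cbind(informative, informative, noise)
  r2 <- rank_features_mutual_information(feats2, labels)
  expect_equal(r2$elimination_order[1], 3)
  # constant column has MI zero and is eliminated first (index tie-break)
  feats3 <- cbind(rep(1, n), informative, rep(2, n))
  r3 <- rank_features_mutual_information(feats3, labels)
  expect_equal(r3$mi[c(1, 3)], c(0, 0))
  expect_equal(r3$elimination_order[1:2], c(1, 3))
  expect_error(rank_features_mutual_information(feats[, 1, drop = FALSE],
                                                labels), "2 features")
})
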