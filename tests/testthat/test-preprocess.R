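test_that("zero-energy signals yield no active segments", {
  x <- matrix(0.3, 4, 1000)  # constant channels equal to their baselines
  segs <- detect_active_segments(x, baseline_means = rep(0.3, 4), fs = 1000)
  expect_equal(nrow(segs), 0)
})

test_that("the threshold is the stated fraction of the peak energy", {
  # single channel, zero baseline: S(n) is the smoothed squared signal; a
  # long strong plateau and a weaker one at exactly 20% of its energy are
  # separated by detecting at th_fraction just below/above 0.2
  fs <- 1000
  x <- numeric(3000)
  x[501:1000] <- 1
  x[2001:2500] <- sqrt(0.2)
  xm <- matrix(x, 1)
  lo <- detect_active_segments(xm, baseline_means = 0, th_fraction = 0.19,
                               fs = fs)
  hi <- detect_active_segments(xm, baseline_means = 0, th_fraction = 0.21,
                               fs = fs)
  expect_equal(nrow(lo), 2)
  expect_equal(nrow(hi), 1)
  # returned sorted and non-overlapping
  expect_true(all(diff(lo$start) > 0))
  expect_true(all(lo$end[-nrow(lo)] <= lo$start[-1]))
})

test_that("segment detection recovers the true action span of a burst", {
  cfg <- noise_config(snr_db = 15, line_amp = 0, seed = 29)
  rec <- generate_recording(2, duration_s = 2, fs = 1000, cfg = cfg,
                            n_channels = 16)
  base <- rowMeans(rec$semg[, 1:500])
  segs <- detect_active_segments(rec, baseline_means = base)
  expect_equal(nrow(segs), 1)
  true_span <- range(which(rec$envelope > 0))
  iou <- interval_iou(segs$start, segs$end, true_span[1] - 1, true_span[2])
  expect_gte(iou, 0.9)
})

test_that("segment detection is invariant to a common channel offset", {
  cfg <- noise_config(snr_db = 12, line_amp = 0, seed = 31)
  rec <- generate_recording(1, duration_s = 2, fs = 1000, cfg = cfg,
                            n_channels = 4)
  base <- rowMeans(rec$semg[, 1:500])
  s1 <- detect_active_segments(rec, baseline_means = base)
  shift <- c(1, -2, 0.5, 3)
  rec2 <- rec
  rec2$semg <- rec$semg + shift
  s2 <- detect_active_segments(rec2, baseline_means = base + shift)
  expect_equal(s1, s2)
})

test_that("channel-count mismatch raises a dimension error", {
  x <- matrix(rnorm(200), 2, 100)
  expect_error(detect_active_segments(x, baseline_means = rep(0, 3),
                                      fs = 100), "channels")
})

test_that("comb filter notches the mains fundamental and harmonics", {
  # designed magnitude response
  expect_lt(20 * log10(comb_response(50, 1000)), -20)
  expect_lt(20 * log10(comb_response(100, 1000)), -20)
  expect_gt(20 * log10(comb_response(75, 1000)), -3)
  expect_gt(20 * log10(comb_response(10, 1000)), -3)
  # steady-state attenuation of a pure 50 Hz sine
  t <- (0:3999) / 1000
  x <- sin(2 * pi * 50 * t)
  y <- comb_filter(x, 1000)
  rms_out <- sqrt(mean(y[2001:4000]^2))
  expect_lt(20 * log10(rms_out / sqrt(0.5)), -20)
  # mid-band tone passes
  x75 <- sin(2 * pi * 75 * t)
  y75 <- comb_filter(x75, 1000)
  expect_gt(20 * log10(sqrt(mean(y75[2001:4000]^2)) / sqrt(0.5)), -3)
})

test_that("comb filter is linear, deterministic, shape-preserving", {
  set.seed(41)
  x <- matrix(rnorm(2 * 600), 2, 600)
  y1 <- comb_filter(x, 1000)
  y2 <- comb_filter(3.7 * x, 1000)
  expect_equal(dim(y1), dim(x))
  expect_lt(max(abs(y2 - 3.7 * y1)), 1e-10)
  expect_identical(y1, comb_filter(x, 1000))
  expect_error(comb_filter(x, 1000, f0 = 600), "Nyquist")
})

test_that("wavelet decomposition reconstructs exactly without thresholding", {
  set.seed(43)
  x <- rnorm(512)
  dec <- wavelet_dec(x, 5)
  expect_lt(max(abs(wavelet_rec(dec) - x)), 1e-8)
  # matrix form, and via wavelet_denoise with thresholding disabled
  xm <- matrix(rnorm(2 * 300), 2, 300)  # length not a power of two
  out <- wavelet_denoise(xm, denoise_config(threshold_rule = "none"))
  expect_lt(max(abs(out - xm)), 1e-8)
  expect_error(wavelet_dec(rnorm(100), 3), "divisible")
  expect_error(denoise_config(basis = "db4"), "unknown wavelet")
})

test_that("hard threshold kernel zeroes small coefficients only", {
  expect_equal(hard_threshold(c(0.5, -2, 0.1), 1), c(0, -2, 0))
  w <- c(-3, -1, 0, 1, 3)
  expect_equal(hard_threshold(w, 1), c(-3, -1, 0, 1, 3) * c(1, 1, 0, 1, 1))
})

test_that("wavelet denoising improves the SNR of noisy smooth bursts", {
  t <- (0:2047) / 1000
  clean <- sin(2 * pi * 8 * t) * exp(-((t - 1) / 0.3)^2)
  improved <- logical(10)
  for (i in 1:10) {
    set.seed(100 + i)
    noise <- rnorm(length(t), 0, sqrt(mean(clean^2)) / 10^(5 / 20))
    noisy <- clean + noise
    den <- wavelet_denoise(noisy)
    snr_in <- 10 * log10(sum(clean^2) / sum((noisy - clean)^2))
    snr_out <- 10 * log10(sum(clean^2) / sum((den - clean)^2))
    improved[i] <- snr_out > snr_in
  }
  expect_true(all(improved))
})

test_that("re-denoising an already denoised signal changes nothing new", {
  set.seed(59)
  t <- (0:1023) / 1000
  x <- sin(2 * pi * 5 * t) + rnorm(1024, 0, 0.3)
  once <- wavelet_denoise(x, denoise_config(level = 4))
  # fix the thresholds implied by the first pass: thresholding the already
  # thresholded coefficients at the same lambda removes nothing
  dec <- wavelet_dec(once, 4)
  d1 <- dec$details[[1]]
  sigma <- stats::mad(d1, constant = 1) / 0.6745
  for (l in 1:4) {
    d <- dec$details[[l]]
    lam <- sigma * sure_threshold(d / max(sigma, .Machine$double.eps))
    kept <- d[abs(d) >= lam]
    expect_equal(hard_threshold(kept, lam), kept, tolerance = 1e-6)
  }
})

test_that("rest-only recordings pass the full chain with no segments", {
  cfg <- noise_config(snr_db = -Inf, seed = 61)
  rec <- generate_recording("rest", duration_s = 1, fs = 1000, cfg = cfg,
                            n_channels = 4)
  clean <- preprocess_recording(rec)
  base <- rowMeans(clean$semg[, 1:500])
  segs <- detect_active_segments(clean, baseline_means = base)
  # no action: the energy trace is all baseline noise, so either nothing
  # exceeds the 15% line for 100 ms, or detection returns a spurious run
  # covering most of the record; assert the former
  expect_equal(nrow(segs), 0)
})
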