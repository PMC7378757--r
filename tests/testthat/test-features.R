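test_that("moment statistics match direct evaluation and the degenerate convention", {
  expect_equal(spatial_statistics(rep(2.5, 101)),
               c(mean = 2.5, var = 0, sd = 0, rms = 2.5, skew = 0, kurt = 0))
  expect_equal(spatial_statistics(c(1, 2, 3)),
               c(mean = 2, var = 2 / 3, sd = 0.816496580927726,
                 rms = 2.160246899469287, skew = 0, kurt = 1.5),
               tolerance = 1e-12)
  expect_error(spatial_statistics(1), "at least 2")
})

test_that("moment statistics agree with brute-force summation to 1e-12", {
  set.seed(101)
  for (i in 1:25) {
    x <- stats::rnorm(sample(2:200, 1), mean = stats::runif(1, -5, 5),
                      sd = stats::runif(1, 0, 3))
    expect_equal(spatial_statistics(x), brute_moments(x), tolerance = 1e-12)
  }
})

test_that("kurtosis of a large normal sample approaches 3", {
  set.seed(7)
  x <- stats::rnorm(1e5)
  expect_equal(unname(spatial_statistics(x)["kurt"]), 3, tolerance = 0.05 / 3)
})

test_that("autocorrelation features recover a sinusoid's period", {
  fs <- 50
  t <- (0:100) / fs
  out <- autocorrelation_features(sin(2 * pi * 5 * t), fs)
  expect_equal(unname(out["acf_main_pos"]), 0)
  expect_equal(unname(out["acf_peak2_pos"]), 0.20)
  expect_gt(unname(out["acf_peak2_amp"]), 0.7)
  # zero-variance channel: degenerate convention
  expect_equal(unname(autocorrelation_features(numeric(101), fs)), c(0, 0, 0))
})

test_that("autocorrelation second peak sits within one lag of the period, 2-12 Hz", {
  fs <- 50
  t <- (0:100) / fs
  for (f in 2:12) {
    out <- autocorrelation_features(sin(2 * pi * f * t + 0.3), fs)
    lag2 <- out["acf_peak2_pos"] * fs
    # at 101 samples, non-integer sample periods can align better at a small
    # multiple of the period; the detected peak is within one lag of one
    expect_lte(min(abs(lag2 - (1:3) * fs / f)), 1)
  }
  # frequencies with an integer sample period recover it within one lag
  for (f in c(2, 5, 10)) {
    out <- autocorrelation_features(sin(2 * pi * f * t + 0.3), fs)
    expect_lte(abs(out["acf_peak2_pos"] * fs - fs / f), 1)
  }
})

test_that("white-noise autocorrelation has no strong secondary peak", {
  fs <- 50
  ok <- 0
  for (s in 1:50) {
    set.seed(s)
    out <- autocorrelation_features(stats::rnorm(101), fs)
    if (out["acf_peak2_amp"] < 0.5) ok <- ok + 1
  }
  expect_gte(ok, 49)
})

test_that("Welch PSD reproduces reference values for a 5 Hz tone plus offset", {
  # expected values frozen from an independent implementation of the same
  # 8-section / 50%-overlap / periodic-Hamming / density-scaled estimator
  fs <- 50
  t <- (0:100) / fs
  psd <- welch_psd(sin(2 * pi * 5 * t) + 0.5, fs)
  expect_equal(psd$frequencies[1], 0)
  expect_equal(psd$frequencies[length(psd$frequencies)], 25)
  expect_equal(psd$frequencies[1:3], c(0, 2.2727272727, 4.5454545455),
               tolerance = 1e-9)
  expect_equal(psd$densities[1:5],
               c(8.0856798188e-02, 4.4402613186e-02, 1.5150752295e-01,
                 5.5791048545e-02, 1.0114094794e-04),
               tolerance = 1e-8)
  # spectral mass concentrates within one grid bin of the tone
  expect_lt(abs(psd$frequencies[which.max(psd$densities)] - 5),
            diff(psd$frequencies[1:2]))
})

test_that("Welch PSD of unit-variance white noise integrates to ~1", {
  set.seed(12)
  x <- stats::rnorm(4096)
  psd <- welch_psd(x, fs = 50)
  f <- psd$frequencies; p <- psd$densities
  integral <- sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
  expect_equal(integral, 1, tolerance = 0.2)
})

test_that("Welch PSD handles degenerate and too-short inputs", {
  psd <- welch_psd(numeric(101), 50)
  expect_true(all(psd$densities == 0))
  expect_true(all(psd$densities >= 0))
  expect_error(welch_psd(stats::rnorm(8), 50), "too short")
})

test_that("spectral peak features order peaks by amplitude and zero-pad", {
  f <- seq(0, 25, by = 0.25)
  bump <- function(f0, a) a * exp(-((f - f0) / 0.4)^2)
  psd <- structure(list(frequencies = f, densities = bump(3, 1) + bump(8, 0.5)),
                   class = "psd_estimate")
  out <- spectral_peak_features(psd)
  expect_equal(unname(out["psd_peak1_pos"]), 3, tolerance = 0.26)
  expect_equal(unname(out["psd_peak2_pos"]), 8, tolerance = 0.26)
  expect_gte(out["psd_peak1_amp"], out["psd_peak2_amp"])
  zero <- structure(list(frequencies = f, densities = numeric(length(f))),
                    class = "psd_estimate")
  expect_equal(unname(spectral_peak_features(zero)), numeric(12))
})

test_that("band powers integrate the PSD over half-open bands", {
  f <- seq(0, 25, by = 0.25)
  zero <- structure(list(frequencies = f, densities = numeric(length(f))),
                    class = "psd_estimate")
  expect_equal(unname(band_powers(zero)), c(0, 0, 0))
  flat <- structure(list(frequencies = f, densities = rep(1, length(f))),
                    class = "psd_estimate")
  expect_equal(unname(band_powers(flat)), c(4.5, 5, 10))
  # sinusoid power identity: amplitude A carries A^2/2 in its band
  fs <- 50; A <- 2
  x <- A * sin(2 * pi * 7 * (0:4095) / fs)
  bp <- band_powers(welch_psd(x, fs))
  expect_equal(unname(bp["bandpower_5_10"]), A^2 / 2, tolerance = 0.1)
  expect_lt(bp["bandpower_0.5_5"], 0.05 * bp["bandpower_5_10"])
  expect_lt(bp["bandpower_10_20"], 0.05 * bp["bandpower_5_10"])
  short <- structure(list(frequencies = seq(0, 15, 0.5),
                          densities = rep(1, 31)), class = "psd_estimate")
  expect_error(band_powers(short), "cover")
})

test_that("the event feature vector has 72 values in fixed interleaved order", {
  nm <- feature_names()
  expect_length(nm, 72)
  expect_false(any(duplicated(nm)))
  # 27 spatial (6 moments + 3 autocorrelation per axis), 45 frequency
  spatial <- grepl("^(mean|var|sd|rms|skew|kurt|acf_)", nm)
  expect_equal(sum(spatial), 27)
  expect_equal(sum(!spatial), 45)
  # ordering sentinel: constant channels 1/2/3 land in slots 1..3
  seg <- make_segment(rep(1, 101), rep(2, 101), rep(3, 101))
  fv <- extract_event_features(seg)
  expect_equal(names(fv)[1:6],
               c("mean.x", "mean.y", "mean.z", "var.x", "var.y", "var.z"))
  expect_equal(unname(fv[1:3]), c(1, 2, 3))
  # determinism: identical segments give bit-identical vectors
  expect_identical(fv, extract_event_features(seg))
})

test_that("variance, rms, PSD amplitudes and band powers are non-negative", {
  set.seed(99)
  for (i in 1:5) {
    seg <- make_segment(stats::rnorm(101), stats::rnorm(101), stats::rnorm(101))
    fv <- extract_event_features(seg)
    nn <- grepl("^(var|sd|rms|psd_peak[0-9]_amp|bandpower)", names(fv))
    expect_true(all(fv[nn] >= 0))
  }
})

test_that("total-acceleration features are the magnitude extrema", {
  seg <- make_segment(numeric(101), numeric(101), rep(1, 101))
  expect_equal(total_acceleration_features(seg),
               c(total_acc_min = 1, total_acc_max = 1))
  x <- numeric(101); y <- numeric(101)
  x[51] <- 3; y[51] <- 4
  seg2 <- make_segment(x, y, numeric(101))
  expect_equal(total_acceleration_features(seg2),
               c(total_acc_min = 0, total_acc_max = 5))
  set.seed(5)
  seg3 <- make_segment(stats::rnorm(101), stats::rnorm(101), stats::rnorm(101))
  ta <- total_acceleration_features(seg3)
  expect_lte(ta["total_acc_min"], ta["total_acc_max"])
})
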