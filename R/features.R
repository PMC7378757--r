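#' Spatial-domain moment statistics of one channel
#'
#' The six statistics computed per axis: mean, variance, standard deviation,
#' root-mean-square, skewness and kurtosis. All moments are population
#' normalised (divisor `N`); kurtosis is the raw fourth standardised moment
#' (3 for a normal distribution), not excess. For a degenerate channel with
#' zero standard deviation, skewness and kurtosis are defined as 0.
#'
#' @param channel Numeric vector, length >= 2.
#' @return Named numeric vector `c(mean, var, sd, rms, skew, kurt)`.
#' @export
spatial_statistics <- function(channel) {
  n <- length(channel)
  if (n < 2) stop("channel must contain at least 2 samples")
  mu <- sum(channel) / n
  d <- channel - mu
  v <- sum(d^2) / n
  s <- sqrt(v)
  rms <- sqrt(sum(channel^2) / n)
  if (s > 0) {
    skew <- sum(d^3) / (n * s^3)
    kurt <- sum(d^4) / (n * s^4)
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = mu, var = v, sd = s, rms = rms, skew = skew, kurt = kurt)
}

# Iterative tallest-peak selection.
# y: sequence; candidates: indices eligible as peaks; radius: exclusion
# radius in index units (candidates within +/- radius of an accepted peak are
# discarded). Amplitude ties break towards the smaller index. Returns up to
# n_peaks accepted indices in detection (amplitude-descending) order.
select_peaks <- function(y, candidates, n_peaks, radius) {
  picked <- integer(0)
  while (length(picked) < n_peaks && length(candidates)) {
    best <- candidates[order(-y[candidates], candidates)][1]
    picked <- c(picked, best)
    candidates <- candidates[abs(candidates - best) > radius]
  }
  picked
}

# interior local maxima: strictly above the previous sample, at least equal
# to the next (the first sample of a plateau is kept); endpoints excluded
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
}

#' Autocorrelation peak features of one channel
#'
#' Computes the biased sample autocorrelation over lags `0..N-1`, normalised
#' to 1 at lag 0, then applies iterative tallest-peak detection with an
#' exclusion radius of `max(1, round(0.3 * period * fs))` lags around each
#' accepted peak (the configured period defaults to one sampling interval,
#' `1/fs`, making the radius one lag). Lag 0 is always the main (first
#' detected) peak; the informative outputs are the position and amplitude of
#' the second detected peak. Positions are reported in seconds (`lag/fs`).
#' A zero-variance channel returns `(0, 0, 0)`.
#'
#' @param channel Numeric vector, length >= 2.
#' @param fs Sampling rate, Hz.
#' @param period Reference period used for the exclusion radius, seconds.
#'   Default `1/fs`.
#' @return Named numeric vector
#'   `c(acf_main_pos, acf_peak2_pos, acf_peak2_amp)`.
#' @export
autocorrelation_features <- function(channel, fs, period = 1 / fs) {
  n <- length(channel)
  if (n < 2) stop("channel must contain at least 2 samples")
  out <- c(acf_main_pos = 0, acf_peak2_pos = 0, acf_peak2_amp = 0)
  d <- channel - mean(channel)
  denom <- sum(d^2)
  if (denom <= 0) return(out)
  r <- as.numeric(stats::acf(channel, lag.max = n - 1, type = "correlation",
                             plot = FALSE, demean = TRUE)$acf)
  radius <- max(1L, as.integer(round(0.3 * period * fs)))
  cand <- unique(c(1L, local_maxima(r)))   # lag 0 admitted as a candidate
  picked <- select_peaks(r, cand, 2L, radius)
  if (length(picked) >= 1) out["acf_main_pos"] <- (picked[1] - 1) / fs
  if (length(picked) >= 2) {
    out["acf_peak2_pos"] <- (picked[2] - 1) / fs
    out["acf_peak2_amp"] <- r[picked[2]]
  }
  out
}

#' Welch power-spectral-density estimate
#'
#' One-sided Welch overlapped-segment-averaging PSD with the classic
#' 8-section geometry: section length `floor(N/4.5)`, 50% overlap, periodic
#' Hamming window, density scaling (power per Hz) such that the trapezoidal
#' integral of the PSD over frequency approximates the signal's mean-square
#' power. No detrending is applied, so the DC bin carries the signal mean.
#'
#' @param channel Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param section_length Samples per section; default `floor(N/4.5)`.
#' @param overlap Fractional overlap between sections, default 0.5.
#' @return An object of class `psd_estimate`: fields `frequencies`
#'   (0..fs/2, ascending) and `densities` (same length, >= 0).
#' @export
welch_psd <- function(channel, fs, section_length = NULL, overlap = 0.5) {
  n <- length(channel)
  if (is.null(section_length)) section_length <- floor(n / 4.5)
  L <- as.integer(section_length)
  if (L < 2 || L > n)
    stop("signal too short for the requested Welch section length")
  step <- max(1L, L - as.integer(floor(L * overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  k <- 0:(L - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * k / L)     # periodic Hamming
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- channel[s:(s + L - 1)] * w
    p <- Mod(stats::fft(seg))^2 / scale
    p <- p[1:nf]
    # one-sided: double everything except DC and (for even L) Nyquist
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  structure(list(frequencies = (0:(nf - 1)) * fs / L,
                 densities = acc / length(starts)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("Welch PSD estimate: %d bins, 0..%g Hz (df = %g Hz)\n",
              length(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Spectral peak features of a PSD estimate
#'
#' Iterative tallest-local-maximum selection on the PSD with an exclusion
#' radius of `min_distance` Hz (at least one grid bin) around each accepted
#' peak. Returns the positions (Hz) of the `n_peaks` highest peaks followed
#' by their amplitudes, in amplitude-descending detection order; missing
#' peaks are zero-padded so the output length is fixed.
#'
#' @param psd A `psd_estimate`.
#' @param n_peaks Number of peaks to report. Default 6.
#' @param min_distance Minimum distance between accepted peaks, Hz. When
#'   `NULL`, one frequency bin.
#' @return Named numeric vector of `2 * n_peaks` values:
#'   `psd_peak1_pos .. psd_peakN_pos, psd_peak1_amp .. psd_peakN_amp`.
#' @export
spectral_peak_features <- function(psd, n_peaks = 6, min_distance = NULL) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$frequencies
  p <- psd$densities
  df <- if (length(f) > 1) f[2] - f[1] else 1
  radius <- max(1L, as.integer(round((min_distance %||% df) / df)))
  cand <- local_maxima(p)
  picked <- select_peaks(p, cand, n_peaks, radius)
  pos <- amp <- numeric(n_peaks)
  if (length(picked)) {
    pos[seq_along(picked)] <- f[picked]
    amp[seq_along(picked)] <- p[picked]
  }
  stats::setNames(c(pos, amp),
                  c(paste0("psd_peak", 1:n_peaks, "_pos"),
                    paste0("psd_peak", 1:n_peaks, "_amp")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectral band powers of a PSD estimate
#'
#' Total power in the 0.5-5, 5-10 and 10-20 Hz bands, computed as the
#' trapezoidal integral of the density with linear interpolation at the band
#' edges. Band membership is half-open (`[lo, hi)`): each internal edge
#' belongs to the band on its right, and the edge values enter each
#' integral only through the interpolated trapezoid (a set of measure zero),
#' so no power is double counted.
#'
#' @param psd A `psd_estimate` covering at least 0..20 Hz.
#' @param bands Matrix-like list of band edges; default the three bands
#'   above.
#' @return Named numeric vector of band powers.
#' @export
band_powers <- function(psd, bands = list(c(0.5, 5), c(5, 10), c(10, 20))) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$frequencies
  p <- psd$densities
  if (max(f) < max(vapply(bands, max, 1)))
    stop("PSD must cover the requested bands (fs/2 >= 20 Hz)")
  one <- function(b) {
    lo <- b[1]; hi <- b[2]
    sel <- f > lo & f < hi
    fx <- c(lo, f[sel], hi)
    px <- c(stats::approx(f, p, lo)$y, p[sel], stats::approx(f, p, hi)$y)
    sum(diff(fx) * (px[-length(px)] + px[-1]) / 2)
  }
  vals <- vapply(bands, one, 1)
  names(vals) <- vapply(bands, function(b)
    sprintf("bandpower_%g_%g", b[1], b[2]), "")
  vals
}

#' Names of the 72-value event feature vector
#'
#' 24 features per axis (6 moment statistics, 3 autocorrelation features,
#' 12 spectral peak features, 3 band powers), interleaved across axes as
#' `f1.x, f1.y, f1.z, f2.x, ...`. The order is fixed across events,
#' subjects and runs.
#'
#' @return Character vector of length 72.
#' @export
feature_names <- function() {
  base <- c("mean", "var", "sd", "rms", "skew", "kurt",
            "acf_main_pos", "acf_peak2_pos", "acf_peak2_amp",
            paste0("psd_peak", 1:6, "_pos"), paste0("psd_peak", 1:6, "_amp"),
            "bandpower_0.5_5", "bandpower_5_10", "bandpower_10_20")
  paste(rep(base, each = 3), rep(c("x", "y", "z"), length(base)), sep = ".")
}

#' Extract the 72-value feature vector of one event segment
#'
#' Per axis: the 6 moment statistics, 3 autocorrelation peak features,
#' 12 Welch-PSD spectral peak features (minimum peak distance
#' `0.3 * fs / N` Hz, at least one grid bin) and 3 band powers, assembled in
#' the interleaved axis order `f1.x, f1.y, f1.z, f2.x, ...`.
#'
#' @param segment An `event_segment`.
#' @return Named numeric vector of length 72 (names from [feature_names()]).
#' @export
extract_event_features <- function(segment) {
  stopifnot(inherits(segment, "event_segment"))
  fs <- segment$fs
  n <- nrow(segment$data)
  per_axis <- vapply(1:3, function(c) {
    ch <- segment$data[, c]
    psd <- welch_psd(ch, fs)
    c(spatial_statistics(ch),
      autocorrelation_features(ch, fs),
      spectral_peak_features(psd, min_distance = 0.3 * fs / n),
      band_powers(psd))
  }, numeric(24))
  stats::setNames(as.vector(t(per_axis)), feature_names())
}

#' Total-acceleration baseline features
#'
#' The minimum and maximum of the per-sample Euclidean magnitude
#' `|a| = sqrt(Fx^2 + Fy^2 + Fz^2)` over the segment: the 2-value baseline
#' feature pair used for comparison against the full 72-value set.
#'
#' @param segment An `event_segment`.
#' @return Named numeric vector `c(total_acc_min, total_acc_max)`.
#' @export
total_acceleration_features <- function(segment) {
  stopifnot(inherits(segment, "event_segment"))
  mag <- acceleration_magnitude(segment$data)
  c(total_acc_min = min(mag), total_acc_max = max(mag))
}

#' Build the per-event feature table of a study
#'
#' @param segments List of `event_segment` (e.g. from [segment_study()]).
#' @param type `"full"` for the 72-value vector, `"total_acceleration"` for
#'   the 2-value magnitude baseline.
#' @return data.frame with columns `subject`, `label`, then one column per
#'   feature, one row per event.
#' @export
extract_study_features <- function(segments, type = c("full", "total_acceleration")) {
  type <- match.arg(type)
  fun <- if (type == "full") extract_event_features else total_acceleration_features
  mat <- t(vapply(segments, fun, fun(segments[[1]])))
  out <- data.frame(
    subject = vapply(segments, function(s) s$subject_id, segments[[1]]$subject_id),
    label = vapply(segments, function(s) s$label, ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(mat, check.names = FALSE))
}
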