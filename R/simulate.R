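#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults reproduce the
#' emulated study design: 35 subjects, each performing the 15-event roster
#' (6 ADL + 9 falls) in one continuous 50 Hz recording, with rests of 5-6 s
#' drawn uniformly between events.
#'
#' @param n_subjects Number of subjects (>= 1). Default 35.
#' @param events List of `activity_template` objects performed, in order, by
#'   every subject. Default [default_templates()].
#' @param rest_gap Length-2 numeric: uniform bounds (seconds) of the rest
#'   between consecutive events. Lower bound must be >= 2 s so that the 2 s
#'   peak-centred segments cannot overlap. Default `c(5, 6)`.
#' @param sampling_rate Sampling rate in Hz. Default 50.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise, in g.
#'   Default 0.03.
#' @param subject_variability Standard deviation of the per-subject
#'   log-normal multiplicative amplitude jitter (one factor per subject).
#'   Default 0.1.
#' @param edge_pad Rest padding at both ends of the recording, seconds.
#'   Default 2.5.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   sample streams bit-identically.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 35, events = default_templates(),
                              rest_gap = c(5, 6), sampling_rate = 50,
                              noise_sd = 0.03, subject_variability = 0.1,
                              edge_pad = 2.5, seed = 20200706L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("configuration error: n_subjects must be >= 1")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("configuration error: sampling_rate must be > 0")
  if (length(rest_gap) != 2 || rest_gap[1] > rest_gap[2] || rest_gap[1] < 2)
    stop("configuration error: rest_gap must be [lo, hi] with lo >= 2 s")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0")
  if (!is.numeric(subject_variability) || subject_variability < 0)
    stop("configuration error: subject_variability must be >= 0")
  if (!length(events) || !all(vapply(events, inherits, TRUE, "activity_template")))
    stop("configuration error: events must be a list of activity templates")
  if (edge_pad < 1)
    stop("configuration error: edge_pad must be >= 1 s (annotations must sit >= 1 s from the edges)")
  structure(list(n_subjects = as.integer(n_subjects), events = events,
                 rest_gap = as.numeric(rest_gap),
                 sampling_rate = as.numeric(sampling_rate),
                 noise_sd = as.numeric(noise_sd),
                 subject_variability = as.numeric(subject_variability),
                 edge_pad = as.numeric(edge_pad), seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  subjects: %d, events/subject: %d (%d Fall)\n", x$n_subjects,
              length(x$events),
              sum(vapply(x$events, function(e) e$label == "Fall", TRUE))))
  cat(sprintf("  fs: %g Hz, rest gap: [%g, %g] s, noise sd: %g g, subject jitter: %g\n",
              x$sampling_rate, x$rest_gap[1], x$rest_gap[2], x$noise_sd,
              x$subject_variability))
  invisible(x)
}

new_triaxial_recording <- function(subject_id, fs, data) {
  colnames(data) <- c("x", "y", "z")
  structure(list(subject_id = subject_id, fs = fs, data = data),
            class = "triaxial_recording")
}

#' Simulate one subject's continuous recording
#'
#' Generates a continuous triaxial recording containing every event of the
#' configured roster in order, separated by rests drawn uniformly from the
#' configured gap interval. During rests the signal is the 1 g gravity
#' baseline (along the longitudinal `z` axis when upright) plus sensor
#' noise; after events that end in a non-upright orientation the subject
#' returns smoothly to upright during the first part of the rest. Each
#' subject carries one multiplicative amplitude factor drawn from a
#' log-normal distribution, so recordings differ across subjects while a
#' fixed seed reproduces every stream exactly.
#'
#' @param config A [simulation_config()].
#' @param subject_index Subject number in `1:config$n_subjects`.
#' @return An object of class `annotated_recording`: fields `recording`
#'   (class `triaxial_recording`) and `annotations` (data.frame with columns
#'   `label`, `time_s`, the nominal event-peak times, strictly increasing).
#' @export
simulate_recording <- function(config, subject_index) {
  stopifnot(inherits(config, "simulation_config"))
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop("subject_index must lie in 1..n_subjects")
  fs <- config$sampling_rate
  set.seed((config$seed + 10007L * as.integer(subject_index)) %% 2147483647L)
  amp_scale <- exp(stats::rnorm(1, 0, config$subject_variability))
  n_ev <- length(config$events)
  gaps <- stats::runif(max(0, n_ev - 1), config$rest_gap[1], config$rest_gap[2])

  base <- c(0, 0, 1)
  rest_block <- function(dur_s, from_ori) {
    n <- round(dur_s * fs)
    if (n <= 0) return(matrix(numeric(0), 0, 3))
    t <- (seq_len(n) - 1) / fs
    if (all(abs(from_ori - base) < 1e-12)) {
      matrix(base, n, 3, byrow = TRUE)
    } else {
      s <- pmin(1, t / 1.5)             # stand back up over 1.5 s
      s <- s * s * (3 - 2 * s)
      ori <- outer(1 - s, from_ori) + outer(s, base)
      ori / sqrt(rowSums(ori^2))
    }
  }

  blocks <- list(rest_block(config$edge_pad, base))
  ann_time <- numeric(n_ev)
  ann_label <- character(n_ev)
  n_sofar <- nrow(blocks[[1]])
  for (i in seq_len(n_ev)) {
    tpl <- config$events[[i]]
    ev <- template_signal(tpl, fs, amp_scale)
    ann_time[i] <- (n_sofar + ev$peak_index - 1) / fs
    ann_label[i] <- tpl$label
    blocks[[length(blocks) + 1L]] <- ev$signal
    n_sofar <- n_sofar + nrow(ev$signal)
    dur <- if (i < n_ev) gaps[i] else config$edge_pad
    r <- rest_block(dur, tpl$post_orientation)
    blocks[[length(blocks) + 1L]] <- r
    n_sofar <- n_sofar + nrow(r)
  }
  sig <- do.call(rbind, blocks)
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), 0, config$noise_sd),
                        nrow(sig), 3)
  structure(list(
    recording = new_triaxial_recording(subject_index, fs, sig),
    annotations = data.frame(label = ann_label, time_s = ann_time,
                             stringsAsFactors = FALSE)),
    class = "annotated_recording")
}

#' Simulate the full study
#'
#' One continuous annotated recording per subject. Under the default roster,
#' segmenting all recordings yields `n_subjects * 15` events of which
#' `n_subjects * 9` carry the label `Fall` (315 of 525 at 35 subjects).
#'
#' @param config A [simulation_config()].
#' @return List of `annotated_recording`, one per subject.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lapply(seq_len(config$n_subjects), function(i) simulate_recording(config, i))
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf("Annotated triaxial recording: subject %s, %d samples at %g Hz (%.1f s), %d events\n",
              format(x$recording$subject_id), nrow(x$recording$data),
              x$recording$fs, nrow(x$recording$data) / x$recording$fs,
              nrow(x$annotations)))
  invisible(x)
}
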