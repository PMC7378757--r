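#' Per-sample Euclidean acceleration magnitude
#'
#' The total acceleration (sum vector) `|a| = sqrt(Fx^2 + Fy^2 + Fz^2)`.
#'
#' @param data An n x 3 matrix of triaxial samples in g.
#' @return Numeric vector of length n.
#' @export
acceleration_magnitude <- function(data) {
  sqrt(rowSums(data^2))
}

boundary_error <- function(msg) {
  stop(structure(class = c("fallsense_boundary_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Locate the highest peak of an event
#'
#' Returns the sample index, within a time window, that maximises the
#' Euclidean magnitude of the triaxial signal. Ties are broken by the
#' earliest index.
#'
#' @param recording A `triaxial_recording`.
#' @param window Length-2 numeric `c(start_s, end_s)` in seconds (clipped to
#'   the recording).
#' @return Integer sample index (1-based, absolute within the recording).
#' @export
locate_event_peak <- function(recording, window) {
  stopifnot(inherits(recording, "triaxial_recording"), length(window) == 2)
  fs <- recording$fs
  n <- nrow(recording$data)
  i1 <- max(1L, as.integer(floor(window[1] * fs)) + 1L)
  i2 <- min(n, as.integer(floor(window[2] * fs)) + 1L)
  if (i2 < i1) stop("empty search window")
  mag <- acceleration_magnitude(recording$data[i1:i2, , drop = FALSE])
  i1 + which.max(mag) - 1L          # which.max takes the earliest maximum
}

#' Extract one 2 s peak-centred event segment
#'
#' Slices `[peak_index - fs, peak_index + fs]` inclusive from all three
#' channels: 2 s centred on the event's highest peak, `2*fs + 1` samples per
#' axis (101 at 50 Hz). Peaks within 1 s of either edge raise a boundary
#' error rather than being padded.
#'
#' @param recording A `triaxial_recording`.
#' @param peak_index Absolute sample index of the event peak (1-based).
#' @param label Class label to attach.
#' @return An object of class `event_segment` with fields `subject_id`,
#'   `label`, `fs` and `data` (`(2*fs+1) x 3` matrix).
#' @export
extract_event_segment <- function(recording, peak_index, label) {
  stopifnot(inherits(recording, "triaxial_recording"))
  fs <- as.integer(round(recording$fs))
  n <- nrow(recording$data)
  if (peak_index - fs < 1 || peak_index + fs > n)
    boundary_error(sprintf(
      "event peak at sample %d (subject %s) lies within 1 s of a recording edge",
      peak_index, format(recording$subject_id)))
  idx <- (peak_index - fs):(peak_index + fs)
  structure(list(subject_id = recording$subject_id, label = label,
                 fs = recording$fs,
                 data = recording$data[idx, , drop = FALSE]),
            class = "event_segment")
}

#' @export
print.event_segment <- function(x, ...) {
  cat(sprintf("Event segment: subject %s, label %s, %d samples/axis at %g Hz\n",
              format(x$subject_id), x$label, nrow(x$data), x$fs))
  invisible(x)
}

#' Segment a continuous annotated recording into labelled event windows
#'
#' For each annotation, the highest magnitude peak is located within
#' `time_s +/- search_halfwidth_s` and a 2 s peak-centred segment is
#' extracted. Events whose peak sits within 1 s of a recording edge are
#' dropped with a warning, never padded.
#'
#' @param annotated An `annotated_recording`.
#' @param search_halfwidth_s Half-width of the peak search window around
#'   each annotation, seconds. The default 2.5 is half the minimum rest gap,
#'   so windows cannot overlap under the simulator's invariants.
#' @return List of `event_segment`, in annotation order.
#' @export
segment_recording <- function(annotated, search_halfwidth_s = 2.5) {
  stopifnot(inherits(annotated, "annotated_recording"))
  ann <- annotated$annotations
  if (is.unsorted(ann$time_s, strictly = TRUE))
    stop("annotations must be strictly increasing in time")
  if (nrow(ann) > 1 && any(diff(ann$time_s) <= 2 * search_halfwidth_s))
    stop("overlapping search windows: reduce search_halfwidth_s")
  segs <- vector("list", nrow(ann))
  keep <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    pk <- locate_event_peak(annotated$recording,
                            ann$time_s[i] + c(-1, 1) * search_halfwidth_s)
    seg <- tryCatch(
      extract_event_segment(annotated$recording, pk, ann$label[i]),
      fallsense_boundary_error = function(e) {
        warning("dropping event ", i, " (", ann$label[i], "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(seg)) { segs[[i]] <- seg; keep[i] <- TRUE }
  }
  segs[keep]
}

#' Segment every recording of a study
#'
#' @param recordings List of `annotated_recording` (e.g. from
#'   [simulate_study()]).
#' @param search_halfwidth_s Passed to [segment_recording()].
#' @return Flat list of `event_segment` across all subjects.
#' @export
segment_study <- function(recordings, search_halfwidth_s = 2.5) {
  do.call(c, lapply(recordings, segment_recording,
                    search_halfwidth_s = search_halfwidth_s))
}
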