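#' Activity classes recognised by the pipeline
#'
#' The seven event classes of the study design: six activities of daily
#' living plus a single `Fall` class into which all fall subtypes collapse.
#'
#' @return Character vector of the seven class labels, in roster order.
#' @export
activity_classes <- function() {
  c("Jumping", "Lying down", "Bending and picking up", "Sitting on a chair",
    "Standing up from chair", "Walking", "Fall")
}

#' Construct an activity template
#'
#' A template parameterises the noiseless waveform of one event: its class
#' label, the duration of the impulsive part (at most 2 s), the peak
#' acceleration magnitude reached at the event's highest peak, a dominant
#' oscillation frequency (0 for aperiodic events), and the orientation of
#' the gravity vector after the event (unit 3-vector in the device frame;
#' the longitudinal axis `z` reads +1 g when standing).
#'
#' @param label One of [activity_classes()].
#' @param subtype Free-text subtype tag (e.g. `"front hard"` for falls);
#'   defaults to the label.
#' @param duration Duration of the impulsive part, seconds (0 < duration <= 2).
#' @param peak_g Peak acceleration magnitude at the event peak, in g (>= 1).
#' @param freq Dominant oscillation frequency in Hz; 0 for aperiodic events.
#' @param post_orientation Unit 3-vector: gravity direction after the event.
#' @param kind Waveform family: `"burst"` (oscillatory, fixed posture),
#'   `"posture"` (slow orientation change with a moderate transient), or
#'   `"impact"` (damped impact transient with a post-event lying orientation).
#' @return An object of class `activity_template`.
#' @export
activity_template <- function(label, subtype = label, duration, peak_g, freq = 0,
                              post_orientation = c(0, 0, 1),
                              kind = c("burst", "posture", "impact")) {
  kind <- match.arg(kind)
  if (!label %in% activity_classes())
    stop("unknown activity label: ", label)
  if (!is.numeric(duration) || duration <= 0 || duration > 2)
    stop("template duration must lie in (0, 2] seconds")
  if (!is.finite(peak_g) || peak_g < 0)
    stop("peak_g must be finite and >= 0")
  post_orientation <- as.numeric(post_orientation)
  nrm <- sqrt(sum(post_orientation^2))
  if (length(post_orientation) != 3 || abs(nrm - 1) > 1e-8)
    stop("post_orientation must be a unit 3-vector")
  structure(list(label = label, subtype = subtype, duration = duration,
                 peak_g = peak_g, freq = freq,
                 post_orientation = post_orientation, kind = kind),
            class = "activity_template")
}

#' Default event roster
#'
#' The per-subject event roster of the emulated study design: six ADL
#' events (jumping, lying down, bending/picking up, sitting on a chair,
#' standing up from a chair, walking) followed by nine fall events
#' (steep fall, plus front/left/right/back falls each performed soft and
#' hard), all mapped to the single class `Fall`.
#'
#' Fall subtypes differ in peak amplitude and in the post-event lying
#' orientation. `fall_scale` multiplies the above-gravity part of every fall
#' peak amplitude; values > 1 widen the gap between fall and ADL peaks and
#' are used to construct deliberately well-separated study conditions.
#'
#' @param fall_scale Multiplier on the above-gravity peak amplitude of the
#'   fall templates (default 1 = the realistic default conditions).
#' @return List of 15 `activity_template` objects in roster order.
#' @export
default_templates <- function(fall_scale = 1) {
  stopifnot(is.numeric(fall_scale), fall_scale > 0)
  adl <- list(
    activity_template("Jumping", duration = 1.2, peak_g = 3.0, freq = 4,
                      kind = "burst"),
    activity_template("Lying down", duration = 1.8, peak_g = 2.2, freq = 0,
                      post_orientation = c(1, 0, 0), kind = "posture"),
    activity_template("Bending and picking up", duration = 2.0, peak_g = 1.6,
                      freq = 0, post_orientation = c(0, 0, 1), kind = "posture"),
    activity_template("Sitting on a chair", duration = 1.0, peak_g = 2.0,
                      freq = 2.5, kind = "burst"),
    activity_template("Standing up from chair", duration = 1.0, peak_g = 1.8,
                      freq = 2.0, kind = "burst"),
    activity_template("Walking", duration = 2.0, peak_g = 1.8, freq = 2,
                      kind = "burst"))
  lying <- list(front = c(1, 0, 0), left = c(0, 1, 0),
                right = c(0, -1, 0), back = c(-1, 0, 0))
  falls <- list(fall_template("steep", 6.0, c(1, 0, 0), fall_scale))
  for (dir in names(lying)) {
    falls <- c(falls,
               list(fall_template(paste(dir, "soft"), 4.0, lying[[dir]], fall_scale),
                    fall_template(paste(dir, "hard"), 5.0, lying[[dir]], fall_scale)))
  }
  c(adl, falls)
}

# amplitude above gravity is scaled, so peak = 1 + scale*(peak_g - 1)
fall_template <- function(subtype, peak_g, post_orientation, fall_scale) {
  activity_template("Fall", subtype = paste("Fall", subtype),
                    duration = 1.6, peak_g = 1 + fall_scale * (peak_g - 1),
                    freq = 9, post_orientation = post_orientation,
                    kind = "impact")
}

# Noiseless waveform of one event at sampling rate fs, as an n x 3 matrix in g.
# amp_scale is the per-subject multiplicative jitter applied to the
# above-gravity amplitude. The gravity baseline enters at 1 g along the
# instantaneous orientation. Returns the matrix plus the peak sample index.
template_signal <- function(tpl, fs, amp_scale = 1) {
  n <- max(3L, round(tpl$duration * fs))
  t <- (seq_len(n) - 1) / fs
  ip <- floor(n / 2) + 1L            # peak falls exactly on a sample
  tp <- t[ip]
  A <- (tpl$peak_g - 1) * amp_scale
  sig <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  smoothstep <- function(u) { u <- pmin(1, pmax(0, u)); u * u * (3 - 2 * u) }
  if (tpl$kind == "burst") {
    env <- exp(-((t - tp) / (0.22 * tpl$duration))^2)
    f <- if (tpl$freq > 0) tpl$freq else 1 / tpl$duration
    sig[, "z"] <- 1 + A * env * cos(2 * pi * f * (t - tp))
    sig[, "x"] <- 0.30 * A * env * sin(2 * pi * f * (t - tp))
    sig[, "y"] <- 0.15 * A * env * sin(4 * pi * f * (t - tp))
  } else if (tpl$kind == "posture") {
    # rotate towards an intermediate/post orientation, transient bump at peak
    target <- tpl$post_orientation
    if (all(abs(target - c(0, 0, 1)) < 1e-12)) {
      # tilt forward ~80 degrees and return (bending-type event)
      tilt <- c(sin(80 * pi / 180), 0, cos(80 * pi / 180))
      s <- smoothstep((t - 0.1) / (tp - 0.15)) -
        smoothstep((t - tp - 0.1) / (tpl$duration - tp - 0.2))
      ori <- outer(1 - s, c(0, 0, 1)) + outer(s, tilt)
    } else {
      s <- smoothstep((t - 0.15) / (tp - 0.2))
      ori <- outer(1 - s, c(0, 0, 1)) + outer(s, target)
    }
    ori <- ori / sqrt(rowSums(ori^2))
    env <- exp(-((t - tp) / 0.10)^2)
    sig <- ori + outer(A * env * cos(2 * pi * 3 * (t - tp)), target)
  } else { # impact
    target <- tpl$post_orientation
    s <- smoothstep((t - (tp - 0.15)) / 0.4)
    ori <- outer(1 - s, c(0, 0, 1)) + outer(s, target)
    ori <- ori / sqrt(rowSums(ori^2))
    dip <- 1 - 0.7 * exp(-((t - (tp - 0.30)) / 0.10)^2)  # brief free-fall dip
    env <- exp(-((t - tp) / 0.06)^2) *
      ifelse(t > tp, exp(-(t - tp) * 4), 1)              # damped after impact
    f <- if (tpl$freq > 0) tpl$freq else 9
    sig <- ori * dip + outer(A * env * cos(2 * pi * f * (t - tp)), target)
  }
  peak <- which.max(sqrt(rowSums(sig^2)))
  list(signal = sig, peak_index = peak)
}
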