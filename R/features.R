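ANGLE_FEATURES <- c("variance", "std_dev", "min_angle", "range", "max_angle",
                    "rep_time_mean", "rep_time_variance", "depth_variance",
                    "movement_stability")

#' Canonical kinematic feature names
#'
#' The nine spine-flexion-angle features, in their fixed canonical order:
#' variance, standard deviation, minimum (full spine flexion angle), range,
#' maximum (spine standing angle), repetition-time mean, repetition-time
#' variance, depth variance, and movement stability.  Feature-subset masks
#' index into this order.
#'
#' @return Character vector of length 9.
#' @export
angle_feature_names <- function() ANGLE_FEATURES

insufficient_repetitions <- function(msg) {
  stop(errorCondition(msg, class = c("spineflex_insufficient_repetitions",
                                     "error", "condition")))
}

#' Detect full-flexion minima of an angle waveform
#'
#' Locates the frames of deepest flexion in each repetition by negating the
#' smoothed angle waveform and applying continuous-wavelet-transform
#' ridge-line peak detection ([find_peaks_cwt()]).  Detected positions are
#' refined to the local minimum of the smoothed waveform within half the
#' minimum separation, minima within `edge_trim_s` of either end are
#' discarded as partial repetitions, and minima closer together than
#' `min_separation_s` are merged keeping the deeper one.
#'
#' @param wave A smoothed `angle_waveform` (see [smooth_waveform()]) of at
#'   least 2 s duration.
#' @param widths_s Range of wavelet widths in seconds.  Widths should cover
#'   the expected width of the flexion *troughs* (roughly half a repetition
#'   period); the default 0.25--1.5 s detects cadences from ~1.5 s to
#'   beyond 5 s per repetition.  Widths much larger than the repetition
#'   period swamp the ridge lines and merge neighbouring repetitions.
#' @param min_separation_s Minimum separation between reported minima in
#'   seconds (default 1).
#' @param edge_trim_s Waveform margin in which minima are discarded as
#'   partial repetitions (default 0.5 s).
#' @return Strictly increasing integer vector of frame indices; an error of
#'   class `spineflex_insufficient_repetitions` if fewer than 2 minima are
#'   found.
#' @export
detect_flexion_minima <- function(wave, widths_s = c(0.25, 1.5),
                                  min_separation_s = 1, edge_trim_s = 0.5) {
  stopifnot(inherits(wave, "angle_waveform"))
  if (!wave$smoothed) {
    stop("waveform must be smoothed first (see smooth_waveform())",
         call. = FALSE)
  }
  n <- length(wave$theta)
  fps <- wave$fps
  if (n < 2 * fps) {
    stop(sprintf("waveform too short for repetition detection (%d frames < 2 s)",
                 n), call. = FALSE)
  }
  w_lo <- max(2L, round(widths_s[1] * fps))
  w_hi <- max(w_lo + 1L, round(widths_s[2] * fps))
  widths <- unique(round(seq(w_lo, w_hi, length.out = 16L)))
  inverted <- max(wave$theta) - wave$theta
  peaks <- find_peaks_cwt(inverted, widths)
  half_sep <- max(1L, round(min_separation_s * fps / 2))
  # refine each detection to the local minimum of the smoothed waveform
  peaks <- vapply(peaks, function(p) {
    lo <- max(1L, p - half_sep)
    hi <- min(n, p + half_sep)
    lo + which.min(wave$theta[lo:hi]) - 1L
  }, numeric(1))
  peaks <- sort(unique(peaks))
  # drop boundary minima (partial repetitions)
  trim <- round(edge_trim_s * fps)
  peaks <- peaks[peaks > trim & peaks <= n - trim]
  # enforce minimum separation, keeping the deeper minimum
  min_sep <- round(min_separation_s * fps)
  if (length(peaks) > 1L) {
    kept <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- kept[length(kept)]
      if (p - last >= min_sep) {
        kept <- c(kept, p)
      } else if (wave$theta[p] < wave$theta[last]) {
        kept[length(kept)] <- p
      }
    }
    peaks <- kept
  }
  if (length(peaks) < 2L) {
    insufficient_repetitions(sprintf(
      "found %d full-flexion minima; at least 2 repetitions are required",
      length(peaks)))
  }
  as.integer(peaks)
}

#' Repetition times from flexion minima
#'
#' The spine-flexion repetition time of each cycle is the frame count
#' between consecutive full-flexion minima of the angle waveform.
#'
#' @param minima_indices Strictly increasing frame indices of full-flexion
#'   minima (at least 2).
#' @param fps Frame rate, retained for unit conversion by callers.
#' @return Integer vector of repetition times in frames (length =
#'   `length(minima_indices) - 1`).
#' @export
repetition_times <- function(minima_indices, fps = 30) {
  if (length(minima_indices) < 2L) {
    insufficient_repetitions("at least 2 minima are needed for repetition times")
  }
  if (any(diff(minima_indices) <= 0)) {
    stop("minima_indices must be strictly increasing", call. = FALSE)
  }
  diff(minima_indices)
}

#' Movement stability of a flexion trial
#'
#' Splits the angle waveform into two halves (at `floor(n/2)`), computes the
#' angle range (max - min) of each half, and returns second-half range minus
#' first-half range.  A positive value means the participant's excursion
#' grew across the trial (e.g. increasing maximum bend angle over
#' repetitions); a negative value means it shrank.
#'
#' @param wave An `angle_waveform` of at least 4 frames.
#' @return Range difference in degrees.
#' @export
movement_stability <- function(wave) {
  stopifnot(inherits(wave, "angle_waveform"))
  n <- length(wave$theta)
  if (n < 4L) stop("waveform must have at least 4 frames", call. = FALSE)
  half <- floor(n / 2)
  first <- wave$theta[seq_len(half)]
  second <- wave$theta[(half + 1L):n]
  (max(second) - min(second)) - (max(first) - min(first))
}

#' Extract the nine kinematic features of a flexion trial
#'
#' Computes, from a smoothed angle waveform, the full feature set used for
#' MI/MCI classification: whole-waveform variance, standard deviation,
#' minimum (full spine flexion angle), range and maximum (spine standing
#' angle); the mean and variance of the repetition times between
#' full-flexion minima; the variance of the flexion depths (angle at each
#' minimum); and the movement stability.  All variances are sample
#' variances (denominator n - 1).
#'
#' @param wave A smoothed `angle_waveform`.
#' @param minima Optional pre-computed minima indices; detected with
#'   [detect_flexion_minima()] when `NULL`.
#' @return Named numeric vector of length 9 in the canonical order of
#'   [angle_feature_names()].  Repetition times are in frames, angles in
#'   degrees, variances in squared units.
#' @export
extract_angle_features <- function(wave, minima = NULL) {
  stopifnot(inherits(wave, "angle_waveform"))
  if (is.null(minima)) minima <- detect_flexion_minima(wave)
  theta <- wave$theta
  tr <- repetition_times(minima, wave$fps)
  depths <- theta[minima]
  feats <- c(
    variance = stats::var(theta),
    std_dev = stats::sd(theta),
    min_angle = min(theta),
    range = max(theta) - min(theta),
    max_angle = max(theta),
    rep_time_mean = mean(tr),
    rep_time_variance = stats::var(tr),
    depth_variance = stats::var(depths),
    movement_stability = movement_stability(wave)
  )
  feats[ANGLE_FEATURES]
}
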