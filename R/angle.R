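#' Spine flexion angle from ankle, hip, and neck landmarks
#'
#' Computes the sagittal spine-flexion angle \eqn{\theta} at the hip, between
#' the hip-to-neck and hip-to-ankle segments, from the law of cosines on the
#' three pairwise Euclidean distances: hip-neck (`hn`), ankle-hip (`ah`) and
#' ankle-neck (`an`),
#' \deqn{\theta = \arccos\left(\frac{hn^2 + ah^2 - an^2}{2\, hn\, ah}\right).}
#' In relaxed standing the three landmarks are nearly collinear and
#' \eqn{\theta \approx 180^\circ}; forward flexion decreases \eqn{\theta}.
#'
#' The angle depends only on distance ratios, so it is invariant under
#' uniform scaling, rotation, translation and axis reflection of the input
#' points.  Pixel coordinates (including image y-down conventions) therefore
#' need no calibration, and 3-D motion-capture coordinates can be used
#' directly.  The arccos argument is clamped to \eqn{[-1, 1]} to guard
#' against floating-point drift for nearly collinear configurations.
#'
#' @param ankle,hip,neck Numeric vectors of length 2 or 3 (a single frame),
#'   or matrices with one row per frame and 2 or 3 columns.  All three
#'   arguments must have the same dimensionality and frame count.
#' @return Numeric vector of angles in degrees, in `(0, 180]`, one per frame.
#' @examples
#' spine_flexion_angle(c(0, 0), c(0, 1), c(0, 2))   # collinear: 180
#' spine_flexion_angle(c(0, 0), c(0, 1), c(1, 1))   # right angle at hip: 90
#' @export
spine_flexion_angle <- function(ankle, hip, neck) {
  a <- as_frame_matrix(ankle, "ankle")
  h <- as_frame_matrix(hip, "hip")
  n <- as_frame_matrix(neck, "neck")
  if (!all(dim(a) == dim(h)) || !all(dim(a) == dim(n))) {
    stop("ankle, hip and neck must have identical dimensions", call. = FALSE)
  }
  hn <- row_norm(n - h)
  ah <- row_norm(h - a)
  an <- row_norm(n - a)
  if (any(hn == 0)) {
    stop(sprintf("degenerate geometry: hip and neck coincide (frame %d)",
                 which(hn == 0)[1L]), call. = FALSE)
  }
  if (any(ah == 0)) {
    stop(sprintf("degenerate geometry: ankle and hip coincide (frame %d)",
                 which(ah == 0)[1L]), call. = FALSE)
  }
  cos_theta <- (hn^2 + ah^2 - an^2) / (2 * hn * ah)
  cos_theta <- pmin(1, pmax(-1, cos_theta))
  acos(cos_theta) * 180 / pi
}

as_frame_matrix <- function(p, what) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (!is.numeric(p) || !(ncol(p) %in% c(2L, 3L))) {
    stop(sprintf("%s must be numeric with 2 or 3 coordinates", what),
         call. = FALSE)
  }
  if (any(!is.finite(p))) {
    stop(sprintf("%s contains non-finite coordinates", what), call. = FALSE)
  }
  p
}

row_norm <- function(m) sqrt(rowSums(m^2))

#' Per-frame keypoint trajectory of a spine flexion trial
#'
#' Container for the sagittal 2-D pixel positions of the ankle, hip and neck
#' keypoints across the frames of one participant's flexion trial, as
#' produced by a pose estimator.  At least 60 frames (2 s at the nominal
#' 30 fps) are needed for downstream repetition-feature extraction.
#'
#' @param participant_id Identifier for the participant/trial.
#' @param ankle,hip,neck Numeric matrices, one row per frame, two columns
#'   (x, y in pixels).
#' @param fps Frames per second (nominal 30).
#' @param confidence Optional data frame or matrix of per-frame, per-keypoint
#'   confidences in `[0, 1]` (columns `ankle`, `hip`, `neck`).
#' @return An object of class `keypoint_trajectory`.
#' @export
keypoint_trajectory <- function(participant_id, ankle, hip, neck, fps = 30,
                                confidence = NULL) {
  ankle <- as_frame_matrix(ankle, "ankle")
  hip <- as_frame_matrix(hip, "hip")
  neck <- as_frame_matrix(neck, "neck")
  n <- nrow(ankle)
  if (n < 1L) stop("trajectory has no frames", call. = FALSE)
  if (nrow(hip) != n || nrow(neck) != n) {
    stop("ankle, hip and neck must have the same number of frames",
         call. = FALSE)
  }
  if (ncol(ankle) != 2L) {
    stop("keypoint trajectories are 2-D (x, y in pixels)", call. = FALSE)
  }
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  # pairwise non-coincidence within every frame
  bad <- which(row_norm(hip - neck) == 0 | row_norm(ankle - hip) == 0 |
                 row_norm(ankle - neck) == 0)
  if (length(bad)) {
    stop(sprintf("coincident keypoints in frame(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(
    list(participant_id = participant_id, fps = fps,
         ankle = ankle, hip = hip, neck = neck, confidence = confidence),
    class = "keypoint_trajectory")
}

#' @export
print.keypoint_trajectory <- function(x, ...) {
  cat(sprintf("<keypoint_trajectory> %s: %d frames @ %g fps (%.1f s)\n",
              x$participant_id, nrow(x$ankle), x$fps, nrow(x$ankle) / x$fps))
  invisible(x)
}

new_angle_waveform <- function(theta, fps, smoothed, source) {
  structure(list(theta = as.numeric(theta), fps = fps,
                 smoothed = isTRUE(smoothed), source = source),
            class = "angle_waveform")
}

#' @export
print.angle_waveform <- function(x, ...) {
  cat(sprintf(
    "<angle_waveform> %d frames @ %g fps, source=%s%s, range [%.1f, %.1f] deg\n",
    length(x$theta), x$fps, x$source, if (x$smoothed) " (smoothed)" else "",
    min(x$theta), max(x$theta)))
  invisible(x)
}

#' Spine-flexion angle waveform from a keypoint trajectory
#'
#' Applies [spine_flexion_angle()] frame by frame, yielding the raw
#' (unsmoothed) angle waveform of the trial.
#'
#' @param traj A [keypoint_trajectory()].
#' @return An `angle_waveform` object (fields `theta` in degrees, `fps`,
#'   `smoothed`, `source = "pose"`).
#' @export
angle_waveform <- function(traj) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  theta <- tryCatch(
    spine_flexion_angle(traj$ankle, traj$hip, traj$neck),
    error = function(e) {
      stop(sprintf("participant %s: %s", traj$participant_id,
                   conditionMessage(e)), call. = FALSE)
    })
  new_angle_waveform(theta, traj$fps, smoothed = FALSE, source = "pose")
}

#' Moving-average smoothing of an angle waveform
#'
#' Smooths the per-frame spine-flexion angle with a centred moving average
#' whose nominal width is `window_frames` (30 frames = 1 s of video at
#' 30 fps).  At the waveform edges the window shrinks symmetrically to the
#' available frames, so no phase lag is introduced and the output never
#' leaves the input value range.  For an even `window_frames` the interior
#' window covers frames `[i - w/2, i + w/2 - 1]`.
#'
#' @param wave An `angle_waveform`.
#' @param window_frames Window width in frames (default 30).
#' @return The smoothed `angle_waveform` (same length, `smoothed = TRUE`).
#' @export
smooth_waveform <- function(wave, window_frames = 30) {
  stopifnot(inherits(wave, "angle_waveform"))
  w <- as.integer(window_frames)
  if (w < 1L) stop("window_frames must be >= 1", call. = FALSE)
  n <- length(wave$theta)
  if (n < w) {
    stop(sprintf("waveform (%d frames) shorter than smoothing window (%d)",
                 n, w), call. = FALSE)
  }
  half_lo <- as.integer(ceiling((w - 1) / 2))  # frames taken before i
  half_hi <- as.integer(floor((w - 1) / 2))    # frames taken after i
  theta <- wave$theta
  # cumulative-sum moving average; where the full window does not fit, the
  # window shrinks symmetrically around i to the available frames
  cs <- c(0, cumsum(theta))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i - half_lo >= 1L && i + half_hi <= n) {
      lo <- i - half_lo
      hi <- i + half_hi
    } else {
      k <- min(i - 1L, n - i)
      lo <- i - k
      hi <- i + k
    }
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  new_angle_waveform(out, wave$fps, smoothed = TRUE, source = wave$source)
}

#' Resample an angle waveform onto a different frame rate
#'
#' Linear time-interpolation onto the target frame grid, preserving the
#' trial duration to within one frame.  Used to bring 120 Hz motion-capture
#' waveforms onto the 30 fps video grid before comparison.
#'
#' @param wave An `angle_waveform`.
#' @param target_fps Target frames per second (> 0).
#' @return The resampled `angle_waveform` at `target_fps`.
#' @export
resample_waveform <- function(wave, target_fps) {
  stopifnot(inherits(wave, "angle_waveform"))
  if (target_fps <= 0) stop("target_fps must be positive", call. = FALSE)
  n <- length(wave$theta)
  t_in <- (seq_len(n) - 1) / wave$fps
  duration <- (n - 1) / wave$fps
  n_out <- floor(duration * target_fps) + 1L
  t_out <- (seq_len(n_out) - 1) / target_fps
  theta <- stats::approx(t_in, wave$theta, xout = t_out, rule = 2)$y
  new_angle_waveform(theta, target_fps, smoothed = wave$smoothed,
                     source = wave$source)
}

#' Mean squared error between two angle waveforms
#'
#' Quantifies the disparity between two angle waveforms on the same frame
#' grid (e.g. pose-estimation versus motion-capture derived), as the mean of
#' squared per-frame differences in degrees squared.  Waveforms must share
#' the same frame rate (use [resample_waveform()] first); lengths may differ
#' by at most 2 frames, in which case both are truncated to the common
#' length.
#'
#' @param a,b `angle_waveform` objects at the same fps.
#' @return Mean squared error in degrees squared.
#' @export
waveform_mse <- function(a, b) {
  stopifnot(inherits(a, "angle_waveform"), inherits(b, "angle_waveform"))
  if (!isTRUE(all.equal(a$fps, b$fps))) {
    stop(sprintf(
      "fps mismatch (%g vs %g): resample one waveform with resample_waveform() first",
      a$fps, b$fps), call. = FALSE)
  }
  n1 <- length(a$theta); n2 <- length(b$theta)
  if (abs(n1 - n2) > 2L) {
    stop(sprintf("waveform lengths differ by %d frames (> 2)", abs(n1 - n2)),
         call. = FALSE)
  }
  m <- min(n1, n2)
  mean((a$theta[seq_len(m)] - b$theta[seq_len(m)])^2)
}
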