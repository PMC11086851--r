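MOCAP_MARKERS <- c("C7", "L4", "LASIS", "RASIS", "LPSIS", "RPSIS")

#' Optical motion-capture trial
#'
#' Container for a 120 Hz retroreflective-marker recording of one spine
#' flexion trial: the seventh cervical vertebra (C7), the fourth lumbar
#' vertebra (L4), and the four pelvic markers (left/right anterior and
#' posterior superior iliac spines).  Used as the criterion measure against
#' which the video-derived angle waveform is validated.
#'
#' @param participant_id Identifier for the participant/trial.
#' @param markers Named list of numeric matrices (one row per frame, three
#'   columns X/Y/Z in lab units) for markers `C7`, `L4`, `LASIS`, `RASIS`,
#'   `LPSIS`, `RPSIS`.
#' @param fps Capture rate in Hz (default 120).
#' @param vertical_axis Which coordinate axis is vertical, with 0 at floor
#'   level: `"x"`, `"y"` (default) or `"z"`.
#' @return An object of class `mocap_trial`.
#' @export
mocap_trial <- function(participant_id, markers, fps = 120,
                        vertical_axis = c("y", "x", "z")) {
  vertical_axis <- match.arg(vertical_axis)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  missing_markers <- setdiff(MOCAP_MARKERS, names(markers))
  if (length(missing_markers)) {
    stop(sprintf("missing marker(s): %s",
                 paste(missing_markers, collapse = ", ")), call. = FALSE)
  }
  markers <- lapply(markers[MOCAP_MARKERS], function(m) {
    m <- if (is.data.frame(m)) as.matrix(m) else m
    storage.mode(m) <- "double"
    m
  })
  n <- nrow(markers[[1L]])
  v_col <- match(vertical_axis, c("x", "y", "z"))
  for (nm in MOCAP_MARKERS) {
    m <- markers[[nm]]
    if (nrow(m) != n || ncol(m) != 3L) {
      stop(sprintf("marker %s must be an n x 3 matrix matching the trial length", nm),
           call. = FALSE)
    }
    gaps <- which(!stats::complete.cases(m) | rowSums(!is.finite(m)) > 0)
    if (length(gaps)) {
      stop(sprintf("marker %s has missing/non-finite frames: %s%s (no gap-filling is applied)",
                   nm, paste(utils::head(gaps, 5L), collapse = ", "),
                   if (length(gaps) > 5L) ", ..." else ""), call. = FALSE)
    }
    if (any(m[, v_col] < 0)) {
      stop(sprintf("marker %s has vertical coordinate(s) below floor level", nm),
           call. = FALSE)
    }
  }
  structure(list(participant_id = participant_id, fps = fps,
                 markers = markers, vertical_axis = vertical_axis),
            class = "mocap_trial")
}

#' @export
print.mocap_trial <- function(x, ...) {
  cat(sprintf("<mocap_trial> %s: %d frames @ %g Hz, vertical axis '%s'\n",
              x$participant_id, nrow(x$markers$C7), x$fps, x$vertical_axis))
  invisible(x)
}

#' Spine-flexion angle waveform from motion-capture markers
#'
#' Computes the same spine-flexion angle as [angle_waveform()], with the
#' pose keypoints replaced by marker constructs: the neck by C7, the hip by
#' the centroid of the four pelvic markers (ASIS and PSIS, left and right),
#' and the ankle by a virtual ankle marker -- the L4 marker with its
#' vertical coordinate set to zero, i.e. a point on the floor directly
#' beneath L4.  The angle is computed from 3-D Euclidean distances; no
#' sagittal-plane projection is applied.
#'
#' @param trial A [mocap_trial()].
#' @return An `angle_waveform` (source `"mocap"`, at the trial's fps).
#' @export
mocap_spine_angle <- function(trial) {
  stopifnot(inherits(trial, "mocap_trial"))
  m <- trial$markers
  neck <- m$C7
  hip <- (m$LASIS + m$RASIS + m$LPSIS + m$RPSIS) / 4
  v_col <- match(trial$vertical_axis, c("x", "y", "z"))
  ankle <- m$L4
  ankle[, v_col] <- 0
  theta <- spine_flexion_angle(ankle, hip, neck)
  new_angle_waveform(theta, trial$fps, smoothed = FALSE, source = "mocap")
}
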