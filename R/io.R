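# File formats: keypoint CSV (participant_id, frame, ankle_x, ankle_y,
# hip_x, hip_y, neck_x, neck_y [, *_conf]), COCO 17-keypoint JSON, TRC-like
# mocap CSV (frame, <MARKER>_X/Y/Z), PROMs CSV, labels CSV, features CSV.

KEYPOINT_COLS <- c("ankle_x", "ankle_y", "hip_x", "hip_y", "neck_x",
                   "neck_y")

#' Read keypoint trajectories from CSV
#'
#' Expects a header with columns `participant_id`, `frame`, `ankle_x`,
#' `ankle_y`, `hip_x`, `hip_y`, `neck_x`, `neck_y` and optional `*_conf`
#' confidence columns; one row per frame.  Rows are grouped by participant
#' and ordered by frame.
#'
#' @param path CSV path.
#' @param fps Frame rate of the recordings (default 30).
#' @return Named list of [keypoint_trajectory()] objects, one per
#'   participant.
#' @export
read_keypoints_csv <- function(path, fps = 30) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "frame", KEYPOINT_COLS)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[, required]))
  if (length(bad)) {
    stop(sprintf("%s: malformed/missing values at line(s) %s",
                 path, paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  out <- lapply(split(df, df$participant_id), function(d) {
    d <- d[order(d$frame), ]
    conf_cols <- intersect(c("ankle_conf", "hip_conf", "neck_conf"),
                           names(d))
    keypoint_trajectory(
      d$participant_id[1L],
      ankle = as.matrix(d[, c("ankle_x", "ankle_y")]),
      hip = as.matrix(d[, c("hip_x", "hip_y")]),
      neck = as.matrix(d[, c("neck_x", "neck_y")]),
      fps = fps,
      confidence = if (length(conf_cols)) d[, conf_cols, drop = FALSE])
  })
  out[order(names(out))]
}

#' Write keypoint trajectories to CSV
#'
#' @param trajectories A [keypoint_trajectory()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(trajectories, path) {
  if (inherits(trajectories, "keypoint_trajectory")) {
    trajectories <- list(trajectories)
  }
  rows <- lapply(trajectories, function(tr) {
    data.frame(participant_id = tr$participant_id,
               frame = seq_len(nrow(tr$ankle)),
               ankle_x = tr$ankle[, 1], ankle_y = tr$ankle[, 2],
               hip_x = tr$hip[, 1], hip_y = tr$hip[, 2],
               neck_x = tr$neck[, 1], neck_y = tr$neck[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# COCO-17 keypoint indices (1-based)
COCO_IDX <- list(left_shoulder = 6L, right_shoulder = 7L, left_hip = 12L,
                 right_hip = 13L, left_ankle = 16L, right_ankle = 17L)

coco_midpoint <- function(kp, left, right, conf_threshold) {
  l <- kp[left, 1:2]; r <- kp[right, 1:2]
  lc <- kp[left, 3]; rc <- kp[right, 3]
  if (lc < conf_threshold && rc >= conf_threshold) {
    list(xy = r, conf = rc)
  } else if (rc < conf_threshold && lc >= conf_threshold) {
    list(xy = l, conf = lc)
  } else {
    list(xy = (l + r) / 2, conf = (lc + rc) / 2)
  }
}

#' Read a COCO 17-keypoint JSON pose track
#'
#' Adapts pose-estimator output in COCO keypoint format to the three
#' landmarks used here: neck = midpoint of the shoulders, hip = midpoint of
#' the hips, ankle = midpoint of the ankles.  If one side's confidence
#' falls below `conf_threshold`, the other side is used alone.  The file
#' must hold an array of frames, each with a `keypoints` array of 51
#' numbers (x, y, confidence per keypoint, COCO ordering).
#'
#' @param path JSON path.
#' @param participant_id Identifier for the trajectory.
#' @param fps Frame rate (default 30).
#' @param conf_threshold Per-side confidence cutoff (default 0.3).
#' @return A [keypoint_trajectory()].
#' @export
read_coco_keypoints <- function(path, participant_id = "P001", fps = 30,
                                conf_threshold = 0.3) {
  frames <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(frames)) stop(sprintf("%s: no frames", path), call. = FALSE)
  n <- length(frames)
  ankle <- hip <- neck <- matrix(NA_real_, n, 2L)
  conf <- matrix(NA_real_, n, 3L,
                 dimnames = list(NULL, c("ankle", "hip", "neck")))
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    kp_raw <- if (!is.null(fr$keypoints)) fr$keypoints else fr
    kp_num <- as.numeric(unlist(kp_raw))
    if (length(kp_num) != 51L) {
      stop(sprintf("%s: frame %d has %d values; expected 51 (17 keypoints x 3)",
                   path, i, length(kp_num)), call. = FALSE)
    }
    kp <- matrix(kp_num, ncol = 3L, byrow = TRUE)
    a <- coco_midpoint(kp, COCO_IDX$left_ankle, COCO_IDX$right_ankle,
                       conf_threshold)
    h <- coco_midpoint(kp, COCO_IDX$left_hip, COCO_IDX$right_hip,
                       conf_threshold)
    s <- coco_midpoint(kp, COCO_IDX$left_shoulder, COCO_IDX$right_shoulder,
                       conf_threshold)
    ankle[i, ] <- a$xy; hip[i, ] <- h$xy; neck[i, ] <- s$xy
    conf[i, ] <- c(a$conf, h$conf, s$conf)
  }
  keypoint_trajectory(participant_id, ankle, hip, neck, fps = fps,
                      confidence = as.data.frame(conf))
}

#' Read a TRC-like mocap CSV
#'
#' Expects a header with `frame` followed by `<MARKER>_X`, `<MARKER>_Y`,
#' `<MARKER>_Z` triplets for the six markers C7, L4, LASIS, RASIS, LPSIS,
#' RPSIS.
#'
#' @param path CSV path.
#' @param participant_id Identifier for the trial.
#' @param fps Capture rate (default 120).
#' @param vertical_axis Vertical axis label (default `"y"`).
#' @return A [mocap_trial()].
#' @export
read_mocap_csv <- function(path, participant_id = "P001", fps = 120,
                           vertical_axis = "y") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$frame), ]
  markers <- lapply(stats::setNames(MOCAP_MARKERS, MOCAP_MARKERS),
                    function(m) {
    cols <- paste0(m, "_", c("X", "Y", "Z"))
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    as.matrix(df[, cols])
  })
  mocap_trial(participant_id, markers, fps = fps,
              vertical_axis = vertical_axis)
}

#' Write a mocap trial to a TRC-like CSV
#'
#' @param trial A [mocap_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mocap_csv <- function(trial, path) {
  stopifnot(inherits(trial, "mocap_trial"))
  out <- data.frame(frame = seq_len(nrow(trial$markers$C7)))
  for (m in MOCAP_MARKERS) {
    mm <- trial$markers[[m]]
    out[[paste0(m, "_X")]] <- mm[, 1]
    out[[paste0(m, "_Y")]] <- mm[, 2]
    out[[paste0(m, "_Z")]] <- mm[, 3]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a labels CSV (participant_id, label in MI/MCI)
#'
#' @param path CSV path.
#' @return Data frame with `participant_id` and validated `label`.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "label") %in% names(df))) {
    stop(sprintf("%s: expected columns participant_id, label", path),
         call. = FALSE)
  }
  encode_labels(df$label)   # validates values
  df
}

#' Write the extracted feature table to CSV
#'
#' @param features Data frame from [cohort_features()] or assembled
#'   manually.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-participant keypoint CSVs under `keypoints/`, optional mocap
#' twin CSVs under `mocap/`, the PROMs and labels CSVs, and a ground-truth
#' manifest JSON recording the spec and every latent parameter.
#'
#' @param cohort A `spineflex_cohort`.
#' @param dir Output directory (created if needed).
#' @param mocap Also write 120 Hz mocap twins (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, mocap = FALSE) {
  dir.create(file.path(dir, "keypoints"), recursive = TRUE,
             showWarnings = FALSE)
  for (p in cohort$participants) {
    write_keypoints_csv(p$trajectory,
                        file.path(dir, "keypoints",
                                  paste0(p$trajectory$participant_id,
                                         ".csv")))
  }
  if (mocap) {
    dir.create(file.path(dir, "mocap"), showWarnings = FALSE)
    for (p in cohort$participants) {
      twin <- generate_mocap_twin(p, cohort$spec)
      write_mocap_csv(twin, file.path(dir, "mocap",
                                      paste0(p$trajectory$participant_id,
                                             ".csv")))
    }
  }
  utils::write.csv(cohort$proms[, c("participant_id", PROMS_FEATURES)],
                   file.path(dir, "proms.csv"), row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  manifest <- list(
    spec = lapply(unclass(cohort$spec), function(x)
      if (is.data.frame(x)) as.list(x) else x),
    participants = lapply(cohort$participants, function(p)
      p$truth[c("class_label", "theta_max", "theta_min", "k", "period_s",
                "depths", "minima_frames")]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
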