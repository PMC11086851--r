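#' Specification of a synthetic MI/MCI cohort
#'
#' Defines the study conditions the simulator emulates: each participant
#' performs 8--10 repetitions of spine flexion recorded at 30 fps, starting
#' from relaxed standing (angle ~172 deg).  The movement-impairment (MI)
#' phenotype flexes less deeply (full-flexion angle ~120 deg) and more
#' slowly (repetition period ~3.5 s) than the motor-control-impairment
#' (MCI) phenotype (~85 deg, ~2.5 s), mirroring restricted versus
#' unrestricted painful movement.  PROMs are drawn from class-conditional
#' truncated normals with heavily overlapping distributions for all
#' measures except the STarT Back tool, which separates moderately
#' (MI mean 3 vs MCI mean 6, sd 1.5 on the 0--9 scale).
#'
#' @param n_mi,n_mci Participants per class (defaults 41 and 42).
#' @param reps_range Inclusive range of repetitions per trial (default
#'   8--10).
#' @param fps Video frame rate (default 30).
#' @param theta_max_mean,theta_max_sd Standing angle distribution in
#'   degrees (172, 3).
#' @param theta_min_mean,theta_min_sd Named per-class (`MI`, `MCI`)
#'   full-flexion angle distribution in degrees.
#' @param period_mean_s,period_sd_s Named per-class repetition period
#'   distribution in seconds.
#' @param depth_jitter_sd Within-trial standard deviation of per-repetition
#'   flexion depth in degrees (default 2).
#' @param pixel_noise_sd Isotropic keypoint noise in pixels (default 1).
#' @param dwell_frac Fraction of each repetition period spent dwelling in
#'   standing posture (default 0.15).
#' @param pad_s Standing lead-in/lead-out of the trial in seconds
#'   (default 0.5).
#' @param hip_height_px,trunk_len_px Segment lengths of the planar
#'   two-segment body model in pixels (350, 300).
#' @param hip_height_mm,trunk_len_mm,l4_height_frac,pelvis_halfwidth_mm,pelvis_depth_mm
#'   Motion-capture twin geometry in millimetres; L4 sits on the
#'   ankle--hip axis at `l4_height_frac` of hip height.
#' @param marker_noise_sd_mm Marker noise of the mocap twin (default 0).
#' @param proms_params Data frame with rows in [proms_feature_names()]
#'   order and columns `mean_mi`, `mean_mci`, `sd`, `min`, `max`.
#' @param seed Integer seed making cohort generation deterministic.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mi = 41, n_mci = 42, reps_range = c(8, 10),
                        fps = 30,
                        theta_max_mean = 172, theta_max_sd = 3,
                        theta_min_mean = c(MI = 120, MCI = 85),
                        theta_min_sd = c(MI = 8, MCI = 8),
                        period_mean_s = c(MI = 3.5, MCI = 2.5),
                        period_sd_s = c(MI = 0.5, MCI = 0.4),
                        depth_jitter_sd = 2, pixel_noise_sd = 1,
                        dwell_frac = 0.15, pad_s = 0.5,
                        hip_height_px = 350, trunk_len_px = 300,
                        hip_height_mm = 950, trunk_len_mm = 520,
                        l4_height_frac = 0.75,
                        pelvis_halfwidth_mm = 120, pelvis_depth_mm = 90,
                        marker_noise_sd_mm = 0,
                        proms_params = default_proms_params(),
                        seed = 1) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  stopifnot(n_mi >= 1, n_mci >= 1, fps > 0,
            length(reps_range) == 2, reps_range[1] <= reps_range[2])
  for (cls in c("MI", "MCI")) {
    if (theta_min_mean[[cls]] >= theta_max_mean) {
      stop(sprintf("theta_min must be below theta_max for class %s", cls),
           call. = FALSE)
    }
  }
  sds <- c(theta_max_sd, theta_min_sd, period_sd_s, depth_jitter_sd,
           pixel_noise_sd, marker_noise_sd_mm)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  spec
}

#' Default class-conditional PROM distributions
#'
#' Weakly separated means for all measures except SBT, reflecting a
#' chronic-NSLBP cohort with acute and severe cases excluded (which
#' homogenises the questionnaire scores).  Scores are truncated to each
#' measure's allowed range and rounded to integers.
#'
#' @return Data frame with columns `mean_mi`, `mean_mci`, `sd`, `min`,
#'   `max`; rows in [proms_feature_names()] order.
#' @export
default_proms_params <- function() {
  data.frame(
    row.names = PROMS_FEATURES,
    mean_mi  = c(55, 30, 40, 20, 36, 34, 3),
    mean_mci = c(58, 33, 41, 22, 34, 35, 6),
    sd       = c(18, 12,  9,  9, 10, 10, 1.5),
    min      = c(0, 0, 17, 0, 0, 0, 0),
    max      = c(100, 100, 68, 52, 60, 70, 9))
}

# truncated-normal draw via inverse CDF (deterministic under the RNG state)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# continuous angle profile theta(t): standing dwell padded raised-cosine
# flexion cycles between theta_max and the per-repetition depths
theta_profile <- function(t, truth) {
  k <- length(truth$depths)
  period <- truth$period_s
  dwell <- truth$dwell_frac
  theta <- rep(truth$theta_max, length(t))
  in_reps <- t >= truth$pad_s & t < truth$pad_s + k * period
  tt <- t[in_reps] - truth$pad_s
  rep_i <- pmin(floor(tt / period) + 1, k)
  u <- tt / period - (rep_i - 1)
  d2 <- dwell / 2
  moving <- u >= d2 & u <= 1 - d2
  v <- (u - d2) / (1 - dwell)
  amp <- truth$theta_max - truth$depths[rep_i]
  th <- rep(truth$theta_max, length(tt))
  th[moving] <- truth$theta_max -
    (amp[moving] * (1 - cos(2 * pi * v[moving])) / 2)
  theta[in_reps] <- th
  theta
}

draw_participant_truth <- function(spec, class_label) {
  theta_max <- min(179, stats::rnorm(1, spec$theta_max_mean,
                                     spec$theta_max_sd))
  theta_min <- stats::rnorm(1, spec$theta_min_mean[[class_label]],
                            spec$theta_min_sd[[class_label]])
  theta_min <- min(theta_min, theta_max - 20)   # keep a real excursion
  k <- sample(seq(spec$reps_range[1], spec$reps_range[2]), 1L)
  period_s <- max(1.5, stats::rnorm(1, spec$period_mean_s[[class_label]],
                                    spec$period_sd_s[[class_label]]))
  depths <- rtrunc_norm(k, theta_min, spec$depth_jitter_sd,
                        5, theta_max - 15)
  truth <- list(class_label = class_label, theta_max = theta_max,
                theta_min = theta_min, k = k, period_s = period_s,
                period_frames = period_s * spec$fps, depths = depths,
                dwell_frac = spec$dwell_frac, pad_s = spec$pad_s)
  # analytic full-flexion minima: mid-movement of each repetition
  truth$minima_s <- spec$pad_s + (seq_len(k) - 0.5) * period_s
  truth$minima_frames <- round(truth$minima_s * spec$fps) + 1L
  truth
}

synth_keypoints <- function(truth, spec) {
  duration <- 2 * spec$pad_s + truth$k * truth$period_s
  n <- floor(duration * spec$fps) + 1L
  t <- (seq_len(n) - 1) / spec$fps
  theta <- theta_profile(t, truth)
  phi <- (180 - theta) * pi / 180
  ankle <- matrix(0, n, 2L)
  hip <- cbind(rep(0, n), rep(spec$hip_height_px, n))
  neck <- hip + spec$trunk_len_px * cbind(sin(phi), cos(phi))
  if (spec$pixel_noise_sd > 0) {
    noise <- function() matrix(stats::rnorm(2L * n, 0, spec$pixel_noise_sd),
                               n, 2L)
    ankle <- ankle + noise()
    hip <- hip + noise()
    neck <- neck + noise()
  }
  list(ankle = ankle, hip = hip, neck = neck, theta = theta, t = t)
}

#' Generate one synthetic participant
#'
#' Draws per-participant standing angle, full-flexion angle, repetition
#' count and period, and per-repetition depths; builds the angle profile as
#' raised-cosine flexion cycles with standing dwell; synthesises ankle/hip/
#' neck keypoints from a planar two-segment model (ankle at the origin, hip
#' vertically above, neck at the end of the trunk segment) plus isotropic
#' pixel noise; and draws class-conditional PROMs.  Uses the current RNG
#' state (see [generate_cohort()] for seeded cohorts).
#'
#' @param spec A [cohort_spec()].
#' @param class_label `"MI"` or `"MCI"`.
#' @param participant_id Identifier for the generated records.
#' @return List with `trajectory` ([keypoint_trajectory()]), `proms`
#'   (one-row data frame), `label`, and `truth` (all latent parameters:
#'   ground-truth angle profile, depths, minima frames).
#' @export
generate_participant <- function(spec, class_label = c("MI", "MCI"),
                                 participant_id = "P001") {
  stopifnot(inherits(spec, "cohort_spec"))
  class_label <- match.arg(class_label)
  truth <- draw_participant_truth(spec, class_label)
  kp <- synth_keypoints(truth, spec)
  truth$theta <- kp$theta
  traj <- keypoint_trajectory(participant_id, kp$ankle, kp$hip, kp$neck,
                              fps = spec$fps)
  pp <- spec$proms_params
  mcol <- if (class_label == "MI") "mean_mi" else "mean_mci"
  scores <- vapply(PROMS_FEATURES, function(f) {
    round(rtrunc_norm(1, pp[f, mcol], pp[f, "sd"], pp[f, "min"],
                      pp[f, "max"]))
  }, numeric(1))
  proms <- as.data.frame(as.list(scores))
  proms <- cbind(participant_id = participant_id, proms)
  list(trajectory = traj, proms = proms, label = class_label, truth = truth)
}

#' Generate a labelled synthetic cohort
#'
#' Deterministic under the spec seed: the same spec yields byte-identical
#' cohorts.  MI participants are generated first, then MCI.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `spineflex_cohort`: `participants` (named list
#'   from [generate_participant()]), `proms` and `labels` data frames, and
#'   the `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("MI", spec$n_mi), rep("MCI", spec$n_mci))
  ids <- sprintf("P%03d", seq_along(labels))
  participants <- with_local_seed(spec$seed, {
    mapply(function(lab, id) generate_participant(spec, lab, id),
           labels, ids, SIMPLIFY = FALSE)
  })
  names(participants) <- ids
  proms <- do.call(rbind, lapply(participants, `[[`, "proms"))
  rownames(proms) <- NULL
  structure(list(participants = participants,
                 proms = validate_proms(proms),
                 labels = data.frame(participant_id = ids, label = labels),
                 spec = spec),
            class = "spineflex_cohort")
}

#' @export
print.spineflex_cohort <- function(x, ...) {
  cat(sprintf("<spineflex_cohort> %d participants (%d MI, %d MCI), seed %d\n",
              length(x$participants), sum(x$labels$label == "MI"),
              sum(x$labels$label == "MCI"), x$spec$seed))
  invisible(x)
}

#' Extract the full 16-feature table of a cohort
#'
#' Runs the kinematic pipeline (angle waveform, smoothing, minima
#' detection, feature extraction) for every participant and joins the
#' PROMs, yielding the feature table the classifier consumes.
#'
#' @param cohort A `spineflex_cohort` (or a list with `participants`,
#'   `proms`, `labels` of the same shape).
#' @param smooth_window Moving-average window in frames (default 30).
#' @return Data frame with `participant_id`, `label`, the nine angle
#'   features and the seven PROMs in canonical order.
#' @export
cohort_features <- function(cohort, smooth_window = 30) {
  feats <- lapply(cohort$participants, function(p) {
    wave <- smooth_waveform(angle_waveform(p$trajectory), smooth_window)
    as.data.frame(as.list(extract_angle_features(wave)))
  })
  angle_df <- do.call(rbind, feats)
  angle_df <- cbind(participant_id = names(cohort$participants), angle_df)
  rownames(angle_df) <- NULL
  out <- merge(cohort$labels, angle_df, by = "participant_id", sort = FALSE)
  out <- merge(out, cohort$proms[, c("participant_id", PROMS_FEATURES)],
               by = "participant_id", sort = FALSE)
  out[, c("participant_id", "label", ANGLE_FEATURES, PROMS_FEATURES)]
}

#' Motion-capture twin of a synthetic participant
#'
#' Realises the participant's ground-truth angle profile as a 120 Hz 3-D
#' marker set: C7 at the end of the trunk segment, the four pelvic markers
#' symmetric about the hip (so their centroid is the hip), and L4 on the
#' vertical ankle--hip axis at a positive height, so that zeroing its
#' vertical coordinate (the virtual-ankle construction) lands exactly on
#' the model's ankle.  Optional isotropic marker noise exercises the
#' criterion-validation error bound.
#'
#' @param participant One element of a cohort's `participants` list.
#' @param spec The [cohort_spec()] used to generate the cohort.
#' @param noise_sd_mm Marker noise standard deviation (default: the spec's
#'   `marker_noise_sd_mm`).
#' @param mocap_fps Capture rate (default 120).
#' @return A [mocap_trial()] with vertical axis `"y"`.
#' @export
generate_mocap_twin <- function(participant, spec,
                                noise_sd_mm = spec$marker_noise_sd_mm,
                                mocap_fps = 120) {
  truth <- participant$truth
  n30 <- nrow(participant$trajectory$ankle)
  duration <- (n30 - 1) / spec$fps
  n <- floor(duration * mocap_fps) + 1L
  t <- (seq_len(n) - 1) / mocap_fps
  theta <- theta_profile(t, truth)
  phi <- (180 - theta) * pi / 180
  hip <- cbind(rep(0, n), rep(spec$hip_height_mm, n), rep(0, n))
  trunk <- spec$trunk_len_mm * cbind(sin(phi), cos(phi), rep(0, n))
  c7 <- hip + trunk
  l4 <- cbind(rep(0, n), rep(spec$l4_height_frac * spec$hip_height_mm, n),
              rep(0, n))
  hw <- spec$pelvis_halfwidth_mm
  hd <- spec$pelvis_depth_mm / 2
  markers <- list(
    C7 = c7, L4 = l4,
    LASIS = hip + matrix(c(hd, 0, -hw), n, 3L, byrow = TRUE),
    RASIS = hip + matrix(c(hd, 0, hw), n, 3L, byrow = TRUE),
    LPSIS = hip + matrix(c(-hd, 0, -hw), n, 3L, byrow = TRUE),
    RPSIS = hip + matrix(c(-hd, 0, hw), n, 3L, byrow = TRUE))
  if (noise_sd_mm > 0) {
    markers <- lapply(markers, function(m)
      m + matrix(stats::rnorm(length(m), 0, noise_sd_mm), nrow(m), 3L))
  }
  mocap_trial(participant$trajectory$participant_id, markers,
              fps = mocap_fps, vertical_axis = "y")
}
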