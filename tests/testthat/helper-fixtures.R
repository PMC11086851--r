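# shared fixtures: all synthetic, built in code at test time

make_wave <- function(theta, fps = 30, smoothed = FALSE, source = "pose") {
  spineflex:::new_angle_waveform(theta, fps, smoothed, source)
}

# small noise-free cohort spec for parameter-recovery checks
noise_free_spec <- function(n_mi = 4, n_mci = 4, seed = 101, ...) {
  cohort_spec(n_mi = n_mi, n_mci = n_mci, pixel_noise_sd = 0,
              marker_noise_sd_mm = 0, seed = seed, ...)
}

# feature table with a known signal structure: `signal_features` separate
# the classes by `delta` (in units of the noise sd), everything else is
# standard normal noise.  Returns a data.frame with canonical columns.
make_signal_features <- function(n_per_class = 50, delta = 6,
                                 signal_features = c("range",
                                                     "rep_time_mean"),
                                 seed = 1) {
  all_feats <- c(angle_feature_names(), proms_feature_names())
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("MI", "MCI"), each = n_per_class)
  df <- as.data.frame(matrix(rnorm(n * length(all_feats)), n,
                             dimnames = list(NULL, all_feats)))
  for (f in signal_features) {
    df[[f]] <- df[[f]] + ifelse(labels == "MI", delta / 2, -delta / 2)
  }
  df$label <- labels
  df
}

# deterministic moving-average oracle by direct summation
naive_moving_average <- function(x, lo_off, hi_off) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i + lo_off)
    hi <- min(n, i + hi_off)
    mean(x[lo:hi])
  }, numeric(1))
}
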