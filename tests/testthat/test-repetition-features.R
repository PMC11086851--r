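cosine_wave <- function(periods = 8, T_s = 3, fps = 30, mean = 140,
                        amp = 40) {
  t <- (0:(periods * T_s * fps)) / fps
  make_wave(mean + amp * cos(2 * pi * t / T_s), fps = fps)
}

test_that("minima of a periodic flexion waveform are found at the analytic positions", {
  wave <- smooth_waveform(cosine_wave(periods = 8, T_s = 3), 30)
  minima <- detect_flexion_minima(wave)
  analytic <- round((3 / 2 + (0:7) * 3) * 30) + 1   # cos = -1
  expect_length(minima, 8)
  expect_true(all(abs(minima - analytic) <= 3))
  expect_true(all(diff(minima) > 0))
})

test_that("constant and unsmoothed waveforms are rejected", {
  const <- smooth_waveform(make_wave(rep(150, 300)), 30)
  expect_error(detect_flexion_minima(const),
               class = "spineflex_insufficient_repetitions")
  expect_error(detect_flexion_minima(cosine_wave()), "smoothed")
})

test_that("generator repetition count is recovered on noise-free trials", {
  spec <- noise_free_spec(seed = 55)
  for (cls in c("MI", "MCI")) {
    p <- generate_participant(spec, cls, paste0("R", cls))
    wave <- smooth_waveform(angle_waveform(p$trajectory), 30)
    minima <- detect_flexion_minima(wave)
    expect_length(minima, p$truth$k)
    expect_true(all(abs(minima - p$truth$minima_frames) <= 5))
  }
})

test_that("repetition times are frame differences of consecutive minima", {
  expect_equal(repetition_times(c(30, 120, 210)), c(90, 90))
  expect_equal(repetition_times(c(10, 50)), 40)
  expect_error(repetition_times(55),
               class = "spineflex_insufficient_repetitions")
  expect_error(repetition_times(c(50, 10)), "increasing")
})

test_that("generator period is recovered through detected repetition times", {
  spec <- noise_free_spec(seed = 77)
  p <- generate_participant(spec, "MI", "R3")
  wave <- smooth_waveform(angle_waveform(p$trajectory), 30)
  tr <- repetition_times(detect_flexion_minima(wave))
  expect_lt(abs(mean(tr) - p$truth$period_frames), 5)
})

test_that("movement stability is the second-half minus first-half range", {
  # symmetric waveform: halves have equal range
  sym <- make_wave(140 + 30 * cos(2 * pi * (0:239) / 60))
  expect_equal(movement_stability(sym), 0)
  # hand-constructed ranges: [100,160] then [90,160] -> +10
  w <- make_wave(c(100, 160, 130, 130, 90, 160, 120, 120))
  expect_equal(movement_stability(w), 10)
  # random waveform vs direct computation
  set.seed(9)
  x <- runif(101, 95, 175)
  half <- floor(101 / 2)
  want <- diff(range(x[(half + 1):101])) - diff(range(x[1:half]))
  expect_equal(movement_stability(make_wave(x)), want)
  expect_error(movement_stability(make_wave(c(150, 150, 150))), "4 frames")
})

test_that("extracted features match hand computation with mocked minima", {
  x <- c(100, 120, 140, 160, 180)
  wave <- make_wave(x, smoothed = TRUE)
  feats <- extract_angle_features(wave, minima = c(1L, 3L, 5L))
  expect_named(feats, angle_feature_names())
  expect_equal(feats[["min_angle"]], 100)
  expect_equal(feats[["max_angle"]], 180)
  expect_equal(feats[["range"]], 80)
  expect_equal(feats[["variance"]], var(x))      # sample variance, ddof 1
  expect_equal(feats[["std_dev"]], sd(x))
  expect_equal(feats[["std_dev"]]^2, feats[["variance"]], tolerance = 1e-9)
  expect_equal(feats[["rep_time_mean"]], 2)
  expect_equal(feats[["rep_time_variance"]], 0)
  expect_equal(feats[["depth_variance"]], var(x[c(1, 3, 5)]))
})

test_that("constant waveform with forced minima gives zero dispersion", {
  wave <- make_wave(rep(150, 120), smoothed = TRUE)
  feats <- extract_angle_features(wave, minima = c(30L, 60L, 90L))
  expect_equal(feats[["variance"]], 0)
  expect_equal(feats[["std_dev"]], 0)
  expect_equal(feats[["min_angle"]], 150)
  expect_equal(feats[["max_angle"]], 150)
  expect_equal(feats[["range"]], 0)
  expect_equal(feats[["depth_variance"]], 0)
})

test_that("noise-free periodic waveforms give near-zero timing and depth variance", {
  spec <- noise_free_spec(seed = 88, depth_jitter_sd = 0)
  p <- generate_participant(spec, "MCI", "R4")
  wave <- smooth_waveform(angle_waveform(p$trajectory), 30)
  feats <- extract_angle_features(wave)
  expect_lt(feats[["rep_time_variance"]], 2)
  expect_lt(feats[["depth_variance"]], 0.05)
})

test_that("features are stable under brief standing padding", {
  spec <- noise_free_spec(seed = 99)
  p <- generate_participant(spec, "MI", "R5")
  wave <- smooth_waveform(angle_waveform(p$trajectory), 30)
  base <- extract_angle_features(wave)
  theta_raw <- angle_waveform(p$trajectory)$theta
  padded <- make_wave(c(rep(theta_raw[1], 5), theta_raw,
                        rep(theta_raw[length(theta_raw)], 5)))
  pf <- extract_angle_features(smooth_waveform(padded, 30))
  expect_lt(abs(pf[["min_angle"]] - base[["min_angle"]]), 0.5)
  expect_lt(abs(pf[["max_angle"]] - base[["max_angle"]]), 0.5)
  expect_lt(abs(pf[["rep_time_mean"]] - base[["rep_time_mean"]]), 3)
  expect_length(pf, 9)
})
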