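test_that("spine flexion angle matches known geometries", {
  expect_equal(spine_flexion_angle(c(0, 0), c(0, 1), c(0, 2)), 180)
  expect_equal(spine_flexion_angle(c(0, 0), c(0, 1), c(1, 1)), 90)
  expect_equal(spine_flexion_angle(c(0, 0), c(1, 0), c(0.5, 0.8660254)), 60,
               tolerance = 1e-6)
})

test_that("angle agrees with a dot-product oracle on random triangles", {
  set.seed(7)
  n <- 1000
  ankle <- matrix(rnorm(2 * n, sd = 100), n, 2)
  hip <- ankle + matrix(rnorm(2 * n, sd = 50), n, 2)
  neck <- hip + matrix(rnorm(2 * n, sd = 50), n, 2)
  got <- spine_flexion_angle(ankle, hip, neck)
  # independent oracle: angle at hip via the dot product of hip->ankle and
  # hip->neck
  u <- ankle - hip
  v <- neck - hip
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  want <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("angle is invariant under similarity transforms and reflection", {
  set.seed(11)
  for (i in 1:50) {
    pts <- matrix(rnorm(6, sd = 10), 3, 2)
    base <- spine_flexion_angle(pts[1, ], pts[2, ], pts[3, ])
    s <- runif(1, 0.1, 50)
    phi <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    shift <- rnorm(2, sd = 100)
    tr <- t(s * R %*% t(pts)) + rep(shift, each = 3)
    expect_lt(abs(spine_flexion_angle(tr[1, ], tr[2, ], tr[3, ]) - base),
              1e-9)
    refl <- pts %*% diag(c(1, -1))   # y-down image coordinates
    expect_lt(abs(spine_flexion_angle(refl[1, ], refl[2, ], refl[3, ]) -
                    base), 1e-9)
  }
})

test_that("degenerate geometry errors name the offending pair", {
  expect_error(spine_flexion_angle(c(0, 0), c(1, 1), c(1, 1)),
               "hip and neck")
  expect_error(spine_flexion_angle(c(1, 1), c(1, 1), c(0, 3)),
               "ankle and hip")
})

test_that("angle waveform recovers the generator's ground-truth angle", {
  p <- generate_participant(noise_free_spec(), "MCI", "T01")
  wave <- angle_waveform(p$trajectory)
  expect_equal(wave$source, "pose")
  expect_false(wave$smoothed)
  expect_lt(max(abs(wave$theta - p$truth$theta)), 1e-6)
})

test_that("upright trajectory gives a constant 180-degree waveform", {
  n <- 100
  traj <- keypoint_trajectory("U1",
                              ankle = cbind(rep(0, n), 0),
                              hip = cbind(rep(0, n), 100),
                              neck = cbind(rep(0, n), 200))
  expect_equal(angle_waveform(traj)$theta, rep(180, n))
})

test_that("trajectory constructor rejects invalid input", {
  expect_error(keypoint_trajectory("E", matrix(0, 0, 2), matrix(0, 0, 2),
                                   matrix(0, 0, 2)), "no frames")
  expect_error(keypoint_trajectory("E", cbind(0, 0), cbind(0, 0),
                                   cbind(1, 1)), "coincident")
  expect_error(keypoint_trajectory("E", cbind(0, 0), cbind(0, 1),
                                   cbind(1, 1), fps = 0), "fps")
})

test_that("smoothing preserves constants, interior ramps, and range", {
  const <- make_wave(rep(150, 120))
  sm <- smooth_waveform(const, 30)
  expect_equal(sm$theta, rep(150, 120))
  expect_true(sm$smoothed)
  expect_length(sm$theta, 120)

  # centred odd window leaves the interior of a linear ramp unchanged
  ramp <- make_wave(seq(100, 160, length.out = 121))
  sm_odd <- smooth_waveform(ramp, 31)
  interior <- 16:106
  expect_equal(sm_odd$theta[interior], ramp$theta[interior],
               tolerance = 1e-10)
  # the default even window shifts a ramp by at most half a frame's slope
  sm_even <- smooth_waveform(ramp, 30)
  slope <- 60 / 120
  expect_lt(max(abs(sm_even$theta[interior] - ramp$theta[interior])),
            slope / 2 + 1e-10)

  # never widens the value range
  set.seed(3)
  noisy <- make_wave(runif(200, 90, 170))
  smn <- smooth_waveform(noisy, 30)
  expect_gte(min(smn$theta), min(noisy$theta))
  expect_lte(max(smn$theta), max(noisy$theta))
})

test_that("smoothing an interior unit impulse spreads 1/window mass", {
  n <- 150
  x <- rep(100, n)
  x[75] <- 101
  sm <- smooth_waveform(make_wave(x), 30)
  # direct-convolution oracle over the interior window span [i-15, i+14]
  spread <- which(abs(sm$theta - 100) > 1e-12)
  expect_length(spread, 30)
  expect_equal(sm$theta[spread], rep(100 + 1 / 30, 30), tolerance = 1e-12)
})

test_that("smoothing rejects too-short waveforms", {
  expect_error(smooth_waveform(make_wave(rep(150, 10)), 30), "shorter")
})

test_that("resampling preserves constants, ramps, and sinusoids", {
  const <- make_wave(rep(120, 481), fps = 120)
  rs <- resample_waveform(const, 30)
  expect_equal(rs$fps, 30)
  expect_length(rs$theta, 121)
  expect_equal(rs$theta, rep(120, 121))

  ramp <- make_wave(seq(90, 170, length.out = 481), fps = 120)
  rs2 <- resample_waveform(ramp, 30)
  expect_equal(rs2$theta, seq(90, 170, length.out = 481)[seq(1, 481, 4)],
               tolerance = 1e-12)

  t120 <- (0:719) / 120   # 6 s
  sine <- make_wave(140 + 30 * sin(2 * pi * t120 / 3), fps = 120)
  rs3 <- resample_waveform(sine, 30)
  t30 <- (seq_along(rs3$theta) - 1) / 30
  expect_lt(max(abs(rs3$theta - (140 + 30 * sin(2 * pi * t30 / 3)))), 0.1)
})

test_that("waveform MSE matches direct computation and contracts", {
  a <- make_wave(rep(150, 50))
  expect_equal(waveform_mse(a, a), 0)
  b <- make_wave(rep(152, 50))
  expect_equal(waveform_mse(a, b), 4)
  set.seed(5)
  x <- make_wave(runif(10, 100, 170))
  y <- make_wave(runif(10, 100, 170))
  expect_equal(waveform_mse(x, y), mean((x$theta - y$theta)^2))
  # fps mismatch instructs resampling; length gap > 2 rejected
  expect_error(waveform_mse(a, make_wave(rep(150, 50), fps = 120)),
               "resample")
  expect_error(waveform_mse(a, make_wave(rep(150, 40))), "differ")
  expect_equal(waveform_mse(a, make_wave(rep(150, 48))), 0)
})
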