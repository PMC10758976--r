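# ROM primitives: static extraction, phase windows, averaging, normalization.

test_that("static ROM measures baseline-to-extremum excursion", {
  ramp <- c(rep(0, 24), seq(0, 150, length.out = 200))
  expect_equal(static_rom(ramp, "sho_flex"), 150, tolerance = 1e-9)
  ## without a hold the baseline is the mean over the first 0.25 s
  pure <- seq(0, 150, length.out = 200)
  expect_equal(static_rom(pure, "sho_flex"), 150 - mean(pure[1:24]),
               tolerance = 1e-9)
  expect_equal(static_rom(rep(12, 100), "sho_flex"), 0)
  series <- c(rep(5, 24), seq(5, 142, length.out = 150), rep(142, 30))
  expect_equal(static_rom(series, "elb_flex"), 137, tolerance = 1e-9)
  ## downward task direction
  down <- c(rep(5, 24), seq(5, -41.2, length.out = 100))
  expect_equal(static_rom(down, "sho_ext"), 46.2, tolerance = 1e-9)
  expect_error(static_rom(rep(1, 10), "sho_flex"), "baseline window")
})

test_that("side averaging is the arithmetic mean with one-sided fallback", {
  expect_equal(average_sides(160, 170), 165)
  expect_equal(average_sides(77.2, 78.3), 77.75)
  expect_equal(average_sides(42.1, 42.1), 42.1)
  expect_warning(got <- average_sides(NA, 88), "missing")
  expect_equal(got, 88)
  expect_error(suppressWarnings(average_sides(NA, NA)), "both sides")
})

test_that("trial averaging pools repetitions", {
  expect_equal(average_trials(c(20, 22, 24, 26, 28)), 24)
  expect_equal(average_trials(31.4), 31.4)
  expect_equal(average_trials(c(29.1, 30.2, 28.9, 29.6, 30.0)), 29.56)
  expect_warning(got <- average_trials(c(10, NA, 14)), "missing")
  expect_equal(got, 12)
  expect_error(average_trials(numeric(0)), "no repetitions")
})

test_that("phase ROM is the windowed excursion", {
  ev <- shot_events(si = 40, sr = 120)
  expect_equal(phase_rom(rep(7, 200), ev, "si_sr"), 0)
  ## rising 10 -> 38 inside the window, excursion to 50 outside
  series <- c(seq(50, 10, length.out = 39),
              seq(10, 38, length.out = 81), seq(38, 50, length.out = 81))
  expect_equal(phase_rom(series, ev, "si_sr"), 28, tolerance = 1e-9)
  set.seed(202)
  x <- cumsum(rnorm(200))
  full <- shot_events(si = 1, sr = 200)
  expect_equal(phase_rom(x, full, "si_sr"), diff(range(x)))
  expect_error(phase_rom(x, ev, "si_st"), "swing-top")
})

test_that("phase ROM is monotone under window inclusion", {
  set.seed(203)
  for (i in 1:25) {
    x <- cumsum(rnorm(300))
    a <- sort(sample(2:299, 2))
    outer_ <- shot_events(si = a[1], sr = a[2] + 1)
    inner <- shot_events(si = a[1] + 1, sr = a[2])
    expect_lte(phase_rom(x, inner, "si_sr"), phase_rom(x, outer_, "si_sr"))
    expect_lte(phase_rom(x, outer_, "si_sr"), diff(range(x)))
  }
})

test_that("shot events enforce their ordering invariant", {
  expect_error(shot_events(si = 100, sr = 50), "ordering")
  expect_error(shot_events(si = 10, sr = 100, st = 5), "ordering")
  ev <- shot_events(si = 10, sr = 100, st = 50)
  expect_true(ev$si < ev$st && ev$st < ev$sr)
})

test_that("normalization and restriction percent follow the control ratio", {
  expect_equal(normalize_rom(20, 20), 1)
  expect_equal(normalize_rom(15, 30), 0.5)
  expect_equal(normalize_rom(20.08, 29.4), 0.683, tolerance = 5e-4)
  expect_error(normalize_rom(10, 0), "> 0")
  expect_equal(restriction_percent(100, 80), 20)
  expect_equal(restriction_percent(63.2, 63.2), 0)
  expect_equal(restriction_percent(29.4, 20.08), 31.7, tolerance = 1e-2)
  expect_lt(restriction_percent(50, 55), 0)  # pads can increase ROM
  expect_error(restriction_percent(0, 10), "> 0")
})

test_that("gimbal unfolding recovers excursions beyond 90 deg on X", {
  prox <- matrix(rep(c(1, 0, 0, 0), each = 180), ncol = 4)
  ang <- c(rep(0, 24), seq(0, -150, length.out = 156))
  dist <- euler_yxz_quat(rep(0, 180), ang, rep(0, 180))
  e <- unfold_gimbal(euler_yxz(joint_quaternion(prox, dist)))
  expect_equal(e$angle_x, ang, tolerance = 1e-6)
  expect_equal(static_rom(e$angle_x, "sho_abd"), 150, tolerance = 1e-6)
  ## no-op away from the singularity
  mild <- euler_yxz(rotation_quat("x", seq(0, 60, length.out = 50)))
  expect_identical(unfold_gimbal(mild), mild)
})
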