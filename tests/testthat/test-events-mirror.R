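# Shot-event detection and handedness mirroring.

test_that("detected events hit generator ground truth within 3 frames", {
  cfg <- generator_config(seed = 501)
  for (task in c("wrist_shot", "slap_shot")) {
    for (p in c(1, 4)) {
      res <- generate_shot_trial(cfg, p, "heilong", task, 1)
      gt <- res$ground_truth$events
      ev <- detect_shot_events(res$trial)
      expect_lte(abs(ev$si - gt$si), 3)
      expect_lte(abs(ev$sr - gt$sr), 3)
      if (task == "slap_shot") {
        expect_lte(abs(ev$st - gt$st), 3)
        expect_true(ev$si < ev$st && ev$st < ev$sr)
      } else {
        expect_true(is.na(ev$st))
        expect_true(is.na(gt$st))
      }
    }
  }
})

test_that("a motionless trial raises a no-shot error", {
  expect_error(detect_shot_events(constant_trial()), "no shot detected")
  expect_error(detect_shot_events(constant_trial(task = "sho_flex")),
               "shot tasks only")
})

test_that("mirroring is an involution that swaps sides", {
  cfg <- generator_config(seed = 502)
  trial <- generate_shot_trial(cfg, 1, "no_pads", "slap_shot", 1)$trial
  back <- mirror_trial(mirror_trial(trial))
  expect_identical(back$handedness, trial$handedness)
  expect_equal(back$segments, trial$segments, tolerance = 1e-12)
  once <- mirror_trial(trial)
  expect_equal(once$segments$upper_arm_L, {
    m <- trial$segments$upper_arm_R
    cbind(w = m[, 1], x = -m[, 2], y = m[, 3], z = -m[, 4])
  }, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("left-handed trials pass through handedness conversion unchanged", {
  cfg <- generator_config(seed = 503)
  trial <- generate_shot_trial(cfg, 1, "no_pads", "wrist_shot", 1)$trial
  expect_identical(trial$handedness, "left")
  expect_identical(mirror_handedness(trial), trial)
})

test_that("converted right-handed shots reproduce the left-handed template", {
  cfg <- generator_config(seed = 504)
  ## participants 8 and 9 are right-handed in the default mix
  res <- generate_shot_trial(cfg, 8, "bauer_nsx", "wrist_shot", 1)
  expect_identical(res$trial$handedness, "right")
  rec <- extract_trial_rom(res$trial)
  gt <- unlist(res$ground_truth$phase_rom)
  key <- paste0(rec$joint_plane, ":", rec$phase)
  expect_lt(max(abs(rec$rom_deg - gt[key])), 1.5)
})
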