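# The synthetic study generator: ground-truth fidelity, determinism,
# stream validity, and the coupled survey.

test_that("noiseless static trials round-trip through the kinematics", {
  cfg <- generator_config(noise_sd = 0, between_sd = 0, interaction_sd = 0,
                          rep_sd = 0, side_sd = 0, seed = 601)
  res <- generate_static_trial(cfg, 1, "no_pads", "sho_flex", 1)
  expect_equal(res$ground_truth$rom_L,
               unname(reference_control_rom()["shoulder_flexion"]))
  ang <- unfold_gimbal(joint_angles(res$trial, "shoulder", "L",
                                    filter = FALSE))
  expect_equal(static_rom(ang$angle_y, "sho_flex"), res$ground_truth$rom_L,
               tolerance = 1e-6)
  ## the filtered pipeline stays within a tenth of a degree
  rec <- extract_trial_rom(res$trial)
  expect_lt(max(abs(rec$rom_deg - res$ground_truth$rom_L)), 0.1)
})

test_that("restriction factors scale the generated ROM", {
  restr <- reference_restriction_factors()
  restr$static[, setdiff(pad_conditions(), "no_pads")] <- 0.85
  cfg <- generator_config(noise_sd = 0, between_sd = 0, interaction_sd = 0,
                          rep_sd = 0, side_sd = 0, restriction = restr,
                          seed = 602)
  ctrl <- generate_static_trial(cfg, 1, "no_pads", "elb_flex", 1)
  pad <- generate_static_trial(cfg, 1, "heilong", "elb_flex", 1)
  a_ctrl <- unfold_gimbal(joint_angles(ctrl$trial, "elbow", "L",
                                       filter = FALSE))$angle_y
  a_pad <- unfold_gimbal(joint_angles(pad$trial, "elbow", "L",
                                      filter = FALSE))$angle_y
  ratio <- static_rom(a_pad, "elb_flex") / static_rom(a_ctrl, "elb_flex")
  expect_equal(ratio, 0.85, tolerance = 1e-6)
})

test_that("generated orientation streams are unit-norm and sign-continuous", {
  cfg <- generator_config(seed = 603)
  for (gen in list(generate_static_trial(cfg, 2, "vik_max", "sho_abd", 1),
                   generate_shot_trial(cfg, 2, "vik_max", "slap_shot", 1))) {
    for (m in gen$trial$segments) {
      expect_lt(max(abs(rowSums(m^2) - 1)), 1e-9)
      dots <- rowSums(m[-1, ] * m[-nrow(m), ])
      expect_true(all(dots >= 0))
    }
  }
})

test_that("the same seed reproduces a study byte for byte", {
  cfg <- tiny_config(seed = 604)
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_study(cfg, d1)
  write_study(cfg, d2)
  for (f in dir(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_error(write_study(cfg, d1), "not empty")
  manifest <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(manifest),
               2 * 1 * 3 * 2)  # participants x reps x tasks x conditions
  expect_setequal(manifest$file, setdiff(dir(d1), c("manifest.csv",
                                                    "survey.csv",
                                                    "ground_truth.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("wrist-shot ground truth carries no swing-top event", {
  cfg <- generator_config(seed = 605)
  res <- generate_shot_trial(cfg, 3, "ibx", "wrist_shot", 2)
  expect_true(is.na(res$ground_truth$events$st))
  expect_false(any(grepl("si_st|st_sr",
                         names(res$ground_truth$phase_rom))))
})

test_that("survey scores stay on the Likert scale and track restriction", {
  cfg <- generator_config(seed = 606)
  sv <- generate_survey(cfg)
  expect_true(all(sv$score %in% 1:5))
  expect_equal(nrow(sv), 9 * 5 * 2 * 4)
  ## full coupling, zero orthogonal noise: ranking exactly inverse
  cfg1 <- generator_config(comfort_coupling = 1, seed = 607)
  sv1 <- generate_survey(cfg1)
  r <- attr(sv1, "restriction")
  tot_r <- (r$shoulder + r$elbow) / 2
  cs <- comfort_scores(sv1)[names(tot_r)]
  expect_identical(rank(cs), rank(-tot_r))
  ## zero coupling: correlation centred on zero across seeds
  rhos <- vapply(1:30, function(s) {
    cfg0 <- generator_config(comfort_coupling = 0, seed = 7000 + s)
    sv0 <- generate_survey(cfg0)
    r0 <- attr(sv0, "restriction")
    t0 <- (r0$shoulder + r0$elbow) / 2
    spearman_corr(comfort_scores(sv0)[names(t0)], -t0)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)
})

test_that("generator validates its configuration", {
  expect_error(generator_config(comfort_coupling = 1.5), "comfort_coupling")
  restr <- reference_restriction_factors()
  restr$static[1, "no_pads"] <- 0.9
  expect_error(generator_config(restriction = restr), "control restriction")
  restr2 <- reference_restriction_factors()
  restr2$wrist[2, 3] <- 1.4
  expect_error(generator_config(restriction = restr2), "\\(0, 1\\]")
})
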