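# Likert aggregation and the comfort-mobility correlation.

## complete single-pad survey with controllable q1/shoulder scores
make_survey <- function(q1_shoulder, pads = "ibx") {
  np <- length(q1_shoulder)
  grid <- expand.grid(participant = sprintf("P%02d", seq_len(np)),
                      pad = pads, protector = protector_types(),
                      question = survey_questions(),
                      stringsAsFactors = FALSE)
  grid$score <- 3L
  sel <- grid$question == "q1_comfort" & grid$protector == "shoulder"
  grid$score[sel] <- as.integer(q1_shoulder[match(grid$participant[sel],
                                                  sprintf("P%02d", seq_len(np)))])
  grid
}

test_that("likert aggregation averages and ranks per pad", {
  sv <- make_survey(rep(3, 9))
  agg <- aggregate_likert(sv)
  expect_true(all(agg$by_protector$mean_score == 3))
  scores <- c(4, 4, 4, 4, 4, 3, 4, 4, 3)
  agg2 <- aggregate_likert(make_survey(scores))
  got <- agg2$by_protector
  got <- got$mean_score[got$question == "q1_comfort" &
                          got$protector == "shoulder"]
  expect_equal(got, mean(scores), tolerance = 1e-12)
  expect_equal(round(got, 1), 3.8)
  expect_true(all(agg2$pooled$mean_score >= 1 & agg2$pooled$mean_score <= 5))
})

test_that("duplicate and incomplete surveys are rejected", {
  sv <- make_survey(rep(4, 5))
  expect_error(aggregate_likert(rbind(sv, sv[1, ])), "duplicate")
  expect_error(aggregate_likert(sv[-1, ]), "incomplete")
  bad <- sv; bad$score[1] <- 6L
  expect_error(aggregate_likert(bad), "1-5")
})

test_that("total ROM sums condition means over the selected tasks", {
  cells <- data.frame(
    participant = rep(c("P01", "P02"), 3),
    condition = "ibx",
    task = rep(c("sho_flex", "elb_flex", "sho_ext"), each = 2),
    phase = "static",
    joint_plane = rep(c("shoulder_flexion", "elbow_flexion",
                        "shoulder_extension"), each = 2),
    rom_deg = c(158, 162, 38, 42, 30, 34))
  expect_equal(total_rom(cells, "ibx", tasks = "sho_flex"), 160)
  expect_equal(total_rom(cells, "ibx", tasks = c("sho_flex", "elb_flex")), 200)
  expect_equal(total_rom(cells, "ibx"), 232)
  expect_error(total_rom(cells, "no_pads"), "empty selection")
})

test_that("comfort-ROM correlation reports rho, p and band", {
  comfort <- c(a = 3.8, b = 3.4, c = 3.0, d = 2.6, e = 2.2)
  rom <- c(a = 800, b = 760, c = 720, d = 680, e = 640)
  res <- comfort_rom_correlation(comfort, rom)
  expect_equal(res$rho, 1)
  expect_identical(res$band, "high")
  rev_ <- comfort_rom_correlation(comfort, -rom)
  expect_lt(rev_$rho, 0)
  expect_error(comfort_rom_correlation(comfort[1:2], rom[1:2]), "3 pads")
  expect_error(comfort_rom_correlation(rep(3, 5), rom),
               "named")
})

test_that("comfort scores pool the comfort question over protectors", {
  sv <- make_survey(rep(4, 9))
  cs <- comfort_scores(sv)
  expect_equal(unname(cs["ibx"]), mean(c(rep(4, 9), rep(3, 9))))
  cs2 <- comfort_scores(sv, include_restricts = TRUE)
  expect_true(cs2["ibx"] != cs["ibx"])
})
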