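## Synthetic study generator: motion trials with ground-truth ROM and shot
## events, plus Likert surveys coupled to the injected restriction.  Every
## random draw comes from a counter-based substream keyed by the global seed
## and the trial labels, so any single trial is reproducible in isolation
## and a study is byte-identical across runs with the same seed.

## deterministic substream seed from the global seed and a label path
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

draw <- function(seed, ..., expr) {
  set.seed(substream_seed(seed, ...))
  expr
}

## minimum-jerk position profile on [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the study design: 9 participants (7 left-handed, 2
#' right-handed shooters), 6 pad conditions, 11 tasks, 5 repetitions at
#' 96 Hz.  Restriction factors (pad ROM over control ROM, in (0, 1]) are
#' seeded from the published condition tables
#' ([reference_restriction_factors()]); the control condition has factor 1
#' everywhere.  Noise defaults reflect motion-capture ROM repeatability:
#' between-participant SD 8 deg, participant-by-condition SD 3 deg,
#' repetition SD 1.5 deg, additive orientation noise 0.5 deg per Euler
#' channel per frame; dynamic amplitudes use proportional counterparts.
#' Comfort scores are coupled to injected restriction with Spearman-style
#' coupling `comfort_coupling` (default 0.9).
#'
#' @param n_participants Number of participants (default 9).
#' @param repetitions Repetitions per cell (default 5).
#' @param sample_rate Sampling frequency in Hz (default 96).
#' @param conditions Condition codes (default [pad_conditions()]).
#' @param tasks Task codes (default [study_tasks()]).
#' @param handedness Per-participant shooting side (default 7 left, 2 right,
#'   recycled to `n_participants`).
#' @param control_rom Named control ROM per static plane (degrees).
#' @param restriction Restriction factor matrices, see
#'   [reference_restriction_factors()].
#' @param between_sd,interaction_sd,rep_sd,side_sd Static ROM noise SDs in
#'   degrees: between participants, participant x condition, repetition, and
#'   left/right asymmetry.
#' @param dyn_participant_cv,dyn_interaction_cv,dyn_rep_cv Proportional
#'   counterparts for the dynamic phase amplitudes.
#' @param noise_sd Additive white orientation noise per Euler channel,
#'   degrees.
#' @param comfort_coupling Comfort-restriction coupling in `[-1, 1]`.
#' @param seed Global seed fixing the whole study.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_participants = 9, repetitions = 5,
                             sample_rate = 96,
                             conditions = pad_conditions(),
                             tasks = study_tasks(),
                             handedness = c(rep("left", 7), rep("right", 2)),
                             control_rom = reference_control_rom(),
                             restriction = reference_restriction_factors(),
                             between_sd = 8, interaction_sd = 3,
                             rep_sd = 1.5, side_sd = 1,
                             dyn_participant_cv = 0.08,
                             dyn_interaction_cv = 0.08, dyn_rep_cv = 0.05,
                             noise_sd = 0.5, comfort_coupling = 0.9,
                             seed = 20230) {
  stopifnot(n_participants >= 1, repetitions >= 1, sample_rate > 0,
            between_sd >= 0, interaction_sd >= 0, rep_sd >= 0, side_sd >= 0,
            noise_sd >= 0, abs(comfort_coupling) <= 1)
  if (!"no_pads" %in% conditions) stop("conditions must include the control")
  for (m in restriction) {
    if (any(m <= 0) || any(m > 1)) stop("restriction factors must be in (0, 1]")
    if (any(m[, "no_pads"] != 1)) stop("control restriction factor must be 1")
  }
  structure(list(
    n_participants = n_participants, repetitions = repetitions,
    sample_rate = sample_rate, conditions = conditions, tasks = tasks,
    handedness = rep_len(handedness, n_participants),
    control_rom = control_rom, restriction = restriction,
    between_sd = between_sd, interaction_sd = interaction_sd,
    rep_sd = rep_sd, side_sd = side_sd,
    dyn_participant_cv = dyn_participant_cv,
    dyn_interaction_cv = dyn_interaction_cv, dyn_rep_cv = dyn_rep_cv,
    noise_sd = noise_sd, comfort_coupling = comfort_coupling,
    seed = seed
  ), class = "generator_config")
}

participant_ids <- function(config) {
  sprintf("P%02d", seq_len(config$n_participants))
}

## ---- latent ROM model ------------------------------------------------------

## participant-level control ROM for a static plane (degrees)
participant_static_rom <- function(config, p_idx, plane) {
  base <- config$control_rom[[plane]]
  draw(config$seed, "part-static", p_idx, plane,
       expr = max(10, base + stats::rnorm(1, 0, config$between_sd)))
}

## participant x condition cell ROM for a static plane (degrees)
cell_static_rom <- function(config, p_idx, condition, plane) {
  f <- config$restriction$static[plane, condition]
  mu <- participant_static_rom(config, p_idx, plane) * f
  draw(config$seed, "cell-static", p_idx, condition, plane,
       expr = max(5, mu + stats::rnorm(1, 0, config$interaction_sd)))
}

## participant x condition phase amplitude for a dynamic plane (degrees)
cell_dynamic_amp <- function(config, p_idx, condition, task, phase, plane) {
  fm <- switch(paste(task, phase, sep = "."),
    wrist_shot.si_sr = config$restriction$wrist,
    slap_shot.si_st = config$restriction$slap_si_st,
    slap_shot.st_sr = config$restriction$slap_st_sr,
    stop("unknown task/phase"))
  base <- switch(paste(task, phase, sep = "."),
    wrist_shot.si_sr = printed_table("wrist"),
    slap_shot.si_st = printed_table("slap")[printed_table("slap")$phase == "si_st", ],
    slap_shot.st_sr = printed_table("slap")[printed_table("slap")$phase == "st_sr", ])
  b <- base$mean_no_pads[base$plane == plane]
  pf_ <- draw(config$seed, "part-dyn", p_idx, task, phase, plane,
              expr = 1 + stats::rnorm(1, 0, config$dyn_participant_cv))
  cf <- draw(config$seed, "cell-dyn", p_idx, condition, task, phase, plane,
             expr = 1 + stats::rnorm(1, 0, config$dyn_interaction_cv))
  max(1, b * pf_ * fm[plane, condition] * cf)
}

## ---- static trials ---------------------------------------------------------

## assemble segment streams for an arm chain from per-joint Euler channels
compose_arm_chain <- function(spine, shoulder, elbow, hand) {
  q_spine <- euler_yxz_quat(spine$y, spine$x, spine$z)
  q_ua <- quat_multiply(q_spine, euler_yxz_quat(shoulder$y, shoulder$x, shoulder$z))
  q_fa <- quat_multiply(q_ua, euler_yxz_quat(elbow$y, elbow$x, elbow$z))
  q_h <- quat_multiply(q_fa, euler_yxz_quat(hand$y, hand$x, hand$z))
  list(upper_arm = q_ua, forearm = q_fa, hand = q_h, spine = q_spine)
}

const_channels <- function(n, y = 0, x = 0, z = 0) {
  list(y = rep(y, n), x = rep(x, n), z = rep(z, n))
}

add_channel_noise <- function(ch, sd, rng_expr_seed) {
  if (sd == 0) return(ch)
  set.seed(rng_expr_seed)
  lapply(ch, function(v) v + stats::rnorm(length(v), 0, sd))
}

#' Generate one static-task trial
#'
#' Builds a smooth minimum-jerk angle profile on the task's joint plane —
#' a 0.5 s anatomical hold, a 1.5 s rise to the peak, a 0.75 s hold and a
#' 0.75 s return — for both sides, converts the joint channels to
#' proximal/distal quaternion streams, and adds white orientation noise on
#' the Euler channels.  The peak excursion is the participant-level control
#' ROM scaled by the condition's restriction factor plus cell/repetition
#' noise.
#'
#' @param config A [generator_config()].
#' @param participant Participant index (1-based) or id (`"P03"`).
#' @param condition Condition code.
#' @param task Static task code.
#' @param repetition Repetition number.
#' @return List with `trial` (a [trial_recording()]) and `ground_truth`
#'   (plane, per-side and cell-level true ROM in degrees).
#' @export
generate_static_trial <- function(config, participant, condition, task,
                                  repetition) {
  p_idx <- if (is.character(participant)) {
    match(participant, participant_ids(config))
  } else as.integer(participant)
  stopifnot(!is.na(p_idx), task %in% static_tasks())
  info <- static_task_table()
  info <- info[info$task == task, ]
  fs <- config$sample_rate
  n <- round(3.5 * fs) + 1L
  t_ <- (seq_len(n) - 1L) / fs
  cell <- cell_static_rom(config, p_idx, condition, info$plane)
  rom_side <- vapply(c("L", "R"), function(side) {
    draw(config$seed, "rep-static", p_idx, condition, task, repetition, side,
         expr = max(2, cell + stats::rnorm(1, 0, config$rep_sd) +
                       stats::rnorm(1, 0, config$side_sd)))
  }, numeric(1))

  ## profile: hold 0.5 s, rise 1.5 s, hold 0.75 s, return 0.75 s
  shape <- numeric(n)
  shape[t_ >= 0.5 & t_ < 2.0] <- min_jerk((t_[t_ >= 0.5 & t_ < 2.0] - 0.5) / 1.5)
  shape[t_ >= 2.0 & t_ < 2.75] <- 1
  shape[t_ >= 2.75] <- 1 - min_jerk((t_[t_ >= 2.75] - 2.75) / 0.75)
  base_angle <- 5

  build_side <- function(side) {
    profile <- base_angle + info$direction * rom_side[[side]] * shape
    joint_ch <- function(joint) {
      ch <- const_channels(n, y = 2, x = 2, z = 2)
      if (joint == info$joint) ch[[info$channel]] <- profile
      ch
    }
    sh <- add_channel_noise(joint_ch("shoulder"), config$noise_sd,
      substream_seed(config$seed, "noise", p_idx, condition, task,
                     repetition, side, "sh"))
    el <- add_channel_noise(joint_ch("elbow"), config$noise_sd,
      substream_seed(config$seed, "noise", p_idx, condition, task,
                     repetition, side, "el"))
    ha <- add_channel_noise(joint_ch("forearm"), config$noise_sd,
      substream_seed(config$seed, "noise", p_idx, condition, task,
                     repetition, side, "ha"))
    compose_arm_chain(const_channels(n), sh, el, ha)
  }
  left <- build_side("L"); right <- build_side("R")
  segments <- list(
    upper_spine = left$spine,
    upper_arm_L = left$upper_arm, upper_arm_R = right$upper_arm,
    forearm_L = left$forearm, forearm_R = right$forearm,
    hand_L = left$hand, hand_R = right$hand)
  trial <- trial_recording(participant_ids(config)[p_idx], condition, task,
                           repetition, config$handedness[p_idx], segments,
                           fs)
  list(trial = trial,
       ground_truth = list(plane = info$plane, cell_rom = cell,
                           rom_L = rom_side[["L"]], rom_R = rom_side[["R"]]))
}

## ---- shot trials ------------------------------------------------------------

## monotone rise/fall channel through the event frames; raised-cosine shape
## keeps the curvature at the swing-top peak non-zero so the extremum stays
## localizable under noise
raised_cos <- function(tau) (1 - cos(pi * pmin(1, pmax(0, tau)))) / 2

shot_channel <- function(n, si, st, sr, a_rise, a_fall, base = 10) {
  idx <- seq_len(n)
  ch <- rep(base, n)
  rise <- idx >= si & idx <= st
  ch[rise] <- base + a_rise * raised_cos((idx[rise] - si) / (st - si))
  fall <- idx > st & idx <= sr
  ch[fall] <- base + a_rise - a_fall * raised_cos((idx[fall] - st) / (sr - st))
  ch[idx > sr] <- base + a_rise - a_fall
  ch
}

## wrist-snap angular-speed profile (deg/s) peaking exactly at sr
snap_speed <- function(n, si, sr, fs, v_load = 250, v_peak = 1200) {
  t_ <- (seq_len(n) - 1L) / fs
  t_si <- (si - 1L) / fs; t_sr <- (sr - 1L) / fs
  ramp_dur <- 0.05; bump_w <- 0.30; decay <- 0.20
  v <- numeric(n)
  v <- v_load * min_jerk((t_ - t_si) / ramp_dur)
  v[t_ < t_si] <- 0
  after <- t_ > t_sr + bump_w
  v[after] <- v_load * (1 - min_jerk((t_[after] - t_sr - bump_w) / decay))
  bump <- abs(t_ - t_sr) <= bump_w
  v[bump] <- v[bump] + (v_peak - v_load) * cos(pi * (t_[bump] - t_sr) / (2 * bump_w))^2
  v
}

#' Generate one shooting trial
#'
#' Builds coordinated multi-joint profiles with embedded shot events.  Every
#' joint plane rises monotonically from shot initiation (SI) to the swing
#' top (ST) and falls to shot release (SR) — for the wrist shot there is a
#' single monotone excursion from SI to SR — so the designed per-phase
#' amplitudes are the ground-truth phase ROMs.  A dedicated wrist-snap
#' rotation gives the lead hand an angular-speed trace that peaks exactly at
#' SR; ground-truth events are recorded by running the event criteria on the
#' noiseless streams.  Right-handed participants are generated by mirroring
#' the left-handed template.
#'
#' @inheritParams generate_static_trial
#' @param task `"wrist_shot"` or `"slap_shot"`.
#' @return List with `trial` and `ground_truth` (events and per-plane,
#'   per-phase true ROM).
#' @export
generate_shot_trial <- function(config, participant, condition, task,
                                repetition) {
  p_idx <- if (is.character(participant)) {
    match(participant, participant_ids(config))
  } else as.integer(participant)
  stopifnot(!is.na(p_idx), task %in% dynamic_tasks())
  fs <- config$sample_rate
  slap <- task == "slap_shot"
  dur <- if (slap) 3.0 else 2.5
  n <- round(dur * fs) + 1L
  ev0 <- if (slap) c(si = 62L, st = 125L, sr = 192L) else c(si = 48L, sr = 120L)
  jit <- draw(config$seed, "events", p_idx, condition, task, repetition,
              expr = sample(-4:4, 1))
  ev <- ev0 + jit
  phases <- shot_phases(task)
  planes <- dynamic_plane_table()

  ## per-phase amplitude for each plane-side, with repetition noise
  amp <- function(plane_side, phase) {
    a <- cell_dynamic_amp(config, p_idx, condition, task, phase, plane_side)
    draw(config$seed, "rep-dyn", p_idx, condition, task, repetition,
         plane_side, phase,
         expr = max(1, a * (1 + stats::rnorm(1, 0, config$dyn_rep_cv))))
  }
  truth_rom <- list()
  side_channels <- function(side, noisy) {
    chans <- list(shoulder = const_channels(n), elbow = const_channels(n),
                  hand = const_channels(n))
    for (i in seq_len(nrow(planes))) {
      ps <- paste0(planes$plane[i], "_", side)
      if (slap) {
        a1 <- amp(ps, "si_st"); a2 <- amp(ps, "st_sr")
        truth_rom[[paste(ps, "si_st", sep = ":")]] <<- a1
        truth_rom[[paste(ps, "st_sr", sep = ":")]] <<- a2
        ch <- shot_channel(n, ev["si"], ev["st"], ev["sr"], a1, a2)
      } else {
        a <- amp(ps, "si_sr")
        truth_rom[[paste(ps, "si_sr", sep = ":")]] <<- a
        ch <- shot_channel(n, ev["si"], ev["sr"], ev["sr"], a, 0)
      }
      jn <- planes$joint[i]
      jn <- if (jn == "forearm") "hand" else jn
      chans[[jn]][[planes$channel[i]]] <- ch
    }
    ## lead-hand snap drives event detection
    if (side == "L") {
      v <- snap_speed(n, ev["si"], ev["sr"], fs)
      chans$hand$y <- cumsum(v) / fs
    }
    if (noisy && config$noise_sd > 0) {
      for (jn in names(chans)) {
        chans[[jn]] <- add_channel_noise(chans[[jn]], config$noise_sd,
          substream_seed(config$seed, "noise", p_idx, condition, task,
                         repetition, side, jn))
      }
    }
    chans
  }
  trunk <- function(noisy) {
    ch <- const_channels(n)
    ch$z <- 15 * min_jerk((seq_len(n) - ev["si"]) / (ev["sr"] - ev["si"]))
    if (noisy && config$noise_sd > 0) {
      ch <- add_channel_noise(ch, config$noise_sd,
        substream_seed(config$seed, "noise", p_idx, condition, task,
                       repetition, "trunk"))
    }
    ch
  }
  build <- function(noisy) {
    sp <- trunk(noisy)
    lf <- side_channels("L", noisy); rt <- side_channels("R", noisy)
    l <- compose_arm_chain(sp, lf$shoulder, lf$elbow, lf$hand)
    r <- compose_arm_chain(sp, rt$shoulder, rt$elbow, rt$hand)
    ident <- matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4,
                    dimnames = list(NULL, c("w", "x", "y", "z")))
    list(head = ident, upper_spine = l$spine, lower_spine = ident,
         upper_arm_L = l$upper_arm, upper_arm_R = r$upper_arm,
         forearm_L = l$forearm, forearm_R = r$forearm,
         hand_L = l$hand, hand_R = r$hand)
  }
  pid <- participant_ids(config)[p_idx]
  ## ground-truth events: the event criteria applied to the noiseless streams
  clean <- trial_recording(pid, condition, task, repetition, "left",
                           build(FALSE), fs)
  truth_events <- detect_shot_events(clean)
  trial <- trial_recording(pid, condition, task, repetition, "left",
                           build(TRUE), fs)
  if (config$handedness[p_idx] == "right") trial <- mirror_trial(trial)
  list(trial = trial,
       ground_truth = list(events = truth_events,
                           template_events = as.list(ev),
                           phase_rom = truth_rom))
}

#' Generate any trial of the design
#'
#' Dispatches to [generate_static_trial()] or [generate_shot_trial()].
#'
#' @inheritParams generate_static_trial
#' @export
generate_trial <- function(config, participant, condition, task, repetition) {
  if (task %in% static_tasks()) {
    generate_static_trial(config, participant, condition, task, repetition)
  } else {
    generate_shot_trial(config, participant, condition, task, repetition)
  }
}

## ---- survey -----------------------------------------------------------------

## mean injected restriction (1 - f) per pad for one protector
protector_restriction <- function(config, protector) {
  f <- config$restriction$static
  planes <- if (protector == "shoulder") {
    grep("^shoulder", rownames(f), value = TRUE)
  } else {
    c("elbow_flexion", "forearm_pronation", "forearm_supination")
  }
  pads <- setdiff(config$conditions, "no_pads")
  colMeans(1 - f[planes, pads, drop = FALSE])
}

#' Generate Likert survey responses coupled to injected restriction
#'
#' Latent-variable model: comfort (Q1) and willingness to wear (Q4) decrease
#' with each pad's injected restriction, perceived restriction (Q3)
#' increases with it, and safety (Q2) is independent.  The coupled component
#' has weight `comfort_coupling`; the orthogonal participant noise has
#' weight `sqrt(1 - coupling^2)`.  A deterministic per-participant leniency
#' offset spreads the rounding thresholds so pad means resolve finely.
#' Scores are clipped to 1-5.
#'
#' @param config A [generator_config()].
#' @return Survey data frame `participant,pad,protector,question,score` plus
#'   an attribute `"restriction"` with the per-pad injected restriction used.
#' @export
generate_survey <- function(config) {
  pads <- setdiff(config$conditions, "no_pads")
  np <- config$n_participants
  cc <- config$comfort_coupling
  lean <- (( seq_len(np) - 0.5) / np - 0.5) * 1.6
  rows <- list()
  restr <- list()
  for (prot in protector_types()) {
    r <- protector_restriction(config, prot)
    restr[[prot]] <- r
    z <- if (length(r) > 1 && stats::sd(r) > 0) {
      (r - mean(r)) / stats::sd(r)
    } else r * 0
    for (p in seq_len(np)) {
      e <- draw(config$seed, "survey", prot, p,
                expr = stats::rnorm(length(pads) * 3))
      e1 <- e[seq_along(pads)]
      e3 <- e[seq_along(pads) + length(pads)]
      e2 <- e[seq_along(pads) + 2 * length(pads)]
      lat1 <- cc * (-z) + sqrt(1 - cc^2) * e1
      lat3 <- cc * z + sqrt(1 - cc^2) * e3
      sc <- function(x) pmin(5L, pmax(1L, as.integer(round(x))))
      q1 <- sc(3.3 + 0.9 * lat1 + lean[p])
      q4 <- sc(3.1 + 0.9 * lat1 + lean[p])
      q3 <- sc(3.0 + 0.9 * lat3 + lean[p])
      q2 <- sc(3.8 + 0.5 * e2 + lean[p])
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant_ids(config)[p],
        pad = rep(pads, 4),
        protector = prot,
        question = rep(survey_questions(), each = length(pads)),
        score = c(q1, q2, q3, q4),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "restriction") <- restr
  out
}

## ---- whole study ------------------------------------------------------------

study_grid <- function(config) {
  g <- expand.grid(repetition = seq_len(config$repetitions),
                   task = config$tasks,
                   condition = config$conditions,
                   participant = participant_ids(config),
                   stringsAsFactors = FALSE)
  g[, c("participant", "condition", "task", "repetition")]
}

#' Write a complete synthetic study to disk
#'
#' Writes one trial CSV per design row (participant x condition x task x
#' repetition), a `manifest.csv`, a `survey.csv`, and a
#' `ground_truth.csv`.  The ground-truth file is for validation only and is
#' never read by the analysis pipeline.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory (default
#'   `FALSE`).
#' @return The manifest data frame, invisibly.
#' @export
write_study <- function(config, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stop("directory '", out_dir, "' is not empty; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- study_grid(config)
  truth_rows <- list()
  manifest <- data.frame(file = character(nrow(grid)), grid,
                         handedness = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- generate_trial(config, g$participant, g$condition, g$task,
                          g$repetition)
    fn <- trial_file_name(g$participant, g$condition, g$task, g$repetition)
    write_trial_csv(res$trial, file.path(out_dir, fn))
    manifest$file[i] <- fn
    manifest$handedness[i] <- res$trial$handedness
    gt <- res$ground_truth
    truth_row <- function(key, value) {
      cbind(g[rep(1L, length(key)), , drop = FALSE],
            data.frame(key = key, value = value, stringsAsFactors = FALSE))
    }
    truth_rows[[i]] <- if (g$task %in% static_tasks()) {
      truth_row(paste0("rom:", gt$plane, ":static"), gt$cell_rom)
    } else {
      ev <- gt$events
      rbind(
        truth_row(paste0("rom:", names(gt$phase_rom)),
                  unlist(gt$phase_rom)),
        truth_row(c("event:si", "event:st", "event:sr"),
                  c(ev$si, ifelse(is.na(ev$st), NA, ev$st), ev$sr)))
    }
  }
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write_survey_csv(generate_survey(config), file.path(out_dir, "survey.csv"))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
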