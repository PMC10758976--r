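## Range-of-motion extraction: static tasks, shot events, phase windows,
## and the aggregation into one ROM record per design cell.

#' Unfold YXZ angles across the middle-axis singularity
#'
#' The X (middle-axis) angle of a YXZ decomposition is confined to
#' [-90, 90]; when the underlying rotation passes +/-90 degrees about X, the
#' decomposition folds (X reflects back while Y and Z both jump by 180).
#' For single-plane movements whose excursion exceeds 90 degrees — e.g.
#' full shoulder abduction — the folded channel would truncate the ROM.
#' This utility detects fold transitions (simultaneous jumps > 90 degrees in
#' the Y and Z channels between consecutive frames) and reconstructs the
#' continuous angles: inside a folded stretch `x` becomes `s*180 - x` (with
#' `s` the sign of X at entry) and Y and Z are shifted back by 180.
#'
#' @param angles Data frame from [euler_yxz()] (columns `angle_y`,
#'   `angle_x`, `angle_z`).
#' @return Data frame of the same shape with continuous channels.
#' @export
unfold_gimbal <- function(angles) {
  y <- angles$angle_y; x <- angles$angle_x; z <- angles$angle_z
  n <- length(x)
  if (n < 2L) return(angles)
  toggle <- abs(diff(y)) > 90 & abs(diff(z)) > 90
  if (!any(toggle)) return(angles)
  fold <- cumsum(c(FALSE, toggle)) %% 2L == 1L
  wrap_back <- function(v) v - sign(v) * 180
  ## process contiguous folded stretches
  r <- rle(fold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    a <- starts[seg]; b <- ends[seg]
    s <- sign(x[a - 1L])
    if (s == 0) s <- sign(x[a])
    x[a:b] <- s * 180 - x[a:b]
    y[a:b] <- wrap_back(y[a:b])
    z[a:b] <- wrap_back(z[a:b])
  }
  out <- angles
  out$angle_y <- y; out$angle_x <- x; out$angle_z <- z
  out
}

#' Static-task range of motion
#'
#' ROM from the initial anatomical angle to the task-direction extremum of
#' the joint-angle channel.  The initial anatomical angle is estimated as the
#' mean of the first `baseline_window` seconds (default 0.25 s, i.e. 24
#' frames at 96 Hz), and the result is the absolute difference between that
#' baseline and the channel's maximum (direction +1) or minimum (direction
#' -1).  ROM is reported as a non-negative magnitude; movement direction is
#' encoded by the task, not the sign.
#'
#' @param angles Numeric joint-angle series in degrees (one channel).
#' @param task A static task code from [static_tasks()], used to look up the
#'   movement direction; alternatively pass `direction` directly.
#' @param sample_rate Sampling frequency in Hz (default 96).
#' @param baseline_window Baseline duration in seconds (default 0.25).
#' @param direction Override: +1 (movement increases the channel) or -1.
#' @return ROM in degrees (scalar, >= 0).
#' @export
#' @examples
#' static_rom(seq(0, 150, length.out = 200), "sho_flex")  # 150 (ramp)
static_rom <- function(angles, task = NULL, sample_rate = 96,
                       baseline_window = 0.25, direction = NULL) {
  if (!is.numeric(angles) || anyNA(angles)) stop("angles must be numeric, no NA")
  if (is.null(direction)) {
    task <- match.arg(task, static_tasks())
    direction <- static_task_table()$direction[static_task_table()$task == task]
  }
  nb <- max(1L, round(baseline_window * sample_rate))
  if (length(angles) <= nb) {
    stop("series shorter than the baseline window (", nb, " frames)")
  }
  baseline <- mean(angles[seq_len(nb)])
  extremum <- if (direction > 0) max(angles) else min(angles)
  abs(extremum - baseline)
}

#' Average left and right ROM
#'
#' Arithmetic mean of the two sides, assuming balanced left/right movement.
#' If one side is missing (`NA`), the present side is propagated with a
#' warning.
#'
#' @param left_rom,right_rom ROM in degrees.
#' @return Mean ROM in degrees.
#' @export
average_sides <- function(left_rom, right_rom) {
  if (is.na(left_rom) && is.na(right_rom)) stop("both sides missing")
  if (is.na(left_rom) || is.na(right_rom)) {
    warning("one side missing; propagating the present side")
    return(ifelse(is.na(left_rom), right_rom, left_rom))
  }
  (left_rom + right_rom) / 2
}

#' Shot events
#'
#' Frame indices segmenting a shooting trial: shot initiation (SI), swing top
#' (ST, slap shot only) and shot release (SR), with `si < st < sr` (or
#' `si < sr` when ST is absent).
#'
#' @param si,sr Frame indices (1-based).
#' @param st Swing-top frame for slap shots, `NA` for wrist shots.
#' @return Object of class `shot_events`.
#' @export
shot_events <- function(si, sr, st = NA) {
  stopifnot(is.finite(si), is.finite(sr), si >= 1)
  if (!is.na(st)) {
    if (!(si < st && st < sr)) stop("event ordering violated: need si < st < sr")
  } else if (!(si < sr)) stop("event ordering violated: need si < sr")
  structure(list(si = as.integer(si),
                 st = if (is.na(st)) NA_integer_ else as.integer(st),
                 sr = as.integer(sr)),
            class = "shot_events")
}

#' @export
print.shot_events <- function(x, ...) {
  cat(sprintf("<shot_events> SI=%d%s SR=%d\n", x$si,
              if (is.na(x$st)) "" else sprintf(" ST=%d", x$st), x$sr))
  invisible(x)
}

#' Detect shot events in a shooting trial
#'
#' Criteria (thresholds configurable):
#' * SR: frame of peak lead-hand angular speed.
#' * SI: walking backward from the peak, the first frame of the contiguous
#'   run in which the hand's angular speed stays above
#'   `threshold_frac` x peak (default 10%).
#' * ST (slap shot only): frame of the extremal backswing — the maximum of
#'   the lead-shoulder flexion channel — between SI and SR.
#'
#' The trial is mirrored to left-handed form first, so the lead side is
#' always the left.  Orientation streams are low-pass filtered and the speed
#' trace is smoothed with the same filter before thresholding.
#'
#' @param trial A shooting [trial_recording()].
#' @param cutoff,order Filter settings (defaults 6 Hz, order 4).
#' @param threshold_frac Fraction of the peak speed defining SI (default 0.1).
#' @param min_peak_speed Minimum plausible peak hand speed in degrees/second;
#'   below it no shot is declared (default 200).
#' @return A [shot_events()] object.
#' @export
detect_shot_events <- function(trial, cutoff = 6, order = 4,
                               threshold_frac = 0.1, min_peak_speed = 200) {
  if (!trial$task %in% dynamic_tasks()) {
    stop("event detection applies to shot tasks only")
  }
  trial <- mirror_handedness(trial)
  hand <- filter_orientation(trial$segments[["hand_L"]], cutoff, order,
                             trial$sample_rate)
  speed <- angular_speed(hand, trial$sample_rate)
  speed <- lowpass_filter(speed, cutoff, order, trial$sample_rate)
  peak <- which.max(speed)
  if (speed[peak] < min_peak_speed) {
    stop("no shot detected: peak hand speed ", round(speed[peak], 1),
         " deg/s is below the minimum of ", min_peak_speed, " deg/s")
  }
  thr <- threshold_frac * speed[peak]
  si <- peak
  while (si > 1L && speed[si - 1L] >= thr) si <- si - 1L
  if (si >= peak) {
    stop("no shot detected: hand speed never falls below the shot-initiation",
         " threshold before the release peak")
  }
  if (trial$task == "slap_shot") {
    flex <- joint_angles(trial, "shoulder", "L", filter = TRUE,
                         cutoff = cutoff, order = order)$angle_y
    win <- seq(si, peak)
    st <- win[which.max(flex[win])]
    if (st <= si || st >= peak) {
      stop("no shot detected: swing top not found between initiation and release")
    }
    shot_events(si, peak, st)
  } else {
    shot_events(si, peak)
  }
}

#' Phase range of motion for a shot
#'
#' Max minus min of the joint-angle channel within the closed frame window of
#' the requested phase (`si_sr` for the wrist shot; `si_st` or `st_sr` for
#' the slap shot).
#'
#' @param angles Numeric joint-angle series in degrees.
#' @param events A [shot_events()] object.
#' @param phase `"si_sr"`, `"si_st"` or `"st_sr"`.
#' @return ROM in degrees (>= 0).
#' @export
phase_rom <- function(angles, events, phase = c("si_sr", "si_st", "st_sr")) {
  phase <- match.arg(phase)
  stopifnot(inherits(events, "shot_events"))
  if (phase != "si_sr" && is.na(events$st)) {
    stop("phase '", phase, "' requires a swing-top event (slap shot only)")
  }
  win <- switch(phase,
    si_sr = seq(events$si, events$sr),
    si_st = seq(events$si, events$st),
    st_sr = seq(events$st, events$sr))
  if (max(win) > length(angles)) stop("event window exceeds series length")
  diff(range(angles[win]))
}

#' Average repeated ROM measurements
#'
#' Mean ROM across the repetitions of one participant x condition x task x
#' joint-plane cell.  Missing repetitions (`NA`) are dropped with a warning.
#'
#' @param rom_values Numeric vector of per-repetition ROM (degrees).
#' @return Mean ROM in degrees.
#' @export
average_trials <- function(rom_values) {
  if (length(rom_values) == 0L) stop("no repetitions to average")
  if (anyNA(rom_values)) {
    warning("missing repetition(s) dropped from the trial average")
    rom_values <- rom_values[!is.na(rom_values)]
    if (length(rom_values) == 0L) stop("no repetitions to average")
  }
  mean(rom_values)
}

#' Normalized ROM relative to the control condition
#'
#' @param pad_rom ROM under a pad condition (degrees).
#' @param control_rom ROM under the unpadded control (degrees, > 0).
#' @return Fraction `pad_rom / control_rom`.
#' @export
normalize_rom <- function(pad_rom, control_rom) {
  if (any(!is.finite(control_rom)) || any(control_rom <= 0)) {
    stop("control ROM must be > 0")
  }
  pad_rom / control_rom
}

#' Percent ROM restriction relative to the control condition
#'
#' `(control - pad) / control * 100`; negative when a pad increases ROM.
#'
#' @param control_mean Control-condition mean ROM (degrees, > 0).
#' @param pad_mean Pad-condition mean ROM (degrees).
#' @return Restriction in percent.
#' @export
restriction_percent <- function(control_mean, pad_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    stop("control mean must be > 0")
  }
  (control_mean - pad_mean) / control_mean * 100
}

## ---- per-trial extraction -------------------------------------------------

#' Extract all ROM records from one trial
#'
#' Static tasks yield one record per side for the task's joint plane; shot
#' tasks are mirrored to left-handed form, segmented via
#' [detect_shot_events()], and yield one record per joint plane x side x
#' phase.
#'
#' @param trial A [trial_recording()].
#' @param cutoff,order Filter settings.
#' @param baseline_window Static baseline duration in seconds.
#' @param event_args List of extra arguments for [detect_shot_events()].
#' @return Data frame with columns `participant`, `condition`, `task`,
#'   `repetition`, `phase`, `joint_plane`, `side`, `rom_deg`.
#' @export
extract_trial_rom <- function(trial, cutoff = 6, order = 4,
                              baseline_window = 0.25, event_args = list()) {
  stopifnot(inherits(trial, "trial_recording"))
  base <- data.frame(participant = trial$participant,
                     condition = trial$condition, task = trial$task,
                     repetition = trial$repetition, stringsAsFactors = FALSE)
  if (trial$task %in% static_tasks()) {
    info <- static_task_table()
    info <- info[info$task == trial$task, ]
    chan <- paste0("angle_", info$channel)
    rows <- lapply(c("L", "R"), function(side) {
      ang <- unfold_gimbal(joint_angles(trial, info$joint, side,
                                        filter = TRUE, cutoff = cutoff,
                                        order = order))[[chan]]
      cbind(base, phase = "static", joint_plane = info$plane, side = side,
            rom_deg = static_rom(ang, trial$task, trial$sample_rate,
                                 baseline_window))
    })
    do.call(rbind, rows)
  } else {
    trial <- mirror_handedness(trial)
    events <- do.call(detect_shot_events,
                      c(list(trial, cutoff = cutoff, order = order),
                        event_args))
    phases <- shot_phases(trial$task)
    planes <- dynamic_plane_table()
    rows <- list()
    for (side in c("L", "R")) {
      for (i in seq_len(nrow(planes))) {
        ang <- joint_angles(trial, planes$joint[i], side, filter = TRUE,
                            cutoff = cutoff, order = order)
        chan <- ang[[paste0("angle_", planes$channel[i])]]
        for (ph in phases) {
          rows[[length(rows) + 1L]] <- cbind(
            base, phase = ph,
            joint_plane = paste0(planes$plane[i], "_", side), side = side,
            rom_deg = phase_rom(chan, events, ph))
        }
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "events") <- events
    out
  }
}

## ---- study-level aggregation ----------------------------------------------

#' Build the per-cell ROM table for a whole study
#'
#' Runs [extract_trial_rom()] over every trial, averages left/right sides for
#' static tasks, then averages repetitions, producing one row per
#' participant x condition x task x phase x joint plane.  A complete design
#' (9 participants x 11 tasks x 6 conditions) has 594 distinct
#' participant x task x condition cells.
#'
#' @param trials Either a list of [trial_recording()] objects, or a directory
#'   containing a `manifest.csv` and the trial CSV files it names.
#' @param cutoff,order,baseline_window,event_args Extraction settings, see
#'   [extract_trial_rom()].
#' @param verbose Print per-trial progress (default `FALSE`).
#' @return Long-format data frame `participant`, `condition`, `task`,
#'   `phase`, `joint_plane`, `rom_deg`.
#' @export
extract_study_rom <- function(trials, cutoff = 6, order = 4,
                              baseline_window = 0.25, event_args = list(),
                              verbose = FALSE) {
  raw <- if (is.character(trials)) {
    dir <- trials
    manifest <- read_manifest(file.path(dir, "manifest.csv"))
    lapply(seq_len(nrow(manifest)), function(i) {
      m <- manifest[i, ]
      trial <- tryCatch(
        read_trial_csv(file.path(dir, m$file), m$participant, m$condition,
                       m$task, m$repetition, m$handedness),
        error = function(e) stop("while reading '", m$file, "': ",
                                 conditionMessage(e)))
      if (verbose) message("ROM <- ", m$file)
      extract_trial_rom(trial, cutoff, order, baseline_window, event_args)
    })
  } else {
    lapply(trials, function(trial) {
      if (verbose) {
        message("ROM <- ", trial$participant, "/", trial$condition, "/",
                trial$task, "/", trial$repetition)
      }
      extract_trial_rom(trial, cutoff, order, baseline_window, event_args)
    })
  }
  aggregate_rom_records(do.call(rbind, raw))
}

#' Aggregate raw per-repetition ROM records into design cells
#'
#' Static records are side-averaged within each repetition
#' ([average_sides()]), then repetitions are averaged ([average_trials()]).
#' Dynamic joint planes keep their side label.
#'
#' @param records Data frame from [extract_trial_rom()] (rows may be pooled
#'   over many trials).
#' @return Cell-level data frame `participant`, `condition`, `task`, `phase`,
#'   `joint_plane`, `rom_deg`.
#' @export
aggregate_rom_records <- function(records) {
  static <- records[records$phase == "static", , drop = FALSE]
  dynamic <- records[records$phase != "static", , drop = FALSE]
  out <- list()
  if (nrow(static)) {
    ## sides first, within repetition
    by_rep <- stats::aggregate(
      rom_deg ~ participant + condition + task + phase + joint_plane + repetition,
      data = static, FUN = mean)
    out$static <- stats::aggregate(
      rom_deg ~ participant + condition + task + phase + joint_plane,
      data = by_rep, FUN = mean)
  }
  if (nrow(dynamic)) {
    out$dynamic <- stats::aggregate(
      rom_deg ~ participant + condition + task + phase + joint_plane,
      data = dynamic, FUN = mean)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant, res$task, res$phase, res$joint_plane,
            match(res$condition, pad_conditions())), ]
}
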