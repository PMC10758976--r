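## Trial recordings: labelled multi-segment orientation time series for one
## task repetition, plus file IO and handedness mirroring.

#' Construct a trial recording
#'
#' Bundles per-segment orientation streams for one repetition of one task by
#' one participant under one pad condition.  All segment streams must share
#' the same length (>= 2 frames) and be unit-norm.  Static tasks require the
#' arm-chain segments; shot tasks the full upper-body set.
#'
#' @param participant Participant identifier (character).
#' @param condition One of [pad_conditions()].
#' @param task One of [study_tasks()].
#' @param repetition Repetition number (integer >= 1).
#' @param handedness `"left"` or `"right"` (shooting side).
#' @param segments Named list of n x 4 quaternion matrices, names from
#'   [upper_body_segments()].
#' @param sample_rate Sampling frequency in Hz (default 96).
#' @return Object of class `trial_recording`.
#' @export
trial_recording <- function(participant, condition, task, repetition,
                            handedness, segments, sample_rate = 96) {
  condition <- match.arg(condition, pad_conditions())
  task <- match.arg(task, study_tasks())
  handedness <- match.arg(tolower(handedness), c("left", "right"))
  stopifnot(is.numeric(repetition), repetition >= 1, sample_rate > 0)
  if (!is.list(segments) || is.null(names(segments)) ||
      any(names(segments) == "")) {
    stop("segments must be a named list of quaternion matrices")
  }
  unknown <- setdiff(names(segments), upper_body_segments())
  if (length(unknown)) stop("unknown segment(s): ", paste(unknown, collapse = ", "))
  required <- if (task %in% static_tasks()) arm_chain_segments()
              else upper_body_segments()
  missing <- setdiff(required, names(segments))
  if (length(missing)) {
    stop("task '", task, "' requires segment(s): ",
         paste(missing, collapse = ", "))
  }
  segments <- lapply(segments, as_quat_matrix)
  lens <- vapply(segments, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("all segment streams must share length")
  if (lens[1] < 2L) stop("segment streams need at least 2 frames")
  for (s in names(segments)) {
    if (max(abs(rowSums(segments[[s]]^2) - 1)) > 1e-6) {
      stop("segment '", s, "' is not unit-norm; normalize first")
    }
  }
  structure(
    list(participant = as.character(participant), condition = condition,
         task = task, repetition = as.integer(repetition),
         handedness = handedness, sample_rate = sample_rate,
         segments = segments),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s | %s | %s | rep %d | %s-handed | %d frames @ %g Hz\n",
    x$participant, x$condition, x$task, x$repetition, x$handedness,
    nrow(x$segments[[1]]), x$sample_rate))
  cat("  segments:", paste(names(x$segments), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(trial) nrow(trial$segments[[1L]])

## ---- joint angles ---------------------------------------------------------

#' Joint-angle time series for one joint of a trial
#'
#' Optionally filters both segment streams ([filter_orientation()]), forms the
#' relative joint quaternion frame by frame ([joint_quaternion()]), and
#' decomposes it in the intrinsic YXZ order ([euler_yxz()]).
#'
#' @param trial A [trial_recording()].
#' @param joint `"shoulder"`, `"elbow"` or `"forearm"`.
#' @param side `"L"` or `"R"`.
#' @param filter Apply the low-pass filter first (default `TRUE`).
#' @param cutoff,order Filter settings (defaults 6 Hz, order 4).
#' @return Data frame with columns `angle_y`, `angle_x`, `angle_z` (degrees)
#'   and `gimbal`.
#' @export
joint_angles <- function(trial, joint, side, filter = TRUE,
                         cutoff = 6, order = 4) {
  segs <- joint_segments(joint, side)
  missing <- setdiff(segs, names(trial$segments))
  if (length(missing)) stop("trial lacks segment(s): ", paste(missing, collapse = ", "))
  qp <- trial$segments[[segs[1L]]]
  qd <- trial$segments[[segs[2L]]]
  if (filter) {
    qp <- filter_orientation(qp, cutoff, order, trial$sample_rate)
    qd <- filter_orientation(qd, cutoff, order, trial$sample_rate)
  }
  euler_yxz(joint_quaternion(qp, qd))
}

## ---- handedness mirroring -------------------------------------------------

#' Mirror a trial across the sagittal plane
#'
#' `mirror_trial()` is the pure geometric operation: left/right segment labels
#' are swapped, each orientation's abduction (X) and axial-rotation (Z)
#' components are negated while the sagittal (Y) component is untouched, and
#' the handedness label flips.  It is an involution:
#' `mirror_trial(mirror_trial(t))` restores `t`.
#'
#' `mirror_handedness()` is the pipeline's pooling step: right-handed trials
#' are converted to left-handed form via `mirror_trial()`, left-handed trials
#' are returned unchanged.
#'
#' @param trial A [trial_recording()].
#' @return A mirrored (or unchanged) `trial_recording`.
#' @export
mirror_trial <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  segs <- trial$segments
  ## conjugation by the sagittal reflection: negate x- and z-axis rotation
  ## components, equivalently negate Euler X and Z channels
  segs <- lapply(segs, function(m) {
    cbind(w = m[, 1], x = -m[, 2], y = m[, 3], z = -m[, 4])
  })
  nm <- names(segs)
  swapped <- nm
  swapped[grepl("_L$", nm)] <- sub("_L$", "_R", nm[grepl("_L$", nm)])
  swapped[grepl("_R$", nm)] <- sub("_R$", "_L", nm[grepl("_R$", nm)])
  names(segs) <- swapped
  trial$segments <- segs[order(match(swapped, upper_body_segments()))]
  trial$handedness <- if (trial$handedness == "left") "right" else "left"
  trial
}

#' @rdname mirror_trial
#' @export
mirror_handedness <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  if (trial$handedness == "right") mirror_trial(trial) else trial
}

## ---- file IO --------------------------------------------------------------

#' Read and write single-trial orientation CSV files
#'
#' The trial dialect has one row per frame and segment:
#' `frame,time_s,segment,qw,qx,qy,qz`.  Trial metadata lives in the manifest
#' (see [read_manifest()]) and is supplied alongside the file.
#'
#' @param path CSV file path.
#' @param participant,condition,task,repetition,handedness Trial labels.
#' @param sample_rate Sampling frequency in Hz.
#' @return `read_trial_csv()` returns a [trial_recording()];
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
read_trial_csv <- function(path, participant, condition, task, repetition,
                           handedness, sample_rate = 96) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "segment", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(df))) {
    stop("malformed trial file '", path, "': expected columns ",
         paste(need, collapse = ","))
  }
  bad <- which(!stats::complete.cases(df[, c("qw", "qx", "qy", "qz")]))
  if (length(bad)) {
    stop("malformed trial file '", path, "': non-numeric quaternion at row ",
         bad[1L] + 1L)
  }
  segments <- lapply(split(df, df$segment), function(d) {
    d <- d[order(d$frame), ]
    quat_normalize(cbind(w = d$qw, x = d$qx, y = d$qy, z = d$qz))
  })
  trial_recording(participant, condition, task, repetition, handedness,
                  segments, sample_rate)
}

#' @rdname read_trial_csv
#' @param trial A [trial_recording()].
#' @export
write_trial_csv <- function(trial, path) {
  n <- n_frames(trial)
  t_s <- (seq_len(n) - 1L) / trial$sample_rate
  rows <- lapply(names(trial$segments), function(s) {
    m <- trial$segments[[s]]
    data.frame(frame = seq_len(n) - 1L, time_s = t_s, segment = s,
               qw = m[, 1], qx = m[, 2], qy = m[, 3], qz = m[, 4])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Study manifest IO
#'
#' The manifest lists one trial file per row:
#' `file,participant,condition,task,repetition,handedness`.
#'
#' @param path Manifest CSV path.
#' @return `read_manifest()` returns a data frame; `write_manifest()` returns
#'   `path` invisibly.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "participant", "condition", "task", "repetition",
            "handedness")
  if (!all(need %in% names(df))) {
    stop("malformed manifest '", path, "': expected columns ",
         paste(need, collapse = ","))
  }
  df
}

#' @rdname read_manifest
#' @param manifest Data frame as produced by the generator.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Canonical trial file name
#'
#' `{participant}_{condition}_{task}_{rep}.csv`.
#'
#' @inheritParams read_trial_csv
#' @return File name (no directory).
#' @export
trial_file_name <- function(participant, condition, task, repetition) {
  sprintf("%s_%s_%s_%d.csv", participant, condition, task, repetition)
}
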