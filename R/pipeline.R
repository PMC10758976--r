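## End-to-end orchestration: inputs (files or generator) -> ROM table ->
## condition statistics -> normalized ROM -> comfort summary and
## comfort-mobility correlations, with a config copy and a run log beside
## the outputs.

#' Build a run configuration
#'
#' All pipeline settings in one serializable list.  Exactly one of
#' `input_dir` (a directory with `manifest.csv`, trial CSVs and
#' `survey.csv`) or `generator` (a [generator_config()] or a list of its
#' arguments) must be supplied.
#'
#' @param input_dir Optional input directory.
#' @param generator Optional generator configuration.
#' @param output_dir Where outputs are written.
#' @param cutoff,order Low-pass filter settings (6 Hz, order 4).
#' @param baseline_window Static baseline window in seconds (0.25).
#' @param event_args Extra arguments for [detect_shot_events()].
#' @param alpha Significance level (0.05).
#' @param sphericity Correction policy for [rm_anova_gg()].
#' @param seed Seed forwarded to the generator when one is requested.
#' @param resume Reuse an existing `rom_table.csv` in the output directory
#'   instead of re-extracting, so a partial run can continue from the ROM
#'   stage (default `FALSE`).
#' @param verbose Log progress messages to the console as well.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, generator = NULL, output_dir,
                       cutoff = 6, order = 4, baseline_window = 0.25,
                       event_args = list(), alpha = 0.05,
                       sphericity = "mauchly", seed = NULL, resume = FALSE,
                       verbose = FALSE) {
  if (is.null(input_dir) == is.null(generator)) {
    stop("supply exactly one of input_dir or generator")
  }
  if (!is.null(generator) && !inherits(generator, "generator_config")) {
    if (!is.null(seed) && is.null(generator$seed)) generator$seed <- seed
    generator <- do.call(generator_config, generator)
  }
  structure(list(input_dir = input_dir, generator = generator,
                 output_dir = output_dir, cutoff = cutoff, order = order,
                 baseline_window = baseline_window, event_args = event_args,
                 alpha = alpha, sphericity = sphericity, seed = seed,
                 resume = resume, verbose = verbose),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file; top-level keys are [run_config()] arguments.
#' @param ... Overrides applied after reading.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(run_config, cfg)
}

## serialize a run_config (generator_config flattened) for the config copy
config_as_yaml <- function(config) {
  x <- unclass(config)
  if (!is.null(x$generator)) {
    g <- unclass(x$generator)
    g$control_rom <- as.list(g$control_rom)
    g$restriction <- lapply(g$restriction, function(m) {
      list(planes = rownames(m), conditions = colnames(m),
           values = as.numeric(m))
    })
    x$generator <- g
  }
  yaml::as.yaml(x)
}

## ---- condition statistics ---------------------------------------------------

#' Participants x conditions matrix for one analysis cell
#'
#' @param cell_table Cell-level ROM table.
#' @param task,phase,joint_plane Selection keys.
#' @param conditions Condition order (default [pad_conditions()]).
#' @return Numeric matrix, participants in rows, conditions in columns.
#' @export
condition_matrix <- function(cell_table, task, phase, joint_plane,
                             conditions = pad_conditions()) {
  sub <- cell_table[cell_table$task == task & cell_table$phase == phase &
                      cell_table$joint_plane == joint_plane, ]
  if (!nrow(sub)) stop("no rows for ", task, "/", phase, "/", joint_plane)
  conditions <- intersect(conditions, unique(sub$condition))
  participants <- sort(unique(sub$participant))
  m <- matrix(NA_real_, length(participants), length(conditions),
              dimnames = list(participants, conditions))
  for (i in seq_len(nrow(sub))) {
    m[sub$participant[i], sub$condition[i]] <- sub$rom_deg[i]
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete design for ", task, "/", phase, "/", joint_plane, ": ",
         paste(rownames(m)[miss[, 1]], colnames(m)[miss[, 2]],
               sep = "x", collapse = ", "))
  }
  m
}

#' Condition-comparison statistics for every joint plane
#'
#' For each task x phase x joint plane: per-condition mean and SD,
#' Shapiro-Wilk screening (minimum per-condition p), repeated-measures ANOVA
#' with Greenhouse-Geisser handling ([rm_anova_gg()]), partial eta-squared
#' with its band, and — when the omnibus test is significant at `alpha` —
#' LSD pairwise markers: for each condition, the 1-based indices of the
#' conditions it differs from (`p < alpha`), comma-separated, mirroring the
#' numeric-superscript convention of condition tables.
#'
#' @param cell_table Cell-level ROM table from [extract_study_rom()].
#' @param alpha Significance level (default 0.05).
#' @param sphericity Passed to [rm_anova_gg()].
#' @param conditions Condition order.
#' @return Data frame, one row per joint plane.
#' @export
condition_stats <- function(cell_table, alpha = 0.05,
                            sphericity = "mauchly",
                            conditions = pad_conditions()) {
  keys <- unique(cell_table[, c("task", "phase", "joint_plane")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    m <- condition_matrix(cell_table, k$task, k$phase, k$joint_plane,
                          conditions)
    fit <- rm_anova_gg(m, sphericity = sphericity, gate_alpha = alpha)
    sw <- suppressWarnings(vapply(seq_len(ncol(m)), function(j) {
      tryCatch(shapiro_wilk(m[, j])$p_value, error = function(e) NA_real_)
    }, numeric(1)))
    out <- data.frame(task = k$task, phase = k$phase,
                      joint_plane = k$joint_plane, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m))) {
      out[[paste0("mean_", colnames(m)[j])]] <- mean(m[, j])
      out[[paste0("sd_", colnames(m)[j])]] <- stats::sd(m[, j])
    }
    out$shapiro_min_p <- suppressWarnings(min(sw, na.rm = TRUE))
    out$f_stat <- fit$f_stat
    out$df_effect <- fit$df_effect
    out$df_error <- fit$df_error
    out$gg_epsilon <- fit$gg_epsilon
    out$p_value <- fit$p_value
    out$eta_sq <- fit$partial_eta_sq
    out$eta_band <- classify_eta_sq(fit$partial_eta_sq)
    marks <- rep("", ncol(m))
    if (is.finite(fit$p_value) && fit$p_value < alpha) {
      ph <- lsd_posthoc(m)
      for (j in seq_len(ncol(m))) {
        sig <- which(ph$p_value[j, ] < alpha)
        marks[j] <- paste(sig, collapse = ",")
      }
    }
    for (j in seq_len(ncol(m))) out[[paste0("sig_", colnames(m)[j])]] <- marks[j]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Normalized ROM table
#'
#' Per joint plane and condition, mean ROM divided by the control-condition
#' mean ([normalize_rom()]).
#'
#' @inheritParams condition_stats
#' @return Data frame `task`, `phase`, `joint_plane`, `condition`,
#'   `normalized_rom`.
#' @export
normalized_rom_table <- function(cell_table, conditions = pad_conditions()) {
  means <- stats::aggregate(rom_deg ~ task + phase + joint_plane + condition,
                            data = cell_table, FUN = mean)
  rows <- list()
  keys <- unique(means[, c("task", "phase", "joint_plane")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- means[means$task == k$task & means$phase == k$phase &
                   means$joint_plane == k$joint_plane, ]
    ctrl <- sub$rom_deg[sub$condition == "no_pads"]
    if (!length(ctrl)) next
    sub$normalized_rom <- normalize_rom(sub$rom_deg, ctrl)
    rows[[length(rows) + 1L]] <- sub[, c("task", "phase", "joint_plane",
                                         "condition", "normalized_rom")]
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$task, res$phase, res$joint_plane,
                   match(res$condition, conditions)), ]
  rownames(res) <- NULL
  res
}

## ---- comfort ----------------------------------------------------------------

#' Comfort vs mobility report
#'
#' Per-pad comfort means ([comfort_scores()]) against per-pad total ROM
#' ([total_rom()]) for three task scopes: static tasks, dynamic tasks
#' (joint planes with a significant condition effect, per the pipeline's own
#' omnibus tests), and both combined.  Each scope yields a Spearman
#' coefficient, p-value and strength band.
#'
#' @param cell_table Cell-level ROM table.
#' @param survey Survey data frame.
#' @param stats_table Output of [condition_stats()] (for the significance
#'   screen of dynamic planes); when `NULL` all dynamic planes are used.
#' @param alpha Significance level for the dynamic-plane screen.
#' @return List with `comfort` (per-pad means), `total_rom` (per pad x
#'   scope) and `correlations` (data frame scope, rho, p_value, band).
#' @export
comfort_mobility_report <- function(cell_table, survey, stats_table = NULL,
                                    alpha = 0.05) {
  comfort <- comfort_scores(survey)
  pads <- names(comfort)
  dyn_keys <- unique(cell_table[cell_table$phase != "static",
                                c("task", "phase", "joint_plane")])
  if (!is.null(stats_table)) {
    st <- stats_table[stats_table$phase != "static" &
                        stats_table$p_value < alpha, ]
    dyn_keys <- dyn_keys[paste(dyn_keys$task, dyn_keys$phase,
                               dyn_keys$joint_plane) %in%
                           paste(st$task, st$phase, st$joint_plane), ]
  }
  tot <- function(cond, scope) {
    if (scope == "static") {
      total_rom(cell_table, cond, tasks = static_tasks())
    } else if (scope == "dynamic") {
      if (!nrow(dyn_keys)) return(NA_real_)
      sum(vapply(seq_len(nrow(dyn_keys)), function(i) {
        total_rom(cell_table, cond, tasks = dyn_keys$task[i],
                  phases = dyn_keys$phase[i],
                  joint_planes = dyn_keys$joint_plane[i])
      }, numeric(1)))
    } else {
      tot(cond, "static") + tot(cond, "dynamic")
    }
  }
  scopes <- c("static", "dynamic", "combined")
  totals <- vapply(scopes, function(s) {
    vapply(pads, function(cond) tot(cond, s), numeric(1))
  }, numeric(length(pads)))
  totals <- matrix(totals, nrow = length(pads),
                   dimnames = list(pads, scopes))
  cors <- do.call(rbind, lapply(scopes, function(s) {
    rom <- totals[, s]
    ct <- tryCatch(comfort_rom_correlation(comfort, rom),
                   error = function(e) NULL)
    if (is.null(ct) || anyNA(rom)) {
      return(data.frame(scope = s, rho = NA_real_, p_value = NA_real_,
                        band = NA_character_, stringsAsFactors = FALSE))
    }
    data.frame(scope = s, rho = ct$rho, p_value = ct$p_value, band = ct$band,
               stringsAsFactors = FALSE)
  }))
  list(comfort = comfort, total_rom = totals, correlations = cors)
}

## ---- the pipeline -----------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Obtains trials (from files or the generator), extracts the cell-level ROM
#' table, computes condition statistics for static tasks and both shots,
#' normalized ROM, the comfort summary and comfort-mobility correlations,
#' and writes everything (plus a config copy and run log) to the output
#' directory:
#' `rom_table.csv`, `stats_static.csv`, `stats_wrist.csv`, `stats_slap.csv`,
#' `normalized_rom.csv`, `comfort_summary.csv`, `correlation_report.csv`,
#' `run_config.yaml`, `run.log`.
#'
#' @param config A [run_config()] or a YAML path accepted by
#'   [load_run_config()].
#' @return Invisibly, a list with all tables and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_ <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    if (isTRUE(config$verbose)) message(line)
  }

  extract_one <- function(trial) {
    rec <- extract_trial_rom(trial, config$cutoff, config$order,
                             config$baseline_window, config$event_args)
    ev <- attr(rec, "events")
    if (!is.null(ev)) {
      log_("events %s/%s/%s/rep%d: SI=%d%s SR=%d%s", trial$participant,
           trial$condition, trial$task, trial$repetition, ev$si,
           if (is.na(ev$st)) "" else sprintf(" ST=%d", ev$st), ev$sr,
           if (trial$handedness == "right") " (mirrored to left)" else "")
    }
    rec
  }

  survey <- if (!is.null(config$generator)) {
    generate_survey(config$generator)
  } else {
    survey_path <- file.path(config$input_dir, "survey.csv")
    if (file.exists(survey_path)) read_survey_csv(survey_path) else NULL
  }

  rom_path <- file.path(out_dir, "rom_table.csv")
  if (isTRUE(config$resume) && file.exists(rom_path)) {
    log_("resuming from existing %s", rom_path)
    rom_table <- utils::read.csv(rom_path, stringsAsFactors = FALSE)
  } else if (!is.null(config$generator)) {
    gen <- config$generator
    log_("generating synthetic study: %d participants x %d tasks x %d conditions x %d reps, seed %d",
         gen$n_participants, length(gen$tasks), length(gen$conditions),
         gen$repetitions, gen$seed)
    grid <- study_grid(gen)
    raw <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      extract_one(generate_trial(gen, g$participant, g$condition, g$task,
                                 g$repetition)$trial)
    })
    rom_table <- aggregate_rom_records(do.call(rbind, raw))
  } else {
    manifest <- read_manifest(file.path(config$input_dir, "manifest.csv"))
    log_("reading %d trials from %s", nrow(manifest), config$input_dir)
    raw <- lapply(seq_len(nrow(manifest)), function(i) {
      m <- manifest[i, ]
      trial <- tryCatch(
        read_trial_csv(file.path(config$input_dir, m$file), m$participant,
                       m$condition, m$task, m$repetition, m$handedness),
        error = function(e) stop("while reading '", m$file, "': ",
                                 conditionMessage(e)))
      extract_one(trial)
    })
    rom_table <- aggregate_rom_records(do.call(rbind, raw))
  }
  n_cells <- nrow(unique(rom_table[, c("participant", "task", "condition")]))
  log_("ROM table: %d rows, %d participant x task x condition cells",
       nrow(rom_table), n_cells)
  utils::write.csv(rom_table, file.path(out_dir, "rom_table.csv"),
                   row.names = FALSE, quote = FALSE)

  stats_all <- condition_stats(rom_table, config$alpha, config$sphericity)
  parts <- list(
    stats_static = stats_all[stats_all$phase == "static", ],
    stats_wrist = stats_all[stats_all$task == "wrist_shot", ],
    stats_slap = stats_all[stats_all$task == "slap_shot", ])
  for (nm in names(parts)) {
    if (nrow(parts[[nm]])) {
      utils::write.csv(parts[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  norm <- normalized_rom_table(rom_table)
  utils::write.csv(norm, file.path(out_dir, "normalized_rom.csv"),
                   row.names = FALSE, quote = FALSE)

  comfort <- NULL
  if (!is.null(survey)) {
    comfort <- comfort_mobility_report(rom_table, survey, stats_all,
                                       config$alpha)
    agg <- aggregate_likert(survey)
    utils::write.csv(agg$pooled, file.path(out_dir, "comfort_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(comfort$correlations,
                     file.path(out_dir, "correlation_report.csv"),
                     row.names = FALSE, quote = FALSE)
    for (i in seq_len(nrow(comfort$correlations))) {
      co <- comfort$correlations[i, ]
      log_("comfort vs %s total ROM: rho=%.3f p=%.4f (%s)", co$scope,
           co$rho, co$p_value, co$band)
    }
  }
  writeLines(config_as_yaml(config), file.path(out_dir, "run_config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(rom_table = rom_table, stats = stats_all,
                 stats_parts = parts, normalized = norm, comfort = comfort,
                 n_cells = n_cells, output_dir = out_dir))
}

## ---- formatted tables -------------------------------------------------------

#' Format condition statistics as publication-style tables
#'
#' One-decimal `mean ± SD` cells with numeric-superscript significance
#' markers (`^i,j` lists the conditions a cell differs from), plus
#' one-decimal F and three-decimal p / eta-squared columns.  Full-precision
#' values live in the machine CSVs; rounding happens only here.
#'
#' @param stats_table Output of [condition_stats()].
#' @param conditions Condition order.
#' @return Data frame of formatted strings.
#' @export
make_paper_tables <- function(stats_table, conditions = pad_conditions()) {
  out <- stats_table[, c("task", "phase", "joint_plane")]
  for (cond in conditions) {
    mcol <- paste0("mean_", cond)
    if (!mcol %in% names(stats_table)) next
    out[[cond]] <- mapply(format_table_cell,
                          stats_table[[mcol]],
                          stats_table[[paste0("sd_", cond)]],
                          stats_table[[paste0("sig_", cond)]])
  }
  out$p <- ifelse(stats_table$p_value < 0.01, "<0.01",
                  sprintf("%.3f", stats_table$p_value))
  out$F <- sprintf("%.3f", stats_table$f_stat)
  out$eta_sq <- sprintf("%.3f", stats_table$eta_sq)
  out
}

#' @rdname make_paper_tables
#' @param mean_value,sd_value Cell mean and SD in degrees.
#' @param marks Comma-separated condition indices (may be empty).
#' @export
format_table_cell <- function(mean_value, sd_value, marks = "") {
  cell <- sprintf("%.1f ± %.1f", mean_value, sd_value)
  if (!is.na(marks) && nzchar(marks)) cell <- paste0(cell, "^", marks)
  cell
}

#' @rdname make_paper_tables
#' @param cell Formatted cell string.
#' @export
parse_table_cell <- function(cell) {
  m <- regmatches(cell,
    regexec("^(-?[0-9.]+) ± ([0-9.]+)(\\^([0-9,]+))?$", cell))[[1]]
  if (!length(m)) stop("unparseable table cell: ", cell)
  list(mean = as.numeric(m[2]), sd = as.numeric(m[3]),
       marks = if (nzchar(m[5])) as.integer(strsplit(m[5], ",")[[1]])
               else integer(0))
}
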