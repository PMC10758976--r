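## Published condition-comparison tables, shipped as plain-text fixtures, and
## the summary quantities derived from them (mean reductions in degrees, mean
## percent limitations, averaged effect sizes).  These tables are inputs to
## the pipeline's reduction/averaging operations; values are kept exactly as
## printed, including internal oddities (see reference_control_rom() for the
## two control means that are inconsistent with the study's own restriction
## percentages).

printed_table_path <- function(which) {
  f <- switch(which,
    static = "table1_static.csv",
    wrist = "table2_wrist.csv",
    slap = "table3_slap.csv",
    stop("unknown table: ", which))
  system.file("extdata", f, package = "padrom", mustWork = TRUE)
}

#' Published condition-comparison tables
#'
#' Per-plane condition means and SDs (degrees), omnibus F, printed p and
#' partial eta-squared for the static tasks, the wrist shot (SI to SR) and
#' the slap shot (SI to ST, ST to SR).
#'
#' @param which `"static"`, `"wrist"` or `"slap"`.
#' @return Data frame with one row per joint plane (and phase, for the slap
#'   shot).
#' @export
printed_table <- function(which = c("static", "wrist", "slap")) {
  which <- match.arg(which)
  utils::read.csv(printed_table_path(which), stringsAsFactors = FALSE,
                  check.names = FALSE)
}

pad_mean_columns <- function() paste0("mean_", setdiff(pad_conditions(), "no_pads"))

#' Derived mobility-restriction summaries from the published tables
#'
#' Recomputes, from the printed condition means and effect sizes, the
#' headline summary quantities:
#' * `abduction_reduction_deg`, `flexion_reduction_deg`: mean shoulder
#'   abduction / flexion reduction in degrees (control mean minus the mean of
#'   the five pad means, static tasks).
#' * `wrist_left_elbow_limitation_pct`: mean percent limitation of left elbow
#'   flexion/extension during the wrist shot ([restriction_percent()] of the
#'   mean pad ROM against the control).
#' * `mean_eta_sq_static`: average partial eta-squared over the nine static
#'   planes.
#' * `mean_eta_sq_left_elbow_dynamic`: average partial eta-squared of the
#'   left elbow flexion/extension plane over the three shot phases.
#' * `mean_eta_sq_forearm_pro_sup`: average partial eta-squared of the static
#'   forearm pronation and supination planes.
#'
#' @return Named list of numeric summaries.
#' @export
derived_table_summaries <- function() {
  static <- printed_table("static")
  wrist <- printed_table("wrist")
  slap <- printed_table("slap")
  pad_cols <- pad_mean_columns()

  reduction_deg <- function(tab, plane_) {
    row <- tab[tab$plane == plane_, ]
    row$mean_no_pads - mean(as.numeric(row[, pad_cols]))
  }
  limitation_pct <- function(tab, plane_) {
    row <- tab[tab$plane == plane_, ]
    restriction_percent(row$mean_no_pads, mean(as.numeric(row[, pad_cols])))
  }

  elbow_l_eta <- c(
    wrist$eta_sq[wrist$plane == "elbow_flex_ext_L"],
    slap$eta_sq[slap$plane == "elbow_flex_ext_L"]
  )
  list(
    abduction_reduction_deg = reduction_deg(static, "shoulder_abduction"),
    flexion_reduction_deg = reduction_deg(static, "shoulder_flexion"),
    wrist_left_elbow_limitation_pct = limitation_pct(wrist, "elbow_flex_ext_L"),
    mean_eta_sq_static = mean(static$eta_sq),
    mean_eta_sq_left_elbow_dynamic = mean(elbow_l_eta),
    mean_eta_sq_forearm_pro_sup = mean(static$eta_sq[static$plane %in%
      c("forearm_pronation", "forearm_supination")])
  )
}

#' Reference control ROM per static plane
#'
#' Control-condition (no pads) means used to seed the synthetic generator.
#' Two printed control means are internally inconsistent with the study's own
#' restriction percentages — the shoulder external-rotation control (printed
#' 138.6, but the stated 8.2-19.5% limitations imply ~70.7) and the elbow
#' flexion control (printed 77.7, but the stated 16.8-27.2% limitations imply
#' 138.6; the two appear transposed in print).  This accessor returns the
#' percentage-consistent values; [printed_table()] keeps the table verbatim.
#'
#' @return Named numeric vector of control ROM (degrees) per static plane.
#' @export
reference_control_rom <- function() {
  static <- printed_table("static")
  ctrl <- stats::setNames(static$mean_no_pads, static$plane)
  ctrl["shoulder_external_rotation"] <- 70.7
  ctrl["elbow_flexion"] <- 138.6
  ctrl
}

#' Reference restriction factors per condition and plane
#'
#' Pad-over-control ROM ratios seeded from the published tables (using the
#' percentage-consistent controls of [reference_control_rom()] for the two
#' inconsistent static rows), clipped to (0, 1].  The control condition is 1
#' for every plane.  Used as the synthetic generator's default effect sizes.
#'
#' @return List of matrices `static` (plane x condition), `wrist`
#'   (plane x condition, SI-SR) and `slap_si_st` / `slap_st_sr`.
#' @export
reference_restriction_factors <- function() {
  pad_cols <- pad_mean_columns()
  conds <- pad_conditions()
  factor_matrix <- function(tab, control) {
    f <- sweep(as.matrix(tab[, pad_cols]), 1L, control, "/")
    f <- pmin(f, 1)
    f <- cbind(1, f)
    dimnames(f) <- list(tab$plane, conds)
    f
  }
  static <- printed_table("static")
  wrist <- printed_table("wrist")
  slap <- printed_table("slap")
  list(
    static = factor_matrix(static,
                           unname(reference_control_rom()[static$plane])),
    wrist = factor_matrix(wrist, wrist$mean_no_pads),
    slap_si_st = factor_matrix(slap[slap$phase == "si_st", ],
                               slap$mean_no_pads[slap$phase == "si_st"]),
    slap_st_sr = factor_matrix(slap[slap$phase == "st_sr", ],
                               slap$mean_no_pads[slap$phase == "st_sr"])
  )
}
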