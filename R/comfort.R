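## Likert survey aggregation and the comfort vs mobility correlation.

#' Survey questions
#'
#' The four statements rated per pad and protector on a 1-5 Likert scale
#' (1 = strongly disagree ... 5 = strongly agree): perceived comfort, safety,
#' motion restriction, and willingness to wear.
#'
#' @return Character vector of question codes.
#' @export
survey_questions <- function() {
  c("q1_comfort", "q2_safe", "q3_restricts", "q4_would_wear")
}

#' @rdname survey_questions
#' @export
protector_types <- function() c("shoulder", "elbow")

check_survey <- function(responses) {
  need <- c("participant", "pad", "protector", "question", "score")
  if (!all(need %in% names(responses))) {
    stop("survey needs columns ", paste(need, collapse = ","))
  }
  if (!all(responses$score %in% 1:5)) stop("scores must be integers 1-5")
  if (!all(responses$question %in% survey_questions())) {
    stop("unknown question code(s)")
  }
  if (!all(responses$protector %in% protector_types())) {
    stop("unknown protector type(s)")
  }
  key <- interaction(responses$participant, responses$pad,
                     responses$protector, responses$question, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate response for participant x pad x protector x question")
  }
  ## completeness: every participant must answer every question for every
  ## pad x protector present in the data
  participants <- unique(responses$participant)
  pads <- unique(responses$pad)
  expected <- length(participants) * length(pads) *
    length(protector_types()) * length(survey_questions())
  if (nrow(responses) != expected) {
    stop("incomplete survey: expected ", expected, " responses (",
         length(participants), " participants x ", length(pads),
         " pads x 2 protectors x 4 questions), got ", nrow(responses))
  }
  responses
}

#' Aggregate Likert responses into per-pad means
#'
#' Arithmetic means per pad x protector x question, plus a pooled (shoulder
#' and elbow combined) mean per pad x question, and a descending-mean rank
#' per question (ties share the average rank).  Ordinal scores are averaged
#' here only for descriptive ranking; inferential testing uses
#' [friedman_test()] and [wilcoxon_signed_rank()].
#'
#' @param responses Data frame with columns `participant`, `pad`,
#'   `protector`, `question`, `score` (integers 1-5); one response per key,
#'   complete over participants.
#' @return List with data frames `by_protector` (pad, protector, question,
#'   mean_score) and `pooled` (pad, question, mean_score, rank).
#' @export
aggregate_likert <- function(responses) {
  responses <- check_survey(responses)
  by_prot <- stats::aggregate(score ~ pad + protector + question,
                              data = responses, FUN = mean)
  names(by_prot)[names(by_prot) == "score"] <- "mean_score"
  pooled <- stats::aggregate(score ~ pad + question, data = responses,
                             FUN = mean)
  names(pooled)[names(pooled) == "score"] <- "mean_score"
  pooled <- do.call(rbind, lapply(split(pooled, pooled$question), function(d) {
    d$rank <- rank(-d$mean_score)
    d
  }))
  rownames(pooled) <- NULL
  list(by_protector = by_prot, pooled = pooled)
}

#' Total ROM for one condition over a task set
#'
#' Sums the condition-mean ROM over the selected tasks / joint planes —
#' the "total ROM" used to summarize how much overall mobility a pad
#' preserves.
#'
#' @param cell_table Cell-level ROM table from [extract_study_rom()] (or the
#'   pipeline's `rom_table.csv`).
#' @param condition Condition code.
#' @param tasks Optional task filter (default: all tasks present).
#' @param phases Optional phase filter.
#' @param joint_planes Optional joint-plane filter.
#' @return Total ROM in degrees (sum of per-cell condition means).
#' @export
total_rom <- function(cell_table, condition, tasks = NULL, phases = NULL,
                      joint_planes = NULL) {
  sel <- cell_table$condition == condition
  if (!is.null(tasks)) sel <- sel & cell_table$task %in% tasks
  if (!is.null(phases)) sel <- sel & cell_table$phase %in% phases
  if (!is.null(joint_planes)) sel <- sel & cell_table$joint_plane %in% joint_planes
  sub <- cell_table[sel, , drop = FALSE]
  if (!nrow(sub)) stop("empty selection for condition '", condition, "'")
  means <- stats::aggregate(rom_deg ~ task + phase + joint_plane, data = sub,
                            FUN = mean)
  sum(means$rom_deg)
}

#' Correlate comfort with total ROM across pads
#'
#' Spearman correlation ([spearman_corr()]) between per-pad comfort scores
#' and per-pad total ROM, with the correlation-strength band
#' ([classify_correlation()]).  Positive rho means more preserved mobility
#' goes with higher comfort.
#'
#' @param comfort Named numeric vector of per-pad comfort means (names are
#'   pad codes).
#' @param rom Named numeric vector of per-pad total ROM (degrees); names must
#'   match `comfort`.
#' @return List with `rho`, `p_value`, `band` and `n_pads`.
#' @export
comfort_rom_correlation <- function(comfort, rom) {
  if (is.null(names(comfort)) || is.null(names(rom))) {
    stop("comfort and rom must be named by pad")
  }
  pads <- intersect(names(comfort), names(rom))
  if (length(pads) < 3) stop("need at least 3 pads with both measures")
  ct <- spearman_corr(comfort[pads], rom[pads])
  list(rho = ct$rho, p_value = ct$p_value,
       band = classify_correlation(ct$rho), n_pads = length(pads))
}

#' Per-pad comfort score
#'
#' The comfort level used for the ROM correlation: the mean of the comfort
#' question scores pooled over shoulder and elbow protectors.  Optionally the
#' restriction question can be folded in reverse-coded (6 - score).
#'
#' @param responses Survey data frame (see [aggregate_likert()]).
#' @param include_restricts Also use the reverse-coded restriction question
#'   (default `FALSE`).
#' @return Named numeric vector of comfort means per pad.
#' @export
comfort_scores <- function(responses, include_restricts = FALSE) {
  responses <- check_survey(responses)
  keep <- responses$question == "q1_comfort"
  sub <- responses[keep, ]
  if (include_restricts) {
    rev_ <- responses[responses$question == "q3_restricts", ]
    rev_$score <- 6 - rev_$score
    sub <- rbind(sub, rev_)
  }
  out <- tapply(sub$score, sub$pad, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Survey CSV IO
#'
#' Long format: `participant,pad,protector,question,score`.
#'
#' @param path CSV path.
#' @return `read_survey_csv()` returns the validated data frame.
#' @export
read_survey_csv <- function(path) {
  check_survey(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_survey_csv
#' @param responses Survey data frame.
#' @export
write_survey_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
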