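#' Proportion of correct choices by condition
#'
#' For rewarded pairs, the correct choice is the stimulus with the higher
#' reward probability (stimulus A, 80%), irrespective of the actual outcome.
#' For bivalent pairs, where probabilities are equal, the measure reflects
#' the proportion of choices for a fixed designated stimulus (A), expected
#' to stay near 0.5.
#'
#' @param records Trial records aligned with `schedule` (practice trials,
#'   if present in both, are dropped).
#' @param schedule A `task_schedule`.
#' @param condition `"rewarded"` or `"bivalent"`.
#' @return The proportion over non-missed trials of the condition.
#' @export
correct_choice_proportion <- function(records, schedule,
                                      condition = c("rewarded", "bivalent")) {
  condition <- match.arg(condition)
  check_alignment(records, schedule)
  keep <- schedule$condition == condition & !schedule$practice &
    !is.na(records$choice) & records$choice != "none"
  if (!any(keep)) {
    stop("no responded trials of condition '", condition, "'", call. = FALSE)
  }
  mean(records$choice[keep] == "A")
}

#' Learning-based subject exclusion
#'
#' Subjects are excluded if they chose the optimal stimulus in less than 50%
#' of the trials during the last eight trials of the rewarded pairs, pooled
#' over the 5 rewarded blocks (40 trials); exactly 50% is kept (strict
#' "less than"). Missed trials count as non-optimal. The per-block reading
#' (every rewarded block individually >= 50%) is also reported for
#' transparency.
#'
#' @inheritParams correct_choice_proportion
#' @return One-row tibble: `criterion` (pooled optimal proportion), `keep`,
#'   `keep_per_block` (stricter per-block reading).
#' @export
learning_exclusion <- function(records, schedule) {
  check_alignment(records, schedule)
  late <- schedule$condition == "rewarded" & !schedule$practice &
    schedule$block_trial >= 9L
  optimal <- !is.na(records$choice) & records$choice == "A"
  crit <- mean(optimal[late])
  per_block <- tapply(optimal[late], schedule$pair_index[late], mean)
  tibble::tibble(criterion = crit,
                 keep = crit >= 0.5,
                 keep_per_block = all(per_block >= 0.5))
}

#' Response-quality subject exclusion
#'
#' Subjects with no response or anticipated responses (reaction time
#' < 100 ms) in more than 10% of the trials are excluded; exactly 10% is
#' kept (strict "more than").
#'
#' @param records Trial records with `choice` and `rt_ms` (main trials).
#' @return One-row tibble: `bad_fraction`, `keep`.
#' @export
response_exclusion <- function(records) {
  rec <- records
  if ("practice" %in% names(rec)) rec <- rec[!rec$practice, , drop = FALSE]
  bad <- is.na(rec$choice) | rec$choice == "none" |
    (!is.na(rec$rt_ms) & rec$rt_ms < 100)
  frac <- mean(bad)
  tibble::tibble(bad_fraction = frac, keep = frac <= 0.10)
}

#' Head-motion subject exclusion
#'
#' Subjects with an estimated maximum absolute movement > 3.0 mm or an
#' average absolute movement > 0.3 mm are excluded; values exactly at the
#' thresholds are kept (strict ">").
#'
#' @param max_abs_mm,mean_abs_mm Non-negative motion summaries in mm.
#' @return One-row tibble: `max_abs_mm`, `mean_abs_mm`, `keep`. Vectorized.
#' @export
motion_exclusion <- function(max_abs_mm, mean_abs_mm) {
  if (any(max_abs_mm < 0 | mean_abs_mm < 0)) {
    stop("motion summaries must be non-negative", call. = FALSE)
  }
  tibble::tibble(max_abs_mm = max_abs_mm, mean_abs_mm = mean_abs_mm,
                 keep = !(max_abs_mm > 3.0 | mean_abs_mm > 0.3))
}

#' Cohort learning curves
#'
#' Mean proportion of optimal (rewarded pairs) / designated (bivalent pairs)
#' choices at each within-block trial position 1–16 across subjects, with
#' normal-approximation 95% confidence bands over subjects.
#'
#' @param cohort_records A list of trial-record tibbles (one per subject),
#'   each aligned with its schedule and carrying `condition`, `block_trial`,
#'   `choice`, `practice` columns (as returned by [simulate_agent()]).
#' @return A tibble: `condition`, `block_trial`, `mean`, `lo`, `hi`,
#'   `n_subjects`, of class `learning_curves`.
#' @export
learning_curves <- function(cohort_records) {
  if (length(cohort_records) < 1) stop("need >= 1 subject", call. = FALSE)
  per_subj <- purrr::imap(cohort_records, function(rec, i) {
    rec <- rec[!rec$practice, , drop = FALSE]
    rec$optimal <- !is.na(rec$choice) & rec$choice == "A"
    out <- dplyr::summarise(
      dplyr::group_by(rec, .data$condition, .data$block_trial),
      p = mean(.data$optimal), .groups = "drop")
    out$subject <- i
    out
  })
  all <- dplyr::bind_rows(per_subj)
  curves <- dplyr::summarise(
    dplyr::group_by(all, .data$condition, .data$block_trial),
    mean = mean(.data$p),
    se = if (dplyr::n() > 1) stats::sd(.data$p) / sqrt(dplyr::n()) else 0,
    n_subjects = dplyr::n(), .groups = "drop")
  curves$lo <- pmax(0, curves$mean - 1.96 * curves$se)
  curves$hi <- pmin(1, curves$mean + 1.96 * curves$se)
  curves <- curves[, c("condition", "block_trial", "mean", "lo", "hi",
                       "n_subjects")]
  class(curves) <- c("learning_curves", class(curves))
  curves
}

#' @method autoplot learning_curves
#' @export
autoplot.learning_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$block_trial, y = .data$mean,
                                       colour = .data$condition,
                                       fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "trial within block", y = "proportion optimal choice") +
    ggplot2::theme_minimal()
}

#' Per-subject QC report
#'
#' Applies the learning, response and motion filters to every subject of a
#' cohort and reports pass/fail with criterion values. Filters are
#' idempotent and order-independent; `keep` is the conjunction.
#'
#' @param cohort_records Named list of per-subject record tibbles.
#' @param schedules List of matching `task_schedule`s (recycled if length 1).
#' @param motion Tibble with columns `subject_id`, `max_abs_mm`,
#'   `mean_abs_mm`, rows aligned with `cohort_records`.
#' @return A tibble, one row per subject: learning criterion, bad-response
#'   fraction, motion summaries, per-filter keep flags and overall `keep`.
#' @export
qc_report <- function(cohort_records, schedules, motion = NULL) {
  n <- length(cohort_records)
  if (length(schedules) == 1L && n > 1L) {
    schedules <- rep(schedules, n)
  }
  ids <- names(cohort_records) %||% as.character(seq_len(n))
  rows <- purrr::map(seq_len(n), function(i) {
    le <- learning_exclusion(cohort_records[[i]], schedules[[i]])
    re <- response_exclusion(cohort_records[[i]])
    tibble::tibble(subject_id = ids[i],
                   learning_criterion = le$criterion,
                   keep_learning = le$keep,
                   bad_response_fraction = re$bad_fraction,
                   keep_response = re$keep)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(motion)) {
    mo <- motion_exclusion(motion$max_abs_mm, motion$mean_abs_mm)
    out$max_abs_mm <- mo$max_abs_mm
    out$mean_abs_mm <- mo$mean_abs_mm
    out$keep_motion <- mo$keep
    out$keep <- out$keep_learning & out$keep_response & out$keep_motion
  } else {
    out$keep <- out$keep_learning & out$keep_response
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
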