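#' Pair specifications for the probabilistic monetary reward task
#'
#' The task presents 10 pairs of stimuli, each for a block of 16 consecutive
#' trials (160 main trials). Five pairs are *rewarded* (one stimulus wins on
#' 80% of trials, the other on 20%) and five are *bivalent* (both stimuli win
#' on 50% of trials). Rewarded pairs occupy block positions 1, 3, 4, 5 and 7.
#'
#' @return A tibble with one row per pair: `pair_index`, `condition`
#'   (`"rewarded"` or `"bivalent"`), `p_win_A`, `p_win_B`. Stimulus A is the
#'   high-probability (optimal) stimulus in rewarded pairs and the designated
#'   reference stimulus in bivalent pairs.
#' @export
#' @examples
#' pair_specs()
pair_specs <- function() {
  rewarded_positions <- c(1L, 3L, 4L, 5L, 7L)
  tibble::tibble(
    pair_index = 1:10,
    condition = ifelse(1:10 %in% rewarded_positions, "rewarded", "bivalent"),
    p_win_A = ifelse(1:10 %in% rewarded_positions, 0.8, 0.5),
    p_win_B = ifelse(1:10 %in% rewarded_positions, 0.2, 0.5)
  )
}

#' Sample inter-trial fixation (jitter) durations
#'
#' Durations are drawn from an exponential distribution truncated to
#' \[1.0, 6.5\] s, with rate calibrated numerically so the population mean is
#' 2.0 s — a standard rapid event-related jitter choice matching the task's
#' stated range and mean.
#'
#' @param n Number of durations to draw (>= 1).
#' @return Numeric vector of `n` durations in seconds, all in \[1.0, 6.5\].
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_jitter(1e4))
sample_jitter <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  rate <- jitter_rate()
  lo <- 1.0
  hi <- 6.5
  # inverse-CDF sampling of the truncated exponential
  u <- stats::runif(n)
  p_lo <- stats::pexp(lo, rate)
  p_hi <- stats::pexp(hi, rate)
  stats::qexp(p_lo + u * (p_hi - p_lo), rate)
}

# Rate of the exponential whose truncation to [1, 6.5] has mean 2.0 s.
# Cached after the first computation.
jitter_rate <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    target <- 2.0
    trunc_mean <- function(rate, lo = 1.0, hi = 6.5) {
      d <- hi - lo
      lo + 1 / rate - d * exp(-rate * d) / (1 - exp(-rate * d))
    }
    cached <<- stats::uniroot(function(r) trunc_mean(r) - target,
                              interval = c(1e-3, 50), tol = 1e-12)$root
    cached
  }
})

#' Generate a full task schedule
#'
#' Builds the 160-trial main task (10 blocks of 16 trials, rewarded blocks at
#' positions 1, 3, 4, 5 and 7) plus optional practice trials. Both stimuli's
#' potential outcomes are pre-sampled per trial as independent
#' Bernoulli(p_win) draws, so agent simulation is replayable and the choice
#' likelihood is conditional on the schedule. Timing follows the trial
#' structure: 2.5 s stimulus presentation, 1 s feedback, then a jittered
#' fixation (1.0–6.5 s, mean 2.0 s).
#'
#' @param seed Non-negative integer seed; identical seeds give identical
#'   schedules.
#' @param n_practice Number of practice trials prepended before the main run
#'   (default 48). Practice trials use the same mechanics, are flagged
#'   `practice = TRUE`, and get their own pair indices (0 > pair_index >= -3).
#' @param t0 Onset of the first main-trial stimulus in seconds (default 0).
#' @return A `task_schedule`: a tibble with one row per trial and columns
#'   `trial`, `pair_index`, `block_trial` (1–16), `condition`, `practice`,
#'   `outcome_if_A`, `outcome_if_B`, `stim_onset_s`, `feedback_onset_s`,
#'   `jitter_s`. The seed is stored in `attr(, "seed")`.
#' @export
#' @examples
#' sched <- generate_schedule(seed = 1)
#' dplyr::count(sched[!sched$practice, ], condition)
generate_schedule <- function(seed, n_practice = 48L, t0 = 0) {
  if (length(seed) != 1L || !is.finite(seed) || seed < 0 ||
      seed != trunc(seed)) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  n_practice <- as.integer(n_practice)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    specs <- pair_specs()
    main <- tidyr::uncount(specs, 16L)
    main$block_trial <- rep(1:16, times = 10)
    main$practice <- FALSE

    sched <- main
    if (n_practice > 0L) {
      # practice blocks cycle rewarded/bivalent pairs, negative indices
      n_blocks <- ceiling(n_practice / 16)
      cond <- rep(c("rewarded", "bivalent"), length.out = n_blocks)
      prac <- tibble::tibble(
        pair_index = rep(-seq_len(n_blocks), each = 16L)[seq_len(n_practice)],
        condition = rep(cond, each = 16L)[seq_len(n_practice)],
        block_trial = rep(1:16, times = n_blocks)[seq_len(n_practice)],
        practice = TRUE
      )
      prac$p_win_A <- ifelse(prac$condition == "rewarded", 0.8, 0.5)
      prac$p_win_B <- ifelse(prac$condition == "rewarded", 0.2, 0.5)
      sched <- dplyr::bind_rows(prac[names(main)], main)
    }

    n <- nrow(sched)
    sched$outcome_if_A <- stats::rbinom(n, 1L, sched$p_win_A)
    sched$outcome_if_B <- stats::rbinom(n, 1L, sched$p_win_B)
    sched$jitter_s <- sample_jitter(n)

    # trial length = stimulus (2.5 s) + feedback (1 s) + jitter
    trial_len <- 2.5 + 1.0 + sched$jitter_s
    sched$stim_onset_s <- t0 + c(0, cumsum(trial_len)[-n])
    sched$feedback_onset_s <- sched$stim_onset_s + 2.5
    sched$trial <- seq_len(n)

    out <- sched[, c("trial", "pair_index", "block_trial", "condition",
                     "practice", "p_win_A", "p_win_B",
                     "outcome_if_A", "outcome_if_B",
                     "stim_onset_s", "feedback_onset_s", "jitter_s")]
    attr(out, "seed") <- seed
    class(out) <- c("task_schedule", class(out))
    out
  })
}

#' Drop practice trials from a schedule (or an aligned trial table)
#'
#' @param schedule A `task_schedule` tibble.
#' @return The main 160-trial portion, with `trial` renumbered from 1.
#' @export
main_trials <- function(schedule) {
  out <- schedule[!schedule$practice, , drop = FALSE]
  out$trial <- seq_len(nrow(out))
  out
}

#' Write / read BIDS-style events tables
#'
#' Serializes a schedule plus (optionally) simulated responses to a
#' BIDS-style events TSV with columns `onset`, `duration`, `trial_type`
#' (`stim_reward`, `stim_bivalent`, `fb_reward`, `fb_bivalent`),
#' `pair_index`, `trial_index`, `response`, `outcome`, `rt_ms`. Each trial
#' contributes a stimulus event and a feedback event.
#'
#' @param schedule A `task_schedule`.
#' @param records Optional trial records aligned with `schedule` (columns
#'   `choice`, `outcome`, `rt_ms`), e.g. from [simulate_agent()]. When
#'   absent, `response`/`outcome`/`rt_ms` are written as `n/a`.
#' @param path File path for the TSV.
#' @return `write_events_tsv()` returns `path` invisibly; `read_events_tsv()`
#'   returns the events tibble with `n/a` parsed to `NA`.
#' @export
write_events_tsv <- function(schedule, path, records = NULL) {
  sch <- main_trials(schedule)
  cond_tag <- ifelse(sch$condition == "rewarded", "reward", "bivalent")
  if (is.null(records)) {
    response <- rep(NA_character_, nrow(sch))
    outcome <- rep(NA_integer_, nrow(sch))
    rt_ms <- rep(NA_real_, nrow(sch))
  } else {
    stopifnot(nrow(records) == nrow(sch))
    response <- as.character(records$choice)
    outcome <- records$outcome
    rt_ms <- records$rt_ms
  }
  stim <- tibble::tibble(
    onset = sch$stim_onset_s, duration = 2.5,
    trial_type = paste0("stim_", cond_tag),
    pair_index = sch$pair_index, trial_index = sch$trial,
    response = response, outcome = outcome, rt_ms = rt_ms
  )
  fb <- tibble::tibble(
    onset = sch$feedback_onset_s, duration = 1.0,
    trial_type = paste0("fb_", cond_tag),
    pair_index = sch$pair_index, trial_index = sch$trial,
    response = response, outcome = outcome, rt_ms = rt_ms
  )
  ev <- dplyr::arrange(dplyr::bind_rows(stim, fb), .data$onset, .data$trial_type)
  ev_out <- dplyr::mutate(ev, dplyr::across(dplyr::everything(),
                                            ~ ifelse(is.na(.x), "n/a", as.character(.x))))
  readr::write_tsv(ev_out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                  col_types = readr::cols(
                    onset = "d", duration = "d", trial_type = "c",
                    pair_index = "i", trial_index = "i",
                    response = "c", outcome = "i", rt_ms = "d"
                  ))
}
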