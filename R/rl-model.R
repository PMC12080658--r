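#' Q-learning value update and reward prediction error
#'
#' The chosen stimulus's expected value (EV) moves toward the outcome by a
#' fraction `alpha` of the reward prediction error (RPE):
#' `rpe = r - ev`, `ev_next = ev + alpha * rpe`. Only the chosen stimulus's
#' EV changes; the unchosen EV carries over unchanged. With outcomes coded
#' 0/1 and `alpha` in \[0, 1\], EVs stay in \[0, 1\] and RPEs in \[-1, 1\].
#'
#' @param ev Current expected value of the chosen stimulus.
#' @param r Outcome, 0 (no win) or 1 (win).
#' @param alpha Learning rate in \[0, 1\].
#' @return A list with elements `rpe` and `ev_next`. Vectorized over inputs.
#' @export
#' @examples
#' update_value(0, 1, 0.5)   # rpe 1, ev_next 0.5
update_value <- function(ev, r, alpha) {
  if (any(alpha < 0 | alpha > 1)) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  rpe <- r - ev
  list(rpe = rpe, ev_next = ev + alpha * rpe)
}

#' Softmax choice probability
#'
#' Probability of choosing stimulus A given the two expected values and the
#' temperature `beta`:
#' `p_A = exp(ev_a / beta) / (exp(ev_a / beta) + exp(ev_b / beta))`.
#' Higher `beta` means more exploratory (closer to 0.5) choices; lower
#' `beta` means more deterministic choices. Computed in the numerically
#' stable logistic form.
#'
#' @param ev_a,ev_b Expected values of the two stimuli.
#' @param beta Temperature, > 0.
#' @return `p_a`, the probability of choosing A. Vectorized.
#' @export
#' @examples
#' choice_probability(1, 0, 0.29)
choice_probability <- function(ev_a, ev_b, beta) {
  if (any(beta <= 0)) stop("`beta` must be > 0", call. = FALSE)
  stats::plogis((ev_a - ev_b) / beta)
}

# Floor for log choice probabilities (guards against -Inf at extreme
# parameters).
LOG_P_FLOOR <- log(1e-12)

#' Simulate a Q-learning agent on a task schedule
#'
#' Plays the task forward: EVs reset to 0 at the start of each 16-trial
#' block, choices are sampled from the softmax probability, the outcome is
#' read from the schedule's pre-sampled outcome of the chosen stimulus, and
#' EVs update by the Q-learning rule. Reaction times are drawn from a
#' log-normal (median ~600 ms) purely as plumbing for QC filters.
#'
#' @param schedule A `task_schedule` from [generate_schedule()]. Practice
#'   trials, if present, are played but flagged.
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Temperature, > 0.
#' @param seed Integer seed for choice sampling.
#' @param p_miss Probability a trial gets no response (default 0).
#' @return A tibble, one row per trial, combining the trial record
#'   (`choice` in `"A"`/`"B"`/`"none"`, `outcome`, `rt_ms`) with the latent
#'   trace (`ev_A`, `ev_B` pre-update values at stimulus onset, `p_choice`
#'   probability of the made choice, `rpe`), plus the schedule's `trial`,
#'   `pair_index`, `condition`, `practice` columns.
#' @export
simulate_agent <- function(schedule, alpha, beta, seed, p_miss = 0) {
  stopifnot(alpha >= 0, alpha <= 1, beta > 0)
  set.seed(seed)
  n <- nrow(schedule)
  u_choice <- stats::runif(n)
  u_miss <- stats::runif(n)
  rt <- stats::rlnorm(n, meanlog = log(600), sdlog = 0.3)

  ev_A <- ev_B <- p_choice <- rpe <- numeric(n)
  choice <- character(n)
  outcome <- integer(n)
  eA <- eB <- 0
  for (t in seq_len(n)) {
    if (schedule$block_trial[t] == 1L) {
      eA <- 0; eB <- 0
    }
    ev_A[t] <- eA; ev_B[t] <- eB
    if (u_miss[t] < p_miss) {
      choice[t] <- "none"
      outcome[t] <- NA_integer_
      p_choice[t] <- NA_real_
      rpe[t] <- NA_real_
      rt[t] <- NA_real_
      next
    }
    pA <- choice_probability(eA, eB, beta)
    if (u_choice[t] < pA) {
      choice[t] <- "A"
      p_choice[t] <- pA
      outcome[t] <- schedule$outcome_if_A[t]
      step <- update_value(eA, outcome[t], alpha)
      rpe[t] <- step$rpe
      eA <- step$ev_next
    } else {
      choice[t] <- "B"
      p_choice[t] <- 1 - pA
      outcome[t] <- schedule$outcome_if_B[t]
      step <- update_value(eB, outcome[t], alpha)
      rpe[t] <- step$rpe
      eB <- step$ev_next
    }
  }
  tibble::tibble(
    trial = schedule$trial,
    pair_index = schedule$pair_index,
    block_trial = schedule$block_trial,
    condition = schedule$condition,
    practice = schedule$practice,
    choice = choice,
    outcome = outcome,
    rt_ms = rt,
    ev_A = ev_A, ev_B = ev_B,
    p_choice = p_choice, rpe = rpe
  )
}

#' Replay the latent trace conditional on observed choices
#'
#' Deterministically recomputes EVs, choice probabilities and RPEs from a
#' sequence of observed choices and outcomes, using the same recursion as
#' [simulate_agent()]. This supplies the trial-wise RPE values used as the
#' fMRI parametric modulator. Missed trials (`choice == "none"`) produce no
#' EV update and have `NA` probability and RPE.
#'
#' @param records Trial records aligned one-to-one with `schedule` rows
#'   (columns `choice`, `outcome`).
#' @param schedule The `task_schedule` the records were collected on.
#' @param alpha,beta Model parameters.
#' @return A tibble with `trial`, `ev_A`, `ev_B` (values at stimulus onset,
#'   before the trial's update), `p_choice`, `rpe`.
#' @export
trace_from_choices <- function(records, schedule, alpha, beta) {
  check_alignment(records, schedule)
  stopifnot(alpha >= 0, alpha <= 1, beta > 0)
  n <- nrow(schedule)
  ev_A <- ev_B <- p_choice <- rpe <- numeric(n)
  eA <- eB <- 0
  for (t in seq_len(n)) {
    if (schedule$block_trial[t] == 1L) {
      eA <- 0; eB <- 0
    }
    ev_A[t] <- eA; ev_B[t] <- eB
    ch <- records$choice[t]
    if (is.na(ch) || ch == "none") {
      p_choice[t] <- NA_real_
      rpe[t] <- NA_real_
      next
    }
    pA <- choice_probability(eA, eB, beta)
    r <- records$outcome[t]
    if (ch == "A") {
      p_choice[t] <- pA
      step <- update_value(eA, r, alpha)
      rpe[t] <- step$rpe
      eA <- step$ev_next
    } else {
      p_choice[t] <- 1 - pA
      step <- update_value(eB, r, alpha)
      rpe[t] <- step$rpe
      eB <- step$ev_next
    }
  }
  tibble::tibble(trial = schedule$trial, ev_A = ev_A, ev_B = ev_B,
                 p_choice = p_choice, rpe = rpe)
}

check_alignment <- function(records, schedule) {
  if (nrow(records) != nrow(schedule)) {
    stop("`records` must align one-to-one with `schedule` trials",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Negative log-likelihood of a choice sequence under the Q-learning model
#'
#' `-sum(log p_choice(t))` over non-missed trials, where `p_choice` comes
#' from the softmax rule applied to the EVs replayed from the observed
#' choices. Log-probabilities are floored at `log(1e-12)` so the result is
#' finite under extreme parameters. Internally computed block-wise: since
#' EVs reset at each 16-trial block and the EV path depends only on `alpha`,
#' blocks are updated in parallel across a vector of candidate parameters
#' (see [nll_surface()]).
#'
#' @inheritParams trace_from_choices
#' @return The negative log-likelihood (>= 0).
#' @export
#' @examples
#' sched <- generate_schedule(1, n_practice = 0)
#' rec <- simulate_agent(sched, 0.4, 0.3, seed = 2)
#' negative_log_likelihood(rec, sched, 0.4, 0.3)
negative_log_likelihood <- function(records, schedule, alpha, beta) {
  drop(nll_surface(records, schedule, alpha, beta))
}

#' Negative log-likelihood over a parameter grid
#'
#' Evaluates the choice-sequence negative log-likelihood at every
#' combination of `alpha` and `beta` values in one pass. The EV-difference
#' path for the chosen stimulus depends only on `alpha`, so it is computed
#' once per `alpha` (all blocks in parallel) and the softmax applied for
#' every `beta`.
#'
#' @inheritParams trace_from_choices
#' @param alpha,beta Numeric vectors of candidate values.
#' @return A `length(alpha) x length(beta)` matrix of NLL values.
#' @export
nll_surface <- function(records, schedule, alpha, beta) {
  check_alignment(records, schedule)
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (any(beta <= 0)) stop("`beta` must be > 0", call. = FALSE)

  keep <- !is.na(records$choice) & records$choice != "none"
  if (!any(keep)) stop("all trials are missed; no likelihood", call. = FALSE)
  # dEV[t] = EV(chosen) - EV(unchosen) at trial t, one row per alpha
  blocks <- unique_block_ids(schedule)
  nA <- length(alpha)
  n <- nrow(schedule)
  dev <- matrix(0, nA, n)
  for (b in split(seq_len(n), blocks)) {
    eA <- rep(0, nA); eB <- rep(0, nA)
    for (t in b) {
      ch <- records$choice[t]
      if (is.na(ch) || ch == "none") next
      r <- records$outcome[t]
      if (ch == "A") {
        dev[, t] <- eA - eB
        eA <- eA + alpha * (r - eA)
      } else {
        dev[, t] <- eB - eA
        eB <- eB + alpha * (r - eB)
      }
    }
  }
  dev <- dev[, keep, drop = FALSE]
  out <- matrix(0, nA, length(beta))
  for (j in seq_along(beta)) {
    logp <- stats::plogis(dev / beta[j], log.p = TRUE)
    logp[logp < LOG_P_FLOOR] <- LOG_P_FLOOR
    out[, j] <- -rowSums(logp)
  }
  dimnames(out) <- list(alpha = NULL, beta = NULL)
  out
}

# Consecutive-block ids robust to practice + main numbering
unique_block_ids <- function(schedule) {
  cumsum(schedule$block_trial == 1L)
}

#' Export a latent trace as TSV
#'
#' @param trace A trace tibble from [trace_from_choices()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  readr::write_tsv(trace, path)
  invisible(path)
}
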