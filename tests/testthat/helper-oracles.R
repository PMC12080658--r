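# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorized code paths.

# Plain per-trial loop for the choice-sequence negative log-likelihood,
# with the softmax written as an explicit exponential ratio.
oracle_nll <- function(records, schedule, alpha, beta) {
  nll <- 0
  evA <- evB <- 0
  for (t in seq_len(nrow(schedule))) {
    if (schedule$block_trial[t] == 1L) {
      evA <- 0; evB <- 0
    }
    ch <- records$choice[t]
    if (is.na(ch) || ch == "none") next
    ea <- exp(evA / beta); eb <- exp(evB / beta)
    pA <- ea / (ea + eb)
    p <- if (ch == "A") pA else 1 - pA
    nll <- nll - log(max(p, 1e-12))
    r <- records$outcome[t]
    if (ch == "A") evA <- evA + alpha * (r - evA) else evB <- evB + alpha * (r - evB)
  }
  nll
}

# Recursive flood fill for connected-component labeling (reference for
# label_clusters).
oracle_flood_fill <- function(bin, connectivity = 26) {
  d <- dim(bin)
  lab <- array(0L, d)
  offs <- if (connectivity == 6) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  cur <- 0L
  for (i in which(bin)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(i, d))
    while (length(stack)) {
      co <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (co[1] < 1 || co[2] < 1 || co[3] < 1 ||
          co[1] > d[1] || co[2] > d[2] || co[3] > d[3]) next
      if (!bin[co[1], co[2], co[3]] || lab[co[1], co[2], co[3]] != 0L) next
      lab[co[1], co[2], co[3]] <- cur
      for (k in seq_len(nrow(offs))) {
        stack[[length(stack) + 1L]] <- co + offs[k, ]
      }
    }
  }
  lab
}

# Build a minimal hand-specified schedule for controlled trials.
# conditions: one per block; outcomes_A/outcomes_B: vectors, one per trial.
toy_schedule <- function(conditions, outcomes_A, outcomes_B,
                         trials_per_block = length(outcomes_A) / length(conditions)) {
  n <- length(outcomes_A)
  stopifnot(n == length(outcomes_B), n == trials_per_block * length(conditions))
  jit <- rep(2, n)
  trial_len <- 2.5 + 1 + jit
  tibble::tibble(
    trial = seq_len(n),
    pair_index = rep(seq_along(conditions), each = trials_per_block),
    block_trial = rep(seq_len(trials_per_block), times = length(conditions)),
    condition = rep(conditions, each = trials_per_block),
    practice = FALSE,
    p_win_A = ifelse(condition == "rewarded", 0.8, 0.5),
    p_win_B = ifelse(condition == "rewarded", 0.2, 0.5),
    outcome_if_A = outcomes_A,
    outcome_if_B = outcomes_B,
    stim_onset_s = c(0, cumsum(trial_len)[-n]),
    feedback_onset_s = c(0, cumsum(trial_len)[-n]) + 2.5,
    jitter_s = jit)
}

# Records tibble from explicit choices on a toy schedule.
toy_records <- function(schedule, choices, rt_ms = 600) {
  outcome <- ifelse(choices == "A", schedule$outcome_if_A,
                    ifelse(choices == "B", schedule$outcome_if_B, NA))
  tibble::tibble(
    trial = schedule$trial, pair_index = schedule$pair_index,
    block_trial = schedule$block_trial, condition = schedule$condition,
    practice = schedule$practice, choice = choices,
    outcome = as.integer(outcome),
    rt_ms = ifelse(choices == "none", NA_real_, rt_ms))
}
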