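test_that("value update follows the delta rule", {
  expect_equal(update_value(0, 1, 0.5), list(rpe = 1.0, ev_next = 0.5))
  expect_equal(update_value(1, 1, 0.7), list(rpe = 0, ev_next = 1))
  expect_equal(update_value(0.5, 0, 0.39), list(rpe = -0.5, ev_next = 0.305))
  expect_error(update_value(0.5, 1, 1.2), "alpha")
})

test_that("softmax choice probability is symmetric, stable, and temperature behaves as described", {
  expect_equal(choice_probability(0.3, 0.3, 0.5), 0.5)
  # closed-form exponential-ratio value, frozen from an independent evaluation
  expect_equal(choice_probability(1, 0, 0.29), 0.9691796815, tolerance = 1e-9)
  # higher temperature -> more exploratory (closer to 0.5)
  expect_lt(abs(choice_probability(1, 0, 100) - 0.5), 0.01)
  expect_gt(choice_probability(1, 0, 0.05), 0.999)
  # numerically stable at extreme EV differences / tiny temperature
  expect_equal(choice_probability(1, 0, 1e-4), 1)
  expect_equal(choice_probability(0, 1, 1e-4), 0)
  expect_error(choice_probability(1, 0, 0), "beta")
})

test_that("simulated agents respect the model's conservation laws", {
  sched <- generate_schedule(5, n_practice = 0)
  set.seed(11)
  for (k in 1:8) {
    a <- runif(1); b <- runif(1, 0.05, 2)
    rec <- simulate_agent(sched, a, b, seed = k)
    expect_true(all(rec$ev_A >= 0 & rec$ev_A <= 1))
    expect_true(all(rec$ev_B >= 0 & rec$ev_B <= 1))
    expect_true(all(abs(rec$rpe) <= 1))
    expect_true(all(rec$p_choice > 0 & rec$p_choice < 1))
    # EVs reset at the start of each block
    expect_true(all(rec$ev_A[rec$block_trial == 1] == 0))
    # outcome read from the schedule's pre-sampled outcome of the choice
    chose_a <- rec$choice == "A"
    expect_equal(rec$outcome[chose_a], sched$outcome_if_A[chose_a])
    expect_equal(rec$outcome[!chose_a], sched$outcome_if_B[!chose_a])
  }
})

test_that("an alpha = 0 agent never learns: EVs stay 0 and every choice is a coin flip", {
  sched <- generate_schedule(5, n_practice = 0)
  rec <- simulate_agent(sched, 0, 0.3, seed = 2)
  expect_true(all(rec$ev_A == 0 & rec$ev_B == 0))
  expect_true(all(rec$p_choice == 0.5))
  expect_identical(rec, simulate_agent(sched, 0, 0.3, seed = 2))
})

test_that("trace replay reproduces the simulation's latent variables", {
  sched <- generate_schedule(9, n_practice = 0)
  rec <- simulate_agent(sched, 0.45, 0.29, seed = 3, p_miss = 0.05)
  tr <- trace_from_choices(rec, sched, 0.45, 0.29)
  expect_equal(tr$ev_A, rec$ev_A)
  expect_equal(tr$ev_B, rec$ev_B)
  expect_equal(tr$p_choice, rec$p_choice)
  expect_equal(tr$rpe, rec$rpe)
  # a win on the first trial of a block is fully surprising
  first_wins <- sched$block_trial == 1 & rec$choice != "none" & rec$outcome == 1
  expect_true(all(tr$rpe[first_wins] == 1))
})

test_that("four-trial hand-computed EV/RPE path is reproduced", {
  sched <- toy_schedule("rewarded", outcomes_A = c(1, 0, 0, 1),
                        outcomes_B = c(0, 1, 1, 0), trials_per_block = 4)
  rec <- toy_records(sched, c("A", "B", "A", "A"))
  tr <- trace_from_choices(rec, sched, 0.4, 0.3)
  # frozen from independent arithmetic
  expect_equal(tr$p_choice, c(0.5, 0.2086085, 0.5, 0.3697398), tolerance = 1e-6)
  expect_equal(tr$rpe, c(1, 1, -0.4, 0.76))
  expect_equal(tr$ev_A, c(0, 0.4, 0.4, 0.24))
  expect_equal(tr$ev_B, c(0, 0, 0.4, 0.4))
})

test_that("negative log-likelihood matches closed forms and the per-trial oracle", {
  sched <- generate_schedule(5, n_practice = 0)
  rec <- simulate_agent(sched, 0.5, 0.3, seed = 4)
  # alpha = 0: every choice probability is 0.5 regardless of beta
  expect_equal(negative_log_likelihood(rec, sched, 0, 0.3), 160 * log(2))
  expect_equal(negative_log_likelihood(rec, sched, 0, 5), 160 * log(2))

  # two-trial toy, frozen from the independent loop oracle
  toy <- toy_schedule("rewarded", outcomes_A = c(1, 0),
                      outcomes_B = c(0, 0), trials_per_block = 2)
  trec <- toy_records(toy, c("A", "A"))
  expect_equal(negative_log_likelihood(trec, toy, 0.5, 0.5),
               1.0064088681, tolerance = 1e-9)

  # vectorized implementation equals the naive loop on random instances
  set.seed(21)
  for (k in 1:30) {
    s2 <- generate_schedule(1000 + k, n_practice = 0)
    r2 <- simulate_agent(s2, runif(1), runif(1, 0.05, 1), seed = k,
                         p_miss = sample(c(0, 0.1), 1))
    a <- runif(1); b <- runif(1, 0.05, 2)
    expect_equal(negative_log_likelihood(r2, s2, a, b),
                 oracle_nll(r2, s2, a, b), tolerance = 1e-10)
  }
})

test_that("nll surface is consistent with pointwise evaluation and missed trials drop out", {
  sched <- generate_schedule(6, n_practice = 0)
  rec <- simulate_agent(sched, 0.4, 0.3, seed = 5, p_miss = 0.2)
  alphas <- c(0, 0.3, 0.7)
  betas <- c(0.1, 0.5)
  surf <- nll_surface(rec, sched, alphas, betas)
  for (i in seq_along(alphas)) for (j in seq_along(betas)) {
    expect_equal(surf[i, j],
                 oracle_nll(rec, sched, alphas[i], betas[j]),
                 tolerance = 1e-10)
  }
  n_used <- sum(rec$choice != "none")
  expect_equal(surf[1, ], rep(n_used * log(2), 2), ignore_attr = TRUE)
  expect_error(negative_log_likelihood(rec[1:10, ], sched, 0.4, 0.3),
               "align")
})

test_that("larger learning rates produce weakly larger EV steps on a fixed choice sequence", {
  sched <- generate_schedule(8, n_practice = 0)
  rec <- simulate_agent(sched, 0.5, 0.3, seed = 6)
  mean_step <- function(alpha) {
    tr <- trace_from_choices(rec, sched, alpha, 0.3)
    mean(alpha * abs(tr$rpe))  # |EV change| of the chosen stimulus
  }
  steps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), mean_step, numeric(1))
  expect_true(all(diff(steps) > 0))
})
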