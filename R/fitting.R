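#' Maximum-likelihood fit of the Q-learning model for one subject
#'
#' Minimizes the choice-sequence negative log-likelihood over
#' (learning rate, temperature) with multi-start bounded local optimization:
#' `n_starts` L-BFGS-B runs from Latin-hypercube start points inside the
#' bounds, plus the box midpoint. Ties are broken by lowest NLL, then
#' smaller temperature.
#'
#' @param records Trial records aligned with `schedule` (see
#'   [simulate_agent()]); missed trials are excluded from the likelihood.
#' @param schedule The `task_schedule` the choices were made on.
#' @param alpha_bounds,beta_bounds Search boxes; defaults `[0, 1]` for the
#'   learning rate and `[0.01, 10]` for the temperature (covers typical
#'   estimates ~0.3 with wide margin while keeping the likelihood finite).
#' @param n_starts Number of optimizer starts (default 10).
#' @param seed Integer seed controlling the start points.
#' @return An object of class `rl_fit`: a list with `alpha_hat`, `beta_hat`,
#'   `nll`, `converged`, `at_boundary`, `n_trials_used`, `n_starts`, `seed`.
#'   Has [generics::tidy()] and [generics::glance()] methods.
#' @export
#' @examples
#' sched <- generate_schedule(1, n_practice = 0)
#' rec <- simulate_agent(sched, 0.45, 0.29, seed = 2)
#' tidy(fit_subject(rec, sched, seed = 3))
fit_subject <- function(records, schedule,
                        alpha_bounds = c(0, 1),
                        beta_bounds = c(0.01, 10),
                        n_starts = 10L, seed = 1L) {
  check_alignment(records, schedule)
  stopifnot(alpha_bounds[1] >= 0, alpha_bounds[2] <= 1,
            beta_bounds[1] > 0, beta_bounds[2] >= beta_bounds[1])
  keep <- !is.na(records$choice) & records$choice != "none"
  if (!any(keep)) stop("all trials missed; nothing to fit", call. = FALSE)

  obj <- function(par) {
    negative_log_likelihood(records, schedule, par[1], par[2])
  }
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, 2)
  starts[, 1] <- alpha_bounds[1] + starts[, 1] * diff(alpha_bounds)
  starts[, 2] <- beta_bounds[1] + starts[, 2] * diff(beta_bounds)
  starts <- rbind(starts, c(mean(alpha_bounds), 0.3))

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = c(alpha_bounds[1], beta_bounds[1]),
                   upper = c(alpha_bounds[2], beta_bounds[2])),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    better <- is.null(best) ||
      res$value < best$value - 1e-9 ||
      (abs(res$value - best$value) <= 1e-9 && res$par[2] < best$par[2])
    if (better) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  tol <- 1e-6
  at_bound <- best$par[1] <= alpha_bounds[1] + tol ||
    best$par[1] >= alpha_bounds[2] - tol ||
    best$par[2] <= beta_bounds[1] + tol ||
    best$par[2] >= beta_bounds[2] - tol

  structure(list(
    alpha_hat = unname(best$par[1]),
    beta_hat = unname(best$par[2]),
    nll = best$value,
    converged = any_conv,
    at_boundary = at_bound,
    n_trials_used = sum(keep),
    n_starts = n_starts,
    seed = seed
  ), class = "rl_fit")
}

#' @method print rl_fit
#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf(
    "Q-learning ML fit: alpha = %.3f, beta = %.3f, nll = %.2f (%d trials%s)\n",
    x$alpha_hat, x$beta_hat, x$nll, x$n_trials_used,
    if (x$at_boundary) ", at boundary" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy rl_fit
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha_hat, x$beta_hat))
}

#' @method glance rl_fit
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, converged = x$converged,
                 at_boundary = x$at_boundary,
                 n_trials_used = x$n_trials_used, n_starts = x$n_starts)
}

#' Group parameters as the median of individual fits
#'
#' Component-wise median of the fitted learning rates and temperatures.
#' These pooled parameters drive the trial-wise RPE regressor used in the
#' imaging model, so every subject's modulator comes from the same model.
#'
#' @param fits A list of `rl_fit` objects, or a tibble with columns
#'   `alpha_hat` and `beta_hat`.
#' @return A tibble with one row: `alpha`, `beta`.
#' @export
group_median_params <- function(fits) {
  if (is.data.frame(fits)) {
    ah <- fits$alpha_hat; bh <- fits$beta_hat
  } else {
    if (length(fits) == 0) stop("need at least one fit", call. = FALSE)
    ah <- vapply(fits, `[[`, numeric(1), "alpha_hat")
    bh <- vapply(fits, `[[`, numeric(1), "beta_hat")
  }
  if (length(ah) == 0) stop("need at least one fit", call. = FALSE)
  tibble::tibble(alpha = stats::median(ah), beta = stats::median(bh))
}

#' Model fit as RMSE between actual and predicted choices
#'
#' With the chosen option coded 1, the model's prediction for the made
#' choice is its probability, so the per-trial error is `1 - p_choice(t)`;
#' the RMSE is the root mean square of these errors over non-missed trials.
#' 0 means perfect prediction; 0.5 is the chance model.
#'
#' @param trace A trace tibble (from [trace_from_choices()] or the trace
#'   columns of [simulate_agent()]) with a `p_choice` column.
#' @return RMSE in \[0, 1\].
#' @export
model_fit_rmse <- function(trace) {
  p <- trace$p_choice
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no non-missed trials in trace", call. = FALSE)
  sqrt(mean((1 - p)^2))
}

#' Parameter-recoverability experiment
#'
#' Simulates `n_agents` agents with known parameters, fits each by maximum
#' likelihood, and summarizes how well the truth is recovered: per-parameter
#' Pearson correlation between true and estimated values, mean bias
#' (estimate minus truth) and RMSE. When the true values of a parameter are
#' constant across agents its correlation is undefined and reported `NA`.
#'
#' @param n_agents Number of simulated agents (>= 2).
#' @param param_sampler Function `(n)` returning a tibble/data.frame with
#'   columns `alpha`, `beta` of true parameters; the default draws
#'   `alpha ~ U(0.1, 0.9)`, `beta ~ U(0.1, 0.6)`.
#' @param seed Integer seed for schedules, choices and fits.
#' @param n_starts Optimizer starts per fit.
#' @return An object of class `rl_recovery`: the per-agent tibble
#'   (`agent`, `alpha_true`, `beta_true`, `alpha_hat`, `beta_hat`, `nll`)
#'   with the summary in `attr(, "summary")`; [generics::glance()] returns
#'   the summary.
#' @export
recoverability_experiment <- function(n_agents,
                                      param_sampler = NULL,
                                      seed = 1L, n_starts = 10L) {
  if (n_agents < 2) stop("need at least 2 agents", call. = FALSE)
  if (is.null(param_sampler)) {
    param_sampler <- function(n) {
      tibble::tibble(alpha = stats::runif(n, 0.1, 0.9),
                     beta = stats::runif(n, 0.1, 0.6))
    }
  }
  set.seed(seed)
  truth <- param_sampler(n_agents)
  sub_seeds <- sample.int(.Machine$integer.max, 3L * n_agents)

  rows <- purrr::map(seq_len(n_agents), function(i) {
    sched <- generate_schedule(sub_seeds[3 * i - 2], n_practice = 0)
    rec <- simulate_agent(sched, truth$alpha[i], truth$beta[i],
                          seed = sub_seeds[3 * i - 1])
    fit <- fit_subject(rec, sched, seed = sub_seeds[3 * i],
                       n_starts = n_starts)
    tibble::tibble(agent = i,
                   alpha_true = truth$alpha[i], beta_true = truth$beta[i],
                   alpha_hat = fit$alpha_hat, beta_hat = fit$beta_hat,
                   nll = fit$nll)
  })
  tab <- dplyr::bind_rows(rows)

  summarize_param <- function(true, est, name) {
    r <- if (stats::sd(true) < 1e-12) NA_real_ else stats::cor(true, est)
    tibble::tibble(parameter = name, correlation = r,
                   bias = mean(est - true),
                   rmse = sqrt(mean((est - true)^2)))
  }
  smry <- dplyr::bind_rows(
    summarize_param(tab$alpha_true, tab$alpha_hat, "alpha"),
    summarize_param(tab$beta_true, tab$beta_hat, "beta"))
  attr(tab, "summary") <- smry
  class(tab) <- c("rl_recovery", class(tab))
  tab
}

#' @method glance rl_recovery
#' @export
glance.rl_recovery <- function(x, ...) attr(x, "summary")

#' Compare a parameter between two groups
#'
#' Returns both the two-group Kruskal–Wallis test (robust to the typically
#' non-normal parameter distributions) and the Welch t test on the same
#' values.
#'
#' @param values_group1,values_group2 Numeric vectors (>= 2 values each).
#' @return A one-row tibble: `kruskal_wallis_H`, `kw_p`, `t_stat`, `t_p`,
#'   `n1`, `n2`.
#' @export
compare_groups <- function(values_group1, values_group2) {
  if (length(values_group1) < 2 || length(values_group2) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  kw <- stats::kruskal.test(list(values_group1, values_group2))
  tt <- stats::t.test(values_group1, values_group2)
  tibble::tibble(
    kruskal_wallis_H = unname(kw$statistic), kw_p = kw$p.value,
    t_stat = unname(tt$statistic), t_p = tt$p.value,
    n1 = length(values_group1), n2 = length(values_group2))
}

#' Plot a recoverability experiment
#'
#' Scatter of estimated versus true values per parameter with the identity
#' line.
#'
#' @param object An `rl_recovery` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rl_recovery
#' @export
autoplot.rl_recovery <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("alpha_true", "beta_true", "alpha_hat", "beta_hat"),
    names_to = c("parameter", ".value"), names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "true value", y = "estimate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
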