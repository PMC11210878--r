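# Euler-Maruyama simulation of therapy courses and ensemble statistics.

as_policy_spec <- function(policy, model) {
  if (is.null(policy)) return(NULL)
  if (inherits(policy, "constant_policy")) {
    check_dose(model, policy$dose)
    list(type = 0L, dose = policy$dose)
  } else if (inherits(policy, "value_field")) {
    list(type = 1L, field = policy$policy)
  } else if (is.matrix(policy) && is.integer(policy)) {
    list(type = 1L, field = policy)
  } else if (inherits(policy, "value_cube")) {
    if (!policy$has_policy) abort("this value_cube has no stored policy")
    list(type = 2L, cube = policy$policy, s_levels = policy$s_levels)
  } else {
    abort("unsupported policy object")
  }
}

policy_label <- function(policy) {
  if (inherits(policy, "constant_policy")) sprintf("constant d=%g", policy$dose)
  else if (inherits(policy, "value_field")) "deterministic-optimal d*"
  else if (inherits(policy, "value_cube"))
    sprintf("threshold-aware (S_bar=%g)", policy$s_bar)
  else "policy"
}

#' Simulate an ensemble of stochastic therapy courses
#'
#' Euler-Maruyama integration of the controlled SDE under a feedback policy,
#' with budget tracking (`ds/dt = -K(x, d)`), barrier detection refined by
#' linear interpolation within the step, and fallback dosing once the budget
#' is depleted. Paths are seeded with counter-based per-path sub-seeds derived
#' from `seed`, so any ensemble replays deterministically (and any single path
#' can be reproduced independently of the others).
#'
#' While the remaining budget `s` is positive the dose comes from `policy`
#' (evaluated at the current `(q, p)` and, for threshold-aware cubes, the
#' current `s`); once `s` hits zero the therapy continues under `fallback`
#' (conventionally the deterministic-optimal policy). The realized cost `J`
#' keeps accumulating either way, so only the distribution of costs beyond
#' `s_bar` depends on the fallback choice.
#'
#' @param model a [controlled_diffusion()] model or parameter set.
#' @param policy a [constant_policy()], a `value_field` (its bang-bang policy)
#'   or a `value_cube` (budget-dependent policy).
#' @param x0 initial state `c(q, p)`.
#' @param s_bar initial cost budget (`Inf` for unconstrained simulation,
#'   appropriate for constant and deterministic-optimal policies).
#' @param dt Euler-Maruyama time step.
#' @param n number of independent paths.
#' @param seed master seed (integer).
#' @param t_max censoring time: paths still interior at `t_max` get outcome
#'   `censored`.
#' @param fallback policy used after budget depletion; required when `policy`
#'   is a `value_cube` and `s_bar` is finite.
#' @return A tibble of class `tx_ensemble` with one row per path: `path`,
#'   `outcome` (`success_within_budget`, `success_over_budget`,
#'   `failure_death`, `censored`), `cost`, `time`, `t_sharp` (budget depletion
#'   time, `NA` if never depleted) and `n_clamp`. Attributes record the
#'   policy description, `x0`, `s_bar`, `dt`, `seed` and `n`.
#' @seealso [simulate_path()], [summarize_ensemble()], [compare_policies()]
#' @export
run_ensemble <- function(model, policy, x0, s_bar = Inf, dt = 1e-3,
                         n = 10000, seed = 1L, t_max = 200, fallback = NULL) {
  model <- as_ctrl_model(model)
  x0 <- as_state(x0)
  check_state(x0[1], x0[2])
  stopifnot(dt > 0, n >= 1, s_bar > 0)
  prim <- as_policy_spec(policy, model)
  if (is.null(fallback)) {
    if (prim$type == 2L && is.finite(s_bar))
      abort(paste("a budget-dependent policy needs a `fallback` policy for",
                  "the post-depletion phase (conventionally the",
                  "deterministic-optimal value_field)"))
    fallback <- policy
  }
  fb <- as_policy_spec(fallback, model)
  res <- simulate_ensemble_cpp(model$tag, model$cpp_par, prim, fb,
                               x0[1], x0[2], s_bar, dt, as.integer(n),
                               as.integer(seed), t_max, FALSE, 1L, 0L)
  out <- tibble(
    path = seq_len(n),
    outcome = classify_outcome(res$outcome, res$J, s_bar),
    cost = res$J, time = res$T, t_sharp = res$t_sharp, n_clamp = res$n_clamp)
  structure(out,
            policy = policy_label(policy), x0 = x0, s_bar = s_bar,
            dt = dt, seed = seed, n = n, model_label = model$label,
            class = c("tx_ensemble", class(out)))
}

classify_outcome <- function(code, J, s_bar) {
  out <- character(length(code))
  out[code == 1 & J <= s_bar] <- "success_within_budget"
  out[code == 1 & J > s_bar] <- "success_over_budget"
  out[code == 2] <- "failure_death"
  out[code == 0] <- "censored"
  factor(out, levels = c("success_within_budget", "success_over_budget",
                         "failure_death", "censored"))
}

#' Simulate a single therapy course and keep its trajectory
#'
#' A one-path version of [run_ensemble()] that records the sampled trajectory.
#' With `seed` fixed it reproduces the corresponding path of any ensemble run
#' with the same master seed.
#'
#' @inheritParams run_ensemble
#' @param path_index which counter-based sub-seed to use (path `path_index`
#'   of the ensemble with master seed `seed`).
#' @param store_every store every `store_every`-th step of the trajectory.
#' @return A tibble of class `tx_path` with columns `time`, `q`, `p`, `dose`
#'   and attributes `outcome`, `cost`, `T`, `t_sharp`.
#' @export
simulate_path <- function(model, policy, x0, s_bar = Inf, dt = 1e-3,
                          seed = 1L, t_max = 200, fallback = NULL,
                          path_index = 1L, store_every = 10L) {
  model <- as_ctrl_model(model)
  x0 <- as_state(x0)
  check_state(x0[1], x0[2])
  stopifnot(dt > 0, s_bar > 0)
  prim <- as_policy_spec(policy, model)
  if (is.null(fallback)) {
    if (prim$type == 2L && is.finite(s_bar))
      abort("a budget-dependent policy needs a `fallback` policy")
    fallback <- policy
  }
  fb <- as_policy_spec(fallback, model)
  # counter-based sub-seeds make path k independent of the ensemble size, so
  # replaying path k is a one-path run with the counter offset to k - 1
  res <- simulate_ensemble_cpp(model$tag, model$cpp_par, prim, fb,
                               x0[1], x0[2], s_bar, dt, 1L,
                               as.integer(seed), t_max, TRUE,
                               as.integer(store_every),
                               as.integer(path_index) - 1L)
  tr <- res$path
  out <- tibble(time = tr$time, q = tr$q, p = tr$p, dose = tr$dose)
  structure(out,
            outcome = as.character(classify_outcome(res$outcome[1], res$J[1], s_bar)),
            cost = res$J[1], T = res$T[1], t_sharp = res$t_sharp[1],
            s_bar = s_bar, policy = policy_label(policy),
            class = c("tx_path", class(out)))
}

#' @export
print.tx_path <- function(x, ...) {
  cat(sprintf("<therapy course: %s | cost %.4g | T %.4g>\n",
              attr(x, "outcome"), attr(x, "cost"), attr(x, "T")))
  NextMethod()
}

#' Summary statistics of a simulated ensemble
#'
#' Success and failure fractions, the empirical `P(J <= s)` at requested
#' thresholds with binomial standard errors, the median realized cost (failed
#' and censored courses count as infinite cost), and the mean cost conditioned
#' on eventual success. If no course succeeds the conditional mean is `NA`.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param thresholds cost thresholds at which to evaluate the CDF (optional).
#' @return A one-row tibble; when `thresholds` are given, a list-column
#'   `cdf` holds a tibble with columns `s`, `p_hat`, `se`.
#' @export
summarize_ensemble <- function(ensemble, thresholds = NULL) {
  stopifnot(inherits(ensemble, "tx_ensemble"), nrow(ensemble) >= 1)
  n <- nrow(ensemble)
  succ <- ensemble$outcome %in% c("success_within_budget", "success_over_budget")
  Jeff <- ifelse(succ, ensemble$cost, Inf)
  out <- tibble(
    n = n,
    success_frac = mean(succ),
    failure_frac = mean(ensemble$outcome == "failure_death"),
    censored_frac = mean(ensemble$outcome == "censored"),
    median_cost = median(Jeff),
    median_cost_success = if (any(succ)) median(ensemble$cost[succ]) else NA_real_,
    mean_cost_success = if (any(succ)) mean(ensemble$cost[succ]) else NA_real_)
  if (!is.null(thresholds)) {
    out$cdf <- list(cdf_estimate(ensemble, thresholds))
  }
  out
}

#' @export
glance.tx_ensemble <- function(x, ...) summarize_ensemble(x)

#' Empirical cost CDF of an ensemble
#'
#' Evaluates `P(J <= s)` at the requested thresholds, counting failed and
#' censored courses as infinite cost (so the CDF is the probability of
#' success within cost `s`, and its limit is the overall success fraction).
#' The standard error is the binomial `sqrt(p(1-p)/n)`.
#'
#' @inheritParams summarize_ensemble
#' @param s thresholds at which to evaluate.
#' @return A tibble with columns `s`, `p_hat`, `se`.
#' @export
cdf_estimate <- function(ensemble, s) {
  stopifnot(inherits(ensemble, "tx_ensemble"))
  succ <- ensemble$outcome %in% c("success_within_budget", "success_over_budget")
  Jeff <- ifelse(succ, ensemble$cost, Inf)
  n <- length(Jeff)
  p_hat <- vapply(s, function(si) mean(Jeff <= si), numeric(1))
  tibble(s = s, p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / n))
}

#' Compare cost CDFs of several policies from a common start
#'
#' Runs one ensemble per policy from the same initial state and aligns their
#' empirical cost CDFs on a common threshold axis. For each threshold-aware
#' (budget-dependent) policy, the threshold-specific advantage at its own
#' budget is reported: the difference between its success-within-budget
#' probability and the best of the other policies at that same threshold,
#' with the standard error of the difference.
#'
#' @param model a model or parameter set.
#' @param x0 initial state `c(q, p)`.
#' @param policies a named list; each element is either a policy object or a
#'   list with elements `policy`, optional `s_bar`, optional `fallback`.
#' @param s_grid thresholds for the CDF table (default: a grid spanning the
#'   observed finite costs).
#' @param dt,n,seed,t_max as in [run_ensemble()].
#' @return A tibble of class `tx_policy_comparison` with columns `policy`,
#'   `s`, `p_hat`, `se`; the `advantage` attribute holds the per-policy
#'   advantage checks, and `ensembles` the underlying ensembles.
#' @export
compare_policies <- function(model, x0, policies, s_grid = NULL, dt = 1e-3,
                             n = 10000, seed = 1L, t_max = 200) {
  model <- as_ctrl_model(model)
  stopifnot(length(policies) >= 1, !is.null(names(policies)))
  norm <- purrr::map(policies, function(pl) {
    if (inherits(pl, c("constant_policy", "value_field", "value_cube")))
      pl <- list(policy = pl)
    pl$s_bar <- pl$s_bar %||% Inf
    pl
  })
  ensembles <- purrr::imap(norm, function(pl, nm) {
    run_ensemble(model, pl$policy, x0, s_bar = pl$s_bar, dt = dt, n = n,
                 seed = seed, t_max = t_max, fallback = pl$fallback)
  })
  if (is.null(s_grid)) {
    finite_costs <- unlist(purrr::map(ensembles, function(e) {
      succ <- e$outcome %in% c("success_within_budget", "success_over_budget")
      e$cost[succ]
    }))
    s_grid <- seq(min(finite_costs), max(finite_costs), length.out = 201)
  }
  tab <- purrr::imap_dfr(ensembles, function(e, nm) {
    dplyr::mutate(cdf_estimate(e, s_grid), policy = nm, .before = 1)
  })
  adv <- purrr::imap_dfr(norm, function(pl, nm) {
    if (!is.finite(pl$s_bar)) return(NULL)
    own <- cdf_estimate(ensembles[[nm]], pl$s_bar)
    others <- purrr::imap_dfr(ensembles[setdiff(names(ensembles), nm)],
                              function(e, onm) {
                                dplyr::mutate(cdf_estimate(e, pl$s_bar),
                                              policy = onm)
                              })
    best <- others[which.max(others$p_hat), ]
    tibble(policy = nm, s_bar = pl$s_bar, p_self = own$p_hat,
           best_other = best$policy, p_other = best$p_hat,
           advantage = own$p_hat - best$p_hat,
           se_diff = sqrt(own$se^2 + best$se^2))
  })
  structure(tab, advantage = adv, ensembles = ensembles,
            class = c("tx_policy_comparison", class(tab)))
}

#' @export
print.tx_policy_comparison <- function(x, ...) {
  adv <- attr(x, "advantage")
  NextMethod()
  if (!is.null(adv) && nrow(adv)) {
    cat("\nThreshold-specific advantage at each policy's own budget:\n")
    print(as_tibble(adv))
  }
  invisible(x)
}

#' @rdname run_ensemble
#' @param x a `tx_ensemble`.
#' @param ... unused.
#' @export
tidy.tx_ensemble <- function(x, ...) as_tibble(x)

#' @rdname run_ensemble
#' @param object a `tx_ensemble`.
#' @export
autoplot.tx_ensemble <- function(object, ...) {
  succ <- object$outcome %in% c("success_within_budget", "success_over_budget")
  costs <- sort(object$cost[succ])
  df <- tibble(cost = costs, p = seq_along(costs) / nrow(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$cost, .data$p)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cost threshold s", y = "P(J <= s)",
                  title = sprintf("Cost CDF | %s", attr(object, "policy")))
}

#' @rdname compare_policies
#' @param object a `tx_policy_comparison`.
#' @export
autoplot.tx_policy_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s, .data$p_hat,
                                       colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cost threshold s", y = "P(J <= s)",
                  title = "Policy cost CDFs")
}
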