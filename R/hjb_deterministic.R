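#' Solve the deterministic optimal-therapy HJB equation
#'
#' Solves the stationary first-order Hamilton-Jacobi-Bellman equation
#' `min_d { K(x, d) + grad(u) . f(x, d) } = 0` for the minimal cumulative
#' treatment cost `u(q, p)` of driving the tumor to the success barrier, with
#' `u = 0` on the stabilization row `p = gamma_r` and `u = u_max` (a large
#' finite stand-in for the infinite cost of failure) on the failure row
#' `p = gamma_f`. The scheme is semi-Lagrangian value iteration: each node is
#' relaxed to `min_d { tau K(d) + u(x + tau f(x, d)) }` with local step
#' `tau = h / |f|` and bilinear interpolation, swept Gauss-Seidel style in
#' four alternating orderings until the sup-norm residual drops below `tol`.
#' Because the dynamics and running cost are affine in the dose, only the
#' extreme doses `{0, d_max}` need to be compared (the policy is bang-bang);
#' ties are broken toward no drugs.
#'
#' @param model a [controlled_diffusion()] model or parameter set. Volatilities
#'   are ignored (the deterministic vector field is used).
#' @param nq,np numbers of grid nodes in `q` (on `[0, 1]`) and `p` (on
#'   `[gamma_r, gamma_f]`, barrier rows included).
#' @param u_max value assigned to the failure row and cap for unreachable
#'   nodes. Default `10 * (d_max + delta) * crossing_time_scale`.
#' @param crossing_time_scale time scale used in the default `u_max`.
#' @param tol sup-norm residual tolerance for the value iteration.
#' @param max_sweeps maximum number of sweep sets (each set is four full
#'   Gauss-Seidel passes in alternating orderings).
#' @return An object of class `value_field`: a list with the value matrix `u`
#'   (`nq x np`), the binary `policy` matrix (1 = treat at `d_max`), the grid
#'   axes `q`, `p`, convergence diagnostics, and the model. Non-convergence
#'   raises a warning carrying the residual history.
#' @seealso [integrate_optimal_trajectory()], [solve_threshold_hjb()]
#' @export
solve_deterministic_hjb <- function(model, nq = 161, np = 161, u_max = NULL,
                                    crossing_time_scale = 5, tol = 1e-6,
                                    max_sweeps = 2000) {
  model <- as_ctrl_model(model)
  stopifnot(nq >= 3, np >= 3)
  pars <- model$params
  if (is.null(u_max))
    u_max <- 10 * (pars$d_max + pars$delta) * crossing_time_scale
  res <- solve_det_hjb_cpp(model$tag, model$cpp_par, as.integer(nq),
                           as.integer(np), u_max, tol, as.integer(max_sweeps))
  if (!res$converged)
    warn(sprintf(
      "deterministic HJB did not reach tol = %g in %d sweep sets (residual %.3g)",
      tol, max_sweeps, res$residual),
      residual_history = res$residual_history)
  structure(
    list(u = res$u, policy = res$policy,
         q = seq(0, 1, length.out = nq),
         p = seq(pars$gamma_r, pars$gamma_f, length.out = np),
         u_max = u_max, tol = tol, sweeps = res$sweeps,
         residual = res$residual, residual_history = res$residual_history,
         converged = res$converged, model = model),
    class = "value_field")
}

#' @export
print.value_field <- function(x, ...) {
  cat(sprintf("<value_field %dx%d | residual %.2g after %d sweep sets | u_max %g>\n",
              length(x$q), length(x$p), x$residual, x$sweeps, x$u_max))
  invisible(x)
}

#' Interpolate a deterministic value field
#'
#' Bilinear interpolation of `u` at arbitrary states.
#'
#' @param field a [solve_deterministic_hjb()] result.
#' @param q,p state coordinates (recycled to a common length).
#' @return Numeric vector of interpolated values.
#' @export
value_at <- function(field, q, p) {
  stopifnot(inherits(field, "value_field"))
  n <- max(length(q), length(p))
  q <- rep_len(q, n); p <- rep_len(p, n)
  interp_bilinear(field$u, field$q, field$p, q, p)
}

interp_bilinear <- function(mat, qs, ps, q, p) {
  hq <- qs[2] - qs[1]; hp <- ps[2] - ps[1]
  x <- (q - qs[1]) / hq; y <- (p - ps[1]) / hp
  i <- pmin(pmax(floor(x), 0), length(qs) - 2)
  j <- pmin(pmax(floor(y), 0), length(ps) - 2)
  tx <- pmin(pmax(x - i, 0), 1); ty <- pmin(pmax(y - j, 0), 1)
  i <- i + 1L; j <- j + 1L  # 1-based
  (1 - tx) * (1 - ty) * mat[cbind(i, j)] + tx * (1 - ty) * mat[cbind(i + 1L, j)] +
    (1 - tx) * ty * mat[cbind(i, j + 1L)] + tx * ty * mat[cbind(i + 1L, j + 1L)]
}

#' Constant-dose feedback policy
#'
#' The trivial feedback policy returning the same dose everywhere; used for
#' the MTD (`dose = d_max`) and no-drug (`dose = 0`) baselines.
#'
#' @param dose constant dose rate.
#' @param model a model or parameter set (used to validate the dose bounds).
#' @return An object of class `constant_policy`.
#' @export
constant_policy <- function(dose, model) {
  model <- as_ctrl_model(model)
  check_dose(model, dose)
  structure(list(dose = dose, model = model), class = "constant_policy")
}

#' @export
print.constant_policy <- function(x, ...) {
  cat("<constant policy: d =", x$dose, ">\n")
  invisible(x)
}

#' Integrate a closed-loop deterministic therapy trajectory
#'
#' Explicit time stepping of the noise-free dynamics `dx/dt = f(x, d)` with
#' the dose looked up from the feedback policy at every step (nearest grid
#' node for grid policies, preserving the bang-bang structure). Stops at the
#' first barrier crossing, refining the crossing time by linear interpolation
#' within the step, or at `t_max`. The realized cost is the integral of
#' `K = d + delta` along the path.
#'
#' @param model a model or parameter set.
#' @param policy a `value_field` (its bang-bang policy is used) or a
#'   [constant_policy()].
#' @param x0 initial state, a length-2 numeric `c(q, p)` (or a list/data frame
#'   with elements `q`, `p`).
#' @param dt time step.
#' @param t_max maximum integration time; reaching it labels the trajectory
#'   `max-time`.
#' @param store_every store every `store_every`-th step in the returned path.
#' @return A tibble of class `tx_trajectory` with columns `time`, `q`, `p`,
#'   `dose` and attributes `cost`, `T`, `outcome`
#'   (`success` / `failure` / `max-time`).
#' @export
integrate_optimal_trajectory <- function(model, policy, x0, dt = 1e-3,
                                         t_max = 200, store_every = 10L) {
  model <- as_ctrl_model(model)
  x0 <- as_state(x0)
  check_state(x0[1], x0[2])
  stopifnot(dt > 0)
  if (inherits(policy, "constant_policy")) {
    ptype <- 0L; cdose <- policy$dose
    pol <- matrix(0L, 2, 2)
  } else if (inherits(policy, "value_field")) {
    ptype <- 1L; cdose <- 0
    pol <- policy$policy
  } else {
    abort("`policy` must be a value_field or a constant_policy")
  }
  res <- integrate_trajectory_cpp(model$tag, model$cpp_par, x0[1], x0[2],
                                  ptype, cdose, pol, dt, t_max,
                                  as.integer(store_every))
  out <- tibble(time = res$time, q = res$q, p = res$p, dose = res$dose)
  structure(out,
            cost = res$cost, T = res$T,
            outcome = c("max-time", "success", "failure")[res$outcome + 1L],
            class = c("tx_trajectory", class(out)))
}

#' @export
print.tx_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s | cost %.4g | T %.4g | %d stored points>\n",
              attr(x, "outcome"), attr(x, "cost"), attr(x, "T"), nrow(x)))
  NextMethod()
}

#' @rdname solve_deterministic_hjb
#' @param x a `value_field` object.
#' @param ... unused.
#' @export
tidy.value_field <- function(x, ...) {
  tidyr::expand_grid(p = x$p, q = x$q) |>
    dplyr::mutate(u = as.vector(x$u),
                  dose = as.vector(x$policy) * x$model$params$d_max) |>
    dplyr::select("q", "p", "u", "dose")
}

#' @rdname solve_deterministic_hjb
#' @export
glance.value_field <- function(x, ...) {
  tibble(nq = length(x$q), np = length(x$p), u_max = x$u_max,
         residual = x$residual, sweeps = x$sweeps, converged = x$converged)
}

#' @rdname solve_deterministic_hjb
#' @param object a `value_field` object.
#' @param what `"value"` for the cost-to-go heatmap, `"policy"` for the
#'   bang-bang dose map.
#' @export
autoplot.value_field <- function(object, what = c("value", "policy"), ...) {
  what <- match.arg(what)
  df <- tidy(object)
  if (what == "value") {
    df$u[df$u >= object$u_max] <- NA_real_
    ggplot2::ggplot(df, ggplot2::aes(.data$q, .data$p, fill = .data$u)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "grey20") +
      ggplot2::labs(fill = "u(q, p)", title = "Deterministic cost-to-go")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$q, .data$p,
                                     fill = factor(.data$dose))) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_manual(values = c("#2166ac", "#fddb27")) +
      ggplot2::labs(fill = "dose", title = "Deterministic-optimal policy")
  }
}

as_state <- function(x0) {
  if (is.list(x0) || is.data.frame(x0)) x0 <- c(x0$q, x0$p)
  x0 <- as.numeric(x0)
  if (length(x0) != 2) abort("`x0` must be a state c(q, p)")
  x0
}
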