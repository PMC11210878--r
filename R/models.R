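#' Controlled drift-diffusion interface for a tumor model
#'
#' Wraps a parameter set into the single model interface consumed by the HJB
#' solvers and the Monte-Carlo simulator: the deterministic vector field
#' `f(x, d)`, the SDE drift `a(x, d)` (including Ito corrections for the
#' reduced coordinates), the diffusion matrix `Sigma(x, d)` whose entries all
#' carry a `q(1-q)` or `p(1-p)` factor (the state cannot diffuse out of the
#' unit square), the running cost `K(x, d) = d + delta`, the terminal-region
#' classifier, and the dose bounds `[0, d_max]`.
#'
#' @param params an [egt_params()], [sr_params()] or [toy_params()] object.
#' @return An object of class `ctrl_model`.
#' @examples
#' mod <- controlled_diffusion(egt_params())
#' deterministic_rate(mod, q = 0.26, p = 0.665, dose = 0)
#' @export
controlled_diffusion <- function(params) {
  stopifnot(inherits(params, "tumor_params"))
  cp <- cpp_model(params)
  structure(
    list(params = params, tag = cp$tag, cpp_par = cp$par,
         n_brownian = cp$n_brownian,
         dose_bounds = c(0, params$d_max),
         label = class(params)[1]),
    class = "ctrl_model")
}

#' @export
print.ctrl_model <- function(x, ...) {
  cat("<controlled diffusion:", x$label, "|", x$n_brownian,
      "Brownian channel(s) | dose in [0,", x$dose_bounds[2], "]>\n")
  invisible(x)
}

as_ctrl_model <- function(x) {
  if (inherits(x, "ctrl_model")) x else controlled_diffusion(x)
}

check_dose <- function(model, dose) {
  if (any(!is.finite(dose)) || any(dose < 0) || any(dose > model$dose_bounds[2]))
    abort(sprintf("dose must lie in [0, %g]", model$dose_bounds[2]))
  invisible(dose)
}

check_state <- function(q, p) {
  if (any(!is.finite(q)) || any(!is.finite(p)))
    abort("tumor state (q, p) must be finite")
  if (any(q < 0 | q > 1 | p < 0 | p > 1))
    abort("tumor state (q, p) must lie in the unit square")
  invisible(NULL)
}

#' Deterministic growth rates of the controlled model
#'
#' Evaluates the noise-free vector field `f(x, d) = (dq/dt, dp/dt)` of the
#' model at one or more states and doses (inputs are recycled to a common
#' length).
#'
#' @param model a [controlled_diffusion()] object (or a parameter set, which
#'   is wrapped automatically).
#' @param q,p state coordinates in `[0, 1]`.
#' @param dose dose rate(s) in `[0, d_max]`.
#' @return A tibble with columns `q`, `p`, `dose`, `dq_dt`, `dp_dt`.
#' @export
deterministic_rate <- function(model, q, p, dose = 0) {
  model <- as_ctrl_model(model)
  n <- max(length(q), length(p), length(dose))
  q <- rep_len(q, n); p <- rep_len(p, n); dose <- rep_len(dose, n)
  check_state(q, p); check_dose(model, dose)
  co <- model_coefficients_cpp(model$tag, model$cpp_par, q, p, dose)
  tibble(q = q, p = p, dose = dose, dq_dt = co$fq, dp_dt = co$fp)
}

#' SDE drift and diffusion of the controlled model
#'
#' Evaluates the drift `a(x, d)` (deterministic rate plus Ito corrections) and
#' the covariance entries of `B = Sigma Sigma^T` at one or more states. For a
#' single state, the full `2 x m` diffusion matrix is available through
#' [diffusion_matrix()].
#'
#' @inheritParams deterministic_rate
#' @return A tibble with columns `q`, `p`, `dose`, `drift_q`, `drift_p`,
#'   `B_qq`, `B_pp`, `B_qp`.
#' @export
sde_coefficients <- function(model, q, p, dose = 0) {
  model <- as_ctrl_model(model)
  n <- max(length(q), length(p), length(dose))
  q <- rep_len(q, n); p <- rep_len(p, n); dose <- rep_len(dose, n)
  check_state(q, p); check_dose(model, dose)
  co <- model_coefficients_cpp(model$tag, model$cpp_par, q, p, dose)
  tibble(q = q, p = p, dose = dose,
         drift_q = co$aq, drift_p = co$ap,
         B_qq = co$Bqq, B_pp = co$Bpp, B_qp = co$Bqp)
}

#' Diffusion matrix at a single state
#'
#' @inheritParams deterministic_rate
#' @return The `2 x m` matrix `Sigma(x, d)` with one column per Brownian
#'   channel; rows are named `q`, `p`.
#' @export
diffusion_matrix <- function(model, q, p, dose = 0) {
  model <- as_ctrl_model(model)
  stopifnot(length(q) == 1, length(p) == 1, length(dose) == 1)
  check_state(q, p); check_dose(model, dose)
  co <- model_coefficients_cpp(model$tag, model$cpp_par, q, p, dose)
  out <- rbind(q = co$sigma_q[1, ], p = co$sigma_p[1, ])
  colnames(out) <- paste0("W", seq_len(ncol(out)))
  out
}

#' Running cost of treatment
#'
#' The instantaneous cost rate `K(x, d) = d + delta`, combining drug usage and
#' the treatment-time penalty. It is affine in the dose and bounded in
#' `[delta, d_max + delta]`.
#'
#' @inheritParams deterministic_rate
#' @return Numeric vector of cost rates.
#' @export
running_cost <- function(model, dose) {
  model <- as_ctrl_model(model)
  check_dose(model, dose)
  dose + model$params$delta
}

#' Classify tumor states into terminal regions
#'
#' Success when `p < gamma_r` (stabilization/remission), failure when
#' `p > gamma_f` (the inequalities are strict: exact barrier hits are
#' interior), otherwise interior.
#'
#' @inheritParams deterministic_rate
#' @return A factor with levels `interior`, `success`, `failure`.
#' @export
classify_state <- function(model, q, p) {
  model <- as_ctrl_model(model)
  n <- max(length(q), length(p))
  q <- rep_len(q, n); p <- rep_len(p, n)
  gr <- model$params$gamma_r; gf <- model$params$gamma_f
  out <- rep("interior", n)
  out[p < gr] <- "success"
  out[p > gf] <- "failure"
  factor(out, levels = c("interior", "success", "failure"))
}

#' Coexistence (heterogeneous-regime) condition of the EGT model
#'
#' Checks the strict double inequality `b_a / (n + 1) < b_v - c < c * n`
#' under which all three cell types coexist and the drug-free replicator
#' dynamics cycle.
#'
#' @param params an [egt_params()] object.
#' @return `TRUE` or `FALSE`.
#' @export
heterogeneous_regime <- function(params) {
  stopifnot(inherits(params, "egt_params"))
  mid <- params$b_v - params$c
  (params$b_a / (params$n + 1) < mid) && (mid < params$c * params$n)
}

#' Reduce raw subpopulation sizes to the (q, p) state
#'
#' For the EGT model, `subpops` must have columns `z_G`, `z_D`, `z_V`
#' (subpopulation sizes); the reduced state is `p = z_G / (z_G + z_D + z_V)`
#' (GLY fraction) and `q = z_V / (z_V + z_D)` (VOP fraction among aerobic
#' cells). For the SR model, columns `z_S`, `z_R` (sizes pre-normalized by the
#' carrying capacity); the reduced state is `p = z_S + m * z_R` (effective
#' tumor size) and `q = z_S / p`. Degenerate denominators (no aerobic cells,
#' or an empty tumor) are an error.
#'
#' @param subpops a data frame of nonnegative subpopulation sizes.
#' @param model a [controlled_diffusion()] model or parameter set identifying
#'   which reduction applies.
#' @return A tibble with columns `q` and `p`.
#' @export
reduce_coordinates <- function(subpops, model) {
  model <- as_ctrl_model(model)
  subpops <- as_tibble(subpops)
  if (model$tag == 0L) {
    need <- c("z_G", "z_D", "z_V")
    if (!all(need %in% names(subpops)))
      abort("EGT reduction needs columns z_G, z_D, z_V")
    zg <- subpops$z_G; zd <- subpops$z_D; zv <- subpops$z_V
    if (any(zg < 0 | zd < 0 | zv < 0)) abort("subpopulation sizes must be nonnegative")
    tot <- zg + zd + zv
    aer <- zd + zv
    if (any(tot == 0)) abort("undefined-coordinate: all subpopulations are zero")
    if (any(aer == 0)) abort("undefined-coordinate: no aerobic cells (z_V + z_D = 0)")
    tibble(q = zv / aer, p = zg / tot)
  } else if (model$tag == 1L) {
    need <- c("z_S", "z_R")
    if (!all(need %in% names(subpops)))
      abort("SR reduction needs columns z_S, z_R")
    zs <- subpops$z_S; zr <- subpops$z_R
    if (any(zs < 0 | zr < 0)) abort("subpopulation sizes must be nonnegative")
    p <- zs + model$params$m * zr
    if (any(p == 0)) abort("undefined-coordinate: empty tumor (p = 0)")
    tibble(q = zs / p, p = p)
  } else {
    abort("no coordinate reduction is defined for the test model")
  }
}

#' Sensitive fraction by cell number
#'
#' Converts the sensitive fraction of effective tumor size `q` into the
#' proportion of sensitive cells by number, `m q / (1 + (m - 1) q)`, which
#' round-trips with [reduce_coordinates()] for the SR model.
#'
#' @param q sensitive fraction(s) of effective tumor size.
#' @param m size ratio between resistant and sensitive cells.
#' @return Numeric vector of number fractions.
#' @export
sensitive_number_fraction <- function(q, m) {
  m * q / (1 + (m - 1) * q)
}
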