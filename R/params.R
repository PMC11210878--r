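#' Parameters of the evolutionary-game (GLY/DEF/VOP) competition model
#'
#' Constructs the parameter set of the replicator-dynamics model of a
#' heterogeneous tumor with three interacting phenotypes: glycolytic (GLY)
#' cells whose acid production benefits all cancer cells, VEGF-overproducing
#' (VOP) aerobic cells that pay a cost to recruit vasculature, and defector
#' (DEF) aerobic cells that free-ride on both public goods. The reduced state
#' is `(q, p)` with `p` the GLY fraction of the tumor and `q` the VOP fraction
#' among aerobic cells. Therapy targets GLY fitness at a dose rate
#' `d in [0, d_max]`; the running cost of treatment is `d + delta` per unit
#' time.
#'
#' Defaults are the values used throughout the worked examples: `b_a = 2.5`,
#' `b_v = 2`, `c = 1`, `n = 4`, `d_max = 3`, `delta = 0.05`, uniform fitness
#' volatilities `0.15`, and barriers `gamma_r = 1 - gamma_f = 0.01`.
#'
#' @param b_a benefit per unit of acidification (GLY public good).
#' @param b_v benefit from oxygen per unit of vascularization (VOP club good).
#' @param c cost of VEGF production paid by VOP cells.
#' @param n interaction-group size minus one (each cell interacts with `n`
#'   neighbours); a positive integer.
#' @param d_max maximum tolerated dose rate (MTD).
#' @param delta treatment-time penalty per unit time; must be positive (it
#'   keeps the running cost bounded away from zero).
#' @param sigma_G,sigma_D,sigma_V fitness volatilities of the GLY, DEF and VOP
#'   subpopulations (scales of the independent Brownian perturbations).
#' @param gamma_r stabilization barrier: therapy succeeds once `p < gamma_r`.
#' @param gamma_f failure barrier: therapy fails once `p > gamma_f`.
#' @return An object of class `c("egt_params", "tumor_params")`.
#' @seealso [sr_params()], [controlled_diffusion()], [heterogeneous_regime()]
#' @examples
#' pars <- egt_params()
#' heterogeneous_regime(pars)
#' @export
egt_params <- function(b_a = 2.5, b_v = 2, c = 1, n = 4L, d_max = 3,
                       delta = 0.05, sigma_G = 0.15, sigma_D = 0.15,
                       sigma_V = 0.15, gamma_r = 0.01, gamma_f = 0.99) {
  p <- list(b_a = b_a, b_v = b_v, c = c, n = as.integer(n), d_max = d_max,
            delta = delta, sigma_G = sigma_G, sigma_D = sigma_D,
            sigma_V = sigma_V, gamma_r = gamma_r, gamma_f = gamma_f)
  check_common_params(p)
  stopifnot("all EGT rates must be nonnegative" =
              all(unlist(p[c("b_a", "b_v", "c")]) >= 0),
            "n must be a positive integer" = p$n >= 1L,
            "volatilities must be nonnegative" =
              all(unlist(p[c("sigma_G", "sigma_D", "sigma_V")]) >= 0))
  structure(p, class = c("egt_params", "tumor_params"))
}

#' Parameters of the sensitive-resistant logistic competition model
#'
#' Constructs the parameter set of a two-type tumor of drug-sensitive (S) and
#' drug-resistant (R) cells sharing a carrying capacity, with resistant cells
#' `m` times larger than sensitive ones. The reduced state is `(q, p)` with
#' `p = z_S + m z_R` the effective tumor size relative to capacity and
#' `q = z_S / p` the sensitive fraction of that effective size. The drug kills
#' sensitive cells at rate `alpha * z_S * d`; sensitive cells suppress
#' resistant ones through the competition term `beta * C * z_S * z_R`. The
#' therapy goal is eradication: driving `p` below the remission barrier
#' `gamma_r` while it never exceeds the failure barrier `gamma_f`.
#'
#' Unlike [egt_params()], this constructor has no numeric defaults for the
#' biological coefficients: supply calibrated values, or use
#' [sr_params_synthetic()] for a synthetic illustration set.
#'
#' @param g_S,g_R intrinsic growth rates of sensitive and resistant cells
#'   (per unit time).
#' @param m size ratio between resistant and sensitive cells.
#' @param C carrying capacity (the subpopulation sizes are assumed
#'   pre-normalized by `C`; the competition coefficient enters as `beta * C`).
#' @param alpha drug efficiency (kill rate per unit dose).
#' @param beta competition coefficient of sensitive on resistant cells.
#' @param d_max,delta,gamma_r,gamma_f as in [egt_params()].
#' @param sigma_S,sigma_R volatilities of the two intrinsic growth rates,
#'   driven by a single shared Brownian motion.
#' @return An object of class `c("sr_params", "tumor_params")`.
#' @export
sr_params <- function(g_S, g_R, m, C, alpha, beta, d_max = 3, delta = 0.05,
                      sigma_S = 0.15, sigma_R = 0.15,
                      gamma_r = 0.01, gamma_f = 0.99) {
  p <- list(g_S = g_S, g_R = g_R, m = m, C = C, alpha = alpha, beta = beta,
            d_max = d_max, delta = delta, sigma_S = sigma_S, sigma_R = sigma_R,
            gamma_r = gamma_r, gamma_f = gamma_f)
  check_common_params(p)
  stopifnot("g_S, g_R, m, C, alpha, beta must all be positive" =
              all(unlist(p[c("g_S", "g_R", "m", "C", "alpha", "beta")]) > 0),
            "volatilities must be nonnegative" =
              p$sigma_S >= 0 && p$sigma_R >= 0)
  structure(p, class = c("sr_params", "tumor_params"))
}

#' Synthetic parameter set for the sensitive-resistant model
#'
#' A synthetic illustration set for [sr_params()], chosen to reproduce the
#' qualitative regime of the A549 / A549-Epo40 lung-cancer cell-line system:
#' similar intrinsic growth rates with the sensitive type slightly faster,
#' strong competitive suppression of resistant by sensitive cells, a drug that
#' kills only sensitive cells much faster than they grow, and a size ratio
#' `m = 30` (which makes a tumor that is 96% sensitive by cell number
#' correspond to a sensitive fraction of effective size `q = 0.45`). These
#' values are synthetic: they are not the published experimental calibration
#' (see [sr_params_reference()]), and no quantitative claim is attached to
#' them. Time units are hours.
#'
#' @param ... overrides passed on to [sr_params()].
#' @return An `sr_params` object.
#' @export
sr_params_synthetic <- function(...) {
  defaults <- list(g_S = 0.031, g_R = 0.026, m = 30, C = 1,
                   alpha = 0.06, beta = 2.75)
  args <- modifyList(defaults, list(...))
  do.call(sr_params, args)
}

#' Published calibration of the sensitive-resistant model (not bundled)
#'
#' The experimentally calibrated coefficients of the sensitive-resistant model
#' (growth rates, size ratio, carrying capacity, competition and
#' drug-efficiency coefficients for the A549 / A549-Epo40 system) are
#' not redistributed with this package, so this function always throws an
#' informative error. Supply
#' the calibrated values to [sr_params()] yourself, or use
#' [sr_params_synthetic()] for a synthetic set suitable for method
#' illustration.
#'
#' @return Never returns; always errors.
#' @export
sr_params_reference <- function() {
  abort(paste(
    "The experimental calibration of the sensitive-resistant model is not",
    "bundled with this package. Supply calibrated values via sr_params(),",
    "or use sr_params_synthetic() for a synthetic illustration set."))
}

#' Parameters of a one-dimensional test model
#'
#' A minimal controlled model used for closed-form verification: `q` is
#' frozen, `p` decays at exactly the dose rate (`dp/dt = -d`), and the
#' optional volatility `sigma` drives `p` through a single Brownian channel
#' with a `p(1-p)` no-escape factor. Under the always-on policy `d = d_max`
#' and `sigma = 0`, the minimal cost from `p` is
#' `(1 + delta / d_max) * (p - gamma_r)`.
#'
#' @param d_max,delta,gamma_r,gamma_f as in [egt_params()].
#' @param sigma volatility of the `p` coordinate.
#' @return An object of class `c("toy_params", "tumor_params")`.
#' @export
toy_params <- function(d_max = 3, delta = 0.05, gamma_r = 0.01,
                       gamma_f = 0.99, sigma = 0) {
  p <- list(d_max = d_max, delta = delta, gamma_r = gamma_r,
            gamma_f = gamma_f, sigma = sigma)
  check_common_params(p)
  structure(p, class = c("toy_params", "tumor_params"))
}

check_common_params <- function(p) {
  num <- unlist(p[setdiff(names(p), "n")])
  if (!all(is.finite(num))) abort("all model parameters must be finite")
  stopifnot("d_max must be positive" = p$d_max > 0,
            "delta must be positive" = p$delta > 0,
            "need 0 < gamma_r < gamma_f < 1" =
              p$gamma_r > 0 && p$gamma_r < p$gamma_f && p$gamma_f < 1)
  invisible(p)
}

#' @export
print.tumor_params <- function(x, ...) {
  kind <- switch(class(x)[1],
                 egt_params = "EGT (GLY/DEF/VOP) competition model",
                 sr_params = "sensitive-resistant competition model",
                 toy_params = "1-D test model")
  cat("<", kind, ">\n", sep = "")
  vals <- vapply(unclass(x), format, character(1))
  cat(paste0("  ", format(names(vals)), " = ", vals), sep = "\n")
  invisible(x)
}

# internal: C++ tag and packed parameter vector
cpp_model <- function(params) {
  if (inherits(params, "egt_params")) {
    list(tag = 0L,
         par = with(params, c(b_a, b_v, c, n, d_max, delta,
                              sigma_G, sigma_D, sigma_V, gamma_r, gamma_f)),
         n_brownian = 3L)
  } else if (inherits(params, "sr_params")) {
    list(tag = 1L,
         par = with(params, c(g_S, g_R, m, beta * C, alpha, d_max, delta,
                              sigma_S, sigma_R, gamma_r, gamma_f)),
         n_brownian = 1L)
  } else if (inherits(params, "toy_params")) {
    list(tag = 2L,
         par = with(params, c(d_max, delta, gamma_r, gamma_f, sigma)),
         n_brownian = 1L)
  } else {
    abort("`params` must be created by egt_params(), sr_params() or toy_params()")
  }
}
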