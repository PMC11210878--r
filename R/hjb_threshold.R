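#' Solve the threshold-aware HJB equation for success probabilities
#'
#' Computes the value cube `v(q, p, s)` — the maximal probability of reaching
#' the success barrier before the failure barrier with cumulative treatment
#' cost at most `s` — together with the budget-dependent bang-bang policy, for
#' every budget in `(0, s_bar]` simultaneously. Since the running cost
#' `K = d + delta` is strictly positive, the second-order HJB equation
#' `max_d { -v_s K + a . grad(v) + 1/2 tr(B D2 v) } = 0` can be rewritten as
#' `v_s = max_d [ a . grad(v) + 1/2 tr(B D2 v) ] / K(d)` and marched
#' explicitly upward in the remaining budget `s` from the boundary data
#' `v(., 0) = 0` off the success region, with `v = 1` on the stabilization row
#' and `v = 0` on the failure row enforced at every level. Spatial
#' discretization: first-order upwind differences for the drift (direction
#' chosen per node and dose), central differences for the second-order terms,
#' and the standard 7-point monotone-leaning stencil for the mixed
#' derivative. The budget step is chosen from the explicit-scheme stability
#' bound (`ds * max |center weight| <= cfl`); values are clipped to `[0, 1]`
#' after each level and the largest clip is reported.
#'
#' @param model a [controlled_diffusion()] model or parameter set (must have
#'   `delta > 0`, which guarantees parabolicity in `s`).
#' @param s_bar maximum budget, the top of the `s` axis.
#' @param nq,np spatial grid sizes as in [solve_deterministic_hjb()].
#' @param ds_store approximate spacing of the stored `s`-slices (the marching
#'   itself uses the much finer stability-bound step).
#' @param cfl stability (CFL) safety factor in `(0, 1]`.
#' @param ds optional explicit budget step; refused with the required bound if
#'   it violates stability.
#' @param store_policy store the bang-bang policy slices as well.
#' @return An object of class `value_cube`: the array `v` (`nq x np x
#'   n_slices`, each entry a probability), a raw `policy` array of the same
#'   shape (1 = treat), axes `q`, `p`, `s`, the marching step `ds`, the
#'   stability bound, and clip statistics.
#' @seealso [cube_value()], [policy_lookup()], [goal_probability_limit()]
#' @export
solve_threshold_hjb <- function(model, s_bar, nq = 161, np = 161,
                                ds_store = 0.01, cfl = 0.9, ds = NULL,
                                store_policy = TRUE) {
  model <- as_ctrl_model(model)
  stopifnot(s_bar > 0, nq >= 3, np >= 3, cfl > 0, cfl <= 1)
  if (model$params$delta <= 0)
    abort("the running cost must be positive everywhere (delta > 0)")
  res <- solve_threshold_cpp(model$tag, model$cpp_par, as.integer(nq),
                             as.integer(np), s_bar, ds_store, cfl,
                             store_policy, ds %||% -1)
  pars <- model$params
  structure(
    list(v = res$v, policy = res$policy, s_levels = res$s_levels,
         q = seq(0, 1, length.out = nq),
         p = seq(pars$gamma_r, pars$gamma_f, length.out = np),
         s = res$s_levels, ds = res$ds, n_levels = res$n_levels,
         cfl_bound = res$cfl_bound, max_clip = res$max_clip,
         s_bar = s_bar, model = model, has_policy = store_policy),
    class = "value_cube")
}

#' @export
print.value_cube <- function(x, ...) {
  cat(sprintf(
    "<value_cube %dx%dx%d | s_bar %g | marching ds %.3g (%g levels) | max clip %.2g>\n",
    length(x$q), length(x$p), length(x$s), x$s_bar, x$ds, x$n_levels, x$max_clip))
  invisible(x)
}

#' Interpolate the success-probability cube
#'
#' Bilinear interpolation in `(q, p)` and linear interpolation across stored
#' budget slices.
#'
#' @param cube a [solve_threshold_hjb()] result.
#' @param q,p,s coordinates (recycled to a common length); `s` is clamped to
#'   the stored range.
#' @return Numeric vector of probabilities.
#' @export
cube_value <- function(cube, q, p, s) {
  stopifnot(inherits(cube, "value_cube"))
  n <- max(length(q), length(p), length(s))
  q <- rep_len(q, n); p <- rep_len(p, n); s <- rep_len(s, n)
  sl <- cube$s_levels
  s <- pmin(pmax(s, sl[1]), sl[length(sl)])
  ds <- (sl[length(sl)] - sl[1]) / (length(sl) - 1)
  k <- pmin(pmax(floor((s - sl[1]) / ds), 0), length(sl) - 2)
  tk <- pmin(pmax((s - sl[1]) / ds - k, 0), 1)
  k <- k + 1L
  lo <- hi <- numeric(n)
  for (kk in unique(k)) {
    sel <- k == kk
    lo[sel] <- interp_bilinear(cube$v[, , kk], cube$q, cube$p, q[sel], p[sel])
    hi[sel] <- interp_bilinear(cube$v[, , kk + 1L], cube$q, cube$p, q[sel], p[sel])
  }
  (1 - tk) * lo + tk * hi
}

#' Look up the threshold-aware bang-bang dose
#'
#' Nearest-node lookup of the stored policy in `(q, p, s)`. A remaining budget
#' `s <= 0` signals budget depletion and returns `NA`; the caller (the
#' simulator) is expected to fall back to another policy. States inside the
#' success region return 0 by convention.
#'
#' @param cube a [solve_threshold_hjb()] result with stored policy.
#' @param q,p state coordinates.
#' @param s remaining budget(s), must be `>= 0` or the lookup signals
#'   depletion via `NA`.
#' @return Numeric dose vector in `{0, d_max}`, with `NA` where `s <= 0`.
#' @export
policy_lookup <- function(cube, q, p, s) {
  stopifnot(inherits(cube, "value_cube"))
  if (!cube$has_policy) abort("this cube was solved with store_policy = FALSE")
  n <- max(length(q), length(p), length(s))
  q <- rep_len(q, n); p <- rep_len(p, n); s <- rep_len(s, n)
  check_state(q, p)
  dmax <- cube$model$params$d_max
  sl <- cube$s_levels
  ds <- (sl[length(sl)] - sl[1]) / (length(sl) - 1)
  i <- pmin(pmax(round((q - cube$q[1]) / (cube$q[2] - cube$q[1])), 0),
            length(cube$q) - 1) + 1L
  j <- pmin(pmax(round((p - cube$p[1]) / (cube$p[2] - cube$p[1])), 0),
            length(cube$p) - 1) + 1L
  k <- pmin(pmax(round((s - sl[1]) / ds), 0), length(sl) - 1) + 1L
  out <- as.numeric(as.integer(cube$policy[cbind(i, j, k)])) * dmax
  # terminal states: no dose by convention
  out[p < cube$model$params$gamma_r | p > cube$model$params$gamma_f] <- 0
  out[s <= 0] <- NA_real_
  out
}

#' Bang-bang switch condition from value-cube gradients
#'
#' The analytic feedback form of the optimal dose: treat at `d_max` when the
#' dose-derivative of the Hamiltonian is negative. For the EGT model this is
#' `v_p p (1 - p) + v_s < 0`; for the SR model,
#' `v_q alpha q (1 - q) + v_p alpha q p + v_s < 0`. The discrete argmax used
#' inside [solve_threshold_hjb()] is authoritative; this predicate serves as a
#' cross-check where the gradients are well-defined.
#'
#' @param model a model or parameter set.
#' @param q,p state coordinates.
#' @param dv_dq,dv_dp,dv_ds gradient estimates of `v` (scheme-consistent
#'   differences).
#' @return Numeric dose vector in `{0, d_max}`.
#' @export
switch_condition <- function(model, q, p, dv_dq, dv_dp, dv_ds) {
  model <- as_ctrl_model(model)
  pars <- model$params
  cond <- if (model$tag == 0L) {
    dv_dp * p * (1 - p) + dv_ds < 0
  } else if (model$tag == 1L) {
    dv_dq * pars$alpha * q * (1 - q) + dv_dp * pars$alpha * q * p + dv_ds < 0
  } else {
    dv_dp + dv_ds < 0
  }
  ifelse(cond, pars$d_max, 0)
}

#' Budget-unconstrained goal probability as the large-budget limit
#'
#' The success probability without any cost constraint, `w(q, p) =
#' sup_d P(reach success before failure)`, is recovered as the limit of the
#' threshold-aware value `v(q, p, s)` as the budget grows. This solves the
#' cube up to `s_bar` and returns the top slice once the sup-norm difference
#' between the two topmost stored slices is below `tol`; otherwise it warns
#' with the residual.
#'
#' @inheritParams solve_threshold_hjb
#' @param tol convergence tolerance on the top stored slices.
#' @return A list of class `goal_probability` with the matrix `w`, the top
#'   policy slice, the residual and the grid axes.
#' @export
goal_probability_limit <- function(model, s_bar, nq = 161, np = 161,
                                   ds_store = 0.05, cfl = 0.9, tol = 1e-3) {
  cube <- solve_threshold_hjb(model, s_bar, nq = nq, np = np,
                              ds_store = ds_store, cfl = cfl)
  ns <- length(cube$s)
  resid <- max(abs(cube$v[, , ns] - cube$v[, , ns - 1L]))
  if (resid > tol)
    warn(sprintf(
      "top slices differ by %.3g > tol = %g: increase s_bar for the budget-free limit",
      resid, tol))
  structure(list(w = cube$v[, , ns], policy = cube$policy[, , ns],
                 residual = resid, converged = resid <= tol,
                 q = cube$q, p = cube$p, s_bar = s_bar, model = cube$model),
            class = "goal_probability")
}

#' @rdname solve_threshold_hjb
#' @param x a `value_cube`.
#' @param s budget slice(s) to return (nearest stored levels; default the top
#'   slice).
#' @param ... unused.
#' @export
tidy.value_cube <- function(x, s = NULL, ...) {
  s <- s %||% max(x$s)
  ks <- unique(vapply(s, function(si) which.min(abs(x$s - si)), integer(1)))
  purrr::map_dfr(ks, function(k) {
    tidyr::expand_grid(p = x$p, q = x$q) |>
      dplyr::mutate(s = x$s[k], v = as.vector(x$v[, , k]),
                    dose = if (x$has_policy)
                      as.numeric(as.integer(x$policy[, , k])) * x$model$params$d_max
                    else NA_real_) |>
      dplyr::select("q", "p", "s", "v", "dose")
  })
}

#' @rdname solve_threshold_hjb
#' @export
glance.value_cube <- function(x, ...) {
  tibble(nq = length(x$q), np = length(x$p), n_slices = length(x$s),
         s_bar = x$s_bar, ds = x$ds, n_levels = x$n_levels,
         cfl_bound = x$cfl_bound, max_clip = x$max_clip)
}

#' @rdname solve_threshold_hjb
#' @param object a `value_cube`.
#' @param what `"value"` or `"policy"`.
#' @export
autoplot.value_cube <- function(object, s = NULL, what = c("value", "policy"),
                                ...) {
  what <- match.arg(what)
  df <- tidy(object, s = s)
  base <- ggplot2::ggplot(df, ggplot2::aes(.data$q, .data$p)) +
    ggplot2::facet_wrap(~round(s, 3))
  if (what == "value") {
    base + ggplot2::geom_raster(ggplot2::aes(fill = .data$v)) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(fill = "P(success\nwithin s)",
                    title = "Threshold-aware success probability")
  } else {
    base + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$dose))) +
      ggplot2::scale_fill_manual(values = c("#2166ac", "#fddb27")) +
      ggplot2::labs(fill = "dose", title = "Threshold-aware policy")
  }
}
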