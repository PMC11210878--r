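test_that("value cube satisfies its boundary conditions and probability bounds", {
  cube <- egt_cube(121, 3)
  np <- length(cube$p); ns <- length(cube$s)
  # success row is certain at every budget, failure row hopeless
  expect_equal(as.vector(cube$v[, 1, ]), rep(1, length(cube$q) * ns))
  expect_equal(as.vector(cube$v[, np, ]), rep(0, length(cube$q) * ns))
  # zero budget means zero success probability off the success region
  expect_equal(as.vector(cube$v[, 2:np, 1]), rep(0, length(cube$q) * (np - 1)))
  # probabilities
  expect_true(all(cube$v >= 0 & cube$v <= 1))
  # non-decreasing in the remaining budget at every spatial node
  expect_gte(min(apply(cube$v, c(1, 2), function(x) min(diff(x)))), -1e-9)
  # clips should be at numerical-noise scale for a stable march
  expect_lt(cube$max_clip, 1e-6)
})

test_that("noise-free limit recovers the indicator of the deterministic value", {
  cube <- toy_cube(sigma = 0)
  exact_u <- (1 + 0.05 / 3) * (cube$p - 0.01)
  vv <- cube$v[3, , ]
  S <- matrix(cube$s, nrow = length(cube$p), ncol = length(cube$s), byrow = TRUE)
  U <- matrix(exact_u, nrow = length(cube$p), ncol = length(cube$s))
  inside <- S - U > 0.05 # comfortably affordable
  inside[length(cube$p), ] <- FALSE # failure row is pinned to 0
  outside <- U - S > 0.05 # comfortably unaffordable
  expect_gt(min(vv[inside]), 0.95)
  expect_lt(max(vv[outside]), 0.05)
})

test_that("analytic switch condition agrees with the discrete argmax away from the switch curve", {
  cube <- egt_cube(121, 3)
  k <- which.min(abs(cube$s - 2))
  np <- length(cube$p); nq <- length(cube$q)
  hp <- cube$p[2] - cube$p[1]; dsl <- cube$s[2] - cube$s[1]
  jj <- 2:(np - 1)
  v_p <- (cube$v[, jj + 1, k] - cube$v[, jj - 1, k]) / (2 * hp)
  v_s <- (cube$v[, jj, k + 1] - cube$v[, jj, k - 1]) / (2 * dsl)
  P <- matrix(cube$p[jj], nq, length(jj), byrow = TRUE)
  Q <- matrix(cube$q, nq, length(jj))
  pred <- switch_condition(egt_params(), Q, P, 0, v_p, v_s)
  stored <- matrix(as.integer(cube$policy[, jj, k]), nq) * 3
  crit <- v_p * P * (1 - P) + v_s
  away <- abs(crit) > 0.1 * max(abs(crit))
  expect_gt(mean(pred[away] == stored[away]), 0.98)

  # on the p-faces the condition degenerates to v_s < 0, which monotonicity
  # forbids, so the predicate prescribes no drugs there
  expect_equal(switch_condition(egt_params(), 0.5, c(0, 1), 0, c(5, 5), c(0.1, 0.1)),
               c(0, 0))
  expect_equal(switch_condition(egt_params(), 0.5, 0.5, 0, 0, 0), 0)
})

test_that("policy lookup signals depletion and reproduces stored entries", {
  cube <- egt_cube(121, 3)
  expect_true(is.na(policy_lookup(cube, 0.5, 0.5, 0)))
  # exact node lookup matches the stored cube entry
  i <- 61L; j <- 61L; k <- 101L
  expect_equal(policy_lookup(cube, cube$q[i], cube$p[j], cube$s[k]),
               as.numeric(as.integer(cube$policy[i, j, k])) * 3)
  # inside the success region the dose is 0 by convention
  expect_equal(policy_lookup(cube, 0.5, 0.001, 2), 0)
  expect_error(policy_lookup(cube, 1.5, 0.5, 2), "unit square")
})

test_that("explicit budget steps violating the stability bound are refused", {
  expect_error(
    solve_threshold_hjb(egt_params(), s_bar = 1, nq = 61, np = 61, ds = 0.5),
    "stability")
})

test_that("large-budget limit approaches the unconstrained goal probability under MTD", {
  w <- fixture("goal_limit", goal_probability_limit(egt_params(), s_bar = 8,
                                                    nq = 81, np = 81,
                                                    tol = 0.02))
  expect_true(w$converged)
  expect_equal(w$w[, 1], rep(1, 81))   # success row
  expect_equal(w$w[, 81], rep(0, 81))  # failure row
  # the limiting policy is MTD wherever the probability field is informative
  mid <- w$w > 0.05 & w$w < 0.95
  expect_gt(mean(w$policy[mid] == 1), 0.75)
  # a short horizon leaves the top slices unconverged and says so
  expect_warning(goal_probability_limit(egt_params(), s_bar = 0.5, nq = 61,
                                        np = 61, tol = 1e-4),
                 "top slices differ")
})

test_that("maximizing over a dense dose lattice never beats the extreme doses", {
  # the marched right-hand side is a ratio of dose-affine expressions, so its
  # maximum over [0, d_max] is attained at an endpoint
  cube <- egt_cube(121, 3)
  pars <- egt_params()
  k <- which.min(abs(cube$s - 1.5))
  hq <- cube$q[2] - cube$q[1]; hp <- cube$p[2] - cube$p[1]
  set.seed(2)
  ii <- sample(3:119, 30); jj <- sample(3:119, 30)
  doses <- seq(0, 3, by = 0.25)
  v <- cube$v[, , k]
  for (t in seq_along(ii)) {
    i <- ii[t]; j <- jj[t]
    q <- cube$q[i]; p <- cube$p[j]
    co <- sde_coefficients(pars, q, p, doses)
    # scheme-consistent one-sided drift differences and central second ones
    dvq_up <- (v[i + 1, j] - v[i, j]) / hq
    dvq_dn <- (v[i, j] - v[i - 1, j]) / hq
    dvp_up <- (v[i, j + 1] - v[i, j]) / hp
    dvp_dn <- (v[i, j] - v[i, j - 1]) / hp
    d2q <- (v[i + 1, j] - 2 * v[i, j] + v[i - 1, j]) / hq^2
    d2p <- (v[i, j + 1] - 2 * v[i, j] + v[i, j - 1]) / hp^2
    d2qp <- (v[i + 1, j + 1] + v[i - 1, j - 1] - v[i + 1, j - 1] -
               v[i - 1, j + 1]) / (4 * hq * hp)
    adv <- ifelse(co$drift_q > 0, co$drift_q * dvq_up, co$drift_q * dvq_dn) +
      ifelse(co$drift_p > 0, co$drift_p * dvp_up, co$drift_p * dvp_dn)
    rhs <- (adv + 0.5 * co$B_qq * d2q + 0.5 * co$B_pp * d2p + co$B_qp * d2qp) /
      running_cost(pars, doses)
    expect_lte(max(rhs), max(rhs[1], rhs[length(rhs)]) + 1e-9)
  }
})

test_that("cube interpolation, tidy and glance behave", {
  cube <- egt_cube(121, 3)
  # interpolation at a stored node is exact
  expect_equal(cube_value(cube, cube$q[40], cube$p[40], cube$s[100]),
               cube$v[40, 40, 100])
  td <- tidy(cube, s = c(1, 3))
  nearest <- cube$s[c(which.min(abs(cube$s - 1)), which.min(abs(cube$s - 3)))]
  expect_equal(sort(unique(td$s)), sort(nearest))
  expect_true(all(td$v >= 0 & td$v <= 1))
  g <- glance(cube)
  expect_equal(g$s_bar, 3)
  expect_s3_class(autoplot(cube, s = 2, what = "policy"), "ggplot")
})
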