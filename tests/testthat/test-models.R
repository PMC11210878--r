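test_that("EGT deterministic rates match hand-evaluated replicator dynamics", {
  pars <- egt_params()
  # frozen values hand-evaluated from the reduced replicator system:
  # sum_k p^k = 2.596868..., q(1-q) = 0.1924, p(1-p) = 0.222775
  r0 <- deterministic_rate(pars, 0.26, 0.665, 0)
  expect_equal(r0$dq_dt, 0.00745496, tolerance = 1e-5)
  expect_equal(r0$dp_dt, 0.0534660, tolerance = 1e-5)
  expect_equal(unlist(r0[, c("dq_dt", "dp_dt")], use.names = FALSE),
               egt_rate_oracle(0.26, 0.665, 0))

  # the dose enters only the p-equation
  r3 <- deterministic_rate(pars, 0.26, 0.665, 3)
  expect_equal(r3$dq_dt, r0$dq_dt)
  expect_equal(r3$dp_dt, 0.222775 * (0.24 - 3), tolerance = 1e-6)

  # logistic factors annihilate their own component
  expect_equal(deterministic_rate(pars, 0.5, 0, 2)$dp_dt, 0)
  expect_equal(deterministic_rate(pars, 0, 0.4, 2)$dq_dt, 0)

  # full lattice against the oracle
  grid <- expand.grid(q = seq(0, 1, 0.2), p = seq(0, 1, 0.2), d = c(0, 1.5, 3))
  got <- deterministic_rate(pars, grid$q, grid$p, grid$d)
  want <- t(mapply(egt_rate_oracle, grid$q, grid$p, grid$d))
  expect_equal(cbind(got$dq_dt, got$dp_dt), unname(want))
})

test_that("SR deterministic rates reduce correctly on faces and match the raw system", {
  pars <- sr_params_synthetic()
  # pure sensitive: composition frozen, drug acts on the whole tumor
  r <- deterministic_rate(pars, 1, 0.5, 2)
  expect_equal(r$dq_dt, 0)
  expect_equal(r$dp_dt, 0.5 * 0.5 * pars$g_S - pars$alpha * 0.5 * 2)
  # full dish: competition is the only force shrinking it
  r <- deterministic_rate(pars, 0.3, 1, 0)
  expect_equal(r$dp_dt, -pars$beta * pars$C * 0.3 * 0.7)
  expect_lte(r$dp_dt, 0)
  # resistant-only tumor grows logistically
  r <- deterministic_rate(pars, 0, 0.4, 3)
  expect_equal(r$dq_dt, 0)
  expect_equal(r$dp_dt, 0.4 * 0.6 * pars$g_R)
  # lattice against the independent oracle
  grid <- expand.grid(q = seq(0, 1, 0.25), p = seq(0, 1, 0.25), d = c(0, 3))
  got <- deterministic_rate(pars, grid$q, grid$p, grid$d)
  want <- t(mapply(function(q, p, d) sr_rate_oracle(q, p, d, pars),
                   grid$q, grid$p, grid$d))
  expect_equal(cbind(got$dq_dt, got$dp_dt), unname(want))
})

test_that("SDE coefficients reduce to the deterministic rates when noise is off", {
  egt0 <- egt_params(sigma_G = 0, sigma_D = 0, sigma_V = 0)
  sr0 <- sr_params_synthetic(sigma_S = 0, sigma_R = 0)
  grid <- expand.grid(q = seq(0, 1, 0.1), p = seq(0, 1, 0.1), d = c(0, 3))
  for (pars in list(egt0, sr0)) {
    co <- sde_coefficients(pars, grid$q, grid$p, grid$d)
    ra <- deterministic_rate(pars, grid$q, grid$p, grid$d)
    expect_equal(co$drift_q, ra$dq_dt)
    expect_equal(co$drift_p, ra$dp_dt)
    expect_equal(co$B_qq, rep(0, nrow(grid)))
    expect_equal(co$B_pp, rep(0, nrow(grid)))
    expect_equal(co$B_qp, rep(0, nrow(grid)))
  }
})

test_that("diffusion vanishes on boundary faces and symmetric volatilities cancel", {
  pars <- egt_params()
  # p faces kill the p-row, q faces kill the q-row
  for (p in c(0, 1)) expect_equal(diffusion_matrix(pars, 0.4, p)["p", ],
                                  c(W1 = 0, W2 = 0, W3 = 0))
  for (q in c(0, 1)) expect_equal(diffusion_matrix(pars, q, 0.4)["q", ],
                                  c(W1 = 0, W2 = 0, W3 = 0))
  # symmetric volatilities: the q-drift correction vanishes at q = 1/2
  co <- sde_coefficients(pars, 0.5, 0.5, 0)
  ra <- deterministic_rate(pars, 0.5, 0.5, 0)
  expect_equal(co$drift_q, ra$dq_dt)

  # SR: equal volatilities make composition noise-free (and correction-free)
  sr <- sr_params_synthetic(sigma_S = 0.15, sigma_R = 0.15)
  expect_equal(unname(diffusion_matrix(sr, 0.3, 0.6)["q", ]), 0)
  co <- sde_coefficients(sr, 0.3, 0.6, 1)
  expect_equal(co$drift_q, deterministic_rate(sr, 0.3, 0.6, 1)$dq_dt)
  # p = 1 kills both SR rows
  expect_equal(unname(diffusion_matrix(sr, 0.3, 1)), matrix(0, 2, 1))

  # no-escape: the rate component normal to every face keeps the state inside
  for (pars2 in list(pars, sr)) {
    expect_equal(deterministic_rate(pars2, c(0, 1), 0.5, 3)$dq_dt, c(0, 0))
    expect_gte(deterministic_rate(pars2, 0.5, 0, 3)$dp_dt, 0)
    expect_lte(deterministic_rate(pars2, 0.5, 1, 0)$dp_dt, 0)
  }
})

test_that("terminal regions use strict barriers", {
  pars <- egt_params() # gamma_r = 0.01, gamma_f = 0.99
  expect_equal(as.character(classify_state(pars, 0.5, 0.005)), "success")
  expect_equal(as.character(classify_state(pars, 0.5, 0.995)), "failure")
  expect_equal(as.character(classify_state(pars, 0.5, 0.5)), "interior")
  # exact barrier hits are interior
  expect_equal(as.character(classify_state(pars, 0.5, c(0.01, 0.99))),
               c("interior", "interior"))
})

test_that("heterogeneous-regime condition is the strict double inequality", {
  expect_true(heterogeneous_regime(egt_params()))     # 0.5 < 1 < 4
  expect_false(heterogeneous_regime(egt_params(b_v = 1)))  # middle term 0
  # boundary case: b_a = 0 and b_v - c = c n fails strictness
  expect_false(heterogeneous_regime(egt_params(b_a = 0, b_v = 5)))
})

test_that("coordinate reduction and the number-fraction identity round-trip", {
  egt <- egt_params()
  red <- reduce_coordinates(data.frame(z_G = 1, z_D = 1, z_V = 2), egt)
  expect_equal(red$q, 2 / 3)
  expect_equal(red$p, 1 / 4)
  red <- reduce_coordinates(data.frame(z_G = 0, z_D = 1, z_V = 0), egt)
  expect_equal(c(red$q, red$p), c(0, 0))
  expect_error(reduce_coordinates(data.frame(z_G = 1, z_D = 0, z_V = 0), egt),
               "undefined-coordinate")
  expect_error(reduce_coordinates(data.frame(z_G = 0, z_D = 0, z_V = 0), egt),
               "undefined-coordinate")

  sr <- sr_params_synthetic() # m = 30
  set.seed(7)
  z <- data.frame(z_S = runif(20, 0.01, 0.5), z_R = runif(20, 0.001, 0.02))
  red <- reduce_coordinates(z, sr)
  expect_equal(red$p, z$z_S + 30 * z$z_R)
  # by-number sensitive fraction equals z_S / (z_S + z_R)
  expect_equal(sensitive_number_fraction(red$q, 30), z$z_S / (z$z_S + z$z_R))
  expect_error(reduce_coordinates(data.frame(z_S = 0, z_R = 0), sr),
               "undefined-coordinate")

  # a tumor 96% sensitive by number at 90% of capacity sits near (0.45, 0.9)
  N <- 0.9 / (0.96 + 30 * 0.04)
  red <- reduce_coordinates(data.frame(z_S = 0.96 * N, z_R = 0.04 * N), sr)
  expect_equal(red$p, 0.9, tolerance = 1e-12)
  expect_equal(red$q, 0.45, tolerance = 0.02)
})

test_that("running cost is affine in the dose and bounded away from zero", {
  pars <- egt_params() # delta = 0.05, d_max = 3
  d <- seq(0, 3, length.out = 7)
  K <- running_cost(pars, d)
  expect_equal(K, d + 0.05)
  expect_true(all(K >= 0.05 & K <= 3.05))
  expect_error(running_cost(pars, 3.5), "dose")
  expect_error(running_cost(pars, -0.1), "dose")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(egt_params(gamma_r = 0.5, gamma_f = 0.4), "gamma")
  expect_error(egt_params(delta = 0), "delta")
  expect_error(egt_params(d_max = -1), "d_max")
  expect_error(egt_params(n = 0), "integer")
  expect_error(sr_params_synthetic(g_S = -1), "positive")
  expect_error(sr_params_reference(), "not bundled")
  expect_error(deterministic_rate(egt_params(), 1.2, 0.5, 0), "unit square")
  expect_error(deterministic_rate(egt_params(), NaN, 0.5, 0), "finite")
})
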