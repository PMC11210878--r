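test_that("noise-free ensembles are degenerate and reproduce the deterministic integrator", {
  pars0 <- egt_params(sigma_G = 0, sigma_D = 0, sigma_V = 0)
  u <- egt_field(161)
  tr <- integrate_optimal_trajectory(pars0, u, c(0.26, 0.665), dt = 1e-3)
  e <- run_ensemble(pars0, u, c(0.26, 0.665), dt = 1e-3, n = 5, seed = 4)
  expect_equal(length(unique(e$cost)), 1L) # all paths identical
  expect_equal(e$cost[1], attr(tr, "cost"), tolerance = 1e-3)
  expect_true(all(e$outcome == "success_within_budget"))

  # dt-refinement: the degenerate cost converges as the step halves
  costs <- vapply(c(4e-3, 2e-3, 1e-3), function(dt) {
    run_ensemble(pars0, u, c(0.26, 0.665), dt = dt, n = 1, seed = 4)$cost
  }, numeric(1))
  expect_lt(abs(costs[3] - costs[2]), abs(costs[2] - costs[1]) + 1e-6)
})

test_that("drug-free courses accrue cost at exactly the time-penalty rate", {
  pars <- egt_params()
  e <- run_ensemble(pars, constant_policy(0, pars), c(0.26, 0.665),
                    dt = 1e-3, n = 200, seed = 5, t_max = 60)
  expect_equal(e$cost, 0.05 * e$time, tolerance = 1e-10)
})

test_that("paths starting in the success region terminate immediately", {
  pars <- egt_params()
  e <- run_ensemble(pars, constant_policy(0, pars), c(0.3, 0.005),
                    dt = 1e-3, n = 3, seed = 6)
  expect_equal(e$cost, rep(0, 3))
  expect_equal(e$time, rep(0, 3))
  expect_true(all(e$outcome == "success_within_budget"))
})

test_that("budget bookkeeping: depletion time is present exactly when the cost exceeds the budget", {
  pars <- egt_params()
  u <- egt_field(161)
  e <- run_ensemble(pars, u, c(0.26, 0.665), s_bar = 4.8, dt = 1e-3,
                    n = 400, seed = 7)
  over <- e$cost > 4.8
  expect_equal(!is.na(e$t_sharp), over)
  expect_true(all(e$t_sharp[over] <= e$time[over] + 1e-9))
  expect_true(all(e$cost >= 0.05 * e$time - 1e-9))
  # outcome labels split successes by the budget
  expect_equal(e$outcome == "success_over_budget",
               over & e$outcome != "failure_death" & e$outcome != "censored")
})

test_that("ensembles replay deterministically and paths are counter-seeded", {
  pars <- egt_params()
  u <- egt_field(161)
  e1 <- run_ensemble(pars, u, c(0.26, 0.665), dt = 2e-3, n = 30, seed = 11)
  e2 <- run_ensemble(pars, u, c(0.26, 0.665), dt = 2e-3, n = 30, seed = 11)
  expect_identical(e1$cost, e2$cost)
  # path k is independent of the ensemble size
  e3 <- run_ensemble(pars, u, c(0.26, 0.665), dt = 2e-3, n = 10, seed = 11)
  expect_identical(e1$cost[1:10], e3$cost)
  # a different seed gives different draws
  e4 <- run_ensemble(pars, u, c(0.26, 0.665), dt = 2e-3, n = 10, seed = 12)
  expect_false(identical(e3$cost, e4$cost))
  # single-path replay with its trajectory
  pth <- simulate_path(pars, u, c(0.26, 0.665), dt = 2e-3, seed = 11,
                       path_index = 3)
  expect_equal(attr(pth, "cost"), e1$cost[3])
  expect_true(all(c("time", "q", "p", "dose") %in% names(pth)))
})

test_that("the fallback policy only affects the right tail of the cost distribution", {
  pars <- egt_params()
  u <- egt_field(161)
  cube <- egt_cube(121, 3)
  sb <- 2.5
  e_dstar <- run_ensemble(pars, cube, c(0.3, 0.3), s_bar = sb, dt = 1e-3,
                          n = 300, seed = 8, fallback = u)
  e_mtd <- run_ensemble(pars, cube, c(0.3, 0.3), s_bar = sb, dt = 1e-3,
                        n = 300, seed = 8,
                        fallback = constant_policy(3, pars))
  # paths that stay within budget never consult the fallback: identical costs
  within <- e_dstar$cost <= sb
  expect_identical(e_dstar$cost[within], e_mtd$cost[within])
  expect_identical(within, e_mtd$cost <= sb)
  # hence the empirical CDFs agree below the budget
  s_grid <- seq(0.5, sb, by = 0.25)
  expect_equal(cdf_estimate(e_dstar, s_grid)$p_hat,
               cdf_estimate(e_mtd, s_grid)$p_hat)
})

test_that("ensemble summaries compute medians and success-conditional means", {
  fake <- structure(
    tibble::tibble(path = 1:3,
                   outcome = factor(rep("success_within_budget", 3),
                                    levels = c("success_within_budget",
                                               "success_over_budget",
                                               "failure_death", "censored")),
                   cost = c(1, 2, 3), time = c(1, 1, 1),
                   t_sharp = NA_real_, n_clamp = 0),
    s_bar = Inf, policy = "test", class = c("tx_ensemble", "tbl_df", "tbl",
                                            "data.frame"))
  s <- summarize_ensemble(fake)
  expect_equal(s$median_cost, 2)
  expect_equal(s$mean_cost_success, 2)
  expect_equal(s$success_frac, 1)

  all_fail <- fake
  all_fail$outcome <- factor(rep("failure_death", 3),
                             levels = levels(fake$outcome))
  s2 <- summarize_ensemble(all_fail)
  expect_equal(s2$median_cost, Inf)
  expect_true(is.na(s2$mean_cost_success))

  withcdf <- summarize_ensemble(fake, thresholds = c(1.5, 2.5))
  expect_equal(withcdf$cdf[[1]]$p_hat, c(1 / 3, 2 / 3))
})

test_that("comparing a policy with itself shows no threshold advantage", {
  pars <- egt_params()
  u <- egt_field(161)
  cube <- egt_cube(121, 3)
  cmp <- compare_policies(
    pars, c(0.3, 0.3),
    list(a = list(policy = cube, s_bar = 2.5, fallback = u),
         b = list(policy = cube, s_bar = 2.5, fallback = u)),
    n = 300, seed = 9)
  adv <- attr(cmp, "advantage")
  expect_equal(adv$advantage, c(0, 0))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("interior paths at the censoring time are reported as censored", {
  pars <- egt_params()
  e <- run_ensemble(pars, constant_policy(0, pars), c(0.26, 0.665),
                    dt = 1e-3, n = 5, seed = 10, t_max = 0.5)
  expect_true(all(e$outcome == "censored"))
})

test_that("cube policies with a finite budget require an explicit fallback", {
  cube <- egt_cube(121, 3)
  expect_error(run_ensemble(egt_params(), cube, c(0.3, 0.3), s_bar = 2,
                            n = 2, seed = 1),
               "fallback")
})
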