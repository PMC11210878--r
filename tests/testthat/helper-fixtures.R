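# Solver fixtures are expensive; build each once per test run and memoise.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

egt_field <- function(n = 161) {
  fixture(paste0("egt_field_", n),
          solve_deterministic_hjb(egt_params(), nq = n, np = n))
}

egt_cube <- function(n = 121, s_bar = 3) {
  fixture(sprintf("egt_cube_%d_%g", n, s_bar),
          solve_threshold_hjb(egt_params(), s_bar = s_bar, nq = n, np = n))
}

toy_field <- function(sigma = 0) {
  fixture(paste0("toy_field_", sigma),
          solve_deterministic_hjb(toy_params(sigma = sigma), nq = 5, np = 201))
}

toy_cube <- function(sigma = 0, s_bar = 1.2) {
  fixture(sprintf("toy_cube_%g_%g", sigma, s_bar),
          solve_threshold_hjb(toy_params(sigma = sigma), s_bar = s_bar,
                              nq = 5, np = 201))
}

# independent hand-written EGT rate (the oracle for the C++ implementation)
egt_rate_oracle <- function(q, p, d, pars = egt_params()) {
  S <- sum(p^(0:pars$n))
  c(q * (1 - q) * (pars$b_v / (pars$n + 1) * S - pars$c),
    p * (1 - p) * (pars$b_a / (pars$n + 1) - (pars$b_v - pars$c) * q - d))
}

# independent hand-written SR rate
sr_rate_oracle <- function(q, p, d, pars) {
  bC <- pars$beta * pars$C
  c((1 - p) * q * (1 - q) * (pars$g_S - pars$g_R) +
      bC * p * q^2 * (1 - q) - pars$alpha * q * (1 - q) * d,
    p * (1 - p) * (pars$g_S * q + pars$g_R * (1 - q)) -
      bC * p^2 * q * (1 - q) - pars$alpha * q * p * d)
}
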