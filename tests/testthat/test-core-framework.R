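# a 3-genotype model with genuinely frequency-dependent perturbations,
# used to exercise the generic machinery beyond the built-in models
three_type_model <- function(epsilon = 0.05) {
  model_spec(
    n_types = 3L,
    rates = rate_decomposition(
      f0 = function(u) 1 + 0.2 * u[1],
      d0 = function(u) 0.3,
      phi = function(u) c(0.1 * u[2], -0.2, 0.3 * u[1] * u[3]),
      eta = function(u) c(0, 0.1 * u[3], -0.05),
      g = function(s) 1 - s / 2,
      h = function(s) 1
    ),
    epsilon = epsilon
  )
}

test_that("frequency derivatives sum to zero and vanish in the neutral limit", {
  set.seed(21)
  m <- three_type_model(0.05)
  m0 <- three_type_model(0)
  for (i in 1:50) {
    u <- as.numeric(rmultinom(1, 1000, runif(3, 0.2, 1))) / 1000
    st <- freq_size_state(u, runif(1, 0.01, 1.9))
    d <- full_rhs(st, m)
    expect_lt(abs(sum(d$du)), 1e-12)
    # neutral limit: frequencies frozen, size equation reduces to the
    # zeroth-order inner equation exactly
    dn <- full_rhs(st, m0)
    expect_identical(dn$du, c(0, 0, 0))
    expect_identical(dn$ds, inner_zeroth_rhs(st, m0)$ds)
    d0 <- outer_zeroth_rhs(u, m, s_star = 1.2)
    expect_lt(abs(sum(d0)), 1e-12)
  }
})

test_that("monomorphic populations and extinction are fixed points", {
  m <- three_type_model(0.1)
  st <- freq_size_state(c(0, 1, 0), 0.5)
  expect_equal(full_rhs(st, m)$du, c(0, 0, 0))
  expect_equal(outer_zeroth_rhs(c(0, 1, 0), m, 1), c(0, 0, 0))
  # no selection differential when phi and eta coincide
  mflat <- model_spec(2L, rate_decomposition(
    f0 = function(u) 1, d0 = function(u) 0.2,
    phi = function(u) c(0.3, 0.3), eta = function(u) c(0.3, 0.3),
    g = function(s) 1 - s, h = function(s) 1), epsilon = 0.1)
  expect_equal(outer_zeroth_rhs(c(0.4, 0.6), mflat, 0.5), c(0, 0))
  # extinction is absorbing
  ext <- freq_size_state(c(0.5, 0.25, 0.25), 0)
  expect_identical(full_rhs(ext, m)$ds, 0)
  expect_identical(inner_zeroth_rhs(ext, m)$ds, 0)
})

test_that("zeroth-order inner dynamics freeze the frequencies", {
  p <- pg_params(mu = 0.2)
  m <- pg_model_spec(p)
  st <- freq_size_state(c(0.5, 0.5), 0.5)
  d <- inner_zeroth_rhs(st, m)
  expect_identical(d$du, c(0, 0))
  # logistic growth at the frozen composition:
  # 1.5 * 0.5 * (1 - 0.5) - 0.2 * 0.5
  expect_equal(d$ds, 0.275)
})

test_that("ecological equilibrium solver finds the logistic fixed point", {
  p <- pg_params(alpha = 1, beta = 1, K = 1, mu = 0.2)
  m <- pg_model_spec(p)
  eq <- ecological_equilibrium(c(0.5, 0.5), m, bracket = c(1e-3, 2))
  expect_equal(eq$s_star, 13 / 15, tolerance = 1e-10)
  expect_true(eq$stable)
  expect_lt(abs(eq$residual), 1e-10)

  # mu = 0: carrying capacity
  eq0 <- ecological_equilibrium(c(0.5, 0.5),
                                pg_model_spec(pg_params(mu = 0)),
                                bracket = c(1e-3, 2))
  expect_equal(eq0$s_star, 1, tolerance = 1e-10)
  expect_true(eq0$stable)
})

test_that("density-independent rates yield a no-equilibrium error", {
  m <- model_spec(2L, rate_decomposition(
    f0 = function(u) 1.5, d0 = function(u) 0.2,
    phi = function(u) c(0, 0), eta = function(u) c(0, 0),
    g = function(s) 1, h = function(s) 1), epsilon = 0.05)
  expect_error(ecological_equilibrium(c(0.5, 0.5), m, c(0.1, 10)),
               "no ecological equilibrium")
  expect_error(outer_zeroth_rhs(c(0.5, 0.5), m,
                                structure(list(s_star = 1, stable = FALSE),
                                          class = "eesep_equilibrium")),
               "invalid equilibrium")
})

test_that("multiple stable equilibria are disambiguated by the initial density", {
  # residual r(S) = -(S-1)(S-2)(S-3): stable roots at 1 and 3
  m <- model_spec(2L, rate_decomposition(
    f0 = function(u) 1, d0 = function(u) 1,
    phi = function(u) c(0, 0), eta = function(u) c(0, 0),
    g = function(s) 1 - (s - 1) * (s - 2) * (s - 3), h = function(s) 1),
    epsilon = 0)
  expect_error(ecological_equilibrium(c(0.5, 0.5), m, c(0.2, 4)),
               "multiple stable equilibria")
  lo <- ecological_equilibrium(c(0.5, 0.5), m, c(0.2, 4), s_init = 0.5)
  hi <- ecological_equilibrium(c(0.5, 0.5), m, c(0.2, 4), s_init = 3.5)
  expect_equal(lo$s_star, 1, tolerance = 1e-9)
  expect_equal(hi$s_star, 3, tolerance = 1e-9)
  expect_equal(nrow(lo$roots), 3L)
  expect_equal(sum(lo$roots$stable), 2L)
})

test_that("integrator reproduces closed-form flows at tight tolerance", {
  # identity flow
  tr <- integrate_ode(function(t, y) c(a = 0, b = 0), c(a = 1, b = -2),
                      times = 0:5)
  expect_true(all(tr$states$a == 1))
  expect_true(all(tr$states$b == -2))
  # logistic growth against its closed form
  tr <- integrate_ode(function(t, y) c(s = y[["s"]] * (1 - y[["s"]])),
                      c(s = 0.5), times = c(0, 1, 2, 5))
  expect_equal(tr$states$s, 1 / (1 + exp(-c(0, 1, 2, 5))),
               tolerance = 1e-8)
  # non-finite derivatives abort with a diagnostic (sqrt of a negative
  # number also raises R's own NaN warning, which is not the point here)
  suppressWarnings(
    expect_error(integrate_ode(function(t, y) c(s = sqrt(y[["s"]] - 2)),
                               c(s = 1), times = 0:2),
                 "non-finite"))
})

test_that("generic full integration stays on the simplex", {
  m <- three_type_model(0.08)
  st0 <- freq_size_state(c(0.2, 0.5, 0.3), 0.05)
  tr <- simulate_full(m, st0, time_grid(50))
  usum <- rowSums(tr$states[, c("u1", "u2", "u3")])
  expect_lt(max(abs(usum - 1)), 1e-8)
  expect_true(all(tr$states$s > 0))
})

test_that("generic integration agrees with the hand-coded public-goods solver", {
  p <- pg_params(kappa = 0.1)
  times <- time_grid(20)
  generic <- simulate_full(pg_model_spec(p),
                           freq_size_state(c(p$a, 1 - p$a), p$b), times)
  direct <- pg_simulate(p, times, "full")
  expect_lt(max(abs(generic$states$u1 - direct$states$u)), 1e-8)
  expect_lt(max(abs(generic$states$s - direct$states$s)), 1e-8)
})

test_that("composite assembly matches at t = 0 and rejects unmatched expansions", {
  p <- pg_params(kappa = 0.01)
  times <- time_grid(50)
  comp <- pg_composite(p, times)
  expect_equal(comp$timescale, "composite_t")
  expect_equal(comp$states$u[1], p$a, tolerance = 1e-12)
  expect_equal(comp$states$s[1], p$b, tolerance = 1e-9)

  # an inner trajectory truncated before it reaches the ecological
  # equilibrium cannot be matched to the outer expansion
  expect_error(pg_composite(p, seq(0, 1, length.out = 21)),
               "unmatched expansion")

  # time-scale bookkeeping: tau-grid mismatches are type errors
  inner <- pg_simulate(p, times, "inner0")
  outer <- pg_outer_trajectory(p, 2 * p$kappa * times, order = 0)
  expect_error(composite_zeroth(inner, outer,
                                c(u = p$a, s = pg_outer_S0(p$a, p)),
                                p$kappa),
               "tau = epsilon \\* t")
  expect_error(composite_zeroth(inner, inner,
                                c(u = p$a, s = pg_outer_S0(p$a, p)),
                                p$kappa),
               "outer_tau")
})

test_that("for t past the transient the composite follows the outer branch", {
  p <- pg_params(kappa = 0.01)
  tgrid <- time_grid(50)
  comp <- pg_composite(p, tgrid)
  outer_u <- pg_outer_trajectory(p, p$kappa * tgrid, order = 0)$states$u
  i50 <- length(tgrid)  # t = 50: inner transient long converged
  expect_lt(abs(comp$states$u[i50] - outer_u[i50]), p$kappa)
})
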