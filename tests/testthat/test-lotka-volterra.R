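test_that("full Lotka-Volterra right-hand side matches direct evaluation", {
  p <- lv_params(alpha = 0.2, beta = 1, delta = 0.5, gamma = 1,
                 epsilon = 0.05)
  d <- lv_full_rhs(1, 1, 0.01, p)
  expect_equal(unname(d["dx"]), 0.2 - (1 + 1.05 * 0.01))
  expect_equal(unname(d["dy1"]), -0.5)
  expect_equal(unname(d["dy2"]), -0.00475)

  # coexistence fixed point of the resident system (no invader)
  d <- lv_full_rhs(p$gamma / p$delta, p$alpha / p$beta, 0, p)
  expect_equal(unname(d), c(0, 0, 0))

  # with epsilon = 0 and y2 = 0 this is the classical 1-prey/1-predator
  # system
  p0 <- lv_params(epsilon = 0)
  d <- lv_full_rhs(1.3, 0.7, 0, p0)
  expect_equal(unname(d["dx"]), 0.2 * 1.3 - 1 * 1.3 * 0.7)
  expect_equal(unname(d["dy1"]), 0.5 * 1.3 * 0.7 - 0.7)
  expect_equal(unname(d["dy2"]), 0)
})

test_that("the (x,u,s) system is the exact image of the abundance system", {
  set.seed(31)
  p <- lv_params(epsilon = 0.08)
  for (i in 1:100) {
    x <- runif(1, 0.1, 3)
    y1 <- runif(1, 0.05, 3)
    y2 <- runif(1, 0.05, 3)
    s <- y1 + y2
    u <- y1 / s
    d3 <- lv_full_rhs(x, y1, y2, p)
    # push the abundance derivatives through the chain rule
    du <- (d3[["dy1"]] * y2 - y1 * d3[["dy2"]]) / s^2
    ds <- d3[["dy1"]] + d3[["dy2"]]
    dt <- lv_uvs_rhs(x, u, s, p)
    expect_rel_equal(dt[["dx"]], d3[["dx"]], 1e-12)
    expect_rel_equal(dt[["du"]], du, 1e-12)
    expect_rel_equal(dt[["ds"]], ds, 1e-12)
  }
})

test_that("predator subsystem fits the generic weak-selection form", {
  set.seed(32)
  p <- lv_params(epsilon = 0.08)
  for (i in 1:100) {
    st <- random_lv_state()
    m <- lv_predator_model_spec(p, st[["x"]])
    d_gen <- full_rhs(freq_size_state(c(st[["u"]], 1 - st[["u"]]),
                                      st[["s"]]), m)
    d_ref <- lv_uvs_rhs(st[["x"]], st[["u"]], st[["s"]], p)
    expect_rel_equal(d_gen$du[1], d_ref[["du"]], 1e-12)
    expect_rel_equal(d_gen$ds, d_ref[["ds"]], 1e-12)
  }
})

test_that("neutral invaders never change the wild-type fraction", {
  p <- lv_params(epsilon = 0)
  set.seed(33)
  for (i in 1:20) {
    st <- random_lv_state()
    expect_identical(lv_uvs_rhs(st[["x"]], st[["u"]], st[["s"]], p)[["du"]],
                     0)
  }
  # and the (x, s) dynamics coincide exactly with the zeroth-order inner
  # system
  st <- c(x = 1.2, u = 0.6, s = 0.8)
  d_full <- lv_uvs_rhs(st[["x"]], st[["u"]], st[["s"]], p)
  d_in <- lv_inner_rhs(0, c(x0 = st[["x"]], u0 = st[["u"]],
                            s0 = st[["s"]]), p)
  expect_identical(d_full[["dx"]], d_in[["x0"]])
  expect_identical(d_full[["ds"]], d_in[["s0"]])
})

test_that("inner expansion freezes u at order 0 and depresses it at order 1", {
  p <- lv_params()
  expect_identical(lv_inner_rhs(0, c(x0 = 1, u0 = 0.4, s0 = 1), p)[["u0"]],
                   0)
  # monomorphic boundary
  d <- lv_inner_rhs(1, c(x0 = 1.5, u0 = 1, s0 = 0.8, x1 = 0.1, u1 = 0.2,
                         s1 = 0.3), p)
  expect_equal(d[["u1"]], 0)
  expect_equal(d[["s1"]],
               p$delta * (1.5 * 0.3 + 0.1 * 0.8) - p$gamma * 0.3)
  # interior: the wild type always loses ground at first order
  set.seed(34)
  for (i in 1:25) {
    st <- random_lv_state()
    d <- lv_inner_rhs(1, c(x0 = st[["x"]], u0 = st[["u"]], s0 = st[["s"]],
                           x1 = rnorm(1), u1 = rnorm(1), s1 = rnorm(1)), p)
    expect_lt(d[["u1"]], 0)
  }
})

test_that("zeroth-order inner system conserves the Lotka-Volterra invariant", {
  p <- lv_params()
  times <- time_grid(200)
  tr <- lv_simulate(p, times, "inner0")
  inv <- lv_first_integral(tr$states$x, tr$states$s, p)
  expect_lt(max(abs(inv - inv[1])), 1e-6)
  # and u stays put exactly
  expect_equal(tr$states$u, rep(tr$states$u[1], length(times)))
})

test_that("outer steady states and replicator closed form are recovered", {
  p <- lv_params(alpha = 0.2, beta = 1, delta = 0.5, gamma = 1)
  oz <- lv_outer_zeroth(p)
  expect_equal(oz$X0, 2)
  expect_equal(oz$S0, 0.2)
  expect_equal(oz$rhs(0), 0)
  expect_equal(oz$rhs(1), 0)
  expect_equal(oz$rhs(0.5), -0.25)

  # integrated slow dynamics against the separable closed form
  a <- p$y1_0 / (p$y1_0 + p$y2_0)
  tr <- integrate_ode(function(t, y) c(U0 = oz$rhs(y[["U0"]])),
                      c(U0 = a), times = c(0, 1, 5, 10),
                      timescale = "outer_tau")
  expect_equal(tr$states$U0, lv_outer_zeroth_solution(a, c(0, 1, 5, 10), p),
               tolerance = 1e-8)
})

test_that("first-order outer corrections match the closed forms", {
  p <- lv_params(alpha = 0.2, beta = 1, delta = 0.5, gamma = 1)
  fo <- lv_outer_first(0.5, 0, p)
  expect_equal(fo$X1, -1)
  expect_equal(fo$S1, -0.1)
  expect_equal(fo$dU1_dtau, 0.125)
  # U0 = 1: no corrections to the populations, pure decay of U1
  fo <- lv_outer_first(1, 0.3, p)
  expect_equal(fo$X1, 0)
  expect_equal(fo$S1, 0)
  expect_equal(fo$dU1_dtau, p$gamma * 0.3)
  # first-order population sizes shrink in proportion to the invader load
  U0 <- seq(0, 1, 0.25)
  fo <- lv_outer_first(U0, 0, p)
  expect_equal(p$gamma / p$delta + p$epsilon * fo$X1,
               (p$gamma / p$delta) * (1 - p$epsilon * (1 - U0)))
  expect_equal(p$alpha / p$beta + p$epsilon * fo$S1,
               (p$alpha / p$beta) * (1 - p$epsilon * (1 - U0)))
})

test_that("assembled approximation levels behave as designed", {
  p <- lv_params(epsilon = 0.05)
  times <- time_grid(20)
  full <- lv_simulate(p, times, "full")
  # u from the full system is non-increasing (selection against wild type)
  expect_true(all(diff(full$states$u) <= 1e-12))

  in0 <- lv_assemble_approximation("inner0", p, times)
  a <- p$y1_0 / (p$y1_0 + p$y2_0)
  expect_equal(in0$states$u, rep(a, length(times)))

  out0 <- lv_assemble_approximation("outer0", p, times)
  expect_equal(out0$states$u,
               lv_outer_zeroth_solution(a, p$epsilon * times, p),
               tolerance = 1e-8)
  expect_true(all(out0$states$x == p$gamma / p$delta))

  # the first-order inner solution tracks the oscillation better than
  # the frozen zeroth-order solution
  in1 <- lv_assemble_approximation("inner1", p, times)
  e0 <- total_error(full, in0, "u")
  e1 <- total_error(full, in1, "u")
  expect_lt(e1, e0)
})
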