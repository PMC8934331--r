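# Independent oracles used across the test files.
#
# The first-order perturbation systems are re-derived symbolically from the
# full right-hand sides with base R's D(): for dy/dt = F(y, eps), writing
# y = y0 + eps*y1 and collecting the eps^1 terms gives the first variation
#   dy1/dt = J_y F(y0, 0) %*% y1 + dF/deps (y0, 0),
# which is exact here because both built-in models are polynomial in eps.
# The oracle shares no code with the hand-written model right-hand sides.

# quoted full right-hand sides, one expression per state variable;
# variable names and the selection-strength symbol appear literally
pg_exprs <- list(
  u = quote(-kappa * u * (1 - u) * (1 - s / K)),
  s = quote(-kappa * s * u * (1 - s / K) +
              alpha * (1 + beta * u) * s * (1 - s / K) - mu * s)
)

lv_exprs <- list(
  x = quote(alpha * x - beta * x * s * (1 + epsilon * (1 - u))),
  u = quote(-epsilon * delta * x * u * (1 - u)),
  s = quote(epsilon * delta * s * x * (1 - u) + delta * s * x - gamma * s)
)

# evaluate an expression with states/params bound in a fresh environment
eval_at <- function(ex, vals) eval(ex, as.list(vals))

# zeroth-order rhs: F evaluated at (y0, eps = 0)
zeroth_order_oracle <- function(exprs, eps_name, y0, params) {
  vals <- c(as.list(params), as.list(y0))
  vals[[eps_name]] <- 0
  vapply(exprs, eval_at, numeric(1L), vals = vals)
}

# first-order rhs via the first variation (symbolic D-derivatives)
first_order_oracle <- function(exprs, state_names, eps_name, y0, y1,
                               params) {
  vals <- c(as.list(params), as.list(y0))
  vals[[eps_name]] <- 0
  vapply(exprs, function(ex) {
    jac <- sum(vapply(state_names, function(v) {
      eval_at(stats::D(ex, v), vals) * y1[[v]]
    }, numeric(1L)))
    jac + eval_at(stats::D(ex, eps_name), vals)
  }, numeric(1L))
}

# outer algebraic corrections by implicit differentiation: the equations
# G_i(z, u, eps) = 0 (z the algebraically slaved states) define z(u, eps);
# at eps = 0, dz/deps solves  (dG/dz) z1 = -dG/deps.
implicit_first_order_oracle <- function(exprs, z_names, eps_name, z0, u0,
                                        params, u_name = "u") {
  vals <- c(as.list(params), as.list(z0))
  vals[[u_name]] <- u0
  vals[[eps_name]] <- 0
  A <- sapply(z_names, function(v)
    vapply(exprs, function(ex) eval_at(stats::D(ex, v), vals), numeric(1L)))
  b <- -vapply(exprs, function(ex) eval_at(stats::D(ex, eps_name), vals),
               numeric(1L))
  solve(A, b)
}

pg_param_list <- function(p) p[c("alpha", "beta", "K", "mu")]
lv_param_list <- function(p) p[c("alpha", "beta", "delta", "gamma")]

# random interior state generators (call set.seed first)
random_pg_state <- function() c(u = runif(1, 0.05, 0.95),
                                s = runif(1, 0.05, 1.5))
random_lv_state <- function() c(x = runif(1, 0.1, 3),
                                u = runif(1, 0.05, 0.95),
                                s = runif(1, 0.1, 3))

expect_rel_equal <- function(actual, expected, rel_tol) {
  scale <- pmax(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected) / scale), rel_tol)
}
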