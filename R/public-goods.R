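#' Public-goods model parameters
#'
#' Producer/free-rider dynamics under logistic growth.  Producers (type
#' 1, frequency `u`) pay a production cost `kappa`; the good raises the
#' growth rate of everyone linearly in the producer frequency, giving
#' frequency-dependent birth factors \eqn{f_1 = \alpha(1+\beta u) -
#' \kappa} and \eqn{f_2 = \alpha(1+\beta u)}.  Density dependence is
#' logistic, \eqn{g(s) = 1 - s/K}, and the per-capita death rate is the
#' constant `mu`.  The cost `kappa` is the small parameter: selection is
#' weak when `kappa` is small.
#'
#' @param alpha baseline growth rate \eqn{\alpha > 0} (1/time).
#' @param beta public-good impact \eqn{\beta \ge 0} (dimensionless).
#' @param kappa production cost \eqn{\kappa \ge 0} (1/time); the
#'   selection strength.
#' @param K carrying capacity (size units).
#' @param mu per-capita death rate, `0 <= mu < alpha` (1/time), which
#'   guarantees a positive ecological equilibrium for every producer
#'   frequency.
#' @param a initial producer frequency in `[0, 1]`.
#' @param b initial total population size, positive.
#' @return An object of class `"pg_params"`.
#' @export
pg_params <- function(alpha = 1, beta = 1, kappa = 0.1, K = 1, mu = 0.2,
                      a = 0.5, b = 0.01) {
  stopifnot(alpha > 0, beta >= 0, kappa >= 0, K > 0,
            mu >= 0, mu < alpha, a >= 0, a <= 1, b > 0)
  structure(list(alpha = alpha, beta = beta, kappa = kappa, K = K, mu = mu,
                 a = a, b = b), class = "pg_params")
}

#' @export
print.pg_params <- function(x, ...) {
  cat(sprintf(paste0("<pg_params> alpha=%g beta=%g kappa=%g K=%g mu=%g ",
                     "(u,s)(0)=(%g, %g)\n"),
              x$alpha, x$beta, x$kappa, x$K, x$mu, x$a, x$b))
  invisible(x)
}

#' Public-goods model as a generic weak-selection model specification
#'
#' Instantiates the generic framework for the public-goods game:
#' `f0(u) = alpha (1 + beta u1)`, `d0 = mu`, `phi = (-1, 0)` (producers
#' pay the cost), `eta = (0, 0)`, `g(s) = 1 - s/K`, `h = 1`, and
#' `epsilon = kappa`.
#'
#' @param p a [pg_params()].
#' @return A [model_spec()] with two genotypes (producer, free-rider).
#' @export
pg_model_spec <- function(p) {
  stopifnot(inherits(p, "pg_params"))
  model_spec(
    n_types = 2L,
    rates = rate_decomposition(
      f0 = function(u) p$alpha * (1 + p$beta * u[1L]),
      d0 = function(u) p$mu,
      phi = function(u) c(-1, 0),
      eta = function(u) c(0, 0),
      g = function(s) 1 - s / p$K,
      h = function(s) 1
    ),
    epsilon = p$kappa
  )
}

#' Full public-goods dynamics in producer frequency and total size
#'
#' \deqn{du/dt = -\kappa u (1-u)(1 - s/K)}
#' \deqn{ds/dt = -\kappa s u (1 - s/K) + \alpha(1+\beta u) s (1 - s/K)
#'       - \mu s}
#'
#' @param u producer frequency in `[0, 1]`.
#' @param s total population size, non-negative.
#' @param p a [pg_params()].
#' @return Named vector `c(du, ds)`.
#' @export
pg_full_rhs <- function(u, s, p) {
  lf <- 1 - s / p$K
  c(du = -p$kappa * u * (1 - u) * lf,
    ds = -p$kappa * s * u * lf + p$alpha * (1 + p$beta * u) * s * lf -
      p$mu * s)
}

#' Inner (ecological time scale) expansion of the public-goods model
#'
#' Zeroth order: the producer frequency is frozen and the size follows
#' logistic growth at the frozen composition,
#' \deqn{du_0/dt = 0, \quad
#'       ds_0/dt = \alpha(1+\beta u_0) s_0 (1 - s_0/K) - \mu s_0.}
#' First order (the corrections are co-integrated with the zeroth order):
#' \deqn{du_1/dt = -u_0 (1-u_0)(1 - s_0/K)}
#' \deqn{ds_1/dt = -s_0 u_0 (1 - s_0/K)
#'       + \alpha(1+\beta u_0) s_1 (1 - 2 s_0/K)
#'       + \alpha\beta u_1 s_0 (1 - s_0/K) - \mu s_1.}
#'
#' @param order 0 or 1.
#' @param state named numeric vector: `c(u0, s0)` for order 0,
#'   `c(u0, s0, u1, s1)` for order 1.
#' @param p a [pg_params()].
#' @return Named derivative vector of the same length as `state`.
#' @export
pg_inner_rhs <- function(order, state, p) {
  stopifnot(order %in% c(0, 1))
  u0 <- state[["u0"]]
  s0 <- state[["s0"]]
  lf <- 1 - s0 / p$K
  ds0 <- p$alpha * (1 + p$beta * u0) * s0 * lf - p$mu * s0
  if (order == 0) return(c(u0 = 0, s0 = ds0))
  u1 <- state[["u1"]]
  s1 <- state[["s1"]]
  du1 <- -u0 * (1 - u0) * lf
  ds1 <- -s0 * u0 * lf +
    p$alpha * (1 + p$beta * u0) * s1 * (1 - 2 * s0 / p$K) +
    p$alpha * p$beta * u1 * s0 * lf - p$mu * s1
  c(u0 = 0, s0 = ds0, u1 = du1, s1 = ds1)
}

#' Outer equilibrium density of the public-goods model
#'
#' The non-trivial solution of
#' \eqn{\alpha(1+\beta U_0) S_0 (1 - S_0/K) = \mu S_0}:
#' \deqn{S_0 = K\left(1 - \frac{\mu}{\alpha(1+\beta U_0)}\right),}
#' positive whenever \eqn{\mu < \alpha(1+\beta U_0)}.
#'
#' @param U0 producer frequency.
#' @param p a [pg_params()].
#' @return The equilibrium density.
#' @export
pg_outer_S0 <- function(U0, p) {
  growth <- p$alpha * (1 + p$beta * U0)
  if (any(p$mu >= growth))
    stop("nonpositive equilibrium density: mu >= alpha (1 + beta U0)",
         call. = FALSE)
  p$K * (1 - p$mu / growth)
}

#' Zeroth-order outer (evolutionary time scale) dynamics
#'
#' Replicator dynamics of the producer frequency on \eqn{\tau = \kappa t}
#' with the density slaved to [pg_outer_S0()]:
#' \deqn{dU_0/d\tau = -\frac{\mu}{\alpha(1+\beta U_0)} U_0 (1 - U_0).}
#' Producers always decline (for `mu > 0`): the selection intensity is
#' the death-limited logistic gap \eqn{1 - S_0/K = \mu/(\alpha(1+\beta
#' U_0))}.
#'
#' @inheritParams pg_outer_S0
#' @return `dU0/dtau`.
#' @export
pg_outer_zeroth_rhs <- function(U0, p) {
  growth <- p$alpha * (1 + p$beta * U0)
  if (any(p$mu >= growth))
    stop("nonpositive equilibrium density: mu >= alpha (1 + beta U0)",
         call. = FALSE)
  -(p$mu / growth) * U0 * (1 - U0)
}

#' First-order outer correction of the public-goods model
#'
#' Collecting the next power of `kappa` in the slow-time expansion gives
#' an algebraic (solvability) equation for the density correction `S1`
#' and an ODE for the frequency correction `U1`.  With
#' \eqn{m = \mu/(\alpha(1+\beta U_0)) = 1 - S_0/K}:
#' \deqn{dS_0/d\tau = -\frac{K\beta\mu^2}{\alpha^2 (1+\beta U_0)^3}
#'       U_0(1-U_0)}
#' \deqn{S_1 = \frac{dS_0/d\tau + S_0 (1 - S_0/K)(U_0 - \alpha\beta U_1)}
#'       {\alpha(1+\beta U_0)(1 - 2S_0/K) - \mu}}
#' \deqn{dU_1/d\tau = U_0(1-U_0)\frac{S_1}{K} + (2U_0 - 1)\, U_1\, m.}
#' The `S1` denominator equals \eqn{\mu - \alpha(1+\beta U_0) < 0} under
#' the positivity condition `mu < alpha (1 + beta U0)`; this is asserted
#' at run time.
#'
#' @param U0 zeroth-order producer frequency.
#' @param U1 first-order frequency correction.
#' @param p a [pg_params()].
#' @return A list with `dS0_dtau`, `S1` and `dU1_dtau`.
#' @export
pg_outer_first_rhs <- function(U0, U1, p) {
  growth <- p$alpha * (1 + p$beta * U0)
  if (any(p$mu >= growth))
    stop("nonpositive equilibrium density: mu >= alpha (1 + beta U0)",
         call. = FALSE)
  S0 <- pg_outer_S0(U0, p)
  m <- p$mu / growth                     # = 1 - S0/K
  dS0 <- -(p$K * p$beta * p$mu^2 / (p$alpha^2 * (1 + p$beta * U0)^3)) *
    U0 * (1 - U0)
  denom <- growth * (1 - 2 * S0 / p$K) - p$mu
  if (any(denom >= 0))
    stop("vanishing or positive S1 denominator; requires ",
         "mu < alpha (1 + beta U0)", call. = FALSE)
  S1 <- (dS0 + S0 * m * (U0 - p$alpha * p$beta * U1)) / denom
  dU1 <- U0 * (1 - U0) * S1 / p$K + (2 * U0 - 1) * U1 * m
  list(dS0_dtau = dS0, S1 = S1, dU1_dtau = dU1)
}

#' Invariant-manifold producer-frequency equation
#'
#' Closed slow-manifold reduction of the producer frequency,
#' \deqn{du/dt = -\frac{\mu\kappa}{\alpha(1+\beta u) - u\kappa}
#'       u(1-u),}
#' obtained by eliminating the density along the invariant manifold of
#' the full system.  A first-order Taylor expansion of the prefactor in
#' `kappa`, followed by the rescaling \eqn{\tau = \kappa t}, recovers the
#' zeroth-order outer dynamics [pg_outer_zeroth_rhs()]; this serves as an
#' independent cross-check of the slow dynamics.
#'
#' @param u producer frequency.
#' @param p a [pg_params()].
#' @return `du/dt` on the fast time scale.
#' @export
pg_invariant_manifold_rhs <- function(u, p) {
  denom <- p$alpha * (1 + p$beta * u) - u * p$kappa
  if (any(denom <= 0))
    stop("nonpositive denominator alpha (1 + beta u) - u kappa",
         call. = FALSE)
  -(p$mu * p$kappa / denom) * u * (1 - u)
}

#' Simulate the public-goods model at a chosen approximation level
#'
#' Integrates the requested system on the fast-time grid `times` and
#' returns producer frequency `u` and total size `s`:
#' \describe{
#'   \item{`full`}{the exact coupled dynamics [pg_full_rhs()].}
#'   \item{`inner0`}{zeroth-order ecological approximation (frozen `u`).}
#'   \item{`inner1`}{first-order ecological approximation, assembled as
#'     `u0 + kappa*u1`, `s0 + kappa*s1` with corrections started at 0.}
#'   \item{`outer0`}{zeroth-order evolutionary approximation, integrated
#'     on `tau = kappa*t` and reported on the `t` grid with the density
#'     slaved to [pg_outer_S0()].}
#'   \item{`outer1`}{first-order evolutionary approximation,
#'     `U0 + kappa*U1` and `S0 + kappa*S1` with `U1(0) = 0`.}
#'   \item{`composite0`}{zeroth-order matched composite,
#'     `inner(t) + outer(kappa t) - overlap` (see [pg_composite()]).}
#' }
#'
#' @param p a [pg_params()].
#' @param times strictly increasing fast-time grid starting at 0.
#' @param level approximation level, see Details.
#' @return An [trajectory()] with columns `u` and `s`.
#' @export
pg_simulate <- function(p, times,
                        level = c("full", "inner0", "inner1",
                                  "outer0", "outer1", "composite0")) {
  stopifnot(inherits(p, "pg_params"))
  level <- match.arg(level)
  switch(level,
    full = {
      rhs <- function(t, y) pg_full_rhs(y[["u"]], y[["s"]], p)
      integrate_ode(rhs, c(u = p$a, s = p$b), times)
    },
    inner0 = {
      rhs <- function(t, y) pg_inner_rhs(0, y, p)
      tr <- integrate_ode(rhs, c(u0 = p$a, s0 = p$b), times)
      trajectory(times, data.frame(u = tr$states$u0, s = tr$states$s0),
                 "inner_t")
    },
    inner1 = {
      rhs <- function(t, y) pg_inner_rhs(1, y, p)
      tr <- integrate_ode(rhs, c(u0 = p$a, s0 = p$b, u1 = 0, s1 = 0), times)
      st <- tr$states
      trajectory(times,
                 data.frame(u = st$u0 + p$kappa * st$u1,
                            s = st$s0 + p$kappa * st$s1),
                 "inner_t")
    },
    outer0 = {
      ot <- pg_outer_trajectory(p, p$kappa * times, order = 0)
      trajectory(times, ot$states, "inner_t")
    },
    outer1 = {
      ot <- pg_outer_trajectory(p, p$kappa * times, order = 1)
      trajectory(times, ot$states, "inner_t")
    },
    composite0 = pg_composite(p, times)
  )
}

#' Outer trajectory of the public-goods model on the slow time grid
#'
#' @param p a [pg_params()].
#' @param tau_times strictly increasing slow-time grid
#'   (\eqn{\tau = \kappa t}).
#' @param order 0 or 1.
#' @return An [trajectory()] tagged `"outer_tau"` with columns `u`, `s`.
#' @export
pg_outer_trajectory <- function(p, tau_times, order = 0) {
  stopifnot(order %in% c(0, 1))
  if (order == 0) {
    rhs <- function(t, y) c(U0 = pg_outer_zeroth_rhs(y[["U0"]], p))
    tr <- integrate_ode(rhs, c(U0 = p$a), tau_times, timescale = "outer_tau")
    U0 <- tr$states$U0
    return(trajectory(tau_times,
                      data.frame(u = U0, s = pg_outer_S0(U0, p)),
                      "outer_tau"))
  }
  rhs <- function(t, y) {
    fo <- pg_outer_first_rhs(y[["U0"]], y[["U1"]], p)
    c(U0 = pg_outer_zeroth_rhs(y[["U0"]], p), U1 = fo$dU1_dtau)
  }
  tr <- integrate_ode(rhs, c(U0 = p$a, U1 = 0), tau_times,
                      timescale = "outer_tau")
  U0 <- tr$states$U0
  U1 <- tr$states$U1
  S1 <- mapply(function(a0, a1) pg_outer_first_rhs(a0, a1, p)$S1, U0, U1)
  trajectory(tau_times,
             data.frame(u = U0 + p$kappa * U1,
                        s = pg_outer_S0(U0, p) + p$kappa * S1),
             "outer_tau")
}

#' Zeroth-order composite solution of the public-goods model
#'
#' Matched-asymptotic composite, uniformly valid across the ecological
#' and evolutionary time scales:
#' \deqn{u_c(t) = u_0(t) + U_0(\kappa t) - a, \quad
#'       s_c(t) = s_0(t) + S_0(\kappa t) -
#'       K\left(1 - \frac{\mu}{\alpha(1+\beta a)}\right),}
#' where `a` is the initial producer frequency and the subtracted terms
#' are the overlap (the common limit of inner and outer solutions).  At
#' `t = 0` the composite reproduces the initial condition exactly.
#'
#' @param p a [pg_params()].
#' @param t_grid strictly increasing fast-time grid starting at 0.
#' @param order approximation order; only 0 is defined.
#' @return An [trajectory()] tagged `"composite_t"` with columns `u`, `s`.
#' @export
pg_composite <- function(p, t_grid, order = 0) {
  if (!identical(as.numeric(order), 0))
    stop("unsupported order: only the zeroth-order composite is defined",
         call. = FALSE)
  if (p$kappa <= 0)
    stop("the composite requires kappa > 0 (the slow time is tau = kappa t)",
         call. = FALSE)
  inner <- {
    rhs <- function(t, y) pg_inner_rhs(0, y, p)
    tr <- integrate_ode(rhs, c(u0 = p$a, s0 = p$b), t_grid)
    trajectory(t_grid, data.frame(u = tr$states$u0, s = tr$states$s0),
               "inner_t")
  }
  outer <- pg_outer_trajectory(p, p$kappa * t_grid, order = 0)
  overlap <- c(u = p$a, s = pg_outer_S0(p$a, p))
  composite_zeroth(inner, outer, overlap, p$kappa)
}
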