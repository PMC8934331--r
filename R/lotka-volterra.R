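#' Lotka-Volterra predator-competition parameters
#'
#' One prey `x` and two competing predators: a wild type `y1` and an
#' invader `y2` that is a factor `1 + epsilon` better at feeding on the
#' prey.  For small `epsilon` the invader's advantage is weak and the
#' fraction of wild-type predators evolves slowly while prey and total
#' predator numbers follow fast Lotka-Volterra cycles.
#'
#' @param alpha prey growth rate (1/time).
#' @param beta predation rate (1/(size time)).
#' @param delta conversion rate of prey into predators (1/(size time)).
#' @param gamma predator death rate (1/time).
#' @param epsilon invader advantage, \eqn{\varepsilon \ge 0}
#'   (dimensionless); the selection strength.
#' @param x0,y1_0,y2_0 initial prey, wild-type predator and invader
#'   sizes, all positive.
#' @return An object of class `"lv_params"`.
#' @export
lv_params <- function(alpha = 0.2, beta = 1, delta = 0.5, gamma = 1,
                      epsilon = 0.05, x0 = 1, y1_0 = 1, y2_0 = 0.01) {
  stopifnot(alpha > 0, beta > 0, delta > 0, gamma > 0, epsilon >= 0,
            x0 > 0, y1_0 > 0, y2_0 > 0)
  structure(list(alpha = alpha, beta = beta, delta = delta, gamma = gamma,
                 epsilon = epsilon, x0 = x0, y1_0 = y1_0, y2_0 = y2_0),
            class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat(sprintf(paste0("<lv_params> alpha=%g beta=%g delta=%g gamma=%g ",
                     "epsilon=%g (x,y1,y2)(0)=(%g, %g, %g)\n"),
              x$alpha, x$beta, x$delta, x$gamma, x$epsilon,
              x$x0, x$y1_0, x$y2_0))
  invisible(x)
}

#' Full Lotka-Volterra system in species abundances
#'
#' \deqn{dx/dt = \alpha x - \beta x (y_1 + (1+\varepsilon) y_2)}
#' \deqn{dy_1/dt = \delta x y_1 - \gamma y_1}
#' \deqn{dy_2/dt = \delta (1+\varepsilon) x y_2 - \gamma y_2}
#'
#' @param x prey size.
#' @param y1 wild-type predator size.
#' @param y2 invading predator size.
#' @param p an [lv_params()].
#' @return Named vector `c(dx, dy1, dy2)`.
#' @export
lv_full_rhs <- function(x, y1, y2, p) {
  c(dx = p$alpha * x - p$beta * x * (y1 + (1 + p$epsilon) * y2),
    dy1 = p$delta * x * y1 - p$gamma * y1,
    dy2 = p$delta * (1 + p$epsilon) * x * y2 - p$gamma * y2)
}

#' Lotka-Volterra system in prey, predator fraction and predator total
#'
#' The exact image of [lv_full_rhs()] under `s = y1 + y2`,
#' `u = y1/(y1 + y2)`:
#' \deqn{dx/dt = \alpha x - \beta x s (1 + \varepsilon(1-u))}
#' \deqn{du/dt = -\varepsilon \delta x u (1-u)}
#' \deqn{ds/dt = \varepsilon \delta s x (1-u) + \delta s x - \gamma s}
#' The wild-type fraction follows replicator-type dynamics with selection
#' intensity \eqn{\varepsilon \delta x} set by the instantaneous prey
#' density.
#'
#' @param x prey size.
#' @param u wild-type fraction of the predator population, in `[0, 1]`.
#' @param s total predator size.
#' @param p an [lv_params()].
#' @return Named vector `c(dx, du, ds)`.
#' @export
lv_uvs_rhs <- function(x, u, s, p) {
  c(dx = p$alpha * x - p$beta * x * s * (1 + p$epsilon * (1 - u)),
    du = -p$epsilon * p$delta * x * u * (1 - u),
    ds = p$epsilon * p$delta * s * x * (1 - u) + p$delta * s * x -
      p$gamma * s)
}

#' Predator subsystem as a generic weak-selection model specification
#'
#' At a frozen prey density `x` the two-predator subsystem has the
#' generic weak-selection form: baseline birth `f0 = delta * x`, death
#' `d0 = gamma`, perturbations `phi = (0, delta * x)` (the invader's
#' feeding advantage), `eta = (0, 0)`, and no density dependence
#' (`g = h = 1`).  The generic [full_rhs()] of this specification
#' reproduces the `(du, ds)` rows of [lv_uvs_rhs()] exactly; the prey
#' equation is model-specific and lives outside the generic form.
#'
#' @param p an [lv_params()].
#' @param x prey density at which the subsystem is evaluated.
#' @return A [model_spec()] with two genotypes (wild type, invader).
#' @export
lv_predator_model_spec <- function(p, x) {
  stopifnot(inherits(p, "lv_params"), is.numeric(x), length(x) == 1L)
  force(x)
  model_spec(
    n_types = 2L,
    rates = rate_decomposition(
      f0 = function(u) p$delta * x,
      d0 = function(u) p$gamma,
      phi = function(u) c(0, p$delta * x),
      eta = function(u) c(0, 0),
      g = function(s) 1,
      h = function(s) 1
    ),
    epsilon = p$epsilon
  )
}

#' Inner (ecological time scale) expansion of the Lotka-Volterra model
#'
#' Zeroth order is a classical one-prey/one-predator system in
#' `(x0, s0)` with the wild-type fraction frozen:
#' \deqn{dx_0/dt = \alpha x_0 - \beta x_0 s_0, \quad du_0/dt = 0, \quad
#'       ds_0/dt = \delta s_0 x_0 - \gamma s_0.}
#' First order:
#' \deqn{dx_1/dt = \alpha x_1 - \beta(x_0(s_1 + s_0(1-u_0)) + x_1 s_0)}
#' \deqn{du_1/dt = -\delta x_0 u_0 (1-u_0)}
#' \deqn{ds_1/dt = \delta s_0 x_0 (1-u_0) + \delta(x_0 s_1 + x_1 s_0)
#'       - \gamma s_1.}
#' The wild-type fraction decreases at first order whenever the prey are
#' present and both predators coexist (\eqn{x_0 u_0 (1-u_0) > 0}).
#'
#' @param order 0 or 1.
#' @param state named numeric vector: `c(x0, u0, s0)` for order 0,
#'   `c(x0, u0, s0, x1, u1, s1)` for order 1.
#' @param p an [lv_params()].
#' @return Named derivative vector of the same length as `state`.
#' @export
lv_inner_rhs <- function(order, state, p) {
  stopifnot(order %in% c(0, 1))
  x0 <- state[["x0"]]
  u0 <- state[["u0"]]
  s0 <- state[["s0"]]
  dx0 <- p$alpha * x0 - p$beta * x0 * s0
  ds0 <- p$delta * s0 * x0 - p$gamma * s0
  if (order == 0) return(c(x0 = dx0, u0 = 0, s0 = ds0))
  x1 <- state[["x1"]]
  u1 <- state[["u1"]]
  s1 <- state[["s1"]]
  dx1 <- p$alpha * x1 -
    p$beta * (x0 * (s1 + s0 * (1 - u0)) + x1 * s0)
  du1 <- -p$delta * x0 * u0 * (1 - u0)
  ds1 <- p$delta * s0 * x0 * (1 - u0) +
    p$delta * (x0 * s1 + x1 * s0) - p$gamma * s1
  c(x0 = dx0, u0 = 0, s0 = ds0, x1 = dx1, u1 = du1, s1 = ds1)
}

#' Zeroth-order outer (evolutionary time scale) dynamics
#'
#' On the slow time \eqn{\tau = \varepsilon t} the prey and total
#' predator populations sit at the coexistence steady state of the
#' fast cycle's mean field, \eqn{X_0 = \gamma/\delta},
#' \eqn{S_0 = \alpha/\beta}, and the wild-type fraction follows a
#' replicator equation with constant selection coefficient equal to the
#' predator death rate:
#' \deqn{dU_0/d\tau = -\delta X_0\, U_0 (1-U_0) = -\gamma\, U_0 (1-U_0).}
#'
#' @param p an [lv_params()].
#' @return A list with the steady states `X0`, `S0` and a function
#'   `rhs(U0)` giving `dU0/dtau`.
#' @export
lv_outer_zeroth <- function(p) {
  stopifnot(inherits(p, "lv_params"))
  list(X0 = p$gamma / p$delta,
       S0 = p$alpha / p$beta,
       rhs = function(U0) -p$gamma * U0 * (1 - U0))
}

#' Closed-form zeroth-order outer solution
#'
#' The replicator equation with constant selection coefficient `gamma`
#' is separable: starting from wild-type fraction `a`,
#' \deqn{U_0(\tau) = \frac{a}{a + (1-a) e^{\gamma\tau}}.}
#'
#' @param a initial wild-type fraction.
#' @param tau slow time (vectorised).
#' @param p an [lv_params()].
#' @return `U0(tau)`.
#' @export
lv_outer_zeroth_solution <- function(a, tau, p) {
  a / (a + (1 - a) * exp(p$gamma * tau))
}

#' First-order outer corrections of the Lotka-Volterra model
#'
#' At first order the prey and predator totals acquire algebraic
#' corrections, \eqn{X_1 = -(\gamma/\delta)(1-U_0)} and
#' \eqn{S_1 = -(\alpha/\beta)(1-U_0)} (both populations sit slightly
#' below the wild-type steady state while the invader is rare), and the
#' frequency correction obeys
#' \deqn{dU_1/d\tau = -\delta X_0 U_1 (1 - 2U_0)
#'       - \delta X_1 U_0 (1-U_0).}
#'
#' @param U0 zeroth-order wild-type fraction.
#' @param U1 first-order frequency correction.
#' @param p an [lv_params()].
#' @return A list with `X1`, `S1` and `dU1_dtau`.
#' @export
lv_outer_first <- function(U0, U1, p) {
  X0 <- p$gamma / p$delta
  X1 <- -(p$gamma / p$delta) * (1 - U0)
  S1 <- -(p$alpha / p$beta) * (1 - U0)
  dU1 <- -p$delta * X0 * U1 * (1 - 2 * U0) -
    p$delta * X1 * U0 * (1 - U0)
  list(X1 = X1, S1 = S1, dU1_dtau = dU1)
}

#' Initial state of the Lotka-Volterra model in `(x, u, s)` variables
#'
#' @param p an [lv_params()].
#' @return Named vector `c(x, u, s)` derived from the abundance initial
#'   condition.
#' @export
lv_initial_state <- function(p) {
  s <- p$y1_0 + p$y2_0
  c(x = p$x0, u = p$y1_0 / s, s = s)
}

#' Simulate the Lotka-Volterra model at a chosen approximation level
#'
#' Integrates the requested system on the fast-time grid `times` and
#' returns prey `x`, wild-type fraction `u` and predator total `s`:
#' \describe{
#'   \item{`full`}{the exact `(x, u, s)` dynamics [lv_uvs_rhs()].}
#'   \item{`inner0`}{zeroth-order ecological approximation (fast cycle,
#'     frozen `u`).}
#'   \item{`inner1`}{first-order ecological approximation, assembled as
#'     `x0 + eps*x1` etc., corrections started at 0.}
#'   \item{`outer0`}{zeroth-order evolutionary approximation on
#'     `tau = eps*t`, reported on the `t` grid with `x`, `s` at their
#'     steady states.}
#'   \item{`outer1`}{first-order evolutionary approximation with the
#'     algebraic corrections of [lv_outer_first()] and `U1(0) = 0`.}
#' }
#'
#' @param p an [lv_params()].
#' @param times strictly increasing fast-time grid starting at 0.
#' @param level approximation level, see Details.
#' @return An [trajectory()] with columns `x`, `u`, `s`.
#' @export
lv_simulate <- function(p, times,
                        level = c("full", "inner0", "inner1",
                                  "outer0", "outer1")) {
  stopifnot(inherits(p, "lv_params"))
  level <- match.arg(level)
  y0 <- lv_initial_state(p)
  switch(level,
    full = {
      rhs <- function(t, y) lv_uvs_rhs(y[["x"]], y[["u"]], y[["s"]], p)
      integrate_ode(rhs, y0, times)
    },
    inner0 = {
      rhs <- function(t, y) lv_inner_rhs(0, y, p)
      tr <- integrate_ode(rhs, c(x0 = y0[["x"]], u0 = y0[["u"]],
                                 s0 = y0[["s"]]), times)
      st <- tr$states
      trajectory(times, data.frame(x = st$x0, u = st$u0, s = st$s0),
                 "inner_t")
    },
    inner1 = {
      rhs <- function(t, y) lv_inner_rhs(1, y, p)
      tr <- integrate_ode(rhs, c(x0 = y0[["x"]], u0 = y0[["u"]],
                                 s0 = y0[["s"]], x1 = 0, u1 = 0, s1 = 0),
                          times)
      st <- tr$states
      trajectory(times,
                 data.frame(x = st$x0 + p$epsilon * st$x1,
                            u = st$u0 + p$epsilon * st$u1,
                            s = st$s0 + p$epsilon * st$s1),
                 "inner_t")
    },
    outer0 = {
      oz <- lv_outer_zeroth(p)
      tau <- p$epsilon * times
      rhs <- function(t, y) c(U0 = oz$rhs(y[["U0"]]))
      tr <- integrate_ode(rhs, c(U0 = y0[["u"]]), tau,
                          timescale = "outer_tau")
      trajectory(times,
                 data.frame(x = oz$X0, u = tr$states$U0, s = oz$S0),
                 "inner_t")
    },
    outer1 = {
      oz <- lv_outer_zeroth(p)
      tau <- p$epsilon * times
      rhs <- function(t, y) {
        c(U0 = oz$rhs(y[["U0"]]),
          U1 = lv_outer_first(y[["U0"]], y[["U1"]], p)$dU1_dtau)
      }
      tr <- integrate_ode(rhs, c(U0 = y0[["u"]], U1 = 0), tau,
                          timescale = "outer_tau")
      U0 <- tr$states$U0
      U1 <- tr$states$U1
      fo <- lv_outer_first(U0, U1, p)
      trajectory(times,
                 data.frame(x = oz$X0 + p$epsilon * fo$X1,
                            u = U0 + p$epsilon * U1,
                            s = oz$S0 + p$epsilon * fo$S1),
                 "inner_t")
    }
  )
}

#' Assemble a Lotka-Volterra approximation trajectory
#'
#' Convenience wrapper around [lv_simulate()] restricted to the
#' approximation levels (the full solution is obtained with
#' `lv_simulate(p, times, "full")`).
#'
#' @param level one of `"inner0"`, `"inner1"`, `"outer0"`, `"outer1"`.
#' @param p an [lv_params()].
#' @param t_grid strictly increasing fast-time grid.
#' @return An [trajectory()] with columns `x`, `u`, `s`.
#' @export
lv_assemble_approximation <- function(level, p, t_grid) {
  level <- match.arg(level, c("inner0", "inner1", "outer0", "outer1"))
  lv_simulate(p, t_grid, level)
}

#' First integral of the zeroth-order Lotka-Volterra cycle
#'
#' The conserved quantity
#' \eqn{\delta x - \gamma \log x + \beta s - \alpha \log s} of the
#' classical prey/predator cycle; useful for checking integration
#' accuracy of the zeroth-order inner system.
#'
#' @param x prey size (vectorised).
#' @param s predator total (vectorised).
#' @param p an [lv_params()].
#' @return The invariant evaluated at `(x, s)`.
#' @export
lv_first_integral <- function(x, s, p) {
  p$delta * x - p$gamma * log(x) + p$beta * s - p$alpha * log(s)
}
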