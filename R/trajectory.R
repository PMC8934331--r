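#' Trajectory container
#'
#' A time grid with one state per time point and a time-scale tag, so
#' that fast-time (`t`) and slow-time (`tau = epsilon * t`) objects
#' cannot be mixed by accident.
#'
#' @param times strictly increasing numeric time grid.
#' @param states data frame (or coercible matrix) with one row per time
#'   point; columns are named state variables (e.g. `u`, `s`, `x`).
#' @param timescale one of `"inner_t"` (fast/ecological time `t`),
#'   `"outer_tau"` (slow/evolutionary time `tau`), `"composite_t"`
#'   (matched composite, reported on `t`).
#' @return An object of class `"eesep_trajectory"` with fields `times`,
#'   `states`, `timescale`.
#' @export
trajectory <- function(times, states,
                       timescale = c("inner_t", "outer_tau", "composite_t")) {
  timescale <- match.arg(timescale)
  stopifnot(is.numeric(times), length(times) >= 1L)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  states <- as.data.frame(states)
  if (nrow(states) != length(times))
    stop("'states' must have one row per time point", call. = FALSE)
  structure(list(times = times, states = states, timescale = timescale),
            class = "eesep_trajectory")
}

#' @export
print.eesep_trajectory <- function(x, ...) {
  cat(sprintf("<eesep_trajectory> %d points on [%g, %g] (%s), variables: %s\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              x$timescale, paste(names(x$states), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.eesep_trajectory <- function(x, ...) {
  cbind(data.frame(time = x$times), x$states,
        data.frame(timescale = x$timescale))
}

#' Integrate an ODE system on a fixed output grid
#'
#' Thin wrapper around the adaptive stiff/non-stiff `lsoda` integrator
#' with tight tolerances (defaults `rtol = 1e-10`, `atol = 1e-12`), far
#' below the leading perturbation error of any approximation studied
#' here, so measured convergence slopes reflect the method rather than
#' the solver.
#'
#' @param rhs function `(t, y) -> dy` returning the derivative of the
#'   state vector `y`.  Non-finite derivatives abort the integration
#'   with a diagnostic.
#' @param y0 named numeric initial state.
#' @param times strictly increasing output grid.
#' @param rtol,atol relative and absolute tolerances.
#' @param timescale time-scale tag for the returned trajectory.
#' @return An [trajectory()] sampled on `times`.
#' @export
integrate_ode <- function(rhs, y0, times, rtol = 1e-10, atol = 1e-12,
                          timescale = "inner_t") {
  stopifnot(is.function(rhs), is.numeric(y0), is.numeric(times))
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  func <- function(t, y, parms) {
    dy <- rhs(t, y)
    if (any(!is.finite(dy)))
      stop(sprintf("non-finite derivative at t = %g", t), call. = FALSE)
    list(dy)
  }
  out <- deSolve::lsoda(y = y0, times = times, func = func,
                        rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop("lsoda failed with istate = ", istate[1L],
         "; see deSolve diagnostics", call. = FALSE)
  if (nrow(out) != length(times))
    stop("integrator stopped early at t = ", out[nrow(out), 1L],
         call. = FALSE)
  states <- as.data.frame(out[, -1L, drop = FALSE])
  names(states) <- names(y0)
  trajectory(times, states, timescale)
}

#' Integrate the full weak-selection system for a generic model
#'
#' Integrates the coupled `(u, s)` dynamics of [full_rhs()] from a
#' [freq_size_state()].  Only the first N-1 frequencies are integrated;
#' the last is closed as \eqn{u_N = 1 - \sum_{i<N} u_i}, which removes
#' numerical drift off the simplex.  Negative round-off down to `-1e-9`
#' is clipped to zero and the frequencies renormalised before each
#' derivative evaluation.
#'
#' @param model a [model_spec()].
#' @param state0 initial [freq_size_state()].
#' @param times strictly increasing output grid (fast time `t`).
#' @inheritParams integrate_ode
#' @return An [trajectory()] with columns `u1 ... uN` and `s`.
#' @export
simulate_full <- function(model, state0, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "model_spec"),
            inherits(state0, "freq_size_state"))
  n <- model$n_types
  if (length(state0$u) != n)
    stop("initial state has ", length(state0$u), " frequencies but the ",
         "model has ", n, " genotypes", call. = FALSE)
  y0 <- c(state0$u[seq_len(n - 1L)], state0$s)
  names(y0) <- c(paste0("u", seq_len(n - 1L)), "s")

  rhs <- function(t, y) {
    u <- close_simplex(y[seq_len(n - 1L)])
    d <- full_rhs(freq_size_state(u, max(y[n], 0)), model)
    c(d$du[seq_len(n - 1L)], d$ds)
  }
  tr <- integrate_ode(rhs, y0, times, rtol = rtol, atol = atol)
  uhead <- as.matrix(tr$states[, seq_len(n - 1L), drop = FALSE])
  ulast <- pmax(1 - rowSums(uhead), 0)
  states <- cbind(as.data.frame(uhead), ulast, tr$states$s)
  names(states) <- c(paste0("u", seq_len(n)), "s")
  trajectory(times, states, "inner_t")
}

## rebuild the full simplex vector from its first N-1 components
close_simplex <- function(uhead) {
  uhead[uhead < 0 & uhead > -1e-9] <- 0
  u <- c(uhead, 1 - sum(uhead))
  if (u[length(u)] < 0 && u[length(u)] > -1e-9) u[length(u)] <- 0
  u / sum(u)
}

#' Matched-asymptotic composite solution (zeroth order)
#'
#' Combines an inner (fast-time) and an outer (slow-time) trajectory into
#' a single approximation uniformly valid on both time scales:
#' componentwise `composite(t) = inner(t) + outer(eps * t) - overlap`,
#' where the overlap is the common matching limit
#' \eqn{\lim_{t\to\infty} \mathrm{inner} = \lim_{\tau\to 0}
#' \mathrm{outer}}.  The outer trajectory must be sampled on
#' `tau = epsilon * times(inner)`; the matching condition is checked and
#' a mismatch beyond `1e-6` signals an unmatched-expansion error.
#'
#' @param inner trajectory tagged `"inner_t"`.
#' @param outer trajectory tagged `"outer_tau"`, same state columns,
#'   sampled at `epsilon * inner$times`.
#' @param overlap_state the common limit as a [freq_size_state()] or a
#'   named numeric vector matching the state columns.
#' @param epsilon the selection strength linking the two time scales.
#' @return An [trajectory()] tagged `"composite_t"` on the inner grid.
#' @export
composite_zeroth <- function(inner, outer, overlap_state, epsilon) {
  stopifnot(inherits(inner, "eesep_trajectory"),
            inherits(outer, "eesep_trajectory"))
  if (inner$timescale != "inner_t" || outer$timescale != "outer_tau")
    stop("'inner' must be tagged inner_t and 'outer' outer_tau",
         call. = FALSE)
  if (!identical(names(inner$states), names(outer$states)))
    stop("inner and outer trajectories must share state columns",
         call. = FALSE)
  if (max(abs(outer$times - epsilon * inner$times)) >
      1e-9 * max(1, epsilon * max(abs(inner$times))))
    stop("outer trajectory must be sampled at tau = epsilon * t",
         call. = FALSE)

  overlap <- overlap_as_vector(overlap_state, names(inner$states))
  nlast <- length(inner$times)
  inner_lim <- as.numeric(inner$states[nlast, ])
  outer_init <- as.numeric(outer$states[1L, ])
  if (max(abs(inner_lim - overlap)) > 1e-6 ||
      max(abs(outer_init - overlap)) > 1e-6)
    stop("unmatched expansion: inner long-time limit and outer initial ",
         "value do not agree with the overlap within 1e-6", call. = FALSE)

  comp <- as.matrix(inner$states) + as.matrix(outer$states) -
    matrix(overlap, nrow = nlast, ncol = length(overlap), byrow = TRUE)
  trajectory(inner$times, as.data.frame(comp), "composite_t")
}

overlap_as_vector <- function(overlap_state, cols) {
  if (inherits(overlap_state, "freq_size_state")) {
    v <- c(overlap_state$u, overlap_state$s)
    if (length(v) != length(cols))
      stop("overlap state does not match trajectory columns", call. = FALSE)
    return(v)
  }
  stopifnot(is.numeric(overlap_state))
  if (!is.null(names(overlap_state))) overlap_state <- overlap_state[cols]
  if (length(overlap_state) != length(cols) || anyNA(overlap_state))
    stop("overlap state does not match trajectory columns", call. = FALSE)
  as.numeric(overlap_state)
}
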