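#' Full coupled frequency/size dynamics
#'
#' Right-hand side of the weak-selection system in the `(u, s)` variables:
#' \deqn{du_i/dt = \varepsilon u_i[(\phi_i - \bar\phi) g(s) -
#'       (\eta_i - \bar\eta) h(s)]}
#' \deqn{ds/dt = \varepsilon s[g(s)\bar\phi - h(s)\bar\eta] +
#'       s[g(s) f_0(u) - h(s) d_0(u)]}
#' with \eqn{\bar\phi = \sum_j u_j \phi_j} and
#' \eqn{\bar\eta = \sum_j u_j \eta_j}.  The frequency derivatives sum to
#' zero, so trajectories stay on the simplex.  At `s = 0` (extinction)
#' all derivatives are zero.
#'
#' @param state a [freq_size_state()].
#' @param model a [model_spec()].
#' @return A list with components `du` (length-N vector) and `ds`.
#' @export
full_rhs <- function(state, model) {
  stopifnot(inherits(state, "freq_size_state"), inherits(model, "model_spec"))
  u <- state$u
  s <- state$s
  if (s == 0) return(list(du = numeric(length(u)), ds = 0))
  r <- model$rates
  phi <- r$phi(u)
  eta <- r$eta(u)
  phib <- sum(u * phi)
  etab <- sum(u * eta)
  gs <- r$g(s)
  hs <- r$h(s)
  du <- model$epsilon * u * ((phi - phib) * gs - (eta - etab) * hs)
  ds <- model$epsilon * s * (gs * phib - hs * etab) +
    s * (gs * r$f0(u) - hs * r$d0(u))
  list(du = du, ds = ds)
}

#' Zeroth-order inner (ecological) dynamics
#'
#' To zeroth order in the selection strength the frequencies are frozen,
#' \eqn{du_{i0}/dt = 0}, and the total size follows
#' \eqn{ds_0/dt = s_0[g(s_0) f_0(u_0) - h(s_0) d_0(u_0)]}: pure density
#' dynamics at the initial genotype composition.
#'
#' @inheritParams full_rhs
#' @return A list with components `du` (exact zeros) and `ds`.
#' @export
inner_zeroth_rhs <- function(state, model) {
  stopifnot(inherits(state, "freq_size_state"), inherits(model, "model_spec"))
  u <- state$u
  s <- state$s
  du <- numeric(length(u))
  if (s == 0) return(list(du = du, ds = 0))
  r <- model$rates
  list(du = du, ds = s * (r$g(s) * r$f0(u) - r$h(s) * r$d0(u)))
}

#' Ecological equilibrium density at fixed genotype composition
#'
#' Solves \eqn{g(S) f_0(u_0) = h(S) d_0(u_0)} for the equilibrium density
#' `S` by scanning the bracket for sign changes of the residual
#' \eqn{r(S) = g(S) f_0(u_0) - h(S) d_0(u_0)} and applying Brent root
#' finding to each sub-bracket.  A root is flagged stable when
#' \eqn{g'(S^\ast) f_0(u_0) < h'(S^\ast) d_0(u_0)} (derivatives by
#' central finite differences with step `1e-6 * max(1, |S*|)`).
#'
#' When several stable roots exist, the one attained by the ecological
#' dynamics depends on the initial density: supply `s_init` and the root
#' closest to the long-time limit of the zeroth-order inner dynamics
#' started from `(u0, s_init)` is selected.  All roots found are reported.
#'
#' @param u0 frequency vector (held fixed).
#' @param model a [model_spec()].
#' @param bracket positive interval `c(lower, upper)` to search.
#' @param s_init optional initial density used to disambiguate between
#'   multiple stable equilibria.
#' @param n_scan number of uniform scan points across the bracket.
#' @return An object of class `"eesep_equilibrium"`: a list with
#'   `s_star`, `stable`, `bracket`, `residual` and a data frame `roots`
#'   of all roots found with their stability flags.
#' @export
ecological_equilibrium <- function(u0, model, bracket, s_init = NULL,
                                   n_scan = 200L) {
  stopifnot(inherits(model, "model_spec"), is.numeric(bracket),
            length(bracket) == 2L, bracket[1] < bracket[2], bracket[1] > 0)
  r <- model$rates
  f0u <- r$f0(u0)
  d0u <- r$d0(u0)
  resid <- function(S) r$g(S) * f0u - r$h(S) * d0u

  grid <- seq(bracket[1], bracket[2], length.out = n_scan)
  vals <- vapply(grid, resid, numeric(1L))
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1L)) {
    if (vals[i] == 0) {
      roots <- c(roots, grid[i])
    } else if (vals[i] * vals[i + 1L] < 0) {
      roots <- c(roots, stats::uniroot(resid, c(grid[i], grid[i + 1L]),
                                       tol = 1e-12)$root)
    }
  }
  if (vals[n_scan] == 0) roots <- c(roots, grid[n_scan])
  roots <- unique(roots)
  if (length(roots) == 0L)
    stop("no ecological equilibrium: residual g(S) f0 - h(S) d0 has no ",
         "sign change in the bracket", call. = FALSE)

  is_stable <- vapply(roots, function(S) {
    step <- 1e-6 * max(1, abs(S))
    gp <- (r$g(S + step) - r$g(S - step)) / (2 * step)
    hp <- (r$h(S + step) - r$h(S - step)) / (2 * step)
    gp * f0u < hp * d0u
  }, logical(1L))

  stable_roots <- roots[is_stable]
  if (length(stable_roots) == 0L) {
    s_star <- roots[1L]
  } else if (length(stable_roots) == 1L) {
    s_star <- stable_roots
  } else {
    if (is.null(s_init))
      stop("multiple stable equilibria found; supply 's_init' so the ",
           "basin reached by the ecological dynamics can be identified",
           call. = FALSE)
    s_lim <- inner_settle(u0, model, s_init)
    s_star <- stable_roots[which.min(abs(stable_roots - s_lim))]
  }

  structure(list(
    s_star = s_star,
    stable = is_stable[match(s_star, roots)],
    bracket = bracket,
    residual = resid(s_star),
    roots = data.frame(s = roots, stable = is_stable)
  ), class = "eesep_equilibrium")
}

## long-time limit of the zeroth-order density dynamics from s_init
inner_settle <- function(u0, model, s_init, t_end = 1e3) {
  r <- model$rates
  rhs <- function(t, y) y * (r$g(y) * r$f0(u0) - r$h(y) * r$d0(u0))
  out <- integrate_ode(rhs, c(s = s_init), times = c(0, t_end))
  unname(out$states$s[2L])
}

#' @export
print.eesep_equilibrium <- function(x, ...) {
  cat(sprintf("<eesep_equilibrium> S* = %.10g (%s), %d root(s) in [%g, %g]\n",
              x$s_star, if (x$stable) "stable" else "unstable",
              nrow(x$roots), x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Zeroth-order outer (evolutionary) dynamics
#'
#' Density-modulated replicator dynamics on the slow time scale
#' \eqn{\tau = \varepsilon t}, with the density slaved to its ecological
#' equilibrium \eqn{S_0^\ast}:
#' \deqn{dU_{i0}/d\tau = U_{i0}[(\phi_i - \bar\phi) g(S_0^\ast) -
#'       (\eta_i - \bar\eta) h(S_0^\ast)].}
#'
#' @param U0 frequency vector on the simplex.
#' @param model a [model_spec()].
#' @param s_star equilibrium density: a positive number or an
#'   `"eesep_equilibrium"` (which must be stable).
#' @return The frequency derivative in \eqn{\tau} (sums to zero).
#' @export
outer_zeroth_rhs <- function(U0, model, s_star) {
  stopifnot(inherits(model, "model_spec"))
  if (inherits(s_star, "eesep_equilibrium")) {
    if (!isTRUE(s_star$stable))
      stop("invalid equilibrium: the outer dynamics require a stable ",
           "ecological equilibrium", call. = FALSE)
    s_star <- s_star$s_star
  }
  r <- model$rates
  phi <- r$phi(U0)
  eta <- r$eta(U0)
  phib <- sum(U0 * phi)
  etab <- sum(U0 * eta)
  U0 * ((phi - phib) * r$g(s_star) - (eta - etab) * r$h(s_star))
}
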