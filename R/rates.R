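#' Weak-selection decomposition of birth and death rates
#'
#' Factorises the per-capita birth rate of genotype i as
#' \eqn{F_i(x) = (f_0(u) + \varepsilon\,\phi_i(u))\, g(s)} and the death rate
#' as \eqn{D_i(x) = (d_0(u) + \varepsilon\,\eta_i(u))\, h(s)}, where
#' `u` is the vector of genotype frequencies and `s` the total population
#' size.  The baseline factors `f0`, `d0` are shared by all genotypes; the
#' perturbations `phi`, `eta` carry the (weak, order-epsilon) fitness
#' differences; `g`, `h` carry the density dependence.
#'
#' @param f0,d0 functions of the frequency vector returning a scalar
#'   baseline birth / death factor (units 1/time).
#' @param phi,eta either a single function of the frequency vector
#'   returning a length-N numeric vector, or a list of N functions each
#'   returning a scalar.  Dimensionless perturbations to birth / death.
#' @param g,h functions of the total size `s` returning a scalar
#'   dimensionless density factor on birth / death.
#'
#' @return An object of class `"rate_decomposition"`.
#' @examples
#' # public-goods rates: producers pay a cost, benefit beta*u is shared
#' rd <- rate_decomposition(
#'   f0 = function(u) 1 + u[1], d0 = function(u) 0.2,
#'   phi = function(u) c(-1, 0), eta = function(u) c(0, 0),
#'   g = function(s) 1 - s, h = function(s) 1)
#' @export
rate_decomposition <- function(f0, d0, phi, eta, g, h) {
  stopifnot(is.function(f0), is.function(d0), is.function(g), is.function(h))
  out <- list(
    f0 = f0, d0 = d0,
    phi = as_vector_fn(phi, "phi"),
    eta = as_vector_fn(eta, "eta"),
    g = g, h = h
  )
  structure(out, class = "rate_decomposition")
}

## accept a list of per-genotype functions or one vector-valued function
as_vector_fn <- function(f, what) {
  if (is.function(f)) return(f)
  if (is.list(f) && all(vapply(f, is.function, logical(1L)))) {
    fns <- f
    return(function(u) vapply(fns, function(fi) fi(u), numeric(1L)))
  }
  stop("'", what, "' must be a function or a list of functions", call. = FALSE)
}

#' Model specification
#'
#' Bundles the number of genotypes, the weak-selection rate decomposition
#' and the selection strength epsilon into a single model object.
#'
#' @param n_types number of genotypes N (integer, at least 2).
#' @param rates a [rate_decomposition()].
#' @param epsilon selection strength \eqn{\varepsilon \ge 0}
#'   (dimensionless).  `epsilon = 0` is the neutral limit in which
#'   frequencies do not move.
#'
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(n_types, rates, epsilon) {
  n_types <- as.integer(n_types)
  stopifnot(length(n_types) == 1L, n_types >= 2L)
  if (!inherits(rates, "rate_decomposition"))
    stop("'rates' must be a rate_decomposition", call. = FALSE)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  structure(list(n_types = n_types, rates = rates, epsilon = epsilon),
            class = "model_spec")
}

#' Frequency/size state
#'
#' Population state as genotype frequencies `u` on the simplex plus total
#' population size `s` (so that abundances are \eqn{x_i = s u_i}).
#'
#' @param u numeric frequency vector; must sum to 1 within 1e-9 and each
#'   component must lie in `[-1e-9, 1 + 1e-9]` (small negative round-off
#'   is tolerated and clipped).
#' @param s total population size, non-negative.
#'
#' @return An object of class `"freq_size_state"` with fields `u` and `s`.
#' @export
freq_size_state <- function(u, s) {
  stopifnot(is.numeric(u), length(u) >= 1L, is.numeric(s), length(s) == 1L)
  if (s < 0) stop("total size 's' must be non-negative", call. = FALSE)
  if (any(u < -1e-9) || any(u > 1 + 1e-9))
    stop("frequencies must lie in [0, 1] (tolerance 1e-9)", call. = FALSE)
  if (abs(sum(u) - 1) > 1e-9)
    stop("frequencies must sum to 1 (tolerance 1e-9)", call. = FALSE)
  u <- pmin(pmax(u, 0), 1)
  structure(list(u = u, s = s), class = "freq_size_state")
}

#' Change of variables: abundances to frequencies plus total size
#'
#' Maps genotype abundances \eqn{x} to \eqn{u_i = x_i / \sum_j x_j} and
#' \eqn{s = \sum_i x_i}.
#'
#' @param x non-negative abundance vector with positive sum.
#' @return A [freq_size_state()].
#' @seealso [abundances_from_frequencies()] for the inverse map.
#' @export
frequencies_from_abundances <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(x)
  if (s <= 0)
    stop("degenerate population: all abundances are zero", call. = FALSE)
  freq_size_state(x / s, s)
}

#' Change of variables: frequencies plus total size to abundances
#'
#' @param state a [freq_size_state()].
#' @return Numeric abundance vector \eqn{x_i = s u_i}.
#' @export
abundances_from_frequencies <- function(state) {
  stopifnot(inherits(state, "freq_size_state"))
  state$s * state$u
}

#' @export
print.rate_decomposition <- function(x, ...) {
  cat("<rate_decomposition> f0,d0 baselines; phi,eta perturbations;",
      "g,h density factors\n")
  invisible(x)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> N = %d genotypes, epsilon = %g\n",
              x$n_types, x$epsilon))
  invisible(x)
}

#' @export
print.freq_size_state <- function(x, ...) {
  cat(sprintf("<freq_size_state> u = (%s), s = %g\n",
              paste(signif(x$u, 6), collapse = ", "), x$s))
  invisible(x)
}
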