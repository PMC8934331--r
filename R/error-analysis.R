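#' Total error between a reference and an approximate trajectory
#'
#' The L2-in-time deviation
#' \deqn{E = \left(\int_0^{T_{max}} \sum_{c} (\mathrm{ref}_c(t) -
#'       \mathrm{approx}_c(t))^2\, dt\right)^{1/2},}
#' computed by composite trapezoid quadrature on the shared time grid.
#' Both trajectories must be sampled on the identical grid and live on
#' the same time scale (a slow-time `outer_tau` trajectory cannot be
#' compared against a fast-time one).
#'
#' @param reference,approx [trajectory()] objects on the same grid.
#' @param components character vector of state columns to include;
#'   default: all columns shared by both trajectories.
#' @return The scalar total error `E >= 0`
#'   (state units times sqrt(time)).
#' @export
total_error <- function(reference, approx, components = NULL) {
  stopifnot(inherits(reference, "eesep_trajectory"),
            inherits(approx, "eesep_trajectory"))
  if (length(reference$times) != length(approx$times) ||
      max(abs(reference$times - approx$times)) >
        1e-12 * max(1, max(abs(reference$times))))
    stop("trajectories are not on the identical time grid", call. = FALSE)
  if (xor(reference$timescale == "outer_tau",
          approx$timescale == "outer_tau"))
    stop("cannot compare trajectories on different time scales ",
         "(fast t vs slow tau)", call. = FALSE)
  if (is.null(components))
    components <- intersect(names(reference$states), names(approx$states))
  missing <- setdiff(components,
                     intersect(names(reference$states),
                               names(approx$states)))
  if (length(missing) > 0L)
    stop("components not present in both trajectories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  resid <- as.matrix(reference$states[, components, drop = FALSE]) -
    as.matrix(approx$states[, components, drop = FALSE])
  sq <- rowSums(resid^2)
  sqrt(pracma::trapz(reference$times, sq))
}

#' Error curve from a selection-strength sweep
#'
#' @param eps_values strictly monotone positive grid of selection
#'   strengths.
#' @param errors total error per value (may contain `NA` for dropped
#'   points).
#' @param meta named list of metadata (model, level, t_max, components).
#' @return An object of class `"eesep_error_curve"`.
#' @export
error_curve <- function(eps_values, errors, meta = list()) {
  stopifnot(is.numeric(eps_values), all(eps_values > 0),
            length(eps_values) == length(errors))
  d <- diff(eps_values)
  if (!(all(d > 0) || all(d < 0)))
    stop("'eps_values' must be strictly monotone", call. = FALSE)
  if (any(errors < 0, na.rm = TRUE))
    stop("errors must be non-negative", call. = FALSE)
  structure(list(eps_values = eps_values, errors = errors, meta = meta),
            class = "eesep_error_curve")
}

#' @export
print.eesep_error_curve <- function(x, ...) {
  cat(sprintf("<eesep_error_curve> %s / %s: %d points, eps in [%g, %g]\n",
              x$meta$model %||% "?", x$meta$level %||% "?",
              length(x$eps_values), min(x$eps_values), max(x$eps_values)))
  print(data.frame(epsilon = x$eps_values, error = x$errors))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.data.frame.eesep_error_curve <- function(x, ...) {
  data.frame(epsilon = x$eps_values, error = x$errors)
}

#' Run an error-scaling sweep over the selection strength
#'
#' For each value of the selection strength, integrates the full model
#' and the requested approximation level from identical initial
#' conditions on a uniform grid over `[0, t_max]` and records the
#' [total_error()].  The sweep is deterministic given its configuration;
#' if the integrator fails at some value the point is dropped (recorded
#' as `NA`) with a warning.
#'
#' Default study conditions: 10 logarithmically spaced selection
#' strengths on `[1e-3, 1e-1]`; the uniform quadrature grid has 20
#' points per unit time (capped at 1e6 points); the public-goods sweep
#' compares `u` and `s` over an ecological window `t_max = 20` (the
#' matched composite is instead compared over `t_max = 2000`, spanning
#' both time scales), and the Lotka-Volterra sweep compares the
#' wild-type fraction `u` over `t_max = 20`.
#'
#' @param model `"public_goods"` or `"lotka_volterra"`.
#' @param level approximation level passed to [pg_simulate()] /
#'   [lv_simulate()] (e.g. `"inner0"`, `"inner1"`, `"composite0"`).
#' @param eps_grid positive, strictly monotone sweep grid; default
#'   `10^seq(-3, -1, length.out = 10)`.
#' @param t_max end of the comparison window (fast time); default by
#'   model and level, see Details.
#' @param base_params a [pg_params()] / [lv_params()] whose selection
#'   strength is overridden by each sweep value; default the model
#'   defaults.
#' @param components state columns entering the error; default by model,
#'   see Details.
#' @param points_per_unit_time density of the uniform comparison grid.
#' @return An [error_curve()].
#' @export
run_scaling_experiment <- function(model = c("public_goods",
                                             "lotka_volterra"),
                                   level,
                                   eps_grid = NULL,
                                   t_max = NULL,
                                   base_params = NULL,
                                   components = NULL,
                                   points_per_unit_time = 20) {
  model <- match.arg(model)
  if (is.null(eps_grid)) eps_grid <- 10^seq(-3, -1, length.out = 10)
  stopifnot(all(eps_grid > 0))

  if (model == "public_goods") {
    if (is.null(base_params)) base_params <- pg_params()
    if (is.null(t_max)) t_max <- if (identical(level, "composite0")) 2000 else 20
    if (is.null(components)) components <- c("u", "s")
    simulate <- function(p, times, lev) pg_simulate(p, times, lev)
    set_eps <- function(p, e) { p$kappa <- e; p }
  } else {
    if (is.null(base_params)) base_params <- lv_params()
    if (is.null(t_max)) t_max <- 20
    if (is.null(components)) components <- "u"
    simulate <- function(p, times, lev) lv_simulate(p, times, lev)
    set_eps <- function(p, e) { p$epsilon <- e; p }
  }

  times <- time_grid(t_max, points_per_unit_time)
  errors <- vapply(eps_grid, function(e) {
    p <- set_eps(base_params, e)
    tryCatch({
      full <- simulate(p, times, "full")
      approx <- simulate(p, times, level)
      total_error(full, approx, components)
    }, error = function(cnd) {
      warning("sweep point eps = ", signif(e, 4), " dropped: ",
              conditionMessage(cnd), call. = FALSE)
      NA_real_
    })
  }, numeric(1L))

  error_curve(eps_grid, errors,
              meta = list(model = model, level = level, t_max = t_max,
                          components = components,
                          n_time = length(times)))
}

#' Uniform comparison grid
#'
#' `points_per_unit_time` points per unit of time on `[0, t_max]`,
#' capped at 1e6 points.
#'
#' @param t_max end time.
#' @param points_per_unit_time grid density.
#' @return Numeric vector of time points starting at 0.
#' @export
time_grid <- function(t_max, points_per_unit_time = 20) {
  n <- min(round(points_per_unit_time * t_max) + 1, 1e6)
  seq(0, t_max, length.out = n)
}

#' Fit a log-log convergence slope to an error curve
#'
#' Ordinary least squares of `log10(E)` on `log10(eps)`.  Non-positive
#' or missing errors are excluded with a warning; at least four points
#' must remain.  For an order-`k` perturbation approximation the slope
#' estimates the convergence exponent `k + 1`.
#'
#' @param curve an [error_curve()].
#' @return An object of class `"eesep_slope_fit"` with `slope`,
#'   `intercept` and `residual_rms`.
#' @export
fit_loglog_slope <- function(curve) {
  stopifnot(inherits(curve, "eesep_error_curve"))
  ok <- is.finite(curve$errors) & curve$errors > 0
  if (any(!ok))
    warning(sum(!ok), " non-positive or missing error value(s) excluded ",
            "from the slope fit", call. = FALSE)
  if (sum(ok) < 4L)
    stop("slope fit requires at least 4 positive error values",
         call. = FALSE)
  lx <- log10(curve$eps_values[ok])
  ly <- log10(curve$errors[ok])
  fit <- stats::lm(ly ~ lx)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    n_points = sum(ok)
  ), class = "eesep_slope_fit")
}

#' @export
print.eesep_slope_fit <- function(x, ...) {
  cat(sprintf(
    "<eesep_slope_fit> slope = %.4f (intercept %.4f, residual RMS %.2g, %d points)\n",
    x$slope, x$intercept, x$residual_rms, x$n_points))
  invisible(x)
}
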