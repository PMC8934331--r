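#' Read a simulation configuration from JSON
#'
#' Schema:
#' \preformatted{
#' {
#'   "model": "public_goods" | "lotka_volterra",
#'   "params": { ... },          # model parameters incl. initial condition
#'   "level": "full" | "inner0" | "inner1" | "outer0" | "outer1"
#'            | "composite0",    # composite0: public_goods only
#'   "t_max": 20,
#'   "n_grid": 401,              # optional; default 20 points/unit time
#'   "eps_grid": [ ... ],        # optional; scaling sweeps only
#'   "components": ["u", "s"]    # optional; scaling sweeps only
#' }
#' }
#' Public-goods `params` keys: `alpha`, `beta`, `kappa`, `K`, `mu` and
#' the initial condition `u0`, `s0`.  Lotka-Volterra keys: `alpha`,
#' `beta`, `delta`, `gamma`, `epsilon`, `x0`, `y1_0`, `y2_0`.
#'
#' @param path path to a JSON file.
#' @return The parsed configuration list (validated).
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$model) ||
      !cfg$model %in% c("public_goods", "lotka_volterra"))
    stop("config 'model' must be \"public_goods\" or \"lotka_volterra\"",
         call. = FALSE)
  if (is.null(cfg$level)) cfg$level <- "full"
  if (is.null(cfg$t_max)) cfg$t_max <- 20
  stopifnot(is.numeric(cfg$t_max), cfg$t_max > 0)
  cfg
}

#' Build a parameter object from a configuration
#'
#' @param cfg a configuration list as returned by [read_model_config()].
#' @return A [pg_params()] or [lv_params()].
#' @export
params_from_config <- function(cfg) {
  cfg <- validate_config(cfg)
  pl <- as.list(cfg$params %||% list())
  if (cfg$model == "public_goods") {
    # u0/s0 in the config are the initial condition (a, b)
    if (!is.null(pl$u0)) { pl$a <- pl$u0; pl$u0 <- NULL }
    if (!is.null(pl$s0)) { pl$b <- pl$s0; pl$s0 <- NULL }
    do.call(pg_params, pl)
  } else {
    do.call(lv_params, pl)
  }
}

#' Simulate a model from a configuration
#'
#' @param cfg a configuration list as returned by [read_model_config()].
#' @return An [trajectory()].
#' @export
simulate_from_config <- function(cfg) {
  cfg <- validate_config(cfg)
  p <- params_from_config(cfg)
  times <- if (!is.null(cfg$n_grid)) {
    seq(0, cfg$t_max, length.out = cfg$n_grid)
  } else {
    time_grid(cfg$t_max)
  }
  if (cfg$model == "public_goods") {
    pg_simulate(p, times, cfg$level)
  } else {
    lv_simulate(p, times, cfg$level)
  }
}

#' Run a scaling sweep from a configuration
#'
#' @param cfg a configuration list; `level` selects the approximation,
#'   `eps_grid`, `t_max` and `components` override the defaults of
#'   [run_scaling_experiment()].
#' @return A list with the [error_curve()] and the
#'   [fit_loglog_slope()] fit.
#' @export
scaling_from_config <- function(cfg) {
  has_tmax <- !is.null(cfg$t_max)
  cfg <- validate_config(cfg)
  curve <- run_scaling_experiment(
    model = cfg$model,
    level = cfg$level,
    eps_grid = cfg$eps_grid,
    t_max = if (has_tmax) cfg$t_max else NULL,
    base_params = params_from_config(cfg),
    components = cfg$components
  )
  list(curve = curve, fit = fit_loglog_slope(curve))
}

#' Write a trajectory to CSV
#'
#' Columns: `time`, the state variables in their trajectory order, and
#' `timescale`; numbers are written with 15 significant digits.
#'
#' @param traj an [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "eesep_trajectory"))
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an error curve and its slope fit
#'
#' Emits `<prefix>_errors.csv` with columns `epsilon,error` and
#' `<prefix>_slope.json` with the fitted slope and sweep metadata.
#'
#' @param result a list with elements `curve` and `fit`, as returned by
#'   [scaling_from_config()].
#' @param prefix output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_scaling_outputs <- function(result, prefix) {
  stopifnot(inherits(result$curve, "eesep_error_curve"),
            inherits(result$fit, "eesep_slope_fit"))
  csv <- paste0(prefix, "_errors.csv")
  js <- paste0(prefix, "_slope.json")
  df <- as.data.frame(result$curve)
  df[] <- lapply(df, function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(df, csv, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- result$curve$meta
  jsonlite::write_json(list(
    model = meta$model, level = meta$level,
    slope = result$fit$slope, intercept = result$fit$intercept,
    rms = result$fit$residual_rms,
    eps_grid = result$curve$eps_values, t_max = meta$t_max
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(errors = csv, slope = js))
}
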