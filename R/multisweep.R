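# Multilevel two-parameter grid search. Each level lays a rectangular grid
# around the current center spanning center*(1 +/- percent) per axis,
# evaluates the black box at every cell, scores it against the target with
# the summed squared error, recenters on the argmin and shrinks the range
# geometrically for the next level.

#' Configure a multilevel two-parameter sweep
#'
#' @param param_names two distinct parameter names (dotted field paths for
#'   XML-configured models, or plain names for in-process fixture models).
#' @param initial_point two numeric values: the starting center of the search.
#' @param points_per_direction grid resolution `n` per axis (integer >= 1);
#'   each level evaluates `n^2` cells.
#' @param percent_per_direction fraction in (0, 1]: the first level spans
#'   `center * (1 - p)` to `center * (1 + p)` on each axis.
#' @param n_levels number of refinement levels (integer >= 1).
#' @param shrink_factor fraction in (0, 1): the per-level multiplier applied
#'   to `percent_per_direction`. Default 0.5 halves the search range each
#'   level.
#' @param lower_bounds per-axis lower clip for grid values; default `c(0, 0)`
#'   (rates, speeds and capacities are nonnegative).
#' @param upper_bounds per-axis upper clip; default unbounded. Set to 1 for
#'   parameters confined to \[0, 1\] such as a migration bias.
#' @param error_metric `"sse"` (positionally paired, e.g. growth curves) or
#'   `"sse_sorted"` (distribution comparison via sorted values / quantiles,
#'   e.g. final cell positions). See [sse()].
#' @param replicate_aggregation `"mean"` or `"median"`: how replicate metric
#'   vectors are combined per grid cell before the error is computed.
#' @return an object of class `sweep_config`.
#' @seealso [run_sweep()]
#' @export
sweep_config <- function(param_names, initial_point,
                         points_per_direction, percent_per_direction,
                         n_levels, shrink_factor = 0.5,
                         lower_bounds = c(0, 0), upper_bounds = c(Inf, Inf),
                         error_metric = c("sse", "sse_sorted"),
                         replicate_aggregation = c("mean", "median")) {
  error_metric <- match.arg(error_metric)
  replicate_aggregation <- match.arg(replicate_aggregation)
  param_names <- as.character(param_names)
  if (length(param_names) != 2 || anyDuplicated(param_names))
    stop("`param_names` must be two distinct names")
  initial_point <- as.numeric(initial_point)
  if (length(initial_point) != 2 || any(!is.finite(initial_point)))
    stop("`initial_point` must be two finite values")
  points_per_direction <- as.integer(points_per_direction)
  if (is.na(points_per_direction) || points_per_direction < 1)
    stop("`points_per_direction` must be an integer >= 1")
  if (!is.numeric(percent_per_direction) || percent_per_direction <= 0 ||
      percent_per_direction > 1)
    stop("`percent_per_direction` must lie in (0, 1]")
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 1) stop("`n_levels` must be an integer >= 1")
  if (!is.numeric(shrink_factor) || shrink_factor <= 0 || shrink_factor >= 1)
    stop("`shrink_factor` must lie in (0, 1)")
  lower_bounds <- rep_len(as.numeric(lower_bounds), 2)
  upper_bounds <- rep_len(as.numeric(upper_bounds), 2)
  if (any(upper_bounds <= lower_bounds)) stop("upper bounds must exceed lower bounds")
  structure(list(param_names = param_names, initial_point = initial_point,
                 points_per_direction = points_per_direction,
                 percent_per_direction = percent_per_direction,
                 n_levels = n_levels, shrink_factor = shrink_factor,
                 lower_bounds = lower_bounds, upper_bounds = upper_bounds,
                 error_metric = error_metric,
                 replicate_aggregation = replicate_aggregation),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat("<sweep_config> ", paste(x$param_names, collapse = " x "), "\n", sep = "")
  cat(sprintf("  initial point (%g, %g); %d points/direction; %g%%/direction; %d levels (shrink %g)\n",
              x$initial_point[1], x$initial_point[2], x$points_per_direction,
              100 * x$percent_per_direction, x$n_levels, x$shrink_factor))
  cat("  error: ", x$error_metric, ", replicates aggregated by ",
      x$replicate_aggregation, "\n", sep = "")
  invisible(x)
}

#' Read a sweep configuration from YAML
#'
#' Keys mirror the [sweep_config()] arguments; two extra sections are
#' recognized: `target: {file: <csv>}` naming the target-data vector (path
#' resolved relative to the YAML file), and an optional `model:` section
#' (`fixture: logistic|chemotaxis`, or `exe:`/`config:`/`metric:`/`replicates:`
#' for an external executable) consumed by [cmd_sweep()].
#'
#' @param path YAML file path.
#' @return list with `config` (a `sweep_config`), `target_file`, `model`.
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path)) stop("sweep config not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(sweep_config)))]
  config <- do.call(sweep_config, args)
  target_file <- y$target$file
  if (!is.null(target_file) && !grepl("^/", target_file))
    target_file <- file.path(dirname(path), target_file)
  list(config = config, target_file = target_file, model = y$model)
}

#' Build the two axis grids of one sweep level
#'
#' Per axis, `n` values linearly spaced over `center * (1 - percent)` to
#' `center * (1 + percent)` (endpoints inclusive; `n = 1` returns the center
#' itself), then clipped to the bounds. An axis whose values all clip to one
#' point collapses to that single value, with a warning.
#'
#' @param center two numeric values.
#' @param percent fraction in (0, 1].
#' @param n points per direction.
#' @param lower_bounds,upper_bounds per-axis clips (length 2).
#' @return list with numeric vectors `axis1`, `axis2`.
#' @examples
#' build_grid(c(0.15, 1000), percent = 0.5, n = 8)
#' @export
build_grid <- function(center, percent, n, lower_bounds = c(0, 0),
                       upper_bounds = c(Inf, Inf)) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2, n >= 1, percent > 0, percent <= 1)
  lower_bounds <- rep_len(as.numeric(lower_bounds), 2)
  upper_bounds <- rep_len(as.numeric(upper_bounds), 2)
  axis <- function(k) {
    c0 <- center[k]
    v <- if (n == 1) c0
         else seq(c0 * (1 - percent), c0 * (1 + percent), length.out = n)
    v <- pmin(pmax(v, lower_bounds[k]), upper_bounds[k])
    if (n > 1 && length(unique(v)) == 1L) {
      warning("axis ", k, " collapsed to the single value ", v[1],
              " after clipping", call. = FALSE)
      v <- v[1]
    }
    v
  }
  list(axis1 = axis(1), axis2 = axis(2))
}

.aggregate_metrics <- function(metrics, how) {
  if (length(metrics) == 1) return(metrics[[1]])
  len <- lengths(metrics)
  if (length(unique(len)) != 1)
    stop("replicate metric vectors differ in length")
  mat <- do.call(rbind, metrics)
  if (how == "mean") colMeans(mat) else apply(mat, 2, stats::median)
}

.error_fun <- function(metric_name) {
  switch(metric_name,
    sse = function(s, t) sse(s, t, align = "paired"),
    sse_sorted = function(s, t) sse(s, t, align = "sorted"),
    stop("unknown error metric: ", metric_name))
}

#' Evaluate one grid level of a sweep
#'
#' Evaluates the black box at every grid cell (replicates aggregated per cell,
#' then scored against the target), in row-major order with axis 1 as the
#' outer loop. The best cell is the first argmin in that order. A cell whose
#' simulation fails scores `+Inf` with a warning; a level where every cell
#' fails is an error.
#'
#' @param model a [black_box()] object.
#' @param grid axis list from [build_grid()].
#' @param target numeric target vector.
#' @param param_names two parameter names for addressing the axes.
#' @param seed base seed passed to every cell (common random numbers), with
#'   replicates offset internally by [run_model()].
#' @param error_metric,aggregation see [sweep_config()].
#' @param level,center,percent metadata recorded in the result.
#' @return an object of class `grid_level`: list with `axis1`, `axis2`,
#'   `cells` (data frame: the two parameters and `error`, row-major), and
#'   `best` (list with `params`, `error`).
#' @export
run_level <- function(model, grid, target, param_names, seed = 0L,
                      error_metric = "sse", aggregation = "mean",
                      level = 1L, center = NULL, percent = NA_real_) {
  a1 <- grid$axis1; a2 <- grid$axis2
  if (length(a1) == 0 || length(a2) == 0) stop("grid must be non-empty")
  err_fun <- .error_fun(error_metric)
  p1 <- rep(a1, each = length(a2))   # row-major: axis 1 varies slowest
  p2 <- rep(a2, times = length(a1))
  errs <- numeric(length(p1))
  for (k in seq_along(p1)) {
    params <- stats::setNames(c(p1[k], p2[k]), param_names)
    errs[k] <- tryCatch({
      metrics <- run_model(model, params, seed)
      if (!all(vapply(metrics, is.numeric, logical(1))))
        stop("model returned a non-numeric metric; supply a processor")
      agg <- .aggregate_metrics(metrics, aggregation)
      err_fun(agg, target)
    }, error = function(e) {
      warning(sprintf("simulation failed at (%s = %g, %s = %g): %s",
                      param_names[1], p1[k], param_names[2], p2[k],
                      conditionMessage(e)), call. = FALSE)
      Inf
    })
  }
  if (all(!is.finite(errs))) stop("all grid cells failed at level ", level)
  b <- which.min(errs)  # first minimum in row-major order
  cells <- data.frame(p1, p2, error = errs)
  names(cells)[1:2] <- param_names
  structure(list(level = level, center = center, percent = percent,
                 axis1 = a1, axis2 = a2, cells = cells,
                 best = list(params = stats::setNames(c(p1[b], p2[b]), param_names),
                             error = errs[b])),
            class = "grid_level")
}

#' @export
print.grid_level <- function(x, ...) {
  cat(sprintf("<grid_level> level %d: %d x %d cells, best error %g at (%s)\n",
              x$level, length(x$axis1), length(x$axis2), x$best$error,
              paste(sprintf("%s = %g", names(x$best$params), x$best$params),
                    collapse = ", ")))
  invisible(x)
}

#' Fit two simulator parameters by a multilevel grid sweep
#'
#' The central fitting routine. Starting from the configured initial point,
#' each level lays an `n` x `n` grid spanning `center * (1 +/- percent)`,
#' evaluates the black-box model at every cell against the target data, takes
#' the minimum-error cell as the next center, and multiplies `percent` by the
#' shrink factor. After the last level the best cell is the parameter
#' estimate.
#'
#' All cells at all levels share the same base seed (common random numbers),
#' which makes the error surface of a stochastic model a deterministic,
#' smooth function of the parameters, and makes the whole sweep exactly
#' reproducible for a given seed.
#'
#' @param model a [black_box()] object.
#' @param config a [sweep_config()].
#' @param target numeric target vector, or a path to a target CSV.
#' @param seed integer seed.
#' @param out_dir optional directory: per level, `level_<k>_grid.csv` and
#'   `level_<k>_best.json` are written there, plus a final `estimate.json`.
#' @param verbose print per-level progress.
#' @return an object of class `multisweep`: `estimate` (named vector),
#'   `levels` (list of `grid_level`), `trajectory` (matrix of centers,
#'   initial point first), `fitted` (aggregated metric at the estimate),
#'   plus the config, target and seed. Supports [coef()], [summary()],
#'   [plot()], [fitted()] and [residuals()].
#' @examples
#' target <- generate_target("logistic", c(K = 1000, r = 0.1))
#' cfg <- sweep_config(c("r", "K"), c(0.15, 1000), 8, 0.5, n_levels = 3)
#' fit <- run_sweep(fixture_black_box("logistic"), cfg, target)
#' coef(fit)
#' @export
run_sweep <- function(model, config, target, seed = 0L, out_dir = NULL,
                      verbose = FALSE) {
  if (!inherits(config, "sweep_config")) stop("`config` must be a sweep_config")
  if (is.character(target)) target <- read_target(target)
  target <- as.numeric(target)
  if (length(target) == 0 || any(!is.finite(target)))
    stop("target must be a non-empty finite vector")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed)

  center <- stats::setNames(config$initial_point, config$param_names)
  trajectory <- matrix(center, nrow = 1,
                       dimnames = list(NULL, config$param_names))
  levels <- vector("list", config$n_levels)
  for (k in seq_len(config$n_levels)) {
    pct <- config$percent_per_direction * config$shrink_factor^(k - 1)
    grid <- build_grid(center, pct, config$points_per_direction,
                       config$lower_bounds, config$upper_bounds)
    lev <- run_level(model, grid, target, config$param_names, seed = seed,
                     error_metric = config$error_metric,
                     aggregation = config$replicate_aggregation,
                     level = k, center = center, percent = pct)
    levels[[k]] <- lev
    if (!is.null(out_dir)) {
      utils::write.csv(lev$cells,
                       file.path(out_dir, sprintf("level_%d_grid.csv", k)),
                       row.names = FALSE)
      jsonlite::write_json(list(params = as.list(lev$best$params),
                                error = lev$best$error, level = k),
                           file.path(out_dir, sprintf("level_%d_best.json", k)),
                           auto_unbox = TRUE, digits = NA)
    }
    center <- lev$best$params
    trajectory <- rbind(trajectory, center)
    if (verbose)
      message(sprintf("level %d: best (%s) error %g", k,
                      paste(sprintf("%g", center), collapse = ", "),
                      lev$best$error))
  }
  estimate <- levels[[config$n_levels]]$best$params
  fitted <- tryCatch(
    .aggregate_metrics(run_model(model, estimate, seed),
                       config$replicate_aggregation),
    error = function(e) NULL)
  res <- structure(list(estimate = estimate, levels = levels,
                        trajectory = trajectory, fitted = fitted,
                        config = config, target = target, seed = seed,
                        model_name = model$name),
                   class = "multisweep")
  if (!is.null(out_dir))
    jsonlite::write_json(list(estimate = as.list(estimate),
                              error = levels[[config$n_levels]]$best$error,
                              seed = seed),
                         file.path(out_dir, "estimate.json"),
                         auto_unbox = TRUE, digits = NA)
  res
}

#' @export
coef.multisweep <- function(object, ...) object$estimate

#' @export
print.multisweep <- function(x, ...) {
  n <- length(x$levels)
  cat("Multilevel grid sweep (", x$model_name, "), ", n, " level",
      if (n > 1) "s", "\n", sep = "")
  cat("  estimate: ", paste(sprintf("%s = %g", names(x$estimate), x$estimate),
                            collapse = ", "), "\n", sep = "")
  cat("  final error (", x$config$error_metric, "): ",
      format(x$levels[[n]]$best$error), "\n", sep = "")
  invisible(x)
}

#' @export
summary.multisweep <- function(object, ...) {
  rows <- lapply(object$levels, function(l) {
    data.frame(level = l$level, percent = l$percent,
               best1 = l$best$params[1], best2 = l$best$params[2],
               error = l$best$error, cells = nrow(l$cells))
  })
  tab <- do.call(rbind, rows)
  names(tab)[3:4] <- object$config$param_names
  rownames(tab) <- NULL
  structure(list(table = tab, estimate = object$estimate,
                 seed = object$seed, model_name = object$model_name),
            class = "summary.multisweep")
}

#' @export
print.summary.multisweep <- function(x, ...) {
  cat("Multilevel grid sweep (", x$model_name, "), seed ", x$seed, "\n\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("\nEstimate: ", paste(sprintf("%s = %g", names(x$estimate), x$estimate),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
fitted.multisweep <- function(object, ...) object$fitted

#' @export
residuals.multisweep <- function(object, ...) {
  if (is.null(object$fitted)) return(NULL)
  if (object$config$error_metric == "sse_sorted" &&
      length(object$fitted) == length(object$target))
    sort(object$fitted) - sort(object$target)
  else object$fitted - object$target
}

#' Heatmap of the error surface at one sweep level
#'
#' @param x a `multisweep` object.
#' @param level which level to draw (default: the last).
#' @param log_scale color on log10(error) (default TRUE).
#' @param ... passed to [graphics::image()].
#' @export
plot.multisweep <- function(x, level = length(x$levels), log_scale = TRUE, ...) {
  lev <- x$levels[[level]]
  z <- matrix(lev$cells$error, nrow = length(lev$axis1),
              ncol = length(lev$axis2), byrow = TRUE)
  if (log_scale) z <- log10(z + .Machine$double.eps)
  graphics::image(lev$axis1, lev$axis2, z,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = x$config$param_names[1], ylab = x$config$param_names[2],
                  main = sprintf("Level %d error surface%s", level,
                                 if (log_scale) " (log10)" else ""), ...)
  graphics::points(lev$best$params[1], lev$best$params[2], pch = 4, cex = 1.5,
                   col = "red", lwd = 2)
  invisible(x)
}
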