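# Self-contained fixture models: every stage of the calibration pipeline can
# be exercised without an external simulator. Two models are provided -- a
# closed-form logistic growth curve and a toy chemotaxis agent model (biased
# persistent random walk in a static linear gradient) -- plus a mock
# executable honoring the child-process contract and target-data generators.

# Evaluate code under a given seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# default observation grid for the logistic fixture (time units)
.LOGISTIC_T_GRID <- seq(0, 100, by = 1)

#' Logistic population growth curve
#'
#' Closed-form logistic growth,
#' \deqn{N(t) = \frac{K N_0}{N_0 + (K - N_0) e^{-r t}},}
#' where `K` is the carrying capacity (maximum population size), `N0` the
#' initial population and `r` the proliferation rate.
#'
#' @param t time point(s); any nonnegative numeric vector.
#' @param K carrying capacity (> 0).
#' @param r proliferation rate (1/time, > 0).
#' @param N0 initial population (> 0, default 10).
#' @return `N(t)`, same length as `t`.
#' @examples
#' logistic_growth(c(0, 50, 100), K = 1000, r = 0.1)
#' @export
logistic_growth <- function(t, K, r, N0 = 10) {
  if (!is.numeric(K) || K <= 0) stop("`K` must be > 0")
  if (!is.numeric(r) || r <= 0) stop("`r` must be > 0")
  if (!is.numeric(N0) || N0 <= 0) stop("`N0` must be > 0")
  K * N0 / (N0 + (K - N0) * exp(-r * t))
}

#' Simulate a chemotaxis scenario (biased persistent random walk)
#'
#' A population of cells starts near the low-y wall of a 2D domain with a
#' static linear attractant gradient pointing toward the far (+y) wall. At
#' each time step every cell moves along the unit direction
#' \deqn{d = \mathrm{normalize}\big((1-b)\,\xi + b\,\hat g\big),}
#' where `b` is the migration bias, \eqn{\hat g = (0, 1)} is the gradient
#' direction and \eqn{\xi} is a persistent random unit vector, re-drawn with
#' probability `dt / persistence_time` per step. `b = 0` is a pure persistent
#' random walk; `b = 1` is deterministic gradient following. Positions are
#' clamped at the domain walls.
#'
#' The random draws consumed per step do not depend on `speed` or `bias`, so
#' for a fixed seed the final positions are smooth functions of those two
#' parameters -- the property the grid search relies on.
#'
#' @param n_cells number of cells (default 100).
#' @param speed cell speed, micron/min (> 0).
#' @param bias migration bias in \[0, 1\].
#' @param persistence_time mean time between direction re-draws, min (> 0).
#' @param dt time step, min; must not exceed `persistence_time`.
#' @param duration total simulated time, min.
#' @param domain `c(x_min, x_max, y_min, y_max)` in micron.
#' @param y0 starting y coordinate (default: 10 micron off the low-y wall).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return data frame with columns `id`, `x`, `y`, `z` (final positions;
#'   `z = 0` for this 2D model), in cell order.
#' @examples
#' pos <- simulate_chemotaxis(n_cells = 10, speed = 2, bias = 1, seed = 1)
#' unique(pos$y)  # deterministic limit: y0 + speed * duration
#' @export
simulate_chemotaxis <- function(n_cells = 100, speed = 2.0, bias = 0.9,
                                persistence_time = 1.0, dt = 0.1,
                                duration = 120, domain = c(0, 500, 0, 500),
                                y0 = domain[3] + 10, seed = 0L) {
  if (!is.numeric(bias) || bias < 0 || bias > 1) stop("`bias` must lie in [0, 1]")
  if (speed <= 0) stop("`speed` must be > 0")
  if (persistence_time <= 0 || dt <= 0 || duration <= 0)
    stop("`persistence_time`, `dt` and `duration` must be > 0")
  if (dt > persistence_time)
    stop("`dt` must not exceed `persistence_time` (unstable persistence discretization)")
  if (length(domain) != 4 || domain[2] <= domain[1] || domain[4] <= domain[3])
    stop("`domain` must be c(x_min, x_max, y_min, y_max) with max > min")
  n_cells <- as.integer(n_cells)
  nsteps <- round(duration / dt)
  margin <- min(10, (domain[2] - domain[1]) / 4)
  x <- if (n_cells == 1) mean(domain[1:2])
       else seq(domain[1] + margin, domain[2] - margin, length.out = n_cells)
  y <- rep(y0, n_cells)
  p_redraw <- dt / persistence_time
  .with_seed(seed, {
    theta <- stats::runif(n_cells, 0, 2 * pi)
    for (s in seq_len(nsteps)) {
      u <- stats::runif(n_cells)
      ang <- stats::runif(n_cells, 0, 2 * pi)
      redraw <- u < p_redraw
      theta[redraw] <- ang[redraw]
      dx <- (1 - bias) * cos(theta)
      dy <- (1 - bias) * sin(theta) + bias
      nrm <- sqrt(dx^2 + dy^2)
      degen <- nrm < 1e-12        # random and gradient pulls cancel exactly
      dx <- ifelse(degen, 0, dx / nrm)
      dy <- ifelse(degen, 1, dy / nrm)
      x <- pmin(pmax(x + speed * dx * dt, domain[1]), domain[2])
      y <- pmin(pmax(y + speed * dy * dt, domain[3]), domain[4])
    }
  })
  data.frame(id = seq_len(n_cells) - 1L, x = x, y = y, z = 0)
}

#' In-process black-box model around a fixture
#'
#' Wraps one of the fixture models as a [black_box()] that needs no settings
#' file or child process. Parameter names: `r`, `K` for `"logistic"` (metric:
#' the growth curve on the default 0..100 time grid); `speed`, `bias` for
#' `"chemotaxis"` (metric: final y coordinates of the cells).
#'
#' @param model `"logistic"` or `"chemotaxis"`.
#' @param replicates replicate runs per evaluation.
#' @param n_cells chemotaxis population size.
#' @param ... further arguments forwarded to [simulate_chemotaxis()].
#' @return a `black_box` object.
#' @export
fixture_black_box <- function(model = c("logistic", "chemotaxis"),
                              replicates = 1L, n_cells = 100, ...) {
  model <- match.arg(model)
  extra <- list(...)
  runner <- switch(model,
    logistic = function(workdir, params, seed)
      logistic_growth(.LOGISTIC_T_GRID, K = params[["K"]], r = params[["r"]]),
    chemotaxis = function(workdir, params, seed)
      do.call(simulate_chemotaxis,
              c(list(n_cells = n_cells, speed = params[["speed"]],
                     bias = params[["bias"]], seed = seed), extra))$y
  )
  black_box(runner = runner, replicates = replicates,
            name = paste0("fixture: ", model))
}

#' Generate target data from a fixture model
#'
#' Emulates the calibration setting where target data come from a known
#' ground truth: the logistic curve on the default time grid, or the final y
#' coordinates of a chemotaxis run.
#'
#' @param model `"logistic"` or `"chemotaxis"`.
#' @param params named values: `c(K=, r=)` or `c(speed=, bias=)`.
#' @param path optional CSV output path (single `value` column).
#' @param seed seed for the stochastic chemotaxis model.
#' @param ... forwarded to [simulate_chemotaxis()].
#' @return the target vector, invisibly when `path` is given.
#' @examples
#' head(generate_target("logistic", c(K = 1000, r = 0.1)))
#' @export
generate_target <- function(model = c("logistic", "chemotaxis"), params,
                            path = NULL, seed = 0L, ...) {
  model <- match.arg(model)
  v <- switch(model,
    logistic = logistic_growth(.LOGISTIC_T_GRID, K = params[["K"]],
                               r = params[["r"]]),
    chemotaxis = simulate_chemotaxis(speed = params[["speed"]],
                                     bias = params[["bias"]],
                                     seed = seed, ...)$y
  )
  if (!is.null(path)) {
    # full round-trip precision: sweeps must see the exact generated values
    writeLines(c("value", vapply(v, .num_str, "")), path)
    return(invisible(v))
  }
  v
}

#' Write a fixture settings file
#'
#' Copies the package's valid reference settings file, optionally overriding
#' fields by dotted path. Overrides are applied without validation, so
#' deliberately invalid files (for testing constraint enforcement) can be
#' produced.
#'
#' @param path output path.
#' @param overrides named list: dotted field path -> numeric value.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' fixture_settings(f, list("cell/default/motility/speed" = 2))
#' @export
fixture_settings <- function(path, overrides = list()) {
  src <- system.file("extdata", "settings_valid.xml", package = "cellcalib")
  doc <- xml2::read_xml(src)
  for (nm in names(overrides)) {
    node <- .resolve_field(doc, nm)
    xml2::xml_text(node) <- .num_str(as.numeric(overrides[[nm]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Create a mock simulator executable
#'
#' Writes an executable Rscript that honors the external-runner contract:
#' invoked as `<exe> <settings-file>` in a workspace, it reads the settings
#' file, runs the corresponding fixture model, and writes snapshot CSVs under
#' `output/`. The chemotaxis mock reads the motility block (speed, bias,
#' persistence time) through the validated schema and the run duration from
#' `overall/max_time`; the logistic mock reads `K` and `r` from the
#' `user_parameters` block and writes one snapshot per 10 time units with
#' `round(N(t))` cell rows. The replicate seed is taken from the `CALIB_SEED`
#' environment variable.
#'
#' @param model `"logistic"` or `"chemotaxis"`.
#' @param dir directory for the script.
#' @return path to the executable script, invisibly.
#' @export
make_mock_executable <- function(model = c("logistic", "chemotaxis"), dir) {
  model <- match.arg(model)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0("mock_", model))
  libs <- paste(sprintf('"%s"', .libPaths()), collapse = ", ")
  header <- c(
    "#!/usr/bin/env Rscript",
    sprintf(".libPaths(c(%s, .libPaths()))", libs),
    "suppressMessages(library(cellcalib))",
    "args <- commandArgs(trailingOnly = TRUE)",
    'cfg <- if (length(args)) args[[1]] else "settings.xml"',
    'seed <- as.integer(Sys.getenv("CALIB_SEED", "0"))',
    'dir.create("output", showWarnings = FALSE)'
  )
  body <- switch(model,
    chemotaxis = c(
      "s <- load_config(cfg)",
      'mot <- s$tree$cells[["default"]]$motility',
      "pos <- simulate_chemotaxis(speed = mot$speed, bias = mot$migration_bias,",
      "                           persistence_time = mot$persistence_time,",
      "                           duration = s$tree$overall$max_time, seed = seed)",
      'write.csv(pos, file.path("output", "cells_00000.csv"), row.names = FALSE)'
    ),
    logistic = c(
      "doc <- xml2::read_xml(cfg)",
      'K <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "//user_parameters/K")))',
      'r <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "//user_parameters/r")))',
      "tt <- seq(0, 100, by = 10)",
      "N <- round(logistic_growth(tt, K = K, r = r))",
      "for (i in seq_along(tt)) {",
      "  n <- N[i]",
      "  df <- data.frame(id = seq_len(n) - 1L, x = numeric(n), y = numeric(n), z = numeric(n))",
      '  write.csv(df, sprintf("output/cells_%05d.csv", i - 1L), row.names = FALSE)',
      "}"
    )
  )
  writeLines(c(header, body), path)
  Sys.chmod(path, "0755")
  invisible(path)
}
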