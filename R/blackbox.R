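# Black-box model wrapper: (optional config updater) + runner + (optional
# output processor) + replicate count. The wrapper maps a named parameter set
# to one metric vector per replicate; it never aggregates -- that is the
# sweep's decision.

.check_params <- function(params) {
  params <- unlist(params)
  # empty is allowed: a model composed only of an executable needs none
  if (length(params) == 0) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(params) || any(!is.finite(params)))
    stop("parameter values must be finite numbers")
  nms <- names(params)
  if (is.null(nms) || any(!nzchar(nms))) stop("parameters must be named")
  if (anyDuplicated(nms)) stop("parameter names must be unique")
  params
}

#' Wrap a simulator as a black-box model
#'
#' A black-box model composes three stages, any of which may be absent except
#' the runner:
#' \enumerate{
#'   \item `updater(config_path, params)`: writes parameter values into the
#'     working copy of the settings file (see [xml_updater()]);
#'   \item `runner(workdir, params, seed)`: runs the simulation in `workdir`,
#'     leaving snapshot files under `workdir/output/` -- or, for in-process
#'     models, simply returning the metric vector;
#'   \item `processor(output_dir)`: reduces the snapshot files to a numeric
#'     metric vector (see [final_cell_count()], [final_coordinates()]).
#' }
#' With no processor, a runner returning a numeric vector supplies the metric
#' directly; otherwise the sorted `output/` file listing is returned as a
#' surrogate, so a model composed only of an executable still runs.
#'
#' @param runner function `(workdir, params, seed)`; see
#'   [make_external_runner()] for child-process executables.
#' @param updater optional function `(config_path, params)`.
#' @param processor optional function `(output_dir)` returning a numeric vector.
#' @param replicates number of independent replicate runs per evaluation
#'   (integer >= 1); replicate `i` receives seed `seed + i - 1`.
#' @param config optional path to a settings file copied into each workspace
#'   as `settings.xml` before the updater runs.
#' @param name label used in printing.
#' @return an object of class `black_box`.
#' @seealso [run_model()], [fixture_black_box()]
#' @export
black_box <- function(runner, updater = NULL, processor = NULL,
                      replicates = 1L, config = NULL, name = "black box") {
  if (!is.function(runner)) stop("`runner` must be a function")
  if (!is.null(updater) && !is.function(updater)) stop("`updater` must be a function")
  if (!is.null(processor) && !is.function(processor)) stop("`processor` must be a function")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("`replicates` must be an integer >= 1")
  if (!is.null(config) && !file.exists(config)) stop("config file not found: ", config)
  structure(list(runner = runner, updater = updater, processor = processor,
                 replicates = replicates, config = config, name = name),
            class = "black_box")
}

#' @export
print.black_box <- function(x, ...) {
  cat("<black_box> ", x$name, "\n", sep = "")
  cat("  replicates: ", x$replicates, "\n", sep = "")
  cat("  updater: ", if (is.null(x$updater)) "none" else "set",
      ", processor: ", if (is.null(x$processor)) "none" else "set", "\n", sep = "")
  exe <- attr(x$runner, "executable")
  if (!is.null(exe)) cat("  executable: ", exe, "\n", sep = "")
  invisible(x)
}

#' Build a runner around an external simulator executable
#'
#' The returned runner launches `executable args... settings.xml` as a child
#' process inside the workspace directory, blocks until it exits, and raises
#' (with the tail of the captured output) on a non-zero exit status. The
#' replicate seed is exposed to the child through the `CALIB_SEED` environment
#' variable; stochastic simulators may read it or fall back to their own
#' seeding. Outputs are expected under `output/` in the workspace.
#'
#' @param executable path to the simulator executable.
#' @param args extra command-line arguments inserted before the settings file,
#'   passed through verbatim.
#' @param timeout wall-clock limit in seconds (0 = none); exceeding it is an
#'   error.
#' @return a runner function for [black_box()].
#' @export
make_external_runner <- function(executable, args = character(), timeout = 0) {
  exe <- normalizePath(executable, mustWork = FALSE)
  f <- function(workdir, params, seed) {
    owd <- setwd(workdir)
    on.exit(setwd(owd))
    out <- suppressWarnings(system2(
      exe, shQuote(c(args, "settings.xml")), stdout = TRUE, stderr = TRUE,
      env = paste0("CALIB_SEED=", seed), timeout = timeout))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop(sprintf("runner exited with status %d:\n%s", status,
                   paste(utils::tail(out, 5), collapse = "\n")), call. = FALSE)
    invisible(NULL)
  }
  attr(f, "executable") <- exe
  f
}

#' Evaluate a black-box model at one parameter set
#'
#' Runs `model$replicates` independent simulations, each in a freshly created
#' isolated workspace (config copy plus an `output/` directory). Replicate `i`
#' uses seed `seed + i - 1`, so a fixed seed makes stochastic runs
#' reproducible. Workspaces are removed on success and kept for inspection on
#' failure.
#'
#' @param model a [black_box()] object.
#' @param params named numeric vector of parameter values; for models with an
#'   XML updater the names are dotted field paths (see [update_field()]).
#' @param seed base integer seed.
#' @return a list with one metric vector per replicate.
#' @examples
#' bb <- fixture_black_box("logistic")
#' curve <- run_model(bb, c(r = 0.1, K = 1000), seed = 1)[[1]]
#' tail(curve, 1)  # population after 100 time units
#' @export
run_model <- function(model, params, seed = 0L) {
  if (!inherits(model, "black_box")) stop("`model` must be a black_box object")
  params <- .check_params(params)
  seed <- as.integer(seed)
  exe <- attr(model$runner, "executable")
  if (!is.null(exe) && !file.exists(exe))
    stop("runner not found: ", exe)  # fail before any config mutation
  lapply(seq_len(model$replicates), function(i) {
    ws <- tempfile("cellcalib-ws-")
    dir.create(ws)
    dir.create(file.path(ws, "output"))
    ok <- FALSE
    on.exit({
      if (ok) unlink(ws, recursive = TRUE)
      else message("run failed; workspace kept at ", ws)
    }, add = TRUE)
    if (!is.null(model$config))
      file.copy(model$config, file.path(ws, "settings.xml"), overwrite = TRUE)
    if (!is.null(model$updater))
      model$updater(file.path(ws, "settings.xml"), params)
    raw <- model$runner(ws, params, seed + i - 1L)
    metric <- if (!is.null(model$processor)) {
      m <- model$processor(file.path(ws, "output"))
      if (length(m) == 0) stop("processor returned no data")
      m
    } else if (is.numeric(raw)) {
      as.numeric(raw)
    } else {
      # bare-executable model: surrogate "metric" is the output listing
      sort(list.files(file.path(ws, "output")))
    }
    ok <- TRUE
    metric
  })
}

#' Default config updater: dotted-path XML edits
#'
#' Returns an updater for [black_box()] that interprets each parameter name as
#' a dotted field path, applies the edits through the validated schema
#' ([update_field()]), and writes the file back in place.
#'
#' @return function `(config_path, params)`.
#' @export
xml_updater <- function() {
  function(config_path, params) {
    s <- load_config(config_path)
    for (nm in names(params)) s <- update_field(s, nm, params[[nm]])
    write_config(s, config_path)
  }
}
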