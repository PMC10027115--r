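# Snapshot reading and metric extraction, plus the calibration error
# function. The reference snapshot dialect is tabular: one CSV per saved
# time point with header id,x,y,z and one row per cell; an optional
# companion substrate_<name>.csv holds a voxel grid as i,j,k,value.

#' Read one simulation snapshot
#'
#' @param path path to a snapshot CSV with columns `id,x,y,z` (one row per
#'   cell; zero rows is valid, e.g. when every cell died).
#' @return an object of class `snapshot`: list with `time` (index parsed from
#'   a trailing number in the filename, `NA` if none) and `cells` (data frame).
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  cells <- utils::read.csv(path)
  required <- c("id", "x", "y", "z")
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop("snapshot ", basename(path), " missing column(s): ",
         paste(missing, collapse = ", "))
  for (cc in required) {
    if (nrow(cells) == 0) cells[[cc]] <- numeric(0)
    else if (!is.numeric(cells[[cc]]))
      stop("snapshot ", basename(path), ": non-numeric values in column ", cc)
  }
  idx <- regmatches(basename(path), regexpr("[0-9]+(?=\\.[^.]+$)",
                                            basename(path), perl = TRUE))
  structure(list(time = if (length(idx)) as.numeric(idx) else NA_real_,
                 cells = cells, source = path),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat("<snapshot> ", nrow(x$cells), " cells",
      if (!is.na(x$time)) paste0(" (index ", x$time, ")"), "\n", sep = "")
  invisible(x)
}

#' Read a substrate concentration grid
#'
#' @param path CSV with columns `i,j,k,value` (voxel indices and
#'   concentration).
#' @return data frame with those columns.
#' @export
read_substrate <- function(path) {
  if (!file.exists(path)) stop("substrate file not found: ", path)
  grid <- utils::read.csv(path)
  missing <- setdiff(c("i", "j", "k", "value"), names(grid))
  if (length(missing))
    stop("substrate ", basename(path), " missing column(s): ",
         paste(missing, collapse = ", "))
  grid
}

#' List snapshot files of an output directory in simulation order
#'
#' Snapshots are ordered lexicographically by filename, which matches the
#' zero-padded numbering simulators emit; substrate companion files are
#' excluded.
#'
#' @param dir output directory.
#' @return character vector of full paths (sorted).
#' @export
snapshot_files <- function(dir) {
  if (!dir.exists(dir)) stop("output directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.csv$")
  files <- files[!grepl("^substrate_", files)]
  if (length(files) == 0) stop("no snapshot files in ", dir)
  file.path(dir, sort(files))
}

.final_snapshot <- function(dir) {
  files <- snapshot_files(dir)
  read_snapshot(files[length(files)])
}

#' Final number of cells in a simulation
#'
#' @param dir output directory containing at least one snapshot.
#' @return integer cell count of the last snapshot.
#' @export
final_cell_count <- function(dir) {
  nrow(.final_snapshot(dir)$cells)
}

#' Final cell coordinates along one axis
#'
#' @param dir output directory containing at least one snapshot.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return numeric vector, one entry per cell of the last snapshot, in stable
#'   cell-id order.
#' @export
final_coordinates <- function(dir, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  cells <- .final_snapshot(dir)$cells
  cells[[axis]][order(cells$id)]
}

#' Summed squared error between simulated and target vectors
#'
#' The calibration objective: \eqn{\sum_i (s_i - t_i)^2}. Two alignment rules
#' are provided. `"paired"` (default) requires equal lengths and compares
#' entries positionally -- appropriate for time series such as growth curves.
#' `"sorted"` compares the two samples as distributions: equal-length vectors
#' are sorted ascending before differencing (quantile matching), and
#' unequal-length vectors are each reduced to 21 empirical quantiles
#' (0, 5, ..., 100%) first. Use `"sorted"` for unordered population outcomes
#' such as final cell positions, which have no natural pairing.
#'
#' @param simulated numeric vector of model output.
#' @param target numeric vector of target data.
#' @param align `"paired"` or `"sorted"`.
#' @return non-negative scalar; zero iff the (aligned) vectors are equal.
#' @examples
#' sse(c(0, 0), c(3, 4))  # 25
#' @export
sse <- function(simulated, target, align = c("paired", "sorted")) {
  align <- match.arg(align)
  s <- as.numeric(simulated)
  t <- as.numeric(target)
  if (length(s) == 0 || length(t) == 0) stop("vectors must be non-empty")
  if (align == "sorted") {
    if (length(s) == length(t)) {
      s <- sort(s); t <- sort(t)
    } else {
      p <- seq(0, 1, by = 0.05)
      s <- stats::quantile(s, p, names = FALSE, type = 7)
      t <- stats::quantile(t, p, names = FALSE, type = 7)
    }
  } else if (length(s) != length(t)) {
    stop("length mismatch: simulated has ", length(s),
         " entries, target has ", length(t))
  }
  sum((s - t)^2)
}

#' Read a target-data vector from CSV
#'
#' Accepts a single-column CSV with or without a header line.
#'
#' @param path CSV path.
#' @return numeric vector.
#' @export
read_target <- function(path) {
  if (!file.exists(path)) stop("target file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  col <- raw[[1]]
  if (suppressWarnings(is.na(as.numeric(col[1])))) col <- col[-1]  # header
  v <- suppressWarnings(as.numeric(col))
  if (length(v) == 0 || any(is.na(v)))
    stop("target file ", basename(path), " is not a numeric column")
  v
}
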