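# Reading, validating, editing and writing PhysiCell-style settings XML.
#
# The settings document is kept as-is (xml2 document) so that elements the
# schema does not model -- user_parameters, custom_data, units attributes,
# comments -- survive a load/edit/write cycle untouched. A parsed, validated
# value tree sits next to the document for programmatic access.

# Constraint kinds: "pos" means strictly > 0, "unit" means within [0, 1],
# "free" means unconstrained (domain bounds may be negative).
.BOUND_LABEL <- c(pos = "> 0", unit = "[0, 1]", free = "unconstrained")

.check_bound <- function(value, kind) {
  switch(kind,
    pos  = value > 0,
    unit = value >= 0 && value <= 1,
    free = TRUE
  )
}

# field -> constraint kind, per phenotype block
.VOLUME_FIELDS <- c(
  total = "pos", fluid_fraction = "unit", nuclear = "pos",
  fluid_change_rate = "pos", cytoplasmic_biomass_change_rate = "pos",
  nuclear_biomass_change_rate = "pos", calcified_fraction = "unit",
  calcification_rate = "pos", relative_rupture_volume = "pos"
)
.MECHANICS_FIELDS <- c(
  cell_cell_adhesion_strength = "pos", cell_cell_repulsion_strength = "pos",
  relative_maximum_adhesion_distance = "pos"
)
.MOTILITY_FIELDS <- c(speed = "pos", persistence_time = "pos", migration_bias = "unit")
.SUBSTANCE_FIELDS <- c(
  diffusion_coefficient = "pos", decay_rate = "pos",
  initial_condition = "pos", dirichlet_boundary_condition = "pos"
)
# XML element names where they differ from the field name
.SUBSTANCE_ELEMENT <- c(
  diffusion_coefficient = "diffusion_coefficient", decay_rate = "decay_rate",
  initial_condition = "initial_condition",
  dirichlet_boundary_condition = "Dirichlet_boundary_condition"
)

# Shortest numeric representation that reparses to the same double.
.num_str <- function(x) {
  s <- as.character(x)
  if (as.numeric(s) == x) return(s)
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

.new_violations <- function() {
  data.frame(path = character(), value = numeric(), constraint = character(),
             stringsAsFactors = FALSE)
}

.constraint_message <- function(violations) {
  lines <- sprintf("  %s: value %s violates constraint %s",
                   violations$path,
                   ifelse(is.na(violations$value), "<non-numeric>",
                          vapply(violations$value, function(v) format(v), "")),
                   violations$constraint)
  paste(c("settings constraint violation:", lines), collapse = "\n")
}

.stop_constraint <- function(violations) {
  cond <- structure(
    class = c("cellcalib_constraint_error", "error", "condition"),
    list(message = .constraint_message(violations), call = NULL,
         violations = violations)
  )
  stop(cond)
}

# Parse the full document into a value tree, collecting constraint
# violations instead of stopping, so a validator can report all of them.
.parse_settings <- function(doc) {
  viol <- .new_violations()
  bad <- function(path, value, constraint) {
    viol[nrow(viol) + 1L, ] <<- list(path, value, constraint)
  }
  # read one numeric leaf; flags non-numeric text, returns NA when absent
  leaf <- function(node, xpath, path) {
    n <- xml2::xml_find_first(node, xpath)
    if (inherits(n, "xml_missing")) return(NA_real_)
    txt <- xml2::xml_text(n)
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v) && nzchar(trimws(txt))) bad(path, NA_real_, "numeric")
    v
  }
  checked <- function(node, xpath, path, kind) {
    v <- leaf(node, xpath, path)
    if (!is.na(v) && !.check_bound(v, kind)) bad(path, v, .BOUND_LABEL[[kind]])
    v
  }
  root <- xml2::xml_root(doc)

  ## domain -----------------------------------------------------------------
  dn <- xml2::xml_find_first(root, "./domain")
  domain <- list()
  for (f in c("x_min", "x_max", "y_min", "y_max", "z_min", "z_max"))
    domain[[f]] <- leaf(dn, paste0("./", f), paste0("domain/", f))
  for (f in c("dx", "dy", "dz"))
    domain[[f]] <- checked(dn, paste0("./", f), paste0("domain/", f), "pos")
  for (ax in c("x", "y", "z")) {
    lo <- domain[[paste0(ax, "_min")]]; hi <- domain[[paste0(ax, "_max")]]
    if (!is.na(lo) && !is.na(hi) && hi <= lo)
      bad(paste0("domain/", ax, "_max"), hi, paste0("> ", ax, "_min"))
  }

  ## overall ----------------------------------------------------------------
  ov <- xml2::xml_find_first(root, "./overall")
  overall <- list()
  for (f in c("max_time", "dt_diffusion", "dt_mechanics", "dt_phenotype"))
    overall[[f]] <- checked(ov, paste0("./", f), paste0("overall/", f), "pos")

  ## substances -------------------------------------------------------------
  substances <- list()
  for (var in xml2::xml_find_all(root, "./microenvironment_setup/variable")) {
    nm <- xml2::xml_attr(var, "name")
    sub <- list(name = nm)
    for (f in names(.SUBSTANCE_FIELDS))
      sub[[f]] <- checked(var, paste0(".//", .SUBSTANCE_ELEMENT[[f]]),
                          paste0("substance/", nm, "/", f), .SUBSTANCE_FIELDS[[f]])
    substances[[nm]] <- sub
  }

  ## cell definitions -------------------------------------------------------
  rate_list <- function(node, inner, path) {
    nodes <- xml2::xml_find_all(node, inner)
    vals <- suppressWarnings(as.numeric(xml2::xml_text(nodes)))
    for (i in seq_along(vals)) {
      if (is.na(vals[i])) bad(paste0(path, "/", i), NA_real_, "numeric")
      else if (vals[i] <= 0) bad(paste0(path, "/", i), vals[i], .BOUND_LABEL[["pos"]])
    }
    vals
  }
  phase_block <- function(node, path) {
    # cycle and (per model) death carry either durations or transition rates
    durs <- rate_list(node, ".//phase_durations/duration",
                      paste0(path, "/phase_durations"))
    rates <- rate_list(node, ".//phase_transition_rates/rate",
                       paste0(path, "/phase_transition_rates"))
    list(phase_durations = durs, phase_transition_rates = rates)
  }
  cells <- list()
  for (def in xml2::xml_find_all(root, "./cell_definitions/cell_definition")) {
    nm <- xml2::xml_attr(def, "name")
    ph <- xml2::xml_find_first(def, "./phenotype")
    cell <- list(name = nm)
    base <- paste0("cell/", nm)

    cyc <- xml2::xml_find_first(ph, "./cycle")
    if (!inherits(cyc, "xml_missing")) {
      cell$cycle <- phase_block(cyc, paste0(base, "/cycle"))
      if (length(cell$cycle$phase_durations) && length(cell$cycle$phase_transition_rates))
        bad(paste0(base, "/cycle"), NA_real_,
            "at most one of phase_durations/phase_transition_rates")
    }

    dth <- xml2::xml_find_first(ph, "./death")
    if (!inherits(dth, "xml_missing")) {
      models <- xml2::xml_find_all(dth, "./model")
      if (length(models) == 0) models <- list(dth)
      durs <- numeric(); rates <- numeric()
      for (m in models) {
        blk <- phase_block(m, paste0(base, "/death"))
        if (length(blk$phase_durations) && length(blk$phase_transition_rates))
          bad(paste0(base, "/death"), NA_real_,
              "at most one of phase_durations/phase_transition_rates per model")
        durs <- c(durs, blk$phase_durations)
        rates <- c(rates, blk$phase_transition_rates)
      }
      cell$death <- list(phase_durations = durs, phase_transition_rates = rates)
    }

    block <- function(name, fields) {
      nd <- xml2::xml_find_first(ph, paste0("./", name))
      if (inherits(nd, "xml_missing")) return(NULL)
      out <- list()
      for (f in names(fields))
        out[[f]] <- checked(nd, paste0("./", f), paste0(base, "/", name, "/", f),
                            fields[[f]])
      out
    }
    cell$volume <- block("volume", .VOLUME_FIELDS)
    cell$mechanics <- block("mechanics", .MECHANICS_FIELDS)
    cell$motility <- block("motility", .MOTILITY_FIELDS)
    cells[[nm]] <- cell
  }

  list(tree = list(domain = domain, overall = overall,
                   substances = substances, cells = cells),
       violations = viol)
}

#' Load and validate a simulator settings file
#'
#' Reads a PhysiCell-style XML settings file into a `cell_settings` object.
#' Every numeric field modeled by the schema (domain geometry, overall timing,
#' substances, cell-definition phenotype blocks) is parsed and checked against
#' its constraint (strictly positive rates/lengths/times; `migration_bias`,
#' `fluid_fraction` and `calcified_fraction` in \[0, 1\]; domain maxima above
#' minima). Elements outside the schema are preserved verbatim for write-back.
#'
#' @param path path to a settings XML file.
#' @return an object of class `cell_settings`: the underlying XML document plus
#'   a parsed value tree (`$tree` with `domain`, `overall`, `substances`,
#'   `cells`).
#' @seealso [update_field()], [write_config()], [validate_config()]
#' @examples
#' f <- system.file("extdata", "settings_valid.xml", package = "cellcalib")
#' s <- load_config(f)
#' s$tree$cells$default$motility$speed
#' @export
load_config <- function(path) {
  if (!is.character(path) || length(path) != 1)
    stop("`path` must be a single file path")
  if (!file.exists(path)) stop("settings file not found: ", path)
  doc <- xml2::read_xml(path)
  parsed <- .parse_settings(doc)
  if (nrow(parsed$violations)) .stop_constraint(parsed$violations)
  structure(list(doc = doc, tree = parsed$tree, source = path),
            class = "cell_settings")
}

#' Validate a settings file and report every constraint violation
#'
#' Unlike [load_config()], which stops at the first sign of trouble, this
#' returns a data frame of all violations (zero rows when the file is valid),
#' one row per offending field with its path, value and violated bound.
#'
#' @param x path to a settings XML file, or a `cell_settings` object.
#' @return data frame with columns `path`, `value`, `constraint`.
#' @export
validate_config <- function(x) {
  doc <- if (inherits(x, "cell_settings")) x$doc else {
    if (!file.exists(x)) stop("settings file not found: ", x)
    xml2::read_xml(x)
  }
  .parse_settings(doc)$violations
}

# Resolve a dotted field path ("cell/default/motility/speed",
# "substance/oxygen/decay_rate", "domain/dx", "overall/max_time",
# "cell/default/cycle/phase_durations/1") to its XML node.
.resolve_field <- function(doc, field) {
  parts <- strsplit(field, "/", fixed = TRUE)[[1]]
  root <- xml2::xml_root(doc)
  fail <- function() stop("unknown field path: ", field, call. = FALSE)
  node <- switch(parts[1],
    domain = {
      if (length(parts) != 2) fail()
      xml2::xml_find_first(root, paste0("./domain/", parts[2]))
    },
    overall = {
      if (length(parts) != 2) fail()
      xml2::xml_find_first(root, paste0("./overall/", parts[2]))
    },
    substance = {
      if (length(parts) != 3 || !parts[3] %in% names(.SUBSTANCE_ELEMENT)) fail()
      var <- xml2::xml_find_first(root, sprintf(
        "./microenvironment_setup/variable[@name='%s']", parts[2]))
      if (inherits(var, "xml_missing")) fail()
      xml2::xml_find_first(var, paste0(".//", .SUBSTANCE_ELEMENT[[parts[3]]]))
    },
    cell = {
      if (length(parts) < 4) fail()
      def <- xml2::xml_find_first(root, sprintf(
        "./cell_definitions/cell_definition[@name='%s']", parts[2]))
      if (inherits(def, "xml_missing")) fail()
      blk <- xml2::xml_find_first(def, paste0("./phenotype/", parts[3]))
      if (inherits(blk, "xml_missing")) fail()
      if (parts[3] %in% c("cycle", "death")) {
        if (length(parts) != 5) fail()
        inner <- switch(parts[4],
          phase_durations = ".//phase_durations/duration",
          phase_transition_rates = ".//phase_transition_rates/rate",
          fail())
        nodes <- xml2::xml_find_all(blk, inner)
        idx <- suppressWarnings(as.integer(parts[5]))
        if (is.na(idx) || idx < 1 || idx > length(nodes)) fail()
        nodes[[idx]]
      } else {
        if (length(parts) != 4) fail()
        xml2::xml_find_first(blk, paste0("./", parts[4]))
      }
    },
    fail()
  )
  if (inherits(node, "xml_missing")) fail()
  node
}

# deep copy: xml2 documents are mutable by reference
.copy_doc <- function(doc) xml2::read_xml(charToRaw(as.character(doc)))

#' Update one field of a settings tree
#'
#' Sets a single numeric field addressed by a flat dotted path and re-validates
#' the whole document; every other field is left untouched. The input object is
#' not modified (a fresh copy is returned), so updates compose functionally.
#'
#' Path dialect: `domain/<field>`, `overall/<field>`,
#' `substance/<name>/<field>`, `cell/<name>/<block>/<field>`, and for the
#' cycle/death lists `cell/<name>/<block>/phase_durations/<i>` (1-based).
#'
#' @param settings a `cell_settings` object from [load_config()].
#' @param field dotted field path, e.g. `"cell/default/motility/speed"`.
#' @param value new numeric value; must satisfy the field's constraint.
#' @return the updated `cell_settings` object.
#' @examples
#' f <- system.file("extdata", "settings_valid.xml", package = "cellcalib")
#' s <- update_field(load_config(f), "cell/default/motility/speed", 12.5)
#' s$tree$cells$default$motility$speed
#' @export
update_field <- function(settings, field, value) {
  if (!inherits(settings, "cell_settings"))
    stop("`settings` must be a cell_settings object from load_config()")
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value))
    stop("`value` must be a single finite number")
  doc <- .copy_doc(settings$doc)
  node <- .resolve_field(doc, field)
  xml2::xml_text(node) <- .num_str(value)
  parsed <- .parse_settings(doc)
  if (nrow(parsed$violations)) .stop_constraint(parsed$violations)
  structure(list(doc = doc, tree = parsed$tree, source = settings$source),
            class = "cell_settings")
}

#' Write a settings tree back to disk
#'
#' Serializes the underlying XML document. Elements not modeled by the schema
#' are emitted unchanged; numeric edits carry full round-trip precision, so
#' `load_config(write_config(s, f))` reproduces `s`'s values exactly.
#'
#' @param settings a `cell_settings` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(settings, path) {
  if (!inherits(settings, "cell_settings"))
    stop("`settings` must be a cell_settings object")
  ok <- tryCatch({ xml2::write_xml(settings$doc, path); TRUE },
                 error = function(e) stop("cannot write settings to ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Flatten all modeled settings values into a named vector
#'
#' Useful for diffing two configurations field by field: names are the dotted
#' field paths accepted by [update_field()].
#'
#' @param settings a `cell_settings` object.
#' @return named numeric vector.
#' @export
config_values <- function(settings) {
  tr <- settings$tree
  out <- list()
  add <- function(prefix, lst, index_lists = FALSE) {
    for (nm in names(lst)) {
      v <- lst[[nm]]
      if (!is.numeric(v)) next
      if (length(v) == 1 && !index_lists) out[[paste0(prefix, nm)]] <<- v
      else for (i in seq_along(v)) out[[paste0(prefix, nm, "/", i)]] <<- v[i]
    }
  }
  add("domain/", tr$domain)
  add("overall/", tr$overall)
  for (nm in names(tr$substances))
    add(paste0("substance/", nm, "/"), tr$substances[[nm]])
  for (nm in names(tr$cells)) {
    cell <- tr$cells[[nm]]
    for (blk in c("cycle", "death", "volume", "mechanics", "motility"))
      if (!is.null(cell[[blk]]))
        add(paste0("cell/", nm, "/", blk, "/"), cell[[blk]],
            index_lists = blk %in% c("cycle", "death"))
  }
  unlist(out)
}

#' @export
print.cell_settings <- function(x, ...) {
  cat("<cell_settings>", if (!is.null(x$source)) paste0(" from ", x$source), "\n", sep = "")
  cat("  substances: ", paste(names(x$tree$substances), collapse = ", "), "\n", sep = "")
  cat("  cell definitions: ", paste(names(x$tree$cells), collapse = ", "), "\n", sep = "")
  cat("  modeled numeric fields: ", length(config_values(x)), "\n", sep = "")
  invisible(x)
}

#' Compare two settings trees on their modeled values
#' @param target,current `cell_settings` objects.
#' @param ... passed to the numeric comparison.
#' @return `TRUE` or a description of the differences.
#' @method all.equal cell_settings
#' @export
all.equal.cell_settings <- function(target, current, ...) {
  all.equal(config_values(target), config_values(current), ...)
}
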