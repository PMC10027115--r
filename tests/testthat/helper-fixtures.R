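# Shared fixtures built in code at test time.

valid_settings_path <- function() {
  system.file("extdata", "settings_valid.xml", package = "cellcalib")
}

# settings file in a temp location, optionally with raw (unvalidated) overrides
local_settings <- function(overrides = list(), env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".xml", .local_envir = env)
  fixture_settings(path, overrides)
  path
}

# One (path, accept value, reject value) triple per Table-style constraint
# cell: strictly positive fields reject -1 (and zero, checked separately),
# unit-interval fields accept the closed boundaries and reject values outside.
constraint_cases <- function() {
  pos <- function(path) list(path = path, good = 1.5, bad = -1.0, kind = "pos")
  unit <- function(path) list(path = path, good = 1.0, bad = 1.5, kind = "unit")
  c(
    lapply(paste0("domain/", c("dx", "dy", "dz")), pos),
    lapply(paste0("overall/", c("max_time", "dt_diffusion", "dt_mechanics",
                                "dt_phenotype")), pos),
    lapply(paste0("substance/oxygen/",
                  c("diffusion_coefficient", "decay_rate", "initial_condition",
                    "dirichlet_boundary_condition")), pos),
    list(pos("cell/default/cycle/phase_durations/1"),
         pos("cell/default/death/phase_transition_rates/1")),
    lapply(paste0("cell/default/volume/",
                  c("total", "nuclear", "fluid_change_rate",
                    "cytoplasmic_biomass_change_rate",
                    "nuclear_biomass_change_rate", "calcification_rate",
                    "relative_rupture_volume")), pos),
    list(unit("cell/default/volume/fluid_fraction"),
         unit("cell/default/volume/calcified_fraction")),
    lapply(paste0("cell/default/mechanics/",
                  c("cell_cell_adhesion_strength", "cell_cell_repulsion_strength",
                    "relative_maximum_adhesion_distance")), pos),
    list(pos("cell/default/motility/speed"),
         pos("cell/default/motility/persistence_time"),
         unit("cell/default/motility/migration_bias"))
  )
}

# settings variant where the cycle uses transition rates and the death model
# uses phase durations (the template ships the opposite), so both list kinds
# of both blocks get accept/reject coverage
settings_with_swapped_phase_lists <- function(env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".xml", .local_envir = env)
  doc <- xml2::read_xml(valid_settings_path())
  cyc <- xml2::xml_find_first(doc, "//cycle/phase_durations")
  xml2::xml_name(cyc) <- "phase_transition_rates"
  entry <- xml2::xml_find_first(cyc, "./duration")
  xml2::xml_name(entry) <- "rate"
  dth <- xml2::xml_find_first(doc, "//death//phase_transition_rates")
  xml2::xml_name(dth) <- "phase_durations"
  entry <- xml2::xml_find_first(dth, "./rate")
  xml2::xml_name(entry) <- "duration"
  xml2::write_xml(doc, path)
  path
}

# write a snapshot CSV under dir and return its path
write_snapshot_csv <- function(dir, name, ids, x, y, z = 0) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, name)
  utils::write.csv(data.frame(id = ids, x = x, y = y, z = z), path,
                   row.names = FALSE)
  path
}

# independent type-7 quantile (linear interpolation of order statistics),
# used as an oracle against the package's distribution alignment
oracle_quantile7 <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# brute-force sse oracle: explicit element loop
oracle_sse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s
}
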