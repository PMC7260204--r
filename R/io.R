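#' Write a trajectory as CSV (with a JSON event log)
#'
#' @param trajectory a `bead_trajectory`.
#' @param path output CSV path; the event log is written next to it as
#'   `<path>.events.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  ev <- attr(trajectory, "events")
  jsonlite::write_json(ev, paste0(path, ".events.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write scenario metrics as JSON
#'
#' @param metrics metrics list from [run_scenario()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Validate a scenario configuration
#'
#' Checks ranges and internal consistency of a `scenario_config` (or a
#' plain list of overrides read from a YAML/JSON config file).  Returns a
#' character vector of problems, empty when the configuration is valid.
#'
#' @param cfg a `scenario_config` from [build_scenario()].
#' @return character vector of problem descriptions (empty if valid).
#' @export
validate_config <- function(cfg) {
  probs <- character(0)
  bad <- function(msg) probs <<- c(probs, msg)
  b <- cfg$bead
  if (is.null(b$radius) || b$radius <= 0) bad("bead.radius must be > 0")
  if (!is.null(b$chi) && b$chi < 0) bad("bead.chi must be >= 0")
  if (!is.null(b$density) && b$density <= 0) bad("bead.density must be > 0")
  if (!is.null(b$friction) && b$friction < 0) bad("bead.friction must be >= 0")
  f <- cfg$field
  if (is.null(f$frequency) || f$frequency <= 0) bad("field.frequency must be > 0")
  p <- cfg$potential
  if (!is.null(p$nx) && p$nx < 3) bad("potential.nx must be >= 3")
  if (!is.null(p$ny) && p$ny < 3) bad("potential.ny must be >= 3")
  if (!is.null(p$z_layers) && is.unsorted(p$z_layers, strictly = TRUE))
    bad("potential.z_layers must be strictly increasing")
  if (!is.null(p$z_layers) && !is.null(b$radius) &&
      min(p$z_layers) < -b$radius / 2)
    bad("potential.z_layers must not go below -radius/2")
  ft <- cfg$fit
  if (!is.null(ft$N) && ft$N < 0) bad("fit.N must be >= 0")
  if (!is.null(ft$sub) && !ft$sub %in% c(3, 5)) bad("fit.sub must be 3 or 5")
  s <- cfg$sim
  if (!is.null(s$max_dt) && s$max_dt <= 0) bad("sim.max_dt must be > 0")
  if (!is.null(s$n_periods) && s$n_periods <= 0) bad("sim.n_periods must be > 0")
  probs
}
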