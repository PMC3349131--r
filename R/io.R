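# Configuration and run-container I/O.
#
# Configs are YAML with explicit units in the field names (mm, cm/s, W/cm^3
# at the boundary; SI internally). Run containers are versioned RDS files
# holding the arrays, the resolved config and provenance, with CSV exporters
# for the common tabular views.

config_schema <- list(
  top = c("label", "scenario", "grid", "solver", "source", "plan", "seed"),
  scenario = c("preset", "v_mean_cm_s", "pair_gap_mm", "angle_deg",
               "focus_offset_mm", "d_mm"),
  grid = c("spacing_mm", "mode"),
  solver = c("dt_s", "scheme", "T_init_c", "dose_cutoff_c"),
  source = c("p0_w_cm3", "fwhm_transverse_mm", "fwhm_axial_mm", "focus_mm"),
  plan = c("kind", "n_points", "pitch_mm", "on_s", "cool_s", "min_sep_mm")
)

check_fields <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config field%s in '%s': %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")))
}

#' Load a run configuration
#'
#' Reads a YAML run configuration, validates its fields against the schema,
#' applies defaults, and converts boundary units (mm, cm/s, W/cm^3) to SI.
#' Every applied default is reported via `message()`.
#'
#' @param path YAML file path
#' @param quiet suppress default-reporting messages
#' @return an object of class `bh_run_config`: list with `scenario` (a
#'   `bh_scenario`), `grid`, `solver`, `source` (or NULL), `plan` (or NULL),
#'   `seed`, `label`
#' @export
load_run_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  parse_run_config(raw, quiet = quiet)
}

parse_run_config <- function(raw, quiet = FALSE) {
  note <- function(...) if (!quiet) message(sprintf(...))
  check_fields(raw, config_schema$top, "top level")
  if (is.null(raw$scenario)) stop("config must name a scenario")
  check_fields(raw$scenario, config_schema$scenario, "scenario")
  sc_args <- list(name = raw$scenario$preset)
  if (!is.null(raw$scenario$v_mean_cm_s))
    sc_args$v_mean <- raw$scenario$v_mean_cm_s / 100
  if (!is.null(raw$scenario$pair_gap_mm))
    sc_args$pair_gap <- raw$scenario$pair_gap_mm * 1e-3
  if (!is.null(raw$scenario$angle_deg)) sc_args$angle <- raw$scenario$angle_deg
  if (!is.null(raw$scenario$focus_offset_mm))
    sc_args$focus_offset <- raw$scenario$focus_offset_mm * 1e-3
  if (!is.null(raw$scenario$d_mm)) sc_args$d <- raw$scenario$d_mm * 1e-3
  else note("scenario: default boundary thickness d = 20 mm")
  scenario <- do.call(preset_scenario, sc_args)

  g <- raw$grid
  if (is.null(g)) stop("config must define a grid")
  check_fields(g, config_schema$grid, "grid")
  mode <- if (is.null(g$mode)) {
    note("grid: default mode 'xyz'")
    "xyz"
  } else g$mode
  size <- if (mode == "axisym") c(scenario$domain_size[1] / 2,
                                  scenario$domain_size[3])
          else scenario$domain_size
  grid <- sim_grid(g$spacing_mm * 1e-3, size, mode = mode)

  s <- raw$solver
  check_fields(s, config_schema$solver, "solver")
  solver_args <- list()
  if (!is.null(s$dt_s)) solver_args$dt <- s$dt_s
  else note("solver: default dt = 0.05 s")
  if (!is.null(s$scheme)) solver_args$scheme <- s$scheme
  if (!is.null(s$T_init_c)) solver_args$T_init <- s$T_init_c
  if (!is.null(s$dose_cutoff_c)) solver_args$dose_cutoff <- s$dose_cutoff_c
  solver <- do.call(solver_config, solver_args)

  source <- NULL
  if (!is.null(raw$source)) {
    so <- raw$source
    check_fields(so, config_schema$source, "source")
    focus <- if (is.null(so$focus_mm)) {
      note("source: default focus at the scenario focus point")
      scenario$focus
    } else so$focus_mm * 1e-3
    source <- fus_source(so$p0_w_cm3, so$fwhm_transverse_mm * 1e-3,
                         so$fwhm_axial_mm * 1e-3, focus = focus,
                         units = "W/cm3")
  }

  plan <- NULL
  if (!is.null(raw$plan)) {
    p <- raw$plan
    check_fields(p, config_schema$plan, "plan")
    pitch <- if (is.null(p$pitch_mm)) 2e-3 else p$pitch_mm * 1e-3
    n_pts <- if (is.null(p$n_points)) 56L else as.integer(p$n_points)
    min_sep <- if (is.null(p$min_sep_mm)) 8e-3 else p$min_sep_mm * 1e-3
    foci <- make_trajectory(p$kind, pitch = pitch, n_points = n_pts,
                            seed = raw$seed,
                            centre = scenario$domain_size[1:2] / 2,
                            min_sep = min_sep)
    plan <- sonication_plan(foci,
                            on = if (is.null(p$on_s)) 20 else p$on_s,
                            cool = if (is.null(p$cool_s)) 5 else p$cool_s,
                            p0 = if (is.null(raw$source)) 16.5e6 else
                              raw$source$p0_w_cm3 * 1e6,
                            kind = p$kind, seed = raw$seed)
  }

  structure(list(label = raw$label %||% "", scenario = scenario,
                 grid = grid, solver = solver, source = source,
                 plan = plan, seed = raw$seed),
            class = "bh_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to YAML
#'
#' @param config a named list in the YAML schema (not a resolved
#'   `bh_run_config`)
#' @param path output path
#' @export
save_run_config <- function(config, path) {
  check_fields(config, config_schema$top, "top level")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Save / load a run container
#'
#' A run container stores the scientific arrays of a run (temperature, dose,
#' masks), the event log when present, the resolved configuration and
#' provenance (package version, seed, timestamp) in one versioned file.
#'
#' @param run a `bh_state` or `bh_treatment` (or any named list of results)
#' @param path output path (`.rds`)
#' @param seed seed recorded as provenance
#' @return `path`, invisibly
#' @export
save_run <- function(run, path, seed = NULL) {
  container <- list(
    format = "fusbioheat-run",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("fusbioheat")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    run = run)
  saveRDS(container, path)
  invisible(path)
}

#' @rdname save_run
#' @export
load_run <- function(path) {
  container <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable run container (truncated or corrupt?): ", path,
         call. = FALSE))
  if (!is.list(container) || !identical(container$format, "fusbioheat-run"))
    stop("not a fusbioheat run container: ", path)
  if (!identical(container$format_version, 1L))
    warning("run container written by a different format version")
  container
}

#' Export the per-event treatment log as CSV
#'
#' @param treatment a `bh_treatment`
#' @param path output CSV path
#' @export
export_event_log <- function(treatment, path) {
  utils::write.csv(treatment$log, path, row.names = FALSE)
  invisible(path)
}

#' Export a probe time-series as CSV (columns t, point_id, T)
#'
#' @param state a `bh_state` carrying `probe_series`
#' @param path output CSV path
#' @export
export_probes <- function(state, path) {
  if (is.null(state$probe_series)) stop("state has no probe series")
  df <- state$probe_series
  names(df) <- c("t", "point_id", "T")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the midplane normalized dose as a CSV matrix
#'
#' @param state a `bh_state`
#' @param path output CSV path
#' @export
export_midplane_dose <- function(state, path) {
  utils::write.table(normalize_dose(midplane(state$dose)), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
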