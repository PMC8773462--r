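# Scenario configuration, presets reproducing the validation studies,
# end-to-end runs with output writing, and convergence studies.

#' Build a scenario configuration
#'
#' A scenario bundles exactly one geometry source (sphere-shell parameters,
#' cell-like generator seed, or a mesh file), the signaling parameters, the
#' integration controls, probe coordinates, and an optional output
#' directory. All physical quantities are in um / s / uM; configuration
#' files use unit-suffixed key names (see [read_scenario_config()]).
#'
#' @param geometry list; one of
#'   `list(type = "sphere_shell", R_o_um=, R_i_um=, edge_um=, seed=)`,
#'   `list(type = "cell_like", edge_um=, seed=)`, or
#'   `list(type = "mesh_file", path=, format=)`.
#' @param params `signaling_parameters`.
#' @param config `simulation_config`.
#' @param name scenario label used in outputs.
#' @param output_dir where [run_scenario()] writes probes.csv, summary.json,
#'   snapshots and run.log; `NULL` = no files.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(geometry, params, config, name = "scenario",
                            output_dir = NULL) {
  stopifnot(is.list(geometry), !is.null(geometry$type),
            inherits(params, "signaling_parameters"),
            inherits(config, "simulation_config"))
  if (!geometry$type %in% c("sphere_shell", "cell_like", "mesh_file"))
    stop("unknown geometry type '", geometry$type, "'")
  structure(list(geometry = geometry, params = params, config = config,
                 name = name, output_dir = output_dir),
            class = "scenario_config")
}

#' Materialize the mesh of a scenario
#'
#' @param geometry the geometry list of a `scenario_config`.
#' @return a `tet_mesh`.
#' @export
build_geometry <- function(geometry) {
  switch(geometry$type,
         sphere_shell = generate_sphere_shell_mesh(
           geometry$R_o_um, geometry$R_i_um, geometry$edge_um,
           seed = geometry$seed %||% 1L),
         cell_like = generate_cell_like_mesh(
           seed = geometry$seed %||% 1L,
           target_edge_length = geometry$edge_um %||% 2),
         mesh_file = read_mesh(geometry$path, geometry$format),
         stop("unknown geometry type '", geometry$type, "'"))
}

#' Named scenario presets
#'
#' Presets reproducing the validation and application studies on the
#' spherical cell model (R_o = 9.34 um, R_i = 5.26 um) and the synthetic
#' cell-like geometry, with the reference parameter set E_AC = 0.1412 uM/s,
#' V_max = 0.295 uM/s, K_M = 2 uM, C_o = 0.05 uM:
#'
#' * `compartmental_pde_only`: uniform cytosolic degradation, no synthesis,
#'   no flux; compartmental decay checked against the kinetics ODE.
#' * `compartmental_ac_only`: uniform synthesis, no degradation; linear
#'   growth.
#' * `compartmental_ac_pde`: synthesis and degradation from t = 0; rises to
#'   the steady state E_AC K_M / (V_max - E_AC).
#' * `membrane_ac_cytosol_pde`: synthesis confined to the plasma membrane as
#'   the equivalent flux beta = 0.3611 uM um/s, degradation in the cytosol,
#'   D = 3 um^2/s; probes at R_o, r = 7.8 um, and R_i.
#' * `dirichlet_shell`: concentrations 4 uM / 1 uM prescribed on the outer /
#'   inner surfaces, D = 30 um^2/s, no kinetics; relaxes to A + B/r; probes
#'   at r = 7.468 and 7.112 um.
#' * `delayed_start`: membrane flux beta = 2 uM um/s from t_s = 10 s,
#'   cytosolic degradation from t_d = 20 s, D = 10 um^2/s, on the sphere
#'   model; subplasmalemmal / cytosolic / perinuclear probes.
#' * `cell_uniform_ac_pde`: the delayed-start loading with t_s = t_d = 0 on
#'   the cell-like geometry.
#' * `cell_delayed_start`: delayed start on the cell-like geometry.
#'
#' @param name preset name; `scenario_presets()` lists all.
#' @param edge_um override the mesh edge length (um).
#' @param seed mesh generator seed.
#' @param t_end_s override end time, s. Defaults are preset-specific.
#' @param output_dir passed through to the scenario.
#' @return `scenario_config` (for `scenario_preset`) or character vector of
#'   names (for `scenario_presets`).
#' @export
scenario_preset <- function(name, edge_um = NULL, seed = 1L,
                            t_end_s = NULL, output_dir = NULL) {
  ro <- 9.34; ri <- 5.26
  sphere <- function(edge) list(type = "sphere_shell", R_o_um = ro,
                                R_i_um = ri, edge_um = edge, seed = seed)
  cell <- function(edge) list(type = "cell_like", edge_um = edge,
                              seed = seed)
  radial_probes <- function(rr) do.call(rbind, lapply(rr, function(r)
    c(r, 0, 0)))
  sc <- switch(
    name,
    compartmental_pde_only = list(
      geometry = sphere(edge_um %||% 4),
      params = signaling_parameters(D = 300, E_AC = 0, V_max = 0.295,
                                    K_M = 2, C_o = 0.05, t_s = 0, t_d = 0),
      config = simulation_config(dt = 1, t_end = t_end_s %||% 300,
                                 probe_points = radial_probes(c(ro, ri)))),
    compartmental_ac_only = list(
      geometry = sphere(edge_um %||% 4),
      params = signaling_parameters(D = 300, E_AC = 0.1412, V_max = 0,
                                    C_o = 0.05),
      config = simulation_config(dt = 1, t_end = t_end_s %||% 60,
                                 probe_points = radial_probes(c(ro, ri)))),
    compartmental_ac_pde = list(
      geometry = sphere(edge_um %||% 4),
      params = signaling_parameters(D = 300, E_AC = 0.1412, V_max = 0.295,
                                    K_M = 2, C_o = 0.05),
      config = simulation_config(dt = 1, t_end = t_end_s %||% 600,
                                 probe_points = radial_probes(c(ro, ri)))),
    membrane_ac_cytosol_pde = list(
      geometry = sphere(edge_um %||% 2.4),
      params = signaling_parameters(
        D = 3, E_AC = 0, V_max = 0.295, K_M = 2, C_o = 0.05,
        beta = c(plasma_membrane = membrane_flux_equivalent(0.1412, ro, ri))),
      config = simulation_config(dt = 2, t_end = t_end_s %||% 600,
                                 probe_points = radial_probes(c(ro, 7.8, ri)))),
    dirichlet_shell = list(
      geometry = sphere(edge_um %||% 2.4),
      params = signaling_parameters(
        D = 30, E_AC = 0, V_max = 0, C_o = 0.05,
        dirichlet = c(plasma_membrane = 4, perinuclear = 1)),
      config = simulation_config(dt = 0.25, t_end = t_end_s %||% 20,
                                 probe_points = radial_probes(c(7.468, 7.112)))),
    delayed_start = list(
      geometry = sphere(edge_um %||% 2.4),
      params = signaling_parameters(
        D = 10, E_AC = 0, V_max = 0.295, K_M = 2, C_o = 0.05,
        t_s = 10, t_d = 20, beta = c(plasma_membrane = 2)),
      config = simulation_config(dt = 1, t_end = t_end_s %||% 300,
                                 snapshot_stride = 1,
                                 probe_points = radial_probes(c(ro, 7.8, ri)))),
    cell_uniform_ac_pde = list(
      geometry = cell(edge_um %||% 2),
      params = signaling_parameters(
        D = 10, E_AC = 0, V_max = 0.295, K_M = 2, C_o = 0.05,
        beta = c(plasma_membrane = 2)),
      config = simulation_config(dt = 1, t_end = t_end_s %||% 300,
                                 probe_points = rbind(c(11.5, 1, 0.3),
                                                      c(7.5, 1, 0.3),
                                                      c(5.5, 1, 0.3)))),
    cell_delayed_start = list(
      geometry = cell(edge_um %||% 2),
      params = signaling_parameters(
        D = 10, E_AC = 0, V_max = 0.295, K_M = 2, C_o = 0.05,
        t_s = 10, t_d = 20, beta = c(plasma_membrane = 2)),
      config = simulation_config(dt = 1, t_end = t_end_s %||% 300,
                                 snapshot_stride = 1,
                                 probe_points = rbind(c(11.5, 1, 0.3),
                                                      c(7.5, 1, 0.3),
                                                      c(5.5, 1, 0.3)))),
    stop("unknown preset '", name, "'; see scenario_presets()"))
  scenario_config(sc$geometry, sc$params, sc$config, name = name,
                  output_dir = output_dir)
}

#' @rdname scenario_preset
#' @export
scenario_presets <- function() {
  c("compartmental_pde_only", "compartmental_ac_only",
    "compartmental_ac_pde", "membrane_ac_cytosol_pde", "dirichlet_shell",
    "delayed_start", "cell_uniform_ac_pde", "cell_delayed_start")
}

#' Run a scenario end to end
#'
#' Builds the mesh, assembles the system, integrates in time, and (when the
#' scenario has an `output_dir`) writes `probes.csv`, `summary.json`, a
#' `snapshots/` VTK series, and `run.log`.
#'
#' @param scenario a `scenario_config` (or a preset name).
#' @param mesh optional pre-built `tet_mesh` overriding the geometry spec.
#' @return the `time_course`, with the run summary attached as attribute
#'   `summary`.
#' @export
run_scenario <- function(scenario, mesh = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(inherits(scenario, "scenario_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(mesh)) mesh <- build_geometry(scenario$geometry)
  tc <- simulate_signaling(mesh, scenario$params, scenario$config)
  elapsed <- proc.time()[["elapsed"]] - t0

  np <- length(tc$probe_nodes)
  summary <- list(
    scenario = scenario$name,
    nodes = nrow(mesh$nodes),
    elements = nrow(mesh$elements),
    t_end_s = scenario$config$t_end,
    dt_s = scenario$config$dt,
    probe_nodes = tc$probe_nodes,
    probe_final_uM = if (np) as.numeric(tc$probes[nrow(tc$probes), ])
                     else numeric(0),
    inner_iterations_mean = if (length(tc$inner_iterations))
      mean(tc$inner_iterations) else 0,
    inner_iterations_max = if (length(tc$inner_iterations))
      max(tc$inner_iterations) else 0,
    elapsed_s = elapsed)
  attr(tc, "summary") <- summary

  if (!is.null(scenario$output_dir)) {
    dir.create(scenario$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_probes_csv(tc, file.path(scenario$output_dir, "probes.csv"))
    jsonlite::write_json(summary,
                         file.path(scenario$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_snapshot_series(tc, file.path(scenario$output_dir, "snapshots"))
    writeLines(c(
      paste("scenario:", scenario$name),
      paste("nodes:", nrow(mesh$nodes), "elements:", nrow(mesh$elements)),
      paste("steps:", length(tc$times) - 1, "dt:", scenario$config$dt),
      paste("inner iterations per step:",
            paste(tc$inner_iterations, collapse = " ")),
      paste("elapsed_s:", signif(elapsed, 4))),
      file.path(scenario$output_dir, "run.log"))
  }
  tc
}

#' Time-step and mesh convergence studies
#'
#' Re-runs a scenario across a list of time steps (`dt_values`) or mesh
#' resolutions (`edge_values`, um) and tabulates the discrepancy of each
#' run's probe curves against a reference: the compartmental kinetics ODE
#' when the scenario is compartmental (no fluxes, no Dirichlet sets), else
#' the finest discretization in the list. The discrepancy is
#' `max_t |C - C_ref|` at the first probe, normalized by the amplitude
#' `max_t |C_ref|`.
#'
#' @param scenario a `scenario_config` or preset name.
#' @param dt_values time steps to compare, s.
#' @param edge_values mesh edge lengths to compare, um.
#' @return data.frame with one row per level: `level` (dt or edge),
#'   `nodes`, `probe_final_uM`, `discrepancy` (relative to amplitude).
#' @export
convergence_study <- function(scenario, dt_values = NULL,
                              edge_values = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  by_dt <- !is.null(dt_values)
  levels <- if (by_dt) dt_values else edge_values
  if (is.null(levels) || length(levels) < 2)
    stop("need at least two dt or mesh levels for a convergence study")

  compartmental <- is.null(scenario$params$beta) &&
    is.null(scenario$params$dirichlet)

  runs <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    sc <- scenario
    if (by_dt) {
      cf <- sc$config
      sc$config <- simulation_config(dt = levels[k], t_end = cf$t_end,
                                     gamma = cf$gamma,
                                     inner_tol = cf$inner_tol,
                                     max_inner = cf$max_inner,
                                     probe_points = cf$probe_points,
                                     probe_ids = cf$probe_ids,
                                     snapshot_stride = cf$snapshot_stride)
    } else {
      sc$geometry$edge_um <- levels[k]
    }
    sc$output_dir <- NULL
    runs[[k]] <- run_scenario(sc)
  }

  disc <- numeric(length(levels))
  if (compartmental) {
    for (k in seq_along(levels)) {
      tc <- runs[[k]]
      ref <- compartmental_timecourse(tc$times, scenario$params$E_AC[[1]],
                                      scenario$params$V_max,
                                      scenario$params$K_M,
                                      scenario$params$C_o)
      disc[k] <- max(abs(tc$probes[, 1] - ref)) / max(abs(ref))
    }
  } else {
    fine <- which.min(levels)
    reftc <- runs[[fine]]
    for (k in seq_along(levels)) {
      tc <- runs[[k]]
      tt <- intersect(round(tc$times, 9), round(reftc$times, 9))
      ia <- match(tt, round(tc$times, 9))
      ib <- match(tt, round(reftc$times, 9))
      disc[k] <- max(abs(tc$probes[ia, 1] - reftc$probes[ib, 1])) /
        max(abs(reftc$probes[ib, 1]))
    }
  }
  data.frame(level = levels,
             nodes = vapply(runs, function(tc) tc$system$n_nodes,
                            numeric(1)),
             probe_final_uM = vapply(runs, function(tc)
               tc$probes[nrow(tc$probes), 1], numeric(1)),
             discrepancy = disc)
}

#' Read a scenario configuration file
#'
#' YAML with unit-suffixed keys. Example:
#' ```
#' name: demo
#' geometry: {type: sphere_shell, R_o_um: 9.34, R_i_um: 5.26,
#'            edge_um: 2.4, seed: 1}
#' parameters:
#'   D_um2_per_s: 10
#'   E_AC_uM_per_s: 0
#'   V_max_uM_per_s: 0.295
#'   K_M_uM: 2
#'   C_o_uM: 0.05
#'   t_s_s: 10
#'   t_d_s: 20
#'   beta_uM_um_per_s: {plasma_membrane: 2}
#'   dirichlet_uM: {}
#' integration: {dt_s: 1, t_end_s: 300, gamma: 0.6667,
#'               snapshot_stride: 10}
#' probes_um: [[9.34, 0, 0], [7.8, 0, 0], [5.26, 0, 0]]
#' output_dir: out
#' ```
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$geometry) || is.null(y$parameters) || is.null(y$integration))
    stop("scenario file must define geometry, parameters and integration")
  p <- y$parameters
  params <- signaling_parameters(
    D = p$D_um2_per_s,
    E_AC = p$E_AC_uM_per_s %||% 0,
    V_max = p$V_max_uM_per_s %||% 0,
    K_M = p$K_M_uM %||% 2,
    C_o = p$C_o_uM %||% 0.05,
    t_s = p$t_s_s %||% 0,
    t_d = p$t_d_s %||% (p$t_s_s %||% 0),
    beta = if (length(p$beta_uM_um_per_s)) unlist(p$beta_uM_um_per_s),
    dirichlet = if (length(p$dirichlet_uM)) unlist(p$dirichlet_uM))
  i <- y$integration
  probes <- if (!is.null(y$probes_um)) {
    do.call(rbind, lapply(y$probes_um, as.numeric))
  }
  config <- simulation_config(
    dt = i$dt_s, t_end = i$t_end_s,
    gamma = i$gamma %||% (2 / 3),
    inner_tol = i$inner_tol %||% 1e-8,
    max_inner = i$max_inner %||% 50L,
    probe_points = probes,
    snapshot_stride = i$snapshot_stride %||% Inf)
  scenario_config(y$geometry, params, config,
                  name = y$name %||% "scenario",
                  output_dir = y$output_dir)
}
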