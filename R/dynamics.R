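# Time integration of the semi-discrete signaling system
#
#   K1 dc/dt + [K2 (+ K3)] c = R1 + R2,
#
# with the three activity phases (diffusion only before t_s; plus synthesis
# from t_s; plus Michaelis-Menten degradation from t_d) and the
# gamma-weighted implicit one-step scheme
#
#   [K1/dt + g (K2+K3)] c_{i+1} = [K1/dt - (1-g) (K2+K3)] c_i
#                                 + (1-g) R_i + g R_{i+1}.
#
# Degradation makes K3 and part of the load state-dependent; each step is
# therefore iterated: the expansion point C1 starts at c_i and is replaced
# by the newest solve until the relative max-norm change is below tolerance.

#' Signaling parameters
#'
#' Physical parameters of the cAMP synthesis/diffusion/degradation model.
#'
#' @param D diffusion coefficient, um^2/s (>= 0).
#' @param E_AC uniform volumetric synthesis rate in the cytosol, uM/s. Use a
#'   named vector/list for per-region rates.
#' @param V_max maximum degradation (hydrolysis) rate, uM/s (>= 0).
#' @param K_M Michaelis constant, uM (> 0).
#' @param C_o initial concentration, uM.
#' @param t_s synthesis (adenylyl cyclase) start time, s.
#' @param t_d degradation (phosphodiesterase) start time, s; requires
#'   `t_s <= t_d`.
#' @param beta named numeric: boundary flux (uM um/s) per face-set label;
#'   positive = influx.
#' @param dirichlet named numeric: prescribed concentration (uM) per
#'   face-set label (all nodes of the set's faces are clamped).
#' @return object of class `signaling_parameters`.
#' @export
signaling_parameters <- function(D, E_AC = 0, V_max = 0, K_M = 2,
                                 C_o = 0.05, t_s = 0, t_d = t_s,
                                 beta = NULL, dirichlet = NULL) {
  stopifnot(D >= 0, V_max >= 0, K_M > 0, C_o >= 0, t_s >= 0)
  if (t_s > t_d)
    stop("degradation cannot start before synthesis: require t_s <= t_d")
  if (!is.null(beta)) {
    beta <- unlist(beta)
    stopifnot(!is.null(names(beta)), all(nzchar(names(beta))),
              all(is.finite(beta)))
  }
  if (!is.null(dirichlet)) {
    dirichlet <- unlist(dirichlet)
    stopifnot(!is.null(names(dirichlet)), all(is.finite(dirichlet)))
  }
  if (is.null(names(E_AC)) && length(E_AC) == 1) {
    E_AC <- c(cytosol = as.numeric(E_AC))
  } else {
    E_AC <- unlist(E_AC)
  }
  structure(list(D = D, E_AC = E_AC, V_max = V_max, K_M = K_M, C_o = C_o,
                 t_s = t_s, t_d = t_d, beta = beta, dirichlet = dirichlet),
            class = "signaling_parameters")
}

#' Simulation (time integration) controls
#'
#' @param dt time step, s (> 0).
#' @param t_end end time, s; must be a multiple of `dt`.
#' @param gamma implicit weight in `[1/2, 1]`. Default 2/3 (Galerkin's
#'   implicit method, unconditionally stable). Values below 1/2 are refused
#'   (conditionally stable).
#' @param inner_tol relative max-norm convergence tolerance for the
#'   quasi-linearization iteration.
#' @param max_inner maximum quasi-linearization iterations per step.
#' @param probe_points numeric k x 3 matrix of probe coordinates (um),
#'   snapped to nearest nodes; or `NULL`.
#' @param probe_ids integer node ids to record directly; or `NULL`.
#' @param snapshot_stride record the full nodal field every this many steps
#'   (step 0 is always recorded); `Inf` keeps only the initial and final
#'   fields.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(dt, t_end, gamma = 2 / 3, inner_tol = 1e-8,
                              max_inner = 50L, probe_points = NULL,
                              probe_ids = NULL, snapshot_stride = Inf) {
  stopifnot(dt > 0, t_end > 0, inner_tol > 0, max_inner >= 1)
  if (gamma < 1 / 2 || gamma > 1)
    stop("gamma must lie in [1/2, 1]; explicit-leaning gamma < 1/2 refused")
  nsteps <- t_end / dt
  if (abs(nsteps - round(nsteps)) > 1e-9 * max(1, nsteps))
    stop("t_end must be an integer multiple of dt")
  structure(list(dt = dt, t_end = t_end, gamma = gamma,
                 inner_tol = inner_tol, max_inner = as.integer(max_inner),
                 probe_points = probe_points, probe_ids = probe_ids,
                 snapshot_stride = snapshot_stride),
            class = "simulation_config")
}

#' Michaelis-Menten degradation rate
#'
#' `M(C) = V_max * C / (K_M + C)`: monotone in `C`, saturating at `V_max`.
#'
#' @param C concentration, uM (vectorized).
#' @param V_max maximum rate, uM/s.
#' @param K_M Michaelis constant, uM.
#' @return degradation rate, uM/s.
#' @export
michaelis_menten_rate <- function(C, V_max, K_M) {
  stopifnot(V_max >= 0, K_M > 0)
  if (any(C < -sqrt(.Machine$double.eps)))
    warning("Michaelis-Menten rate evaluated at negative concentration")
  V_max * C / (K_M + C)
}

#' Quasi-linearization of the Michaelis-Menten term
#'
#' First-order expansion of `M(C)` about the expansion point `C1`, written
#' as `M(C) ~ a C + (E_AC - b)` so the semi-discrete reaction enters as a
#' matrix coefficient `a` and the load carries
#' `b = E_AC - V_max C1^2 / (K_M + C1)^2`, with
#' `a = V_max K_M / (K_M + C1)^2`. Exact at the expansion point:
#' `a * C1 + (E_AC - b) = M(C1)`.
#'
#' @param C1 expansion point(s), uM (vectorized).
#' @param V_max,K_M Michaelis-Menten parameters.
#' @param E_AC synthesis rate folded into the load (vectorized over
#'   elements).
#' @return list with components `a` (1/s) and `b` (uM/s).
#' @export
quasi_linearize <- function(C1, V_max, K_M, E_AC = 0) {
  stopifnot(V_max >= 0, K_M > 0)
  denom <- (K_M + C1)^2
  list(a = V_max * K_M / denom,
       b = E_AC - V_max * C1^2 / denom)
}

#' Activity phase at a time point
#'
#' The governing equation has three phases: diffusion only for `t < t_s`,
#' diffusion + synthesis for `t_s <= t < t_d`, and diffusion + synthesis +
#' degradation for `t >= t_d` (intervals closed on the left).
#'
#' @param t time, s (>= 0; vectorized).
#' @param t_s,t_d synthesis and degradation start times, s.
#' @return character: `"diffusion_only"`, `"synthesis"`, or
#'   `"synthesis_and_degradation"`.
#' @export
phase_of <- function(t, t_s, t_d) {
  stopifnot(all(t >= 0), t_s <= t_d)
  ifelse(t < t_s, "diffusion_only",
         ifelse(t < t_d, "synthesis", "synthesis_and_degradation"))
}

# Load vector at time t given quasi-linearization coefficients already
# folded into R2b (deg list from degradation_terms, or NULL).
load_at <- function(system, params, t, deg = NULL) {
  ph <- phase_of(t, params$t_s, params$t_d)
  if (ph == "diffusion_only") return(numeric(system$n_nodes))
  if (ph == "synthesis") return(system$R1 + system$R2s)
  # V_max = 0 makes the quasi-linearized load reduce to the synthesis load
  system$R1 + (if (is.null(deg)) system$R2s else deg$R2b)
}

# Dirichlet node set from the parameters' face-set labels.
dirichlet_nodes <- function(system, params) {
  if (is.null(params$dirichlet)) return(list(nodes = integer(0),
                                             values = numeric(0)))
  nodes <- integer(0); values <- numeric(0)
  for (lb in names(params$dirichlet)) {
    fs <- system$mesh$face_sets[[lb]]
    if (is.null(fs))
      stop("Dirichlet label '", lb, "' is not a face set of the mesh")
    nd <- unique(as.vector(face_set_triples(system$mesh, fs)))
    nodes <- c(nodes, nd)
    values <- c(values, rep(params$dirichlet[[lb]], length(nd)))
  }
  keep <- !duplicated(nodes)
  list(nodes = nodes[keep], values = values[keep])
}

#' Advance the system by one time step
#'
#' One gamma-weighted implicit step from `t_i` to `t_i + dt`. While
#' degradation is active at the target time, the quasi-linearization is
#' iterated: the expansion point `C1` starts at `c_i`, the degradation
#' matrix `K3` and load are rebuilt from the element means of `C1`, the
#' reduced linear system is re-solved, and `C1` is replaced by the new
#' solution until the relative max-norm change falls below
#' `config$inner_tol` (error after `config$max_inner` iterations). Matrices
#' and loads on the `t_i` side reflect the phase at `t_i`, those on the
#' target side the phase at `t_i + dt`.
#'
#' @param state length-n nodal concentration vector at `t_i` (uM).
#' @param system an `assembled_system`.
#' @param params `signaling_parameters`.
#' @param config `simulation_config`.
#' @param t_i current time, s.
#' @param cache optional environment reused across steps to keep the sparse
#'   factorization when the system matrix is unchanged.
#' @return list with `c` (length-n concentrations at `t_i + dt`) and
#'   `iterations` (inner iteration count; 1 when degradation is inactive or
#'   linear).
#' @export
advance_time_step <- function(state, system, params, config, t_i,
                              cache = NULL) {
  if (any(!is.finite(state)))
    stop("non-finite nodal concentrations entering step at t = ", t_i)
  dt <- config$dt; g <- config$gamma
  t_n <- t_i + dt
  deg_i <- phase_of(t_i, params$t_s, params$t_d) ==
    "synthesis_and_degradation" && params$V_max > 0
  deg_n <- phase_of(t_n, params$t_s, params$t_d) ==
    "synthesis_and_degradation" && params$V_max > 0

  dir <- if (is.null(cache) || is.null(cache$dir)) {
    dirichlet_nodes(system, params)
  } else cache$dir
  if (!is.null(cache)) cache$dir <- dir

  lhs_base <- system$K1 / dt + g * system$K2
  rhs_mat_c <- (system$K1 / dt - (1 - g) * system$K2) %*% state

  c1 <- state
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (deg_n || deg_i) {
      deg <- degradation_terms(system, c1, params$V_max, params$K_M)
    } else deg <- NULL
    lhs <- lhs_base
    rhs <- as.numeric(rhs_mat_c)
    if (deg_n) lhs <- lhs + g * deg$K3
    if (deg_i) rhs <- rhs - as.numeric(((1 - g) * deg$K3) %*% state)
    rhs <- rhs + (1 - g) * load_at(system, params, t_i, deg) +
      g * load_at(system, params, t_n, deg)

    red <- apply_dirichlet(lhs, rhs, dir$nodes, dir$values)
    if (length(red$free)) {
      reuse <- !is.null(cache) && !deg_n && !deg_i &&
        isTRUE(cache$fact_valid) && identical(cache$fact_dt, dt)
      if (reuse) {
        sol <- Matrix::solve(cache$fact, red$rhs)
      } else {
        fact <- Matrix::Cholesky(Matrix::forceSymmetric(red$matrix),
                                 LDL = FALSE, perm = TRUE)
        sol <- Matrix::solve(fact, red$rhs)
        if (!is.null(cache) && !deg_n && !deg_i) {
          cache$fact <- fact; cache$fact_valid <- TRUE; cache$fact_dt <- dt
        }
      }
      cnew <- red$recover(sol)
    } else {
      cnew <- red$recover(numeric(0))
    }
    if (any(!is.finite(cnew)))
      stop("solver produced non-finite concentrations at t = ", t_n)

    if (!deg_n) break
    delta <- max(abs(cnew - c1)) / max(max(abs(cnew)), 1e-30)
    c1 <- cnew
    if (delta <= config$inner_tol) break
    if (iter >= config$max_inner)
      stop("quasi-linearization did not converge in ", config$max_inner,
           " iterations at t = ", t_n, " (last relative change ",
           signif(delta, 3), ")")
  }
  if (min(cnew) < -1e-6)
    warning("transient negative concentration (min ", signif(min(cnew), 3),
            " uM) at t = ", t_n, "; not clamped")
  list(c = cnew, iterations = iter)
}

#' Run a cAMP signaling simulation
#'
#' Assembles (if needed) and marches the system from `t = 0` to
#' `config$t_end`, recording probe concentrations at every step and full
#' nodal fields every `config$snapshot_stride` steps. The initial field is
#' `C_o` everywhere, with Dirichlet nodes held at their prescribed values.
#' `t_s` and `t_d` must fall on the time grid.
#'
#' @param mesh a `tet_mesh` (or an `assembled_system` to reuse an assembly).
#' @param params `signaling_parameters`.
#' @param config `simulation_config`.
#' @return A `time_course`: list with `times` (s), `probes` (matrix steps x
#'   probes, uM), `probe_nodes` (node ids), `snapshots` (named list of
#'   full nodal vectors, names = times), `final` (nodal vector at `t_end`),
#'   `inner_iterations` (per step), and `params`/`config` echoes.
#' @export
simulate_signaling <- function(mesh, params, config) {
  stopifnot(inherits(params, "signaling_parameters"),
            inherits(config, "simulation_config"))
  for (tt in c(t_s = params$t_s, t_d = params$t_d)) {
    k <- tt / config$dt
    if (tt < config$t_end && abs(k - round(k)) > 1e-9 * max(1, k))
      stop("activation times t_s and t_d must be integer multiples of dt ",
           "(phase changes are snapped to the time grid)")
  }
  system <- if (inherits(mesh, "assembled_system")) mesh else {
    assemble_global(mesh, params$D,
                    face_flux_map = as.list(params$beta %||% list()),
                    volumetric_rate_map = as.list(params$E_AC))
  }

  nsteps <- round(config$t_end / config$dt)
  times <- seq(0, by = config$dt, length.out = nsteps + 1)

  pid <- integer(0)
  if (!is.null(config$probe_ids)) pid <- as.integer(config$probe_ids)
  if (!is.null(config$probe_points))
    pid <- c(pid, probe_nodes(system$mesh, config$probe_points)$node)

  dirset <- dirichlet_nodes(system, params)
  state <- rep(params$C_o, system$n_nodes)
  state[dirset$nodes] <- dirset$values

  probes <- matrix(NA_real_, nrow = nsteps + 1, ncol = length(pid))
  if (length(pid)) probes[1, ] <- state[pid]
  snaps <- list(); snaps[[format_time(0)]] <- state
  iters <- integer(nsteps)

  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nsteps)) {
    # invalidate the cached factorization when the phase of the target time
    # changes (loads/matrices switch structure at t_s and t_d)
    if (phase_of(times[i + 1], params$t_s, params$t_d) !=
        phase_of(times[i], params$t_s, params$t_d))
      cache$fact_valid <- FALSE
    st <- advance_time_step(state, system, params, config, times[i],
                            cache = cache)
    state <- st$c
    iters[i] <- st$iterations
    if (length(pid)) probes[i + 1, ] <- state[pid]
    if (is.finite(config$snapshot_stride) &&
        i %% config$snapshot_stride == 0)
      snaps[[format_time(times[i + 1])]] <- state
  }
  snaps[[format_time(times[nsteps + 1])]] <- state

  structure(list(times = times, probes = probes, probe_nodes = pid,
                 snapshots = snaps, final = state,
                 inner_iterations = iters, params = params, config = config,
                 system = system),
            class = "time_course")
}

format_time <- function(t) trimws(formatC(t, format = "g", digits = 12))

#' @export
print.time_course <- function(x, ...) {
  cat("time_course: ", length(x$times), " steps to t = ",
      x$times[length(x$times)], " s; ", length(x$probe_nodes),
      " probes; ", length(x$snapshots), " snapshots\n", sep = "")
  if (length(x$inner_iterations))
    cat("  inner iterations: mean ", round(mean(x$inner_iterations), 2),
        ", max ", max(x$inner_iterations), "\n", sep = "")
  invisible(x)
}

#' Write probe time courses to CSV
#'
#' Columns `time_s` and one `node_<id>_uM` column per probe.
#'
#' @param tc a `time_course`.
#' @param path output CSV path.
#' @export
write_probes_csv <- function(tc, path) {
  df <- data.frame(time_s = tc$times)
  for (k in seq_along(tc$probe_nodes))
    df[[paste0("node_", tc$probe_nodes[k], "_uM")]] <- tc$probes[, k]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write stored field snapshots as a VTK series
#'
#' One legacy `.vtk` file per stored snapshot, named
#' `<prefix>_<index>.vtk`, with the scalar array `cAMP_uM`.
#'
#' @param tc a `time_course`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return paths of the files written.
#' @export
write_snapshot_series <- function(tc, dir, prefix = "snapshot") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- tc$system$mesh
  paths <- character(0)
  for (k in seq_along(tc$snapshots)) {
    p <- file.path(dir, sprintf("%s_%04d.vtk", prefix, k - 1))
    write_vtk(mesh, p, values = tc$snapshots[[k]])
    paths <- c(paths, p)
  }
  paths
}

#' Discrete total cAMP content
#'
#' `1' K1 c`: the mass-matrix-weighted integral of the concentration field
#' over the domain (uM um^3). Conserved exactly by the scheme in the absence
#' of fluxes, sources, and degradation.
#'
#' @param system an `assembled_system`.
#' @param state nodal concentration vector.
#' @export
total_content <- function(system, state) {
  stopifnot(length(state) == system$n_nodes)
  as.numeric(rep(1, system$n_nodes) %*% (system$K1 %*% state))
}
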