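# Closed-form and high-accuracy reference solutions used to validate the
# finite element model: the compartmental (well-mixed) kinetics ODE, the
# spherical-shell diffusion steady state, and the membrane-flux equivalence
# of a volumetric synthesis rate.

#' Compartmental cAMP kinetics
#'
#' In the absence of boundary fluxes, with synthesis and degradation uniform
#' over the domain, the concentration is spatially uniform and obeys the
#' well-mixed ODE `dC/dt = E_AC - V_max C / (K_M + C)`, independent of
#' geometry and of the diffusion coefficient. This evaluates `C(t)` either
#' from the closed-form implicit relation obtained by separation of
#' variables (default; each evaluation is a bracketed root solve to 1e-12
#' absolute) or by adaptive high-order numerical integration
#' (`method = "ode"`, [deSolve::ode()] at 1e-10/1e-12 tolerances). The two
#' routes are mutually independent and agree to ~1e-10, which the test
#' suite uses as a cross-check.
#'
#' Closed form: with `m = E_AC - V_max` and `q = E_AC K_M`, separation of
#' variables gives the strictly monotone time map
#' `T(C) = (C - C_o)/m + (K_M - q/m)/m * log((m C + q)/(m C_o + q))`
#' (for `m != 0`; the `V_max = 0` branch is the explicit line
#' `C = C_o + E_AC t`, and `m = 0` integrates to a quadratic in `C`).
#'
#' @param t_grid times, s (non-negative, increasing).
#' @param E_AC synthesis rate, uM/s.
#' @param V_max,K_M Michaelis-Menten degradation parameters.
#' @param C_o initial concentration, uM.
#' @param method `"closed_form"` or `"ode"`.
#' @return numeric vector of concentrations (uM) on `t_grid`.
#' @export
compartmental_timecourse <- function(t_grid, E_AC, V_max, K_M, C_o,
                                     method = c("closed_form", "ode")) {
  method <- match.arg(method)
  stopifnot(all(t_grid >= 0), E_AC >= 0, V_max >= 0, K_M > 0, C_o >= 0)
  if (method == "ode") {
    tg <- sort(unique(c(0, t_grid)))
    out <- deSolve::ode(y = c(C = C_o), times = tg,
                        func = function(t, y, p)
                          list(E_AC - michaelis_menten_rate(y, V_max, K_M)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    return(unname(out[match(t_grid, tg), "C"]))
  }
  if (V_max == 0) return(C_o + E_AC * t_grid)

  m <- E_AC - V_max
  q <- E_AC * K_M
  time_of <- function(C) {
    if (m != 0) {
      (C - C_o) / m + (K_M - q / m) / m * log((m * C + q) / (m * C_o + q))
    } else {
      (K_M * (C - C_o) + (C^2 - C_o^2) / 2) / q
    }
  }
  rate0 <- E_AC - michaelis_menten_rate(C_o, V_max, K_M)
  css <- suppressWarnings(compartmental_steady_state(E_AC, V_max, K_M))
  vapply(t_grid, function(t) {
    if (t == 0 || rate0 == 0) return(C_o)
    if (rate0 > 0) {
      hi <- if (is.finite(css)) css else C_o + E_AC * t
      lo <- C_o
      # T(C) -> Inf as C -> css; shrink the upper end inside the bracket
      hi <- lo + (hi - lo) * (1 - 1e-15)
      if (time_of(hi) < t) return(hi)
    } else {
      # decay: C stays in (floor, C_o]; floor is css (or 0 when E_AC = 0)
      fl <- if (is.finite(css)) css else 0
      # lower bound: linearized fastest decay rate V_max/K_M
      lo <- max(fl * (1 + 1e-15), C_o * exp(-V_max / K_M * t) * 0.5,
                1e-300)
      hi <- C_o
      while (time_of(lo) < t && lo > 1e-300) lo <- lo * 0.5
      if (lo <= 1e-300 && time_of(lo) < t) return(0)
    }
    stats::uniroot(function(C) time_of(C) - t, lower = min(lo, hi),
                   upper = max(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Compartmental steady state
#'
#' Root of `E_AC = V_max C / (K_M + C)`: `C_ss = E_AC K_M / (V_max - E_AC)`
#' when `E_AC < V_max`; 0 when `E_AC = 0`; no finite steady state (returns
#' `Inf` with a warning) when `E_AC >= V_max > 0` or when degradation is
#' absent but synthesis is active.
#'
#' @param E_AC synthesis rate, uM/s.
#' @param V_max,K_M degradation parameters.
#' @return steady-state concentration, uM (possibly `Inf`).
#' @export
compartmental_steady_state <- function(E_AC, V_max, K_M) {
  stopifnot(E_AC >= 0, V_max >= 0, K_M > 0)
  if (E_AC == 0) return(0)
  if (E_AC >= V_max) {
    warning("no finite steady state: synthesis E_AC = ", E_AC,
            " uM/s is not below V_max = ", V_max, " uM/s")
    return(Inf)
  }
  E_AC * K_M / (V_max - E_AC)
}

#' Spherical-shell diffusion steady state
#'
#' The steady diffusion (Laplace) profile between two concentric spheres
#' with prescribed concentrations is `C(r) = A + B / r`, with `A`, `B`
#' fixed by the boundary values at `R_i` and `R_o`. Independent of the
#' diffusion coefficient.
#'
#' @param r radii at which to evaluate, um; must lie in `[R_i, R_o]`.
#' @param R_o,R_i outer and inner radii, um.
#' @param C_at_Ro,C_at_Ri prescribed concentrations, uM.
#' @return concentrations at `r`, uM.
#' @export
shell_steady_state <- function(r, R_o, R_i, C_at_Ro, C_at_Ri) {
  stopifnot(R_i > 0, R_o > R_i)
  tol <- 1e-9 * R_o
  if (any(r < R_i - tol | r > R_o + tol))
    stop("radius outside the shell [R_i, R_o]")
  B <- (C_at_Ri - C_at_Ro) / (1 / R_i - 1 / R_o)
  A <- C_at_Ro - B / R_o
  A + B / r
}

#' Membrane flux equivalent to a volumetric synthesis rate
#'
#' The plasma-membrane influx `beta` carrying the same total synthesis
#' activity as the uniform volumetric rate `E_AC` over the spherical-shell
#' cytosol: `E_AC V_c = beta S_p` gives
#' `beta = E_AC (R_o^3 - R_i^3) / (3 R_o^2)`.
#'
#' @param E_AC volumetric synthesis rate, uM/s.
#' @param R_o,R_i cell and nucleus radii, um.
#' @return flux `beta`, uM um/s.
#' @examples
#' membrane_flux_equivalent(0.1412, 9.34, 5.26)  # 0.3611 uM um/s
#' @export
membrane_flux_equivalent <- function(E_AC, R_o, R_i) {
  stopifnot(R_o > 0, R_i >= 0, R_i < R_o)
  E_AC * (R_o^3 - R_i^3) / (3 * R_o^2)
}

#' Degradation rate ratio
#'
#' `V_max / K_M` (1/s): in the low-concentration regime (`C << K_M`) the
#' Michaelis-Menten term reduces to first-order decay at this rate, so
#' compartmental degradation curves with equal ratios coincide.
#'
#' @param V_max maximum degradation rate, uM/s.
#' @param K_M Michaelis constant, uM.
#' @return ratio, 1/s.
#' @export
rate_ratio <- function(V_max, K_M) {
  stopifnot(K_M > 0)
  V_max / K_M
}

#' Export oracle evaluations as CSV
#'
#' Convenience for plotting reference curves against FEM probes: writes
#' `time_s`, `C_uM`.
#'
#' @param t_grid times, s.
#' @param C concentrations, uM.
#' @param path output path.
#' @export
write_oracle_csv <- function(t_grid, C, path) {
  utils::write.csv(data.frame(time_s = t_grid, C_uM = C), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
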