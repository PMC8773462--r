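test_that("Michaelis-Menten rate is exact, saturating, and warns below zero", {
  expect_equal(michaelis_menten_rate(2, 0.295, 2), 0.1475)
  expect_equal(michaelis_menten_rate(0, 0.295, 2), 0)
  expect_equal(michaelis_menten_rate(1e9, 0.295, 2), 0.295, tolerance = 1e-6)
  expect_true(all(diff(michaelis_menten_rate(seq(0, 10, 0.1), 0.295, 2)) > 0))
  expect_warning(michaelis_menten_rate(-0.1, 0.295, 2), "negative")
})

test_that("quasi-linearization coefficients match the expansion formulas", {
  q0 <- quasi_linearize(0, 0.295, 2, E_AC = 0.1412)
  expect_equal(q0$a, 0.295 / 2)
  expect_equal(q0$b, 0.1412)

  q2 <- quasi_linearize(2, 0.295, 2, E_AC = 0)
  expect_equal(q2$a, 0.036875)
  expect_equal(q2$b, -0.07375)

  # exactness at the expansion point: a C1 + (E_AC - b) = M(C1)
  for (c1 in c(0, 0.05, 0.5, 2, 17)) {
    q <- quasi_linearize(c1, 0.295, 2, E_AC = 0.1412)
    expect_equal(q$a * c1 + (0.1412 - q$b),
                 michaelis_menten_rate(c1, 0.295, 2), tolerance = 1e-12)
  }
})

test_that("phase selection follows the three-branch activity schedule", {
  expect_equal(phase_of(5, 10, 20), "diffusion_only")
  expect_equal(phase_of(10, 10, 20), "synthesis")   # closed on the left
  expect_equal(phase_of(19.999, 10, 20), "synthesis")
  expect_equal(phase_of(20, 10, 20), "synthesis_and_degradation")
  expect_equal(phase_of(c(0, 50), 0, 0),
               rep("synthesis_and_degradation", 2))
  expect_error(signaling_parameters(D = 1, t_s = 20, t_d = 10), "t_s <= t_d")
})

test_that("single steps reproduce steady states and the compartmental ODE", {
  m <- sphere_mesh(edge = 4, seed = 1)
  cf <- simulation_config(dt = 1, t_end = 10)

  # zero loads, uniform state: exact fixed point
  p0 <- signaling_parameters(D = 30, E_AC = 0, V_max = 0, C_o = 0.05)
  sys <- assemble_global(m, 30)
  st <- advance_time_step(rep(0.05, sys$n_nodes), sys, p0, cf, 0)
  expect_equal(st$c, rep(0.05, sys$n_nodes), tolerance = 1e-12)
  expect_equal(st$iterations, 1L)

  # one degradation step tracks a high-accuracy ODE integration at the
  # scheme's first-order accuracy, improving linearly under dt refinement
  p1 <- signaling_parameters(D = 30, E_AC = 0, V_max = 0.295, K_M = 2,
                             C_o = 0.05, t_d = 0)
  st1 <- advance_time_step(rep(0.05, sys$n_nodes), sys, p1, cf, 0)
  ref <- compartmental_timecourse(1, 0, 0.295, 2, 0.05, method = "ode")
  err1 <- max(abs(st1$c - ref)) / ref
  expect_lt(err1, 5e-3)
  expect_gt(st1$iterations, 1L)
  cf01 <- simulation_config(dt = 0.1, t_end = 10)
  st01 <- advance_time_step(rep(0.05, sys$n_nodes), sys, p1, cf01, 0)
  ref01 <- compartmental_timecourse(0.1, 0, 0.295, 2, 0.05, method = "ode")
  err01 <- max(abs(st01$c - ref01)) / ref01
  expect_lt(err01, 0.2 * err1)

  # V_max = 0 keeps the inner loop linear: exactly one iteration
  p2 <- signaling_parameters(D = 30, E_AC = 0.1412, V_max = 0, C_o = 0.05)
  sys2 <- assemble_global(m, 30,
                          volumetric_rate_map = list(cytosol = 0.1412))
  st2 <- advance_time_step(rep(0.05, sys2$n_nodes), sys2, p2, cf, 0)
  expect_equal(st2$iterations, 1L)
})

test_that("quiescent runs stay at C_o and synthesis-only runs are exactly linear", {
  m <- sphere_mesh(edge = 4, seed = 1)
  p <- signaling_parameters(D = 3, E_AC = 0, V_max = 0, C_o = 0.05)
  tc <- simulate_signaling(m, p, simulation_config(dt = 5, t_end = 50))
  expect_equal(tc$final, rep(0.05, nrow(m$nodes)), tolerance = 1e-12)

  psyn <- signaling_parameters(D = 3, E_AC = 0.1412, V_max = 0, C_o = 0.05)
  tcs <- simulate_signaling(m, psyn,
                            simulation_config(dt = 1, t_end = 30,
                                              probe_points = rbind(c(PAR$R_o, 0, 0))))
  expect_equal(tcs$probes[, 1], 0.05 + 0.1412 * tcs$times, tolerance = 1e-10)
})

test_that("compartmental runs are uniform and independent of D and geometry", {
  cf <- simulation_config(dt = 1, t_end = 120,
                          probe_points = rbind(c(8, 0.5, 0.2)))
  ref <- compartmental_timecourse(seq(0, 120), PAR$E_AC, PAR$V_max,
                                  PAR$K_M, PAR$C_o)
  finals <- c()
  for (mesh in list(sphere_mesh(edge = 4, seed = 1), cell_mesh(edge = 2))) {
    for (D in c(0.3, 300)) {
      p <- signaling_parameters(D = D, E_AC = PAR$E_AC, V_max = PAR$V_max,
                                K_M = PAR$K_M, C_o = PAR$C_o)
      tc <- suppressWarnings(simulate_signaling(mesh, p, cf))
      expect_lt(max(abs(tc$final - mean(tc$final))), 1e-10)
      expect_lt(curve_discrepancy(tc$probes[, 1], ref), 0.01)
      finals <- c(finals, mean(tc$final))
    }
  }
  expect_lt(diff(range(finals)), 1e-9)
})

test_that("total content is conserved without sources, fluxes or degradation", {
  m <- sphere_mesh(edge = 2.4, seed = 2)
  sys <- assemble_global(m, 30)
  p <- signaling_parameters(D = 30, E_AC = 0, V_max = 0, C_o = 0.05)
  cf <- simulation_config(dt = 1, t_end = 10)
  set.seed(1)
  state <- 0.05 + stats::runif(sys$n_nodes) * 0.1
  tot0 <- total_content(sys, state)
  for (i in 0:9) state <- advance_time_step(state, sys, p, cf, i)$c
  expect_lt(abs(total_content(sys, state) - tot0) / tot0, 1e-10)
})

test_that("quasi-linearization reduces to first-order decay for C << K_M", {
  m <- sphere_mesh(edge = 4, seed = 1)
  p <- signaling_parameters(D = 300, E_AC = 0, V_max = 59, K_M = 1000,
                            C_o = 0.05, t_d = 0)
  tc <- simulate_signaling(m, p,
                           simulation_config(dt = 1, t_end = 60,
                                             probe_points = rbind(c(PAR$R_o, 0, 0))))
  expect_lt(curve_discrepancy(tc$probes[, 1],
                              0.05 * exp(-0.059 * tc$times)), 0.005)
})

test_that("the scheme is stable across coarse time steps and preserves the steady state", {
  m <- sphere_mesh(edge = 4, seed = 1)
  css <- compartmental_steady_state(PAR$E_AC, PAR$V_max, PAR$K_M)
  for (dt in c(1, 5, 10)) {
    p <- signaling_parameters(D = 300, E_AC = PAR$E_AC, V_max = PAR$V_max,
                              K_M = PAR$K_M, C_o = PAR$C_o)
    tc <- simulate_signaling(m, p, simulation_config(dt = dt, t_end = 600))
    expect_true(all(is.finite(unlist(tc$snapshots))))
    expect_true(max(abs(tc$final)) < 10 * css)
    expect_lt(abs(mean(tc$final) - css) / css, 0.02)
  }
})

test_that("configuration guards refuse off-grid activations and bad gamma", {
  expect_error(simulation_config(dt = 1, t_end = 10, gamma = 0.3),
               "gamma")
  expect_error(simulation_config(dt = 3, t_end = 10), "multiple")
  m <- sphere_mesh(edge = 4, seed = 1)
  p <- signaling_parameters(D = 1, E_AC = 0.1, t_s = 2.5, t_d = 2.5)
  expect_error(simulate_signaling(m, p,
                                  simulation_config(dt = 2, t_end = 10)),
               "multiples of dt")
})

test_that("probe recording, snapshots and CSV output are consistent", {
  m <- sphere_mesh(edge = 4, seed = 1)
  p <- signaling_parameters(D = 3, E_AC = PAR$E_AC, V_max = 0, C_o = 0.05)
  cf <- simulation_config(dt = 1, t_end = 10, snapshot_stride = 5,
                          probe_points = rbind(c(PAR$R_o, 0, 0),
                                               c(PAR$R_i, 0, 0)))
  tc <- simulate_signaling(m, p, cf)
  expect_equal(tc$times, 0:10)
  expect_equal(dim(tc$probes), c(11L, 2L))
  expect_equal(unname(tc$probes[1, ]), rep(0.05, 2))
  expect_setequal(names(tc$snapshots), c("0", "5", "10"))
  expect_equal(tc$snapshots[["10"]], tc$final)

  f <- withr::local_tempfile(fileext = ".csv")
  write_probes_csv(tc, f)
  tab <- read.csv(f)
  expect_equal(names(tab)[1], "time_s")
  expect_equal(ncol(tab), 3)
  expect_equal(tab$time_s, 0:10)
})
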