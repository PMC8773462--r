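test_that("presets are enumerable and validated before compute", {
  expect_true(all(c("compartmental_pde_only", "membrane_ac_cytosol_pde",
                    "delayed_start") %in% scenario_presets()))
  expect_error(scenario_preset("nope"), "unknown preset")
  expect_error(scenario_config(list(type = "torus"),
                               signaling_parameters(D = 1),
                               simulation_config(dt = 1, t_end = 1)),
               "unknown geometry")
})

test_that("compartmental degradation preset reproduces the kinetics oracle", {
  sc <- scenario_preset("compartmental_pde_only", t_end_s = 120)
  tc <- run_scenario(sc)
  ref <- compartmental_timecourse(tc$times, 0, PAR$V_max, PAR$K_M, PAR$C_o)
  expect_lt(curve_discrepancy(tc$probes[, 1], ref), 0.01)
  s <- attr(tc, "summary")
  expect_equal(s$scenario, "compartmental_pde_only")
  expect_equal(s$nodes, nrow(tc$system$mesh$nodes))
})

test_that("membrane-flux scenario orders probes by distance from the synthesis source", {
  tc <- run_scenario("membrane_ac_cytosol_pde")
  fin <- tc$probes[nrow(tc$probes), ]
  # outer (subplasmalemmal) >= mid-cytosol >= perinuclear at steady state
  expect_gte(fin[1], fin[2])
  expect_gte(fin[2], fin[3])
  # bracketed by the compartmental steady state scale
  css <- compartmental_steady_state(PAR$E_AC, PAR$V_max, PAR$K_M)
  expect_gt(fin[3], 0.5 * css)
  expect_lt(fin[1], 2 * css)
})

test_that("delayed-start scenario is flat, then rises linearly, then saturates", {
  tc <- run_scenario(scenario_preset("delayed_start", t_end_s = 120))
  tt <- tc$times
  # flat at C_o before synthesis starts
  pre <- vapply(tc$snapshots[as.numeric(names(tc$snapshots)) < 10],
                function(s) max(abs(s - PAR$C_o)), numeric(1))
  expect_lt(max(pre), 1e-10)
  # strictly rising during the synthesis-only window
  pr <- tc$probes[, 1]
  expect_true(all(diff(pr[tt >= 10 & tt <= 20]) > 0))
  # synthesis-only: total content grows exactly linearly on steps fully
  # inside the synthesis window (membrane influx, no degradation yet)
  sys <- tc$system
  tot <- vapply(as.character(13:19),
                function(k) total_content(sys, tc$snapshots[[k]]),
                numeric(1))
  expect_lt(max(abs(diff(diff(tot)))) / abs(mean(diff(tot))), 1e-8)
  # slope decreases once degradation starts at t_d = 20
  expect_lt(pr[tt == 22] - pr[tt == 21], pr[tt == 20] - pr[tt == 19])
  # beta = 2 exceeds the sphere's degradation capacity (beta S/V > V_max),
  # so the late curve tends to a linear asymptote with slope
  # beta S/V - V_max rather than a plateau
  sp <- sum(vapply(seq_len(nrow(sys$mesh$face_sets$plasma_membrane)),
                   function(k) {
                     fs <- sys$mesh$face_sets$plasma_membrane
                     tri <- sys$mesh$elements[fs$element[k],
                       campfem:::TET_LOCAL_FACES[fs$face[k], ]]
                     face_area(sys$mesh$nodes[tri, ])
                   }, numeric(1)))
  slope_inf <- 2 * sp / sum(element_volumes(sys$mesh)) - PAR$V_max
  late_slope <- (pr[tt == 120] - pr[tt == 115]) / 5
  expect_equal(late_slope, slope_inf, tolerance = 0.1)
  expect_lt(late_slope, (pr[tt == 20] - pr[tt == 15]) / 5)
})

test_that("run_scenario writes the documented outputs", {
  out <- withr::local_tempdir()
  sc <- scenario_preset("compartmental_ac_only", t_end_s = 10,
                        output_dir = out)
  tc <- run_scenario(sc)
  expect_true(file.exists(file.path(out, "probes.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "run.log")))
  expect_gt(length(list.files(file.path(out, "snapshots"),
                              pattern = "\\.vtk$")), 0)
  s <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(s$scenario, "compartmental_ac_only")
  expect_equal(s$t_end_s, 10)
  tab <- read.csv(file.path(out, "probes.csv"))
  expect_equal(nrow(tab), 11)
})

test_that("scenario YAML configs round trip into runnable scenarios", {
  path <- system.file("extdata", "delayed_start_sphere.yaml",
                      package = "campfem")
  sc <- read_scenario_config(path)
  expect_s3_class(sc, "scenario_config")
  expect_equal(sc$params$t_s, 10)
  expect_equal(sc$params$t_d, 20)
  expect_equal(sc$params$beta[["plasma_membrane"]], 2)
  expect_equal(sc$config$dt, 1)
  expect_equal(sc$geometry$R_o_um, 9.34)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("name: x", bad)
  expect_error(read_scenario_config(bad), "must define")
})

test_that("time-step refinement reduces the compartmental error monotonically", {
  sc <- scenario_preset("compartmental_ac_pde", t_end_s = 200)
  tab <- convergence_study(sc, dt_values = c(10, 5, 1))
  expect_equal(tab$level, c(10, 5, 1))
  expect_true(all(diff(tab$discrepancy) < 0))
  expect_true(all(is.finite(tab$probe_final_uM)))
  # identical configs give identical tables
  tab2 <- convergence_study(sc, dt_values = c(10, 5, 1))
  expect_identical(tab, tab2)
  expect_error(convergence_study(sc, dt_values = 5), "at least two")
})
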