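test_that("abiotic reactor washes out to the influent concentration", {
  cfg <- reactor_config(duration = 120)
  sim <- simulate_reactor(cfg, guilds = list())
  c_in <- cfg$influent_nh4_load / cfg$influent_flow
  last <- nrow(sim$true_chem)
  expect_equal(sim$true_chem$effluent_nh4[last] / cfg$influent_flow, c_in,
               tolerance = 1e-6)
  expect_equal(sim$true_chem$effluent_no2[last], 0, tolerance = 1e-8)
  expect_lt(sim$true_chem$effluent_no3[last] / cfg$influent_flow, 1e-6)
  expect_equal(sim$n2_rate[last], 0)
})

test_that("anammox produces nitrate and dinitrogen in the fixed 0.26:2.04 ratio", {
  cfg <- reactor_config(duration = 1)     # evaluate mid-reaction
  amx <- default_guilds()["AMX"]
  sim <- simulate_reactor(cfg, amx,
                          init = list(nh4 = 40, no2 = 60, no3 = 0,
                                      attached = c(AMX = 10),
                                      suspended = c(AMX = 0)))
  D <- cfg$influent_flow / cfg$working_volume
  fd <- unname(sim$final_derivs)
  no3_end <- sim$true_chem$effluent_no3[nrow(sim$true_chem)] / cfg$influent_flow
  prod_no3 <- fd[3] + D * no3_end          # mg N/L/d formed by reaction
  prod_n2 <- fd[4]
  expect_gt(prod_n2, 1e-4)                 # reaction actually running
  expect_equal(prod_no3 / prod_n2, 0.26 / 2.04, tolerance = 1e-6)
})

test_that("disturbance resuspends attached biomass and conserves totals", {
  st <- list(attached = c(A = 10, B = 4), suspended = c(A = 2, B = 1))
  expect_identical(apply_disturbance(st, 0), st)
  full <- apply_disturbance(st, 1)
  expect_equal(unname(full$attached), c(0, 0))
  expect_equal(unname(full$suspended), c(12, 5))
  for (f in c(0.25, 0.5, 0.9)) {
    out <- apply_disturbance(st, f)
    expect_equal(out$attached + out$suspended, st$attached + st$suspended)
  }
  expect_error(apply_disturbance(st, 1.2), "mixing_fraction")
  expect_error(apply_disturbance(st, -0.1), "mixing_fraction")
})

test_that("tracer mean residence time equals V/Q", {
  expect_equal(tracer_mean_residence_time(reactor_config(working_volume = 1,
                                                         influent_flow = 1)),
               1.0, tolerance = 1e-3)
  m1 <- tracer_mean_residence_time(reactor_config(working_volume = 2,
                                                  influent_flow = 0.8))
  m2 <- tracer_mean_residence_time(reactor_config(working_volume = 4,
                                                  influent_flow = 0.8))
  expect_equal(m1, 2.5, tolerance = 1e-2)
  expect_equal(m2 / m1, 2, tolerance = 1e-2)     # linear in V at fixed Q
  expect_error(tracer_mean_residence_time(reactor_config(), horizon = 2),
               "horizon too short")
})

test_that("nitrogen is conserved and states stay non-negative across runs", {
  for (seed in c(2, 9)) {
    run <- cached_run(seed)
    sim <- run$sim
    expect_lt(max(abs(sim$balance_error)), 1e-3)   # within 0.1% of the load
    expect_true(all(sim$guild_biomass >= 0))
    expect_true(all(as.matrix(sim$true_chem[, c("effluent_nh4",
                                                "effluent_no2",
                                                "effluent_no3")]) >= 0))
    expect_true(all(sim$n2_rate >= -1e-9))
  }
})

test_that("oversized integrator step is rejected", {
  expect_error(simulate_reactor(reactor_config(dt = 5)), "step size")
})

test_that("simulated steady-state chemistry round-trips through the partition", {
  cfg <- reactor_config(duration = 1500)
  sim <- simulate_reactor(cfg)
  last <- nrow(sim$true_chem)
  p <- partition_nitrogen(sim$true_chem[last, , drop = FALSE])
  true_n2 <- sim$n2_rate[last]
  expect_equal(p$n2, true_n2, tolerance = 1e-5)
  expect_equal(p$ap_no3, true_n2 * 0.26 / 2.04, tolerance = 1e-5)
})

test_that("taxon profiles are simplex-valued and stages are planted as scheduled", {
  run <- cached_run(11)
  prof <- run$sim$taxon_profile
  expect_true(all(abs(rowSums(prof) - 1) < 1e-9))
  expect_true(all(prof >= 0))
  expect_identical(run$truth$stages,
                   c(rep(1L, 13), rep(2L, 21), rep(3L, 22)))
})

test_that("configuration validation rejects impossible reactors", {
  expect_error(reactor_config(working_volume = -1), "working_volume")
  expect_error(reactor_config(influent_nh4_load = -5), "influent_nh4_load")
  expect_error(reactor_config(duration = 0.1, dt = 0.25), "duration")
})
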