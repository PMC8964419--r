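test_that("closed-form bimolecular oracle handles its edge cases", {
  expect_equal(closed_form_bimolecular(2, 1, 5, 0), 2)
  expect_equal(closed_form_bimolecular(2, 1, 0, c(0, 10, 100)), rep(2, 3))
  expect_equal(closed_form_bimolecular(1, 1, 1, 1), 0.5)
  # unequal-concentration form approaches the excess difference
  expect_equal(closed_form_bimolecular(2, 1, 1, 1e6), 1, tolerance = 1e-6)
})

test_that("the integrator matches second-order and pseudo-first-order kinetics", {
  tt <- seq(0, 30, by = 0.5)
  st <- solver_settings(rtol = 1e-10, atol = 1e-12, t_grid = tt)

  sim <- simulate_network(bimolecular_net(1, 1, k = 1), st)
  expect_equal(sim$conc[, "A"], closed_form_bimolecular(1, 1, 1, tt),
               tolerance = 1e-6)

  sim2 <- simulate_network(bimolecular_net(2, 0.5, k = 0.8), st)
  expect_equal(sim2$conc[, "A"], closed_form_bimolecular(2, 0.5, 0.8, tt),
               tolerance = 1e-6)

  # pseudo-first-order limit: B in overwhelming excess, A decays
  # exponentially (short window keeps values above the absolute tolerance)
  ts <- seq(0, 2, by = 0.05)
  sim3 <- simulate_network(bimolecular_net(1e-6, 10, k = 0.5),
                           solver_settings(rtol = 1e-10, atol = 1e-14,
                                           t_grid = ts))
  expect_equal(sim3$conc[, "A"], 1e-6 * exp(-0.5 * 10 * ts),
               tolerance = 1e-6)
})

test_that("a zero-template network produces no output", {
  ckt <- library_circuit("unregulated_sensor")
  ckt$templates[[1]]$concentration_uM <- 0
  sim <- simulate_network(compile_network(ckt), coarse_grid())
  expect_true(all(mef_trace(sim)$mef == 0))
})

test_that("without gates the transcript accumulates linearly at k_tx * template", {
  ckt <- library_circuit("unregulated_sensor")
  ckt$gates[[1]]$concentration <- 0
  p <- default_params
  sim <- simulate_network(compile_network(ckt, p), coarse_grid())
  expect_equal(sim$conc[, "InvadeR_u"], p$k_tx * 0.05 * sim$t,
               tolerance = 1e-6)
})

test_that("activation_time interpolates the first crossing", {
  flat <- data.frame(time = 0:100, value = rep(0, 101))
  expect_true(is.na(activation_time(flat, 0.5)))
  linear <- data.frame(time = 0:100, value = (0:100) / 100)
  expect_equal(activation_time(linear, 0.5), 50)
  expect_error(activation_time(linear, -1), "threshold")
})

test_that("conservation holds to 1e-8 on every library circuit", {
  for (nm in circuit_library()$name) {
    ckt <- library_circuit(nm)
    cond <- stats::setNames(rep(100, length(ckt$ligand_names)),
                            ckt$ligand_names)
    sim <- simulate_network(compile_network(ckt, default_params, cond),
                            coarse_grid())
    rep <- check_conservation(sim, tol = 1e-8)
    expect_true(all(rep$ok), label = nm)
  }
})

test_that("conservation checking flags corrupted trajectories and handles empty networks", {
  net <- compile_network(library_circuit("unregulated_sensor"))
  sim <- simulate_network(net, coarse_grid())
  sim$conc[31, "gate_SignalGate"] <- sim$conc[31, "gate_SignalGate"] + 0.5
  rep <- check_conservation(sim)
  expect_false(all(rep$ok))
  expect_false(rep$ok[rep$moiety == "gate:SignalGate"])

  empty <- mass_action_network(data.frame(name = "A", init = 1), list())
  esim <- simulate_network(empty, coarse_grid())
  expect_equal(nrow(check_conservation(esim)), 0)
})

test_that("halving the step cap changes the endpoint by less than 0.1 percent", {
  net <- compile_network(library_circuit("aTc_sensor"), default_params,
                         condition = c(aTc = 10))
  f <- function(h) {
    sim <- simulate_network(net, solver_settings(t_grid = seq(0, 120, 1),
                                                 max_step = h))
    m <- mef_trace(sim)$mef
    m[length(m)]
  }
  expect_lt(abs(f(1) - f(0.5)) / f(0.5), 1e-3)
})

test_that("integration failures name the offending species", {
  net <- bimolecular_net(1, 1)
  net$S["C", 1] <- -1  # corrupt stoichiometry: C is consumed from zero
  expect_error(simulate_network(net, solver_settings(t_grid = 0:100)),
               "integration failure.*'C'")
})

test_that("trajectory tables are tidy and written on request", {
  sim <- simulate_network(compile_network(library_circuit("unregulated_sensor")),
                          coarse_grid(10, 1))
  df <- trajectory_table(sim)
  expect_setequal(names(df), c("time", "species", "concentration"))
  expect_equal(nrow(df), 11 * ncol(sim$conc))
})
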