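# ADC / kinetic-comparator tests use the graded zinc sensor and the
# unregulated comparator base; the full four-tube zinc design is exercised
# in the acceptance suite.

test_that("critical threshold is 0 for a repressed input and fixes the endpoint", {
  zs <- library_circuit("zinc_sensor")
  expect_equal(as.numeric(critical_threshold(zs, 0, params = default_params)),
               0)
  th <- critical_threshold(zs, 3, params = default_params)
  expect_gt(as.numeric(th), 0)
  expect_lt(abs(attr(th, "mef") - 0.5), 5e-3)
})

test_that("critical threshold is non-decreasing in the input concentration", {
  zs <- library_circuit("zinc_sensor")
  ths <- vapply(c(1, 3, 8), function(x)
    as.numeric(critical_threshold(zs, x, params = default_params)),
    numeric(1))
  expect_true(all(diff(ths) > 0))
})

test_that("a single breakpoint yields a working comparator", {
  zs <- library_circuit("zinc_sensor")
  cmp <- design_thresholds(zs, breakpoints = 4, params = default_params)
  expect_length(cmp$thresholds, 1)
  below <- simulate_adc(cmp, 1)
  above <- simulate_adc(cmp, 6)
  expect_equal(below$n_on, 0)
  expect_equal(below$decoded, "< 4")
  expect_equal(above$n_on, 1)
  expect_equal(above$decoded, ">= 4")
})

test_that("activation time grows with the threshold ratio over 0x-8x", {
  base <- library_circuit("comparator_base")
  sig <- base$gates[[1]]$concentration
  delays <- vapply(c(0, 0.5, 1, 2, 4, 8) * sig, function(theta) {
    ckt <- add_threshold_gate(base, theta)
    sim <- simulate_network(compile_network(ckt, default_params),
                            solver_settings(t_grid = seq(0, 120, 1)))
    at <- activation_time(sim, 0.5)
    if (is.na(at)) Inf else at
  }, numeric(1))
  expect_true(all(diff(delays) > 0))
  # a zero threshold gate is indistinguishable from no threshold gate
  sim0 <- simulate_network(compile_network(base, default_params),
                           solver_settings(t_grid = seq(0, 120, 1)))
  expect_lt(abs(delays[1] - activation_time(sim0, 0.5)), 1)
})

test_that("activation delay follows the quasi-static theta/production law", {
  base <- library_circuit("comparator_base")
  p <- default_params
  # 8-nt threshold vs 4-nt reporter: rate ratio 100, quasi-static regime
  expect_gte(toehold_rate(8, p) / toehold_rate(4, p), 100)
  production <- p$k_tx * 0.05
  t0 <- activation_time(simulate_network(compile_network(base, p),
                                         solver_settings(t_grid = seq(0, 120, 0.5))),
                        0.5)
  for (theta in c(2, 4, 6)) {
    ckt <- add_threshold_gate(base, theta)
    at <- activation_time(simulate_network(compile_network(ckt, p),
                                           solver_settings(t_grid = seq(0, 120, 0.5))),
                          0.5)
    expect_equal(at - t0, theta / production, tolerance = 0.1)
  }
})

test_that("monotonicity audits pass for valid designs and fail for shuffled thresholds", {
  zs <- library_circuit("zinc_sensor")
  design <- design_thresholds(zs, breakpoints = c(2, 5),
                              params = default_params)
  aud <- audit_monotonicity(design, c(0, 1, 3, 7, 12))
  expect_true(attr(aud, "pass"))
  expect_true(all(aud$thermometer))

  empty <- audit_monotonicity(design, numeric())
  expect_true(attr(empty, "pass"))
  expect_equal(nrow(empty), 0)

  bad <- design
  bad$thresholds <- rev(bad$thresholds)
  aud_bad <- audit_monotonicity(bad, c(3, 4))
  expect_false(attr(aud_bad, "pass"))
})

test_that("designs serialize to JSON and back", {
  zs <- library_circuit("zinc_sensor")
  design <- design_thresholds(zs, breakpoints = 4, params = default_params)
  path <- withr::local_tempfile(fileext = ".json")
  write_adc_design(design, path)
  back <- read_adc_design(path)
  expect_equal(back$thresholds, design$thresholds)
  expect_equal(back$base_circuit, design$base_circuit)
  expect_equal(back$params, design$params)
  expect_equal(simulate_adc(back, 6)$n_on, 1)
})

test_that("ungraded sensors are rejected with a diagnostic, not a design", {
  flat <- library_circuit("comparator_base")
  flat$ligand_names <- "zinc"  # ligand present but disconnected from output
  expect_error(design_thresholds(flat, c(2, 5), params = default_params),
               "audit failure")
})
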