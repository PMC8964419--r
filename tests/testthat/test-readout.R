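test_that("calibration recovers the conversion factor exactly from clean standards", {
  std <- generate_standards(conversion_factor = 1000, intercept = 80,
                            noise = noise_model(additive_sd = 0,
                                                multiplicative_cv = 0),
                            seed = 1)
  cal <- fit_mef_calibration(std)
  expect_equal(cal$conversion_factor, 1000, tolerance = 1e-9)
  expect_equal(cal$intercept, 80, tolerance = 1e-9)
  expect_equal(cal$linear_range_max, 3.125)
  # a trace equal to the blank converts to 0 MEF; one slope unit above to 1
  expect_equal(to_mef(80, cal), 0)
  expect_equal(to_mef(1080, cal), 1)
})

test_that("saturated concentrations are excluded from the fit set", {
  std <- generate_standards(conversion_factor = 1000, intercept = 0,
                            noise = noise_model(additive_sd = 0,
                                                multiplicative_cv = 0,
                                                saturation_ceiling = 30000),
                            seed = 1)
  expect_true(any(std$saturated))
  cal <- fit_mef_calibration(std)
  expect_true(all(cal$excluded_saturated >= 30))
  expect_equal(cal$conversion_factor, 1000, tolerance = 1e-9)
})

test_that("degenerate standards raise informative errors", {
  std <- generate_standards(noise = noise_model(additive_sd = 0,
                                                multiplicative_cv = 0))
  expect_error(fit_mef_calibration(std[std$concentration > 5, ]), "blank")
  sat_all <- transform(std, saturated = TRUE)
  expect_error(fit_mef_calibration(sat_all), "saturated")
})

test_that("MEF conversion round-trips generated data within noise", {
  cf <- 700
  std <- generate_standards(conversion_factor = cf, intercept = 50,
                            noise = noise_model(additive_sd = 0.01,
                                                multiplicative_cv = 0.002),
                            seed = 3)
  cal <- fit_mef_calibration(std)
  expect_equal(cal$conversion_factor, cf, tolerance = 0.02)
  mefs <- to_mef(std$value, cal)
  expect_equal(mefs, std$concentration, tolerance = 0.15)
})

test_that("trace normalization matches the printed formula", {
  tr <- data.frame(time = 0:120, mef = 1 + 0.02 * (0:120))
  out <- normalize_trace(tr, max_mef = 1 + 0.02 * 120)
  expect_equal(out$mef[1], 0)
  expect_equal(out$mef, (0:120) / 120)
  expect_equal(max(out$mef), 1)
  expect_error(normalize_trace(tr, max_mef = 0.5), "baseline")
})

test_that("normalization is invariant under affine rescaling of raw units", {
  sim <- simulate_network(compile_network(library_circuit("aTc_sensor"),
                                          default_params, c(aTc = 10)),
                          coarse_grid(60, 2))
  mef <- mef_trace(sim)
  rescale <- function(cf, b) {
    raw <- mef$mef * cf + b
    std <- generate_standards(conversion_factor = cf, intercept = b,
                              noise = noise_model(0, 0), seed = 1)
    cal <- fit_mef_calibration(std)
    normalize_trace(data.frame(time = mef$time, mef = to_mef(raw, cal)),
                    max_mef = max(to_mef(raw, cal)))
  }
  expect_equal(rescale(1000, 50)$mef, rescale(350, 900)$mef,
               tolerance = 1e-8)
})

test_that("ON calls use a strict threshold", {
  expect_equal(call_on_off(c(0.6, 0.4, 0.5)), c("ON", "OFF", "OFF"))
})

test_that("truth-table evaluation is deterministic and annotated", {
  ckt <- library_circuit("NOT_tet")
  t1 <- evaluate_truth_table(ckt, default_params, settings = coarse_grid())
  t2 <- evaluate_truth_table(ckt, default_params, settings = coarse_grid())
  expect_identical(t1, t2)
  expect_true(attr(t1, "all_match"))
  expect_equal(t1$expected, c("ON", "OFF"))

  js <- format_truth_table(t1, "json")
  expect_true(jsonlite::validate(js))
  md <- format_truth_table(t1, "markdown")
  expect_match(md, "mef")
})

test_that("induced sensors are detected quickly, uninduced never", {
  p <- default_params
  induced <- simulate_network(
    compile_network(library_circuit("aTc_sensor"), p, c(aTc = 10)),
    solver_settings(t_grid = seq(0, 120, 1)))
  expect_lte(time_to_detection(induced), 10)

  uninduced <- simulate_network(
    compile_network(library_circuit("aTc_sensor"), p, c(aTc = 0)),
    solver_settings(t_grid = seq(0, 120, 1)))
  expect_true(is.na(time_to_detection(uninduced)))

  no_gate <- library_circuit("aTc_sensor")
  no_gate$gates[[1]]$concentration <- 0
  sim0 <- simulate_network(compile_network(no_gate, p, c(aTc = 10)),
                           coarse_grid())
  expect_true(is.na(time_to_detection(sim0)))
})

test_that("EC50 interpolation finds half-maximum on a log grid", {
  conc <- c(0, 0.5, 1, 2, 4, 8)
  resp <- c(0, 0.02, 0.05, 0.5, 0.95, 1)
  ec <- estimate_ec50(conc, resp)
  expect_gt(ec, 1)
  expect_lt(ec, 2.01)
  expect_true(is.na(estimate_ec50(conc, c(1, rep(0.1, 5)))))
})
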