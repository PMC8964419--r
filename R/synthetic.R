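#' Plate-reader noise model
#'
#' A stylized replicate-scatter model for synthetic reads: each reading is
#' `signal * (1 + cv * e1) + sd * e2` with independent standard-normal
#' draws, optionally clipped at the instrument's saturation ceiling
#' (arbitrary-unit generators only). Defaults visually match the replicate
#' +/- s.d. scale of cell-free kinetics runs; they are stylized, not fitted.
#'
#' @param additive_sd Additive noise s.d. (uM MEF).
#' @param multiplicative_cv Proportional noise coefficient of variation.
#' @param saturation_ceiling Reading ceiling in arbitrary units.
#' @return A `noise_model` list.
#' @export
noise_model <- function(additive_sd = 0.05, multiplicative_cv = 0.02,
                        saturation_ceiling = Inf) {
  if (additive_sd < 0 || multiplicative_cv < 0)
    stop("noise magnitudes must be >= 0", call. = FALSE)
  structure(list(additive_sd = additive_sd,
                 multiplicative_cv = multiplicative_cv,
                 saturation_ceiling = saturation_ceiling),
            class = "noise_model")
}

apply_noise <- function(signal, noise, sd_scale = 1) {
  n <- length(signal)
  signal * (1 + noise$multiplicative_cv * stats::rnorm(n)) +
    noise$additive_sd * sd_scale * stats::rnorm(n)
}

#' Generate noisy replicate fluorescence time courses
#'
#' Forward-simulates the circuit under one input condition, samples the MEF
#' trace on a plate-reader grid (1-min intervals for 2 h by default), and
#' applies replicate noise. Pure in (inputs, seed): the same call
#' regenerates bit-identical data.
#'
#' @param circuit A [circuit_spec()].
#' @param params [kinetic_params()].
#' @param condition Named ligand concentrations (uM).
#' @param noise A [noise_model()].
#' @param interval,duration Sampling interval and run length (min).
#' @param replicates Number of replicate wells.
#' @param seed Integer seed.
#' @return Data frame: `time`, `replicate`, `mef`; the noiseless simulated
#'   trace is attached as attribute `truth`.
#' @export
generate_trace <- function(circuit, params = kinetic_params(),
                           condition = NULL, noise = noise_model(),
                           interval = 1, duration = 120, replicates = 3,
                           seed = 1) {
  settings <- solver_settings(t_grid = seq(0, duration, by = interval))
  sim <- simulate_network(compile_network(circuit, params, condition),
                          settings)
  truth <- mef_trace(sim)
  out <- with_seed(seed, {
    reps <- lapply(seq_len(replicates), function(r)
      data.frame(time = truth$time, replicate = r,
                 mef = apply_noise(truth$mef, noise)))
    do.call(rbind, reps)
  })
  attr(out, "truth") <- truth
  attr(out, "condition") <- condition
  out
}

#' Generate a fluorescein calibration standard plate
#'
#' Emulates the MEF standardization plate: serial dilutions from a stock
#' (two-fold by default) plus a buffer blank -- 12 samples in total -- each
#' read in nine replicates. Readings are
#' `intercept + conversion_factor * concentration` plus noise, clipped and
#' flagged at the saturation ceiling.
#'
#' @param stock Stock concentration (uM fluorescein).
#' @param n_samples Number of samples including the blank.
#' @param replicates Replicates per sample.
#' @param conversion_factor True slope (a.u. per uM).
#' @param intercept True blank reading (a.u.).
#' @param dilution_factor Serial dilution factor.
#' @param noise A [noise_model()]; additive noise is scaled into a.u. by the
#'   conversion factor.
#' @param seed Integer seed.
#' @return Data frame: `concentration` (uM), `replicate`, `value` (a.u.),
#'   `saturated` (logical).
#' @export
generate_standards <- function(stock = 50, n_samples = 12, replicates = 9,
                               conversion_factor = 1000, intercept = 50,
                               dilution_factor = 2, noise = noise_model(),
                               seed = 1) {
  stopifnot(conversion_factor > 0, n_samples >= 2, dilution_factor > 1)
  concs <- c(stock / dilution_factor^(0:(n_samples - 2)), 0)
  with_seed(seed, {
    rows <- lapply(concs, function(cc) {
      clean <- intercept + conversion_factor * cc
      vals <- apply_noise(rep(clean, replicates), noise,
                          sd_scale = conversion_factor)
      sat <- vals >= noise$saturation_ceiling
      data.frame(concentration = cc, replicate = seq_len(replicates),
                 value = pmin(vals, noise$saturation_ceiling),
                 saturated = sat)
    })
    do.call(rbind, rows)
  })
}

#' Generate an endpoint dose--response series
#'
#' Simulates the sensor at each ligand concentration, reads the endpoint MEF
#' at `read_time` (1 h by default, matching endpoint dose--response reads),
#' and applies replicate noise.
#'
#' @param circuit Single-ligand sensor circuit.
#' @param ligand_grid Ligand concentrations (uM).
#' @param read_time Endpoint time (min).
#' @param params [kinetic_params()].
#' @param noise A [noise_model()].
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return Data frame: `concentration`, `replicate`, `mef`; noiseless
#'   endpoints as attribute `truth`.
#' @export
generate_dose_response <- function(circuit, ligand_grid, read_time = 60,
                                   params = kinetic_params(),
                                   noise = noise_model(), replicates = 3,
                                   seed = 1) {
  if (!length(ligand_grid)) stop("ligand_grid must be non-empty",
                                 call. = FALSE)
  lig <- circuit$ligand_names
  if (length(lig) != 1)
    stop("generate_dose_response expects a single-ligand sensor",
         call. = FALSE)
  settings <- solver_settings(t_grid = seq(0, read_time, by = 1))
  truth <- vapply(ligand_grid, function(cc) {
    sim <- simulate_network(
      compile_network(circuit, params, stats::setNames(cc, lig)), settings)
    tr <- mef_trace(sim)
    tr$mef[length(tr$mef)]
  }, numeric(1))
  out <- with_seed(seed, {
    rows <- lapply(seq_along(ligand_grid), function(i)
      data.frame(concentration = ligand_grid[i],
                 replicate = seq_len(replicates),
                 mef = apply_noise(rep(truth[i], replicates), noise)))
    do.call(rbind, rows)
  })
  attr(out, "truth") <- data.frame(concentration = ligand_grid, mef = truth)
  out
}

#' Multi-condition trace bundle for parameter estimation
#'
#' The default identifiability suite for the aTc-responsive sensor: four
#' conditions spanning uninduced, near the dose--response corner, saturating
#' induction, and saturating induction behind a threshold gate. The
#' thresholded condition swaps the reporter for a kinetically limited
#' variant (short 4-nt toehold, sub-stoichiometric amount): with the
#' saturated-toehold reporter displacement is never rate-limiting and the
#' maximum displacement rate would be invisible in the data, whereas the
#' slow reporter's exhaustion kinetics pin it. Together the four traces
#' constrain transcription, displacement and ligand-release rates.
#'
#' @param circuit Sensor circuit (default: packaged aTc sensor).
#' @param params True [kinetic_params()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param ligand_levels Ligand concentrations (uM) for the unthresholded
#'   conditions.
#' @param threshold_uM Threshold-gate amount of the thresholded condition.
#' @param slow_reporter_toehold_nt,slow_reporter_uM Reporter configuration
#'   of the thresholded condition.
#' @param interval,duration Sampling grid (min).
#' @return List of trace entries, each `list(circuit, condition, data)` with
#'   `data` from [generate_trace()].
#' @export
generate_fit_bundle <- function(circuit = library_circuit("aTc_sensor"),
                                params = kinetic_params(),
                                noise = noise_model(), seed = 1,
                                ligand_levels = c(0, 5, 10),
                                threshold_uM = 2,
                                slow_reporter_toehold_nt = 4,
                                slow_reporter_uM = 1, interval = 1,
                                duration = 120) {
  lig <- circuit$ligand_names
  entries <- lapply(seq_along(ligand_levels), function(i)
    list(circuit = circuit,
         condition = stats::setNames(ligand_levels[i], lig)))
  slow <- circuit
  is_sig <- vapply(slow$gates, function(g) g$kind == "signal", logical(1))
  slow$gates[[which(is_sig)]]$toehold_nt <- slow_reporter_toehold_nt
  slow$gates[[which(is_sig)]]$concentration <- slow_reporter_uM
  thr <- add_threshold_gate(slow, threshold_uM)
  entries <- c(entries, list(list(
    circuit = thr,
    condition = stats::setNames(max(ligand_levels), lig))))
  for (i in seq_along(entries)) {
    entries[[i]]$data <- generate_trace(
      entries[[i]]$circuit, params, entries[[i]]$condition, noise,
      interval = interval, duration = duration, replicates = 1,
      seed = seed + i)
  }
  entries
}
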