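# Kinetic comparator and analog-to-digital converter design.
#
# A threshold gate shares the signal gate's invader but carries a longer
# (8 nt) toehold, so it consumes invader before the reporter can react;
# signal only appears after the threshold gate is exhausted. Tuning the
# threshold-gate amount therefore sets the time (equivalently, the minimum
# input concentration at a fixed read time) at which a tube turns ON.

#' Add a threshold gate to a sensor circuit
#'
#' @param circuit A circuit with exactly one signal gate.
#' @param theta Threshold-gate concentration (uM).
#' @param toehold_nt Threshold toehold length (default 8 nt; must exceed the
#'   signal gate's for thresholding to work).
#' @return The circuit with a `threshold` gate consuming the signal gate's
#'   first invader.
#' @export
add_threshold_gate <- function(circuit, theta, toehold_nt = 8) {
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  is_sig <- vapply(circuit$gates, function(g) g$kind == "signal", logical(1))
  if (sum(is_sig) != 1)
    stop("circuit must have exactly one signal gate", call. = FALSE)
  inv <- circuit$gates[[which(is_sig)]]$invader_names[1]
  circuit$gates <- c(circuit$gates, list(
    gate_spec("ThresholdGate", "threshold", concentration = theta,
              toehold_nt = toehold_nt, invader_names = inv)))
  circuit$name <- paste0(circuit$name, "+threshold")
  circuit
}

adc_endpoint_mef <- function(circuit, params, condition, theta, read_time,
                             settings = NULL) {
  ckt <- add_threshold_gate(circuit, theta)
  if (is.null(settings))
    settings <- solver_settings(t_grid = seq(0, read_time, by = 1))
  sim <- simulate_network(compile_network(ckt, params, condition = condition),
                          settings)
  tr <- mef_trace(sim)
  stats::approx(tr$time, tr$mef, xout = read_time, rule = 2)$y
}

#' Critical threshold-gate concentration for one input level
#'
#' Bisection on the threshold-gate concentration `theta` such that the
#' simulated endpoint satisfies `MEF(read_time) = on_threshold_mef`: the
#' largest threshold that still lets this input turn the tube ON. Returns 0
#' if the tube is OFF even without a threshold gate.
#'
#' @param circuit Sensor circuit (one signal gate, one ligand).
#' @param input_conc Ligand concentration (uM).
#' @param read_time Read time (min).
#' @param params [kinetic_params()].
#' @param on_threshold_mef ON-call level (uM MEF).
#' @param rel_tol Relative bisection tolerance on theta.
#' @return Critical theta (uM), with the endpoint MEF at the returned theta
#'   as attribute `mef`.
#' @export
critical_threshold <- function(circuit, input_conc, read_time = 100,
                               params = kinetic_params(),
                               on_threshold_mef = 0.5, rel_tol = 1e-3) {
  lig <- circuit$ligand_names
  if (length(lig) != 1)
    stop("critical_threshold expects a single-ligand sensor", call. = FALSE)
  cond <- stats::setNames(input_conc, lig)
  f <- function(theta) adc_endpoint_mef(circuit, params, cond, theta,
                                        read_time) - on_threshold_mef
  f0 <- f(0)
  if (f0 <= 0) return(structure(0, mef = f0 + on_threshold_mef))
  # bracket: untresholded endpoint bounds the consumable invader
  hi <- f0 + on_threshold_mef + 0.5
  fhi <- f(hi)
  tries <- 0
  while (fhi > 0 && tries < 20) {
    hi <- hi * 2; fhi <- f(hi); tries <- tries + 1
  }
  if (fhi > 0)
    stop("non-bracketing: tube remains ON at any threshold-gate amount",
         call. = FALSE)
  lo <- 0; flo <- f0
  while ((hi - lo) > rel_tol * max(hi, rel_tol)) {
    mid <- (hi + lo) / 2
    fm <- f(mid)
    if (fm > 0) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  theta <- (hi + lo) / 2
  structure(theta, mef = f(theta) + on_threshold_mef)
}

#' Design a thermometer-coded ADC tube strip
#'
#' Calibrates one threshold-gate concentration per tube so that the strip
#' thermometer-encodes the ligand concentration at the read time: tube `j`
#' turns ON for inputs at or above breakpoint `c_j` and stays OFF at or
#' below `c_{j-1}`. Each threshold is the critical threshold at the
#' geometric midpoint of the adjacent breakpoints (dose--response is
#' log-scaled, so the geometric mean places both breakpoints safely inside
#' their ON/OFF regions); the lower edge of the first bin defaults to a
#' quarter of the first breakpoint. The design is audited by simulation at
#' every breakpoint before being returned.
#'
#' @param circuit Single-ligand sensor circuit.
#' @param breakpoints Strictly increasing ligand concentrations (uM), one
#'   per tube.
#' @param read_time Read time (min), default 100.
#' @param params [kinetic_params()].
#' @param blank Lower edge of the first bin (uM).
#' @param on_threshold_mef ON-call level (uM MEF).
#' @return An `adc_design`: `base_circuit`, `thresholds` (uM), `breakpoints`,
#'   `read_time`, `on_threshold_mef`, and the audit table `audit`.
#' @examples
#' \donttest{
#' design <- design_thresholds(library_circuit("zinc_sensor"),
#'                             breakpoints = c(2, 3.5, 5, 10))
#' simulate_adc(design, 4)
#' }
#' @export
design_thresholds <- function(circuit, breakpoints, read_time = 100,
                              params = kinetic_params(),
                              blank = breakpoints[1] / 4,
                              on_threshold_mef = 0.5) {
  if (any(diff(breakpoints) <= 0) || any(breakpoints <= 0))
    stop("breakpoints must be positive and strictly increasing",
         call. = FALSE)
  edges <- c(blank, breakpoints)
  mids <- sqrt(edges[-length(edges)] * edges[-1])
  thetas <- vapply(mids, function(m)
    as.numeric(critical_threshold(circuit, m, read_time, params,
                                  on_threshold_mef)), numeric(1))
  if (any(diff(thetas) <= 0) || any(thetas <= 0))
    stop("audit failure: critical thresholds are not strictly increasing (",
         paste(signif(thetas, 4), collapse = ", "),
         "); the sensor response is not graded over these breakpoints",
         call. = FALSE)
  design <- structure(list(base_circuit = circuit, thresholds = thetas,
                           breakpoints = breakpoints, read_time = read_time,
                           on_threshold_mef = on_threshold_mef,
                           params = params),
                      class = "adc_design")
  audit <- lapply(seq_along(breakpoints), function(j) {
    pat <- simulate_adc(design, breakpoints[j])
    data.frame(input = breakpoints[j], n_on = pat$n_on,
               thermometer = pat$thermometer)
  })
  audit <- do.call(rbind, audit)
  if (!all(audit$thermometer) ||
      !identical(audit$n_on, seq_along(breakpoints)))
    stop("audit failure: breakpoints do not activate 1..J tubes (got ",
         paste(audit$n_on, collapse = ", "), ")", call. = FALSE)
  design$audit <- audit
  design
}

#' @export
print.adc_design <- function(x, ...) {
  cat(sprintf("<adc_design> %s: %d tubes, read at %g min (ON > %g MEF)\n",
              x$base_circuit$name, length(x$thresholds), x$read_time,
              x$on_threshold_mef))
  cat("  thresholds (uM):", paste(signif(x$thresholds, 4), collapse = ", "),
      "\n")
  cat("  breakpoints (uM):", paste(x$breakpoints, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an ADC tube strip at one input concentration
#'
#' Runs each tube (the base sensor plus that tube's threshold gate), calls
#' ON/OFF at the design's read time, and decodes the resulting pattern into
#' a concentration interval.
#'
#' @param design An [design_thresholds()] result.
#' @param input_conc Ligand concentration (uM).
#' @return A `tube_pattern`: `calls` (ON/OFF per tube), `n_on`,
#'   `thermometer` (is the pattern an ON-prefix?), `decoded_interval`
#'   (numeric lower/upper bounds, uM) and `decoded` (printable label).
#' @export
simulate_adc <- function(design, input_conc) {
  cond <- stats::setNames(input_conc, design$base_circuit$ligand_names)
  mefs <- vapply(design$thresholds, function(th)
    adc_endpoint_mef(design$base_circuit, design$params, cond, th,
                     design$read_time), numeric(1))
  on <- mefs > design$on_threshold_mef
  n_on <- sum(on)
  thermometer <- all(on == (seq_along(on) <= n_on))
  bp <- design$breakpoints
  interval <- if (n_on == 0) c(0, bp[1]) else if (n_on == length(bp))
    c(bp[n_on], Inf) else c(bp[n_on], bp[n_on + 1])
  decoded <- if (n_on == 0) sprintf("< %g", bp[1]) else if
    (n_on == length(bp)) sprintf(">= %g", bp[n_on]) else
      sprintf("[%g, %g)", bp[n_on], bp[n_on + 1])
  structure(list(calls = ifelse(on, "ON", "OFF"), mef = mefs, n_on = n_on,
                 thermometer = thermometer, decoded_interval = interval,
                 decoded = decoded, input = input_conc),
            class = "tube_pattern")
}

#' @export
print.tube_pattern <- function(x, ...) {
  cat(sprintf("<tube_pattern> input %g uM: [%s] -> %s uM\n", x$input,
              paste(x$calls, collapse = " "), x$decoded))
  invisible(x)
}

#' Audit thermometer behavior of a design over an input grid
#'
#' @param design An `adc_design`.
#' @param input_grid Ligand concentrations to sweep (uM).
#' @return Data frame (`input`, `pattern`, `n_on`, `thermometer`) with
#'   attribute `pass`: every pattern is a thermometer code and the ON count
#'   is non-decreasing in the input.
#' @export
audit_monotonicity <- function(design, input_grid) {
  if (!length(input_grid)) {
    out <- data.frame(input = numeric(), pattern = character(),
                      n_on = integer(), thermometer = logical())
    attr(out, "pass") <- TRUE
    return(out)
  }
  rows <- lapply(sort(input_grid), function(x) {
    pat <- simulate_adc(design, x)
    data.frame(input = x, pattern = paste(pat$calls, collapse = ""),
               n_on = pat$n_on, thermometer = pat$thermometer)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$thermometer) && !is.unsorted(out$n_on)
  out
}

#' Serialize / restore an ADC design as JSON
#'
#' @param design An `adc_design`.
#' @param path File path.
#' @return `write_adc_design` returns `path` invisibly; `read_adc_design`
#'   returns the design.
#' @export
write_adc_design <- function(design, path) {
  doc <- list(
    base_circuit = circuit_to_list(design$base_circuit),
    thresholds = design$thresholds,
    breakpoints = design$breakpoints,
    read_time = design$read_time,
    on_threshold_mef = design$on_threshold_mef,
    params = unclass(design$params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_adc_design
#' @export
read_adc_design <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    base_circuit = circuit_from_list(doc$base_circuit),
    thresholds = as.numeric(unlist(doc$thresholds)),
    breakpoints = as.numeric(unlist(doc$breakpoints)),
    read_time = doc$read_time,
    on_threshold_mef = doc$on_threshold_mef,
    params = do.call(kinetic_params, lapply(doc$params, unlist))
  ), class = "adc_design")
}
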