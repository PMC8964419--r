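#' Fit a fluorescein calibration curve (MEF standardization)
#'
#' Converts arbitrary plate-reader units to micromolar equivalent fluorescein
#' (MEF). Replicate readings are averaged per concentration, the blank
#' average is subtracted from all values, concentrations with any saturated
#' replicate are excluded, and a least-squares line is fitted over the linear
#' range of fluorescence (0--3.125 uM fluorescein by default); its slope is
#' the conversion factor.
#'
#' @param standards Data frame with columns `concentration` (uM fluorescein,
#'   including a 0 blank), `value` (arbitrary units) and optionally
#'   `saturated` (logical). One row per replicate reading.
#' @param linear_range_max Highest concentration included in the fit (uM).
#' @return A `calibration_curve`: `conversion_factor` (a.u. per uM),
#'   `intercept` (blank average, a.u.), `linear_range_max`,
#'   `excluded_saturated` (concentrations dropped), `n_points`.
#' @examples
#' std <- generate_standards(conversion_factor = 1000, seed = 1,
#'                           noise = noise_model(additive_sd = 0))
#' fit_mef_calibration(std)$conversion_factor
#' @export
fit_mef_calibration <- function(standards, linear_range_max = 3.125) {
  stopifnot(all(c("concentration", "value") %in% names(standards)))
  sat <- if ("saturated" %in% names(standards)) standards$saturated else
    rep(FALSE, nrow(standards))
  sat_conc <- unique(standards$concentration[sat])
  keep <- !standards$concentration %in% sat_conc
  if (!any(keep)) stop("all standard concentrations are saturated",
                       call. = FALSE)
  df <- standards[keep, ]
  means <- stats::aggregate(value ~ concentration, data = df, FUN = mean)
  if (!0 %in% means$concentration)
    stop("standards must include a blank (concentration 0)", call. = FALSE)
  blank <- means$value[means$concentration == 0]
  means$value <- means$value - blank
  fitset <- means[means$concentration <= linear_range_max, ]
  if (nrow(fitset) < 3)
    stop("fewer than 3 usable standard concentrations in the linear range",
         call. = FALSE)
  fit <- stats::lm(value ~ concentration, data = fitset)
  cf <- unname(stats::coef(fit)["concentration"])
  if (!is.finite(cf) || cf <= 0)
    stop("calibration slope is not positive; check standards", call. = FALSE)
  structure(list(conversion_factor = cf, intercept = blank,
                 linear_range_max = linear_range_max,
                 excluded_saturated = sort(sat_conc),
                 n_points = nrow(fitset)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("<calibration_curve> %.6g a.u./uM (blank %.6g a.u., ",
                     "%d points <= %.4g uM"), x$conversion_factor,
              x$intercept, x$n_points, x$linear_range_max))
  if (length(x$excluded_saturated))
    cat(sprintf(", %d saturated conc. excluded", length(x$excluded_saturated)))
  cat(")\n")
  invisible(x)
}

#' Convert arbitrary fluorescence units to MEF
#'
#' `(raw - blank) / conversion_factor`, vectorized.
#'
#' @param raw Arbitrary-unit reading(s).
#' @param cal A [fit_mef_calibration()] result.
#' @return MEF in uM fluorescein.
#' @export
to_mef <- function(raw, cal) {
  stopifnot(inherits(cal, "calibration_curve"))
  (raw - cal$intercept) / cal$conversion_factor
}

#' Baseline-and-maximum normalization of an MEF trace
#'
#' Normalizes a kinetic trace for model--data comparison:
#' `f(x) = (MEF_t=x - MEF_t=0) / (MaxMEF - MEF_t=0)`, where `MaxMEF` is the
#' maximum MEF across all conditions being compared. Exactly 0 at t = 0 and
#' 1 where the trace reaches `MaxMEF`.
#'
#' @param trace Data frame with columns `time` and `mef`.
#' @param max_mef The maximum MEF among all compared reactions (uM).
#' @return The trace with `mef` replaced by the normalized value.
#' @export
normalize_trace <- function(trace, max_mef) {
  m0 <- trace$mef[trace$time == min(trace$time)][1]
  if (max_mef <= m0)
    stop("max_mef must exceed the baseline MEF at t = 0", call. = FALSE)
  trace$mef <- (trace$mef - m0) / (max_mef - m0)
  trace
}

#' ON/OFF call for an endpoint MEF value
#'
#' A reaction is called ON when its MEF value strictly exceeds the visible
#' threshold (default 0.5 uM fluorescein).
#'
#' @param mef MEF value(s), uM.
#' @param on_threshold_mef Threshold (uM).
#' @return Character vector of `"ON"`/`"OFF"`.
#' @export
call_on_off <- function(mef, on_threshold_mef = 0.5) {
  ifelse(mef > on_threshold_mef, "ON", "OFF")
}

#' Evaluate a circuit's logic truth table by simulation
#'
#' Simulates every enumerated input condition of the circuit, reads the MEF
#' endpoint at `read_time`, calls ON/OFF, and compares against the circuit's
#' intended logic.
#'
#' @param circuit A [circuit_spec()] with `intended_logic`.
#' @param params [kinetic_params()].
#' @param read_time Endpoint read time (min); kinetic runs are 2 h, so logic
#'   is read at 120 min by default.
#' @param on_level Ligand ON concentration (uM).
#' @param on_threshold_mef ON-call threshold (uM MEF).
#' @param settings Optional [solver_settings()]; the grid is truncated /
#'   extended to reach `read_time`.
#' @return A `truth_table` data.frame: one row per condition with ligand
#'   columns, `mef`, `call`, `expected`, `match`; attribute `all_match`.
#' @examples
#' \donttest{
#' evaluate_truth_table(library_circuit("AND_tet_zn"))
#' }
#' @export
evaluate_truth_table <- function(circuit, params = kinetic_params(),
                                 read_time = 120, on_level = 100,
                                 on_threshold_mef = 0.5, settings = NULL) {
  if (is.null(circuit$intended_logic))
    stop("circuit has no intended_logic label", call. = FALSE)
  conds <- enumerate_conditions(circuit, on_level)
  if (is.null(settings))
    settings <- solver_settings(t_grid = seq(0, read_time, by = 1))
  rows <- lapply(seq_len(max(nrow(conds), 1)), function(i) {
    cond <- if (ncol(conds)) stats::setNames(as.numeric(conds[i, ]),
                                             colnames(conds)) else numeric()
    net <- compile_network(circuit, params, condition = cond)
    sim <- simulate_network(net, settings)
    tr <- mef_trace(sim)
    mef <- stats::approx(tr$time, tr$mef, xout = read_time, rule = 2)$y
    expected <- expected_output(circuit$intended_logic, cond)
    data.frame(as.list(cond), mef = mef,
               call = call_on_off(mef, on_threshold_mef),
               expected = ifelse(expected, "ON", "OFF"),
               match = (mef > on_threshold_mef) == expected,
               check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "all_match") <- all(tab$match)
  attr(tab, "read_time") <- read_time
  attr(tab, "on_threshold_mef") <- on_threshold_mef
  class(tab) <- c("truth_table", "data.frame")
  tab
}

#' Export a truth table as JSON or Markdown
#'
#' @param tab A [evaluate_truth_table()] result.
#' @param format `"json"` or `"markdown"`.
#' @param path Optional output file.
#' @return Character scalar (invisibly if written to `path`).
#' @export
format_truth_table <- function(tab, format = c("json", "markdown"),
                               path = NULL) {
  format <- match.arg(format)
  out <- if (format == "json") {
    as.character(jsonlite::toJSON(as.data.frame(tab), dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE))
  } else {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1, function(r)
      paste0("| ", paste(format(r, digits = 4), collapse = " | "), " |"))
    paste(c(hdr, sep, body), collapse = "\n")
  }
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Time to detection of a simulated or measured sensor
#'
#' First time at which the MEF trace exceeds the visible ON threshold
#' (activation time of the fluorescence readout).
#'
#' @param x A `sim_result` or a data.frame with `time` and `mef` columns.
#' @param on_threshold_mef Visibility threshold (uM MEF).
#' @return Minutes, or `NA_real_` if not reached on the simulated window.
#' @export
time_to_detection <- function(x, on_threshold_mef = 0.5) {
  if (inherits(x, "sim_result")) x <- mef_trace(x)
  activation_time(x, on_threshold_mef)
}

#' Interpolated half-maximal concentration of a dose--response series
#'
#' Averages replicates per concentration, takes the half-maximum of the mean
#' response, and log-linearly interpolates the first crossing between
#' adjacent positive concentrations of the titration.
#'
#' @param concentration,response Numeric vectors (replicate rows allowed).
#' @return EC50 in the concentration's units (`NA_real_` if the response
#'   never crosses half-maximum within the titration).
#' @export
estimate_ec50 <- function(concentration, response) {
  means <- stats::aggregate(list(response = response),
                            list(concentration = concentration), FUN = mean)
  means <- means[order(means$concentration), ]
  half <- max(means$response) / 2
  pos <- means[means$concentration > 0, ]
  i <- which(pos$response > half)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(pos$concentration[1])
  lo <- pos[i - 1, ]; hi <- pos[i, ]
  10^(log10(lo$concentration) +
        (half - lo$response) / (hi$response - lo$response) *
        (log10(hi$concentration) - log10(lo$concentration)))
}
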