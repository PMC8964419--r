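#' Solver settings for network integration
#'
#' Defaults mirror the plate-reader protocol: a dense output grid at 1-min
#' spacing over a 2 h run, integrated with a stiff-capable method (TMSD rate
#' constants span several decades across toehold lengths).
#'
#' @param rtol,atol Relative/absolute integration tolerances (atol in uM).
#' @param max_step Maximum internal step (min).
#' @param t_grid Output time grid in minutes, strictly increasing from 0.
#' @param stiff Use the stiff-capable `lsoda` integrator (otherwise `ode45`).
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-10, max_step = Inf,
                            t_grid = seq(0, 120, by = 1), stiff = TRUE) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing from 0", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 t_grid = t_grid, stiff = stiff),
            class = "solver_settings")
}

#' Integrate a reaction network
#'
#' Solves the mass-action initial-value problem on the settings' time grid.
#' Values more negative than `-atol` indicate integration failure; smaller
#' negative excursions are clipped to zero.
#'
#' @param net A `reaction_network` from [compile_network()].
#' @param settings A [solver_settings()].
#' @return A `sim_result`: `t` (minutes), `conc` (time x species matrix, uM),
#'   plus provenance (`circuit_name`, `condition`, the network).
#' @examples
#' net <- compile_network(library_circuit("unregulated_sensor"))
#' sim <- simulate_network(net)
#' tail(mef_trace(sim))
#' @export
simulate_network <- function(net, settings = solver_settings()) {
  y0 <- stats::setNames(net$species$init, net$species$name)
  k <- net$k
  ridx <- net$react_idx
  S <- net$S
  n_rx <- length(k)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- numeric(n_rx)
    for (j in seq_len(n_rx)) v[j] <- k[j] * prod(y[ridx[[j]]])
    list(drop(S %*% v))
  }
  method <- if (settings$stiff) "lsoda" else "ode45"
  out <- deSolve::ode(y = y0, times = settings$t_grid, func = rhs,
                      parms = NULL, method = method,
                      rtol = settings$rtol, atol = settings$atol,
                      hmax = if (is.finite(settings$max_step))
                        settings$max_step else NULL)
  if (nrow(out) < length(settings$t_grid))
    stop(sprintf("integration failure at t = %g min (solver stopped early)",
                 out[nrow(out), 1]), call. = FALSE)
  conc <- unname(out[, -1, drop = FALSE])
  dimnames(conc) <- list(NULL, net$species$name)
  neg_tol <- max(settings$atol, settings$rtol * max(abs(conc)))
  bad <- conc < -neg_tol
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "integration failure: species '%s' reached %.3g uM at t = %g min",
      colnames(conc)[i[2]], conc[i[1], i[2]], settings$t_grid[i[1]]),
      call. = FALSE)
  }
  conc[conc < 0] <- 0
  structure(list(t = settings$t_grid, conc = conc,
                 circuit_name = net$circuit_name, condition = net$condition,
                 network = net, settings = settings),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s: %d species x %d time points (0-%g min)\n",
              x$circuit_name, ncol(x$conc), length(x$t), max(x$t)))
  if (length(x$condition))
    cat("  condition:", paste(names(x$condition), x$condition, sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Extract the simulated fluorescence (MEF) trace
#'
#' The model reports released fluorophore strand concentration, which is the
#' simulated MEF readout (uM fluorescein equivalents).
#'
#' @param sim A `sim_result`.
#' @return Data frame with columns `time` (min) and `mef` (uM).
#' @export
mef_trace <- function(sim) {
  obs <- sim$network$observable
  if (is.na(obs)) stop("network has no signal gate / fluorophore observable",
                       call. = FALSE)
  data.frame(time = sim$t, mef = sim$conc[, obs])
}

#' Tidy (long) trajectory table
#'
#' @param sim A `sim_result`.
#' @param path Optional CSV path (tidy long format: time, species,
#'   concentration).
#' @return A long-format data.frame.
#' @export
trajectory_table <- function(sim, path = NULL) {
  df <- data.frame(
    time = rep(sim$t, times = ncol(sim$conc)),
    species = rep(colnames(sim$conc), each = length(sim$t)),
    concentration = as.vector(sim$conc)
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Closed-form second-order kinetics (test oracle)
#'
#' Remaining concentration of A for the irreversible bimolecular reaction
#' A + B -> C with rate constant `k`. Uses the equal-concentration form
#' `c0 / (1 + k c0 t)` when the initial concentrations coincide and the
#' distinct-concentration exponential form otherwise.
#'
#' @param c0_a,c0_b Initial concentrations (uM).
#' @param k Rate constant (uM^-1 min^-1).
#' @param t Time(s) in minutes.
#' @return Remaining A (uM), vectorized over `t`.
#' @export
closed_form_bimolecular <- function(c0_a, c0_b, k, t) {
  stopifnot(c0_a >= 0, c0_b >= 0, k >= 0, all(t >= 0))
  if (k == 0 || c0_a == 0) return(rep(c0_a, length(t)))
  if (isTRUE(all.equal(c0_a, c0_b)))
    return(c0_a / (1 + k * c0_a * t))
  d <- c0_a - c0_b
  c0_a * d / (c0_a - c0_b * exp(-k * d * t))
}

#' First threshold-crossing time of a trace
#'
#' Finds the first grid interval in which the observable exceeds the
#' threshold and refines the crossing by linear interpolation. This is the
#' activation time of a thresholded (kinetic comparator) reaction.
#'
#' @param x A `sim_result` or a data.frame with columns `time` and a value
#'   column.
#' @param threshold Crossing level (same units as the observable; >= 0).
#' @param observable Species name when `x` is a `sim_result` (default: the
#'   MEF observable).
#' @return Crossing time in minutes, or `NA_real_` if never crossed.
#' @export
activation_time <- function(x, threshold, observable = NULL) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (inherits(x, "sim_result")) {
    tt <- x$t
    v <- if (is.null(observable)) mef_trace(x)$mef else x$conc[, observable]
  } else {
    tt <- x[[1]]
    v <- x[[2]]
  }
  above <- v > threshold
  if (above[1]) return(tt[1])
  i <- which(above)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- tt[i - 1]; t1 <- tt[i]; v0 <- v[i - 1]; v1 <- v[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Conservation drift report
#'
#' Evaluates every conserved total along the trajectory and reports the
#' maximum relative drift.
#'
#' @param sim A `sim_result`.
#' @param net The network it was simulated from (defaults to the one stored
#'   in `sim`).
#' @param tol Relative drift tolerance used for the `ok` flag.
#' @return Data frame: `moiety`, `initial` (uM), `max_rel_drift`, `ok`.
#' @export
check_conservation <- function(sim, net = sim$network, tol = 1e-8) {
  vecs <- conservation_vectors(net)
  if (!length(vecs))
    return(data.frame(moiety = character(), initial = numeric(),
                      max_rel_drift = numeric(), ok = logical()))
  rows <- lapply(names(vecs), function(m) {
    tot <- drop(sim$conc %*% vecs[[m]])
    ref <- max(abs(tot[1]), 1e-12)
    drift <- max(abs(tot - tot[1])) / ref
    data.frame(moiety = m, initial = tot[1], max_rel_drift = drift,
               ok = drift < tol)
  })
  do.call(rbind, rows)
}
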