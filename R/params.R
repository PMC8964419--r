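#' Kinetic parameter set for biosensor TMSD circuits
#'
#' Bundles every rate constant the network compiler uses. Units are fixed
#' package-wide: concentrations in uM, time in minutes, bimolecular rate
#' constants in uM^-1 min^-1. The shipped defaults are the package's
#' calibrated set: literature-scale magnitudes (T7 transcription turnover,
#' diffusion-limited TMSD at saturating toehold length) refined against the
#' repressed/induced TetR sensor conditions so that the simulated sensor
#' reproduces low-leak repression, sub-10-minute induced detection and a
#' half-maximal aTc response in the low-micromolar range.
#'
#' @param k_tx Transcript production rate per free template (min^-1). Lumped
#'   pseudo-first-order constant absorbing T7 RNAP and NTP levels, which are
#'   in large excess over nM-scale templates during a 2 h run.
#' @param k_on_op,k_off_op TF--operator association (uM^-1 min^-1) and
#'   dissociation (min^-1). Their ratio is the operator Kd (default 0.05 uM).
#' @param k_on_lig,k_off_lig Default TF--ligand binding constants for the
#'   lumped cooperative step (order = ligand stoichiometry). Individual
#'   transcription factors may override these (see [tf_spec()]).
#' @param k_tmsd_max Saturated strand-displacement rate constant, reached at
#'   toehold length >= `n_sat` (uM^-1 min^-1).
#' @param decade_per_nt Decades of rate lost per nucleotide of toehold below
#'   saturation (dimensionless, default 1).
#' @param n_sat Toehold length (nt) at which displacement saturates.
#' @param mismatch_penalty Multiplier in (0, 1] applied to displacement across
#'   an engineered mismatch (the NOT-gate bias against the competing path).
#' @param clamp_leak0,clamp_decay_per_bp AND-gate leak law: a single invader
#'   produces output at `clamp_leak0 * 10^(-clamp_decay_per_bp * clamp_bp)`.
#' @param k_rev_toehold_exchange Reverse rate (min^-1) of the reversible first
#'   AND-gate step (toehold exchange).
#' @param structure_penalty Default per-transcript multiplier in (0, 1] on the
#'   invader's TMSD rates, representing inhibitory RNA secondary structure.
#'   Per-template overrides live on the template spec.
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- kinetic_params()
#' toehold_rate(4, p) / toehold_rate(8, p)  # 100-fold slower at 4 nt
#' @export
kinetic_params <- function(k_tx = 2,
                           k_on_op = 20, k_off_op = 1,
                           k_on_lig = 100, k_off_lig = 0.01,
                           k_tmsd_max = 60,
                           decade_per_nt = 1, n_sat = 6,
                           mismatch_penalty = 0.05,
                           clamp_leak0 = 0.6, clamp_decay_per_bp = 0.6,
                           k_rev_toehold_exchange = 1,
                           structure_penalty = 1) {
  p <- list(
    k_tx = k_tx, k_on_op = k_on_op, k_off_op = k_off_op,
    k_on_lig = k_on_lig, k_off_lig = k_off_lig,
    k_tmsd_max = k_tmsd_max, decade_per_nt = decade_per_nt, n_sat = n_sat,
    mismatch_penalty = mismatch_penalty,
    clamp_leak0 = clamp_leak0, clamp_decay_per_bp = clamp_decay_per_bp,
    k_rev_toehold_exchange = k_rev_toehold_exchange,
    structure_penalty = structure_penalty
  )
  rates <- unlist(p[c("k_tx", "k_on_op", "k_off_op", "k_on_lig", "k_off_lig",
                      "k_tmsd_max", "clamp_leak0", "k_rev_toehold_exchange")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  if (p$mismatch_penalty <= 0 || p$mismatch_penalty > 1)
    stop("mismatch_penalty must be in (0, 1]", call. = FALSE)
  if (p$structure_penalty <= 0 || p$structure_penalty > 1)
    stop("structure_penalty must be in (0, 1]", call. = FALSE)
  if (p$n_sat < 1) stop("n_sat must be >= 1", call. = FALSE)
  if (p$decade_per_nt < 0) stop("decade_per_nt must be >= 0", call. = FALSE)
  class(p) <- "kinetic_params"
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>  (uM, min)\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Toehold-length law for strand-displacement rate constants
#'
#' Displacement accelerates roughly tenfold per added toehold nucleotide
#' until it saturates at `n_sat` nucleotides:
#' `k(n) = k_tmsd_max * 10^(-decade_per_nt * max(0, n_sat - n))`.
#' The law is non-decreasing in `n` and equals `k_tmsd_max` for `n >= n_sat`.
#'
#' @param toehold_nt Toehold length in nucleotides (>= 1); vectorized.
#' @param params A [kinetic_params()] object.
#' @return Rate constant(s) in uM^-1 min^-1.
#' @export
toehold_rate <- function(toehold_nt, params = kinetic_params()) {
  if (any(toehold_nt < 1)) stop("toehold_nt must be >= 1", call. = FALSE)
  params$k_tmsd_max * 10^(-params$decade_per_nt * pmax(0, params$n_sat - toehold_nt))
}

#' Read or write kinetic parameters as JSON
#'
#' The JSON carries an explicit units block so parameter files are
#' self-describing.
#'
#' @param params A [kinetic_params()] object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   [kinetic_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  doc <- list(
    units = list(concentration = "uM", time = "min",
                 bimolecular_rate = "uM^-1 min^-1"),
    params = unclass(params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(kinetic_params, as.list(doc$params))
}
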