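#' Circuit component constructors
#'
#' A circuit is described declaratively by the DNA templates it transcribes,
#' the allosteric transcription factors (aTFs) regulating them, the ligand
#' inputs, and the DNA/RNA gates that process the transcribed invader strands.
#' Units are uM and minutes throughout; template concentrations are entered in
#' nM (the working scale in this system) and converted to uM on construction.
#'
#' @name circuit-components
NULL

#' @describeIn circuit-components A ligand input at a given concentration (uM).
#' @param name Identifier.
#' @param concentration Concentration in uM (must be >= 0).
#' @export
ligand_input <- function(name, concentration = 0) {
  if (concentration < 0) stop_field(paste0("ligand '", name, "'"),
                                    "concentration must be >= 0")
  structure(list(name = name, concentration = concentration),
            class = "ligand_input")
}

#' @describeIn circuit-components An allosteric transcription factor. The
#'   lumped cooperative ligand-binding step has mass-action order
#'   `ligand_stoichiometry`; `k_on_lig`/`k_off_lig`, when given, override the
#'   global constants in [kinetic_params()] for this factor.
#' @param operator_id Operator sequence identifier this factor binds.
#' @param dimer_total Total dimer concentration (uM).
#' @param ligand_name Cognate ligand identifier.
#' @param ligand_stoichiometry Ligands bound per dimer in the lumped step
#'   (1 or 2).
#' @param k_on_lig,k_off_lig Optional per-factor ligand binding constants.
#' @export
tf_spec <- function(name, operator_id, dimer_total, ligand_name,
                    ligand_stoichiometry = 2,
                    k_on_lig = NULL, k_off_lig = NULL) {
  path <- paste0("tf '", name, "'")
  if (dimer_total < 0) stop_field(path, "dimer_total must be >= 0")
  if (!ligand_stoichiometry %in% c(1, 2))
    stop_field(path, "ligand_stoichiometry must be 1 or 2")
  structure(list(name = name, operator_id = operator_id,
                 dimer_total = dimer_total, ligand_name = ligand_name,
                 ligand_stoichiometry = ligand_stoichiometry,
                 k_on_lig = k_on_lig, k_off_lig = k_off_lig),
            class = "tf_spec")
}

#' @describeIn circuit-components A transcription template. `operator_id =
#'   NULL` means unregulated (constitutive T7 transcription).
#' @param transcript_name Name of the RNA species this template produces
#'   (an invader strand or an RNA NOT gate).
#' @param concentration_nM Template concentration in nM (stored as uM).
#' @param tx_efficiency_factor Multiplier on the transcription rate,
#'   representing template-to-template variation in T7 transcription
#'   efficiency.
#' @param structure_penalty Optional multiplier in (0, 1] on the TMSD rates of
#'   the transcript this template produces, representing inhibitory RNA
#'   secondary structure; `NULL` uses the global default.
#' @export
template_spec <- function(name, transcript_name, operator_id = NULL,
                          concentration_nM = 50, tx_efficiency_factor = 1,
                          structure_penalty = NULL) {
  path <- paste0("template '", name, "'")
  if (concentration_nM < 0) stop_field(path, "concentration must be >= 0")
  if (tx_efficiency_factor <= 0)
    stop_field(path, "tx_efficiency_factor must be > 0")
  if (!is.null(structure_penalty) &&
      (structure_penalty <= 0 || structure_penalty > 1))
    stop_field(path, "structure_penalty must be in (0, 1]")
  structure(list(name = name, transcript_name = transcript_name,
                 operator_id = operator_id,
                 concentration_uM = concentration_nM / 1000,
                 tx_efficiency_factor = tx_efficiency_factor,
                 structure_penalty = structure_penalty),
            class = "template_spec")
}

#' @describeIn circuit-components A strand-displacement gate. Kinds:
#'   `signal` (fluorophore/quencher reporter duplex), `threshold` (unlabeled
#'   consumer with a longer toehold), `or_gate` (translator releasing an
#'   output strand), `and_gate` (two-invader gate with clamp and drivers), and
#'   `not_rna` (transcribed RNA gate that sequesters its invader; its
#'   concentration is set by transcription, so `concentration = NULL`).
#'   Signal gates may be invaded by one or two distinct strands (e.g. the
#'   IMPLY architectures route both a mismatch-carrying invader and a clean
#'   translator output into the same reporter); `invader_mismatch` flags,
#'   per invader, an engineered mismatch that slows that displacement path.
#' @param kind One of `"signal"`, `"threshold"`, `"or_gate"`, `"and_gate"`,
#'   `"not_rna"`.
#' @param concentration Gate concentration in uM (`NULL` for `not_rna`).
#' @param toehold_nt Toehold length in nucleotides (>= 1).
#' @param clamp_bp Clamp length in bp (and_gate only).
#' @param invader_names Ordered identifiers of the strand(s) this gate
#'   consumes (two for `and_gate`, in binding order).
#' @param invader_mismatch Logical, recycled along `invader_names`.
#' @param output_name Output strand released (or_gate/and_gate).
#' @export
gate_spec <- function(name, kind, concentration = NULL, toehold_nt = 8,
                      clamp_bp = 0, invader_names, invader_mismatch = FALSE,
                      output_name = NULL) {
  path <- paste0("gate '", name, "'")
  kinds <- c("signal", "threshold", "or_gate", "and_gate", "not_rna")
  if (!kind %in% kinds)
    stop_field(path, paste0("unknown gate kind '", kind, "' (use one of ",
                            paste(kinds, collapse = ", "), ")"))
  if (toehold_nt < 1) stop_field(path, "toehold_nt must be >= 1")
  if (clamp_bp < 0) stop_field(path, "clamp_bp must be >= 0")
  n_inv <- length(invader_names)
  if (kind == "and_gate" && n_inv != 2)
    stop_field(path, "and_gate requires exactly 2 invader_names")
  if (kind %in% c("threshold", "or_gate", "not_rna") && n_inv != 1)
    stop_field(path, paste0(kind, " requires exactly 1 invader name"))
  if (kind == "signal" && !n_inv %in% c(1, 2))
    stop_field(path, "signal gate takes 1 or 2 invader names")
  if (kind %in% c("or_gate", "and_gate") && is.null(output_name))
    stop_field(path, paste0(kind, " requires an output_name"))
  if (kind == "not_rna") {
    if (!is.null(concentration))
      stop_field(path, "not_rna gates are produced by a template; omit concentration")
  } else {
    if (is.null(concentration) || concentration < 0)
      stop_field(path, "concentration (uM) must be >= 0")
  }
  invader_mismatch <- rep_len(as.logical(invader_mismatch), n_inv)
  structure(list(name = name, kind = kind, concentration = concentration,
                 toehold_nt = toehold_nt, clamp_bp = clamp_bp,
                 invader_names = invader_names,
                 invader_mismatch = invader_mismatch,
                 output_name = output_name),
            class = "gate_spec")
}

#' Assemble a circuit specification
#'
#' @param name Circuit identifier.
#' @param templates List of [template_spec()] objects.
#' @param tfs List of [tf_spec()] objects.
#' @param gates List of [gate_spec()] objects.
#' @param ligand_names Ordered character vector of the circuit's ligand
#'   inputs (the truth-table input order).
#' @param intended_logic Optional logic label: a list with `label` (one of
#'   NOT, OR, AND, NOR, IMPLY, NIMPLY, NAND, BUFFER) and `inputs` (ordered
#'   ligand names; order matters for the directional IMPLY/NIMPLY).
#' @return A `circuit_spec` object. Construction does not validate
#'   cross-references; call [validate_circuit()].
#' @seealso [library_circuit()], [validate_circuit()], [compile_network()]
#' @export
circuit_spec <- function(name, templates, tfs = list(), gates,
                         ligand_names = character(), intended_logic = NULL) {
  spec <- structure(list(name = name, templates = templates, tfs = tfs,
                         gates = gates, ligand_names = ligand_names,
                         intended_logic = intended_logic,
                         schema_version = 1L),
                    class = "circuit_spec")
  spec
}

#' @export
print.circuit_spec <- function(x, ...) {
  lg <- if (is.null(x$intended_logic)) "none" else
    paste0(x$intended_logic$label, "(",
           paste(x$intended_logic$inputs, collapse = ", "), ")")
  cat(sprintf("<circuit_spec> %s\n", x$name))
  cat(sprintf("  templates: %d | aTFs: %d | gates: %d | ligands: %s\n",
              length(x$templates), length(x$tfs), length(x$gates),
              if (length(x$ligand_names)) paste(x$ligand_names, collapse = ", ")
              else "none"))
  cat(sprintf("  intended logic: %s\n", lg))
  invisible(x)
}

# Names of species produced by templates or gates (used for validation and
# for resolving invader references).
producer_names <- function(spec) {
  c(vapply(spec$templates, `[[`, "", "transcript_name"),
    unlist(lapply(spec$gates, function(g) g$output_name)))
}

#' Validate a circuit specification
#'
#' Checks cross-references (operators to aTFs, invaders and not_rna gates to
#' producers), structural invariants (unique producers, exactly one signal
#' gate, acyclic gate graph terminating at the signal gate) and value ranges.
#'
#' @param spec A [circuit_spec()].
#' @return Character vector of diagnostics; `character(0)` when valid.
#' @export
validate_circuit <- function(spec) {
  out <- character()
  note <- function(path, msg) out <<- c(out, sprintf("%s: %s", path, msg))

  tf_ops <- vapply(spec$tfs, `[[`, "", "operator_id")
  if (anyDuplicated(tf_ops))
    note("tfs", paste0("operator '", tf_ops[duplicated(tf_ops)][1],
                       "' has more than one transcription factor"))
  tf_ligs <- vapply(spec$tfs, `[[`, "", "ligand_name")
  for (lg in tf_ligs)
    if (!lg %in% spec$ligand_names)
      note("tfs", paste0("ligand '", lg, "' not in circuit ligand_names"))

  prods <- producer_names(spec)
  if (anyDuplicated(prods))
    note("producers", paste0("species '", prods[duplicated(prods)][1],
                             "' is produced by more than one template or gate"))

  for (i in seq_along(spec$templates)) {
    tm <- spec$templates[[i]]
    path <- sprintf("templates[%d] '%s'", i, tm$name)
    if (!is.null(tm$operator_id) && !tm$operator_id %in% tf_ops)
      note(path, paste0("operator '", tm$operator_id,
                        "' has no transcription factor"))
  }

  gate_names <- vapply(spec$gates, `[[`, "", "name")
  for (i in seq_along(spec$gates)) {
    g <- spec$gates[[i]]
    path <- sprintf("gates[%d] '%s'", i, g$name)
    for (inv in g$invader_names)
      if (!inv %in% prods)
        note(path, paste0("invader '", inv,
                          "' is not produced by any template or gate"))
    if (g$kind == "not_rna") {
      producers <- vapply(spec$templates,
                          function(tm) identical(tm$transcript_name, g$name),
                          logical(1))
      if (sum(producers) != 1)
        note(path, "not_rna gate must be the transcript of exactly one template")
    }
  }

  n_signal <- sum(vapply(spec$gates, function(g) g$kind == "signal", logical(1)))
  if (n_signal != 1)
    note("gates", sprintf("circuit must contain exactly one signal gate (found %d)",
                          n_signal))

  # gate dependency graph: edge producer-gate -> consumer-gate via strands
  if (length(spec$gates) && n_signal == 1) {
    made_by_gate <- lapply(spec$gates, function(g) g$output_name %||% character())
    names(made_by_gate) <- gate_names
    reach <- function(gname, seen = character()) {
      if (gname %in% seen) return(NA)  # cycle
      g <- spec$gates[[match(gname, gate_names)]]
      if (is.null(g$output_name)) return(TRUE)
      consumers <- gate_names[vapply(spec$gates, function(h)
        g$output_name %in% h$invader_names, logical(1))]
      if (!length(consumers)) return(FALSE)
      res <- vapply(consumers, reach, NA, seen = c(seen, gname))
      if (anyNA(res)) NA else all(res)
    }
    for (gn in gate_names) {
      r <- reach(gn)
      if (is.na(r)) { note("gates", "gate dependency graph contains a cycle"); break }
      if (!isTRUE(r))
        note(paste0("gate '", gn, "'"),
             "output strand never reaches the signal gate")
    }
  }
  out
}

#' Enumerate binary input conditions for a circuit
#'
#' Produces the full truth-table input set: each of the circuit's `n` ligands
#' at 0 or `on_level` uM, in canonical binary order with the first ligand as
#' the most significant bit (so two ligands enumerate (0,0), (0,1), (1,0),
#' (1,1)).
#'
#' @param circuit A [circuit_spec()].
#' @param on_level ON concentration in uM (> 0).
#' @return A data.frame with one column per ligand and `2^n` rows.
#' @export
enumerate_conditions <- function(circuit, on_level = 100) {
  if (on_level <= 0) stop("on_level must be > 0", call. = FALSE)
  ligs <- circuit$ligand_names
  n <- length(ligs)
  if (n == 0) {
    df <- data.frame(row.names = 1)
    return(df[, 0, drop = FALSE])
  }
  idx <- 0:(2^n - 1)
  cols <- lapply(seq_len(n), function(j) {
    bit <- bitwAnd(idx %/% 2^(n - j), 1L)
    bit * on_level
  })
  names(cols) <- ligs
  as.data.frame(cols, check.names = FALSE)
}

#' Expected truth value of a logic label at one input condition
#'
#' @param intended_logic The `intended_logic` element of a circuit.
#' @param condition Named numeric vector of ligand concentrations (uM).
#' @return `TRUE` for expected ON.
#' @export
expected_output <- function(intended_logic, condition) {
  x <- condition[intended_logic$inputs] > 0
  switch(intended_logic$label,
         BUFFER = unname(x[1]),
         NOT    = !x[1],
         OR     = x[1] || x[2],
         AND    = x[1] && x[2],
         NOR    = !(x[1] || x[2]),
         NAND   = !(x[1] && x[2]),
         IMPLY  = !x[1] || x[2],
         NIMPLY = x[1] && !x[2],
         stop("unknown logic label: ", intended_logic$label, call. = FALSE))
}
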