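circuit_to_list <- function(spec) {
  list(
    schema_version = spec$schema_version,
    name = spec$name,
    ligand_names = as.list(spec$ligand_names),
    intended_logic = spec$intended_logic,
    templates = lapply(spec$templates, function(tm) {
      out <- list(name = tm$name, transcript_name = tm$transcript_name,
                  concentration_nM = tm$concentration_uM * 1000,
                  tx_efficiency_factor = tm$tx_efficiency_factor)
      if (!is.null(tm$operator_id)) out$operator_id <- tm$operator_id
      if (!is.null(tm$structure_penalty))
        out$structure_penalty <- tm$structure_penalty
      out
    }),
    tfs = lapply(spec$tfs, function(tf) {
      out <- list(name = tf$name, operator_id = tf$operator_id,
                  dimer_total = tf$dimer_total, ligand_name = tf$ligand_name,
                  ligand_stoichiometry = tf$ligand_stoichiometry)
      if (!is.null(tf$k_on_lig)) out$k_on_lig <- tf$k_on_lig
      if (!is.null(tf$k_off_lig)) out$k_off_lig <- tf$k_off_lig
      out
    }),
    gates = lapply(spec$gates, function(g) {
      out <- list(name = g$name, kind = g$kind, toehold_nt = g$toehold_nt,
                  clamp_bp = g$clamp_bp,
                  invader_names = as.list(g$invader_names),
                  invader_mismatch = as.list(g$invader_mismatch))
      if (!is.null(g$concentration)) out$concentration <- g$concentration
      if (!is.null(g$output_name)) out$output_name <- g$output_name
      out
    })
  )
}

circuit_from_list <- function(doc) {
  if (!is.list(doc) || is.null(doc$name))
    stop("circuit document must be a mapping with a 'name' field", call. = FALSE)
  grab <- function(x, field, path, default = NULL) {
    if (is.null(x[[field]])) {
      if (!is.null(default) || field %in% c("operator_id", "structure_penalty",
                                            "k_on_lig", "k_off_lig",
                                            "concentration", "output_name"))
        return(default)
      stop_field(paste0(path, ".", field), "missing required field")
    }
    x[[field]]
  }
  templates <- lapply(seq_along(doc$templates), function(i) {
    tm <- doc$templates[[i]]; path <- sprintf("templates[%d]", i)
    template_spec(
      name = grab(tm, "name", path),
      transcript_name = grab(tm, "transcript_name", path),
      operator_id = tm$operator_id,
      concentration_nM = grab(tm, "concentration_nM", path),
      tx_efficiency_factor = tm$tx_efficiency_factor %||% 1,
      structure_penalty = tm$structure_penalty
    )
  })
  tfs <- lapply(seq_along(doc$tfs), function(i) {
    tf <- doc$tfs[[i]]; path <- sprintf("tfs[%d]", i)
    tf_spec(
      name = grab(tf, "name", path),
      operator_id = grab(tf, "operator_id", path),
      dimer_total = grab(tf, "dimer_total", path),
      ligand_name = grab(tf, "ligand_name", path),
      ligand_stoichiometry = tf$ligand_stoichiometry %||% 2,
      k_on_lig = tf$k_on_lig, k_off_lig = tf$k_off_lig
    )
  })
  gates <- lapply(seq_along(doc$gates), function(i) {
    g <- doc$gates[[i]]; path <- sprintf("gates[%d]", i)
    gate_spec(
      name = grab(g, "name", path),
      kind = grab(g, "kind", path),
      concentration = g$concentration,
      toehold_nt = g$toehold_nt %||% 8,
      clamp_bp = g$clamp_bp %||% 0,
      invader_names = unlist(grab(g, "invader_names", path)),
      invader_mismatch = unlist(g$invader_mismatch %||% FALSE),
      output_name = g$output_name
    )
  })
  logic <- doc$intended_logic
  if (!is.null(logic)) logic$inputs <- unlist(logic$inputs)
  circuit_spec(name = doc$name, templates = templates, tfs = tfs,
               gates = gates, ligand_names = unlist(doc$ligand_names) %||%
                 character(), intended_logic = logic)
}

#' Serialize a circuit to canonical JSON
#'
#' @param spec A [circuit_spec()].
#' @param pretty Pretty-print the JSON.
#' @return A JSON string (class `json`).
#' @seealso [parse_circuit()] for the inverse.
#' @export
serialize_circuit <- function(spec, pretty = FALSE) {
  jsonlite::toJSON(circuit_to_list(spec), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = pretty)
}

#' Parse a circuit document (YAML or JSON)
#'
#' Accepts the structured-text circuit schema (version 1): a mapping with
#' `name`, `templates`, `tfs`, `gates`, `ligand_names` and optional
#' `intended_logic`. Template concentrations are given in nM and normalized
#' to uM. The parsed circuit is validated; dangling references or invalid
#' values raise errors naming the offending field.
#'
#' @param text A character scalar holding the document (JSON if it starts
#'   with `{`, otherwise YAML).
#' @return A validated [circuit_spec()].
#' @export
parse_circuit <- function(text) {
  text <- paste(text, collapse = "\n")
  doc <- if (grepl("^\\s*\\{", text)) {
    jsonlite::fromJSON(text, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(text)
  }
  spec <- circuit_from_list(doc)
  problems <- validate_circuit(spec)
  if (length(problems))
    stop("invalid circuit document:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  spec
}

#' Read / write circuit files
#'
#' @param path File path; `.json`/`.yaml`/`.yml` both supported on read,
#'   JSON written on write.
#' @param spec A [circuit_spec()].
#' @return `read_circuit` returns a validated [circuit_spec()];
#'   `write_circuit` returns `path` invisibly.
#' @export
read_circuit <- function(path) {
  parse_circuit(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @rdname read_circuit
#' @export
write_circuit <- function(spec, path) {
  writeLines(serialize_circuit(spec, pretty = TRUE), path)
  invisible(path)
}
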