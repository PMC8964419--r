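# Mass-action network compilation.
#
# Species carry a composition multiset over conserved "moieties" (DNA strands,
# protein, ligand molecules) so that conservation vectors can be constructed
# by bookkeeping and verified algebraically against the stoichiometry matrix.
# Transcribed RNA strands are produced catalytically and carry no conserved
# moiety.

new_network_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$species <- list()     # name -> list(role, init, comp)
  env$reactions <- list()
  env
}

nb_species <- function(env, name, role, init = 0, comp = numeric()) {
  if (!is.null(env$species[[name]])) {
    # first registration wins for role/comp; inits accumulate
    env$species[[name]]$init <- env$species[[name]]$init + init
  } else {
    env$species[[name]] <- list(role = role, init = init, comp = comp)
  }
  name
}

nb_reaction <- function(env, reactants, products, k, label) {
  # reactants/products: named integer multiplicities
  env$reactions[[length(env$reactions) + 1L]] <-
    list(reactants = reactants, products = products, k = k, label = label)
  invisible(env)
}

comp1 <- function(...) {
  v <- c(...)
  v[v != 0]
}

#' Compile a circuit into a mass-action reaction network
#'
#' Expands a [circuit_spec()] into explicit species and mass-action reactions:
#' TF--operator binding (repression), the lumped cooperative TF--ligand step,
#' pseudo-first-order transcription catalytic in template, and one TMSD
#' reaction set per gate. Signal gates release free fluorophore strand,
#' threshold and RNA NOT gates consume invader to waste, translator (OR)
#' gates release their output strand, and AND gates expand to a reversible
#' toehold-exchange capture, an irreversible output release, and a
#' clamp-suppressed leak reaction.
#'
#' @param circuit A validated [circuit_spec()].
#' @param params A [kinetic_params()] object.
#' @param condition Named numeric vector of ligand concentrations (uM);
#'   unnamed ligands default to 0.
#' @return A `reaction_network` with elements `species` (data.frame: name,
#'   role, init), `reactions`, stoichiometry matrix `S` (species x reactions),
#'   rate constants `k`, reaction `labels`, composition matrix `comp`, the
#'   `observable` species name (free fluorophore) and provenance fields.
#' @seealso [simulate_network()], [conservation_vectors()]
#' @export
compile_network <- function(circuit, params = kinetic_params(),
                            condition = NULL) {
  problems <- validate_circuit(circuit)
  if (length(problems))
    stop("invalid circuit:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  cond <- stats::setNames(rep(0, length(circuit$ligand_names)),
                          circuit$ligand_names)
  if (!is.null(condition)) {
    extra <- setdiff(names(condition), circuit$ligand_names)
    if (length(extra))
      stop("condition names not in circuit ligands: ",
           paste(extra, collapse = ", "), call. = FALSE)
    cond[names(condition)] <- condition
  }

  env <- new_network_builder()

  # structure penalty of each transcribed strand (1 for DNA output strands)
  struct_pen <- function(strand) {
    for (tm in circuit$templates)
      if (identical(tm$transcript_name, strand))
        return(tm$structure_penalty %||% params$structure_penalty)
    1
  }

  # conserved-moiety contribution of an invader strand: DNA output strands
  # released by gates persist in downstream wastes; RNA transcripts do not
  # carry a conserved moiety
  strand_moiety <- function(inv) {
    made_by_gate <- any(vapply(circuit$gates, function(g)
      identical(g$output_name, inv), logical(1)))
    if (made_by_gate) stats::setNames(1, paste0("strand:", inv)) else numeric()
  }

  # ligands
  for (lg in circuit$ligand_names)
    nb_species(env, paste0("ligand_", lg), "ligand", init = cond[[lg]],
               comp = comp1(stats::setNames(1, paste0("ligand:", lg))))

  # transcription factors
  tf_by_op <- list()
  for (tf in circuit$tfs) {
    tf_by_op[[tf$operator_id]] <- tf
    m <- paste0("tf:", tf$name)
    nb_species(env, paste0("tf_", tf$name), "TF_free", init = tf$dimer_total,
               comp = comp1(stats::setNames(1, m)))
    s <- tf$ligand_stoichiometry
    lig_sp <- paste0("ligand_", tf$ligand_name)
    holo <- nb_species(env, paste0("tflig_", tf$name), "TF_ligand_complex",
                       comp = comp1(stats::setNames(1, m),
                                    stats::setNames(s, paste0("ligand:",
                                                              tf$ligand_name))))
    kon <- tf$k_on_lig %||% params$k_on_lig
    koff <- tf$k_off_lig %||% params$k_off_lig
    nb_reaction(env, stats::setNames(c(1, s), c(paste0("tf_", tf$name), lig_sp)),
                stats::setNames(1, holo), kon,
                paste0("ligand_binding:", tf$name))
    nb_reaction(env, stats::setNames(1, holo),
                stats::setNames(c(1, s), c(paste0("tf_", tf$name), lig_sp)),
                koff, paste0("ligand_release:", tf$name))
  }

  # templates: repression + transcription
  for (tm in circuit$templates) {
    t_sp <- nb_species(env, paste0("template_", tm$name), "template",
                       init = tm$concentration_uM,
                       comp = comp1(stats::setNames(1, paste0("template:",
                                                              tm$name))))
    if (!is.null(tm$operator_id)) {
      tf <- tf_by_op[[tm$operator_id]]
      b_sp <- nb_species(env, paste0("template_", tm$name, "_bound"),
                         "template_TF_complex",
                         comp = comp1(stats::setNames(1, paste0("template:",
                                                                tm$name)),
                                      stats::setNames(1, paste0("tf:",
                                                                tf$name))))
      nb_reaction(env, stats::setNames(c(1, 1), c(paste0("tf_", tf$name), t_sp)),
                  stats::setNames(1, b_sp), params$k_on_op,
                  paste0("operator_binding:", tm$name))
      nb_reaction(env, stats::setNames(1, b_sp),
                  stats::setNames(c(1, 1), c(paste0("tf_", tf$name), t_sp)),
                  params$k_off_op, paste0("operator_release:", tm$name))
    }
    # transcript species role: rna_gate if some not_rna gate bears its name
    is_rna_gate <- any(vapply(circuit$gates, function(g)
      g$kind == "not_rna" && identical(g$name, tm$transcript_name), logical(1)))
    tr_sp <- nb_species(env, tm$transcript_name,
                        if (is_rna_gate) "rna_gate" else "transcript")
    nb_reaction(env, stats::setNames(1, t_sp),
                stats::setNames(c(1, 1), c(t_sp, tr_sp)),
                params$k_tx * tm$tx_efficiency_factor,
                paste0("transcription:", tm$name))
  }

  # gates
  for (g in circuit$gates) {
    g_m <- stats::setNames(1, paste0("gate:", g$name))
    base_rate <- toehold_rate(g$toehold_nt, params)
    if (g$kind == "not_rna") {
      # the gate species is the transcript registered above (role rna_gate)
      inv <- g$invader_names
      waste <- nb_species(env, paste0("waste_", g$name), "waste",
                          comp = comp1(strand_moiety(inv)))
      nb_reaction(env, stats::setNames(c(1, 1), c(g$name, inv)),
                  stats::setNames(1, waste),
                  base_rate * struct_pen(inv),
                  paste0("sequestration:", g$name))
      next
    }
    gate_sp <- nb_species(env, paste0("gate_", g$name), "dna_gate",
                          init = g$concentration,
                          comp = if (is.null(g$output_name)) comp1(g_m) else
                            comp1(g_m, stats::setNames(1, paste0("strand:",
                                                                 g$output_name))))
    if (g$kind == "signal") {
      fl <- nb_species(env, "fluor_free", "fluorophore_free",
                       comp = comp1(stats::setNames(1, paste0("fluor:",
                                                              g$name))))
      # quenched gate also carries the fluorophore strand
      env$species[[gate_sp]]$comp <- comp1(
        env$species[[gate_sp]]$comp,
        stats::setNames(1, paste0("fluor:", g$name)))
      for (j in seq_along(g$invader_names)) {
        inv <- g$invader_names[j]
        waste <- nb_species(env, paste0("waste_", g$name, "_", inv), "waste",
                            comp = comp1(g_m, strand_moiety(inv)))
        rate <- base_rate * struct_pen(inv) *
          (if (g$invader_mismatch[j]) params$mismatch_penalty else 1)
        nb_reaction(env, stats::setNames(c(1, 1), c(inv, gate_sp)),
                    stats::setNames(c(1, 1), c(fl, waste)), rate,
                    paste0("signal_tmsd:", g$name, ":", inv))
      }
    } else if (g$kind == "threshold") {
      inv <- g$invader_names
      waste <- nb_species(env, paste0("waste_", g$name), "waste",
                          comp = comp1(g_m, strand_moiety(inv)))
      nb_reaction(env, stats::setNames(c(1, 1), c(inv, gate_sp)),
                  stats::setNames(1, waste),
                  base_rate * struct_pen(inv) *
                    (if (g$invader_mismatch[1]) params$mismatch_penalty else 1),
                  paste0("threshold_tmsd:", g$name))
    } else if (g$kind == "or_gate") {
      inv <- g$invader_names
      out <- nb_species(env, g$output_name, "released_output",
                        comp = comp1(stats::setNames(1, paste0("strand:",
                                                               g$output_name))))
      waste <- nb_species(env, paste0("waste_", g$name), "waste",
                          comp = comp1(g_m, strand_moiety(inv)))
      nb_reaction(env, stats::setNames(c(1, 1), c(inv, gate_sp)),
                  stats::setNames(c(1, 1), c(out, waste)),
                  base_rate * struct_pen(inv) *
                    (if (g$invader_mismatch[1]) params$mismatch_penalty else 1),
                  paste0("or_tmsd:", g$name))
    } else if (g$kind == "and_gate") {
      inv1 <- g$invader_names[1]; inv2 <- g$invader_names[2]
      out <- nb_species(env, g$output_name, "released_output",
                        comp = comp1(stats::setNames(1, paste0("strand:",
                                                               g$output_name))))
      int <- nb_species(env, paste0("int_", g$name), "intermediate",
                        comp = comp1(g_m, stats::setNames(1, paste0("strand:",
                                                                    g$output_name))))
      waste <- nb_species(env, paste0("waste_", g$name), "waste",
                          comp = comp1(g_m))
      waste_leak <- nb_species(env, paste0("waste_", g$name, "_leak"), "waste",
                               comp = comp1(g_m))
      # reversible toehold exchange (first invader capture)
      nb_reaction(env, stats::setNames(c(1, 1), c(inv1, gate_sp)),
                  stats::setNames(1, int),
                  base_rate * struct_pen(inv1),
                  paste0("and_capture:", g$name))
      nb_reaction(env, stats::setNames(1, int),
                  stats::setNames(c(1, 1), c(inv1, gate_sp)),
                  params$k_rev_toehold_exchange,
                  paste0("and_capture_rev:", g$name))
      # irreversible output release at the saturated rate (full toehold
      # revealed by the exchange step)
      nb_reaction(env, stats::setNames(c(1, 1), c(inv2, int)),
                  stats::setNames(c(1, 1), c(out, waste)),
                  params$k_tmsd_max * struct_pen(inv2),
                  paste0("and_release:", g$name))
      # clamp-suppressed leak by the first invader alone
      leak_k <- params$clamp_leak0 *
        10^(-params$clamp_decay_per_bp * g$clamp_bp)
      nb_reaction(env, stats::setNames(c(1, 1), c(inv1, gate_sp)),
                  stats::setNames(c(1, 1), c(out, waste_leak)), leak_k,
                  paste0("and_leak:", g$name))
    }
  }

  finalize_network(env, circuit, params, cond)
}

finalize_network <- function(env, circuit, params, cond) {
  sp_names <- names(env$species)
  n_sp <- length(sp_names)
  rxns <- env$reactions
  n_rx <- length(rxns)
  S <- matrix(0, n_sp, n_rx, dimnames = list(sp_names, NULL))
  react_idx <- vector("list", n_rx)
  for (j in seq_len(n_rx)) {
    r <- rxns[[j]]
    for (nm in names(r$reactants)) S[nm, j] <- S[nm, j] - r$reactants[[nm]]
    for (nm in names(r$products)) S[nm, j] <- S[nm, j] + r$products[[nm]]
    react_idx[[j]] <- rep(match(names(r$reactants), sp_names),
                          times = r$reactants)
  }
  moieties <- sort(unique(unlist(lapply(env$species, function(s)
    names(s$comp)))))
  comp <- matrix(0, n_sp, length(moieties),
                 dimnames = list(sp_names, moieties))
  for (nm in sp_names) {
    cc <- env$species[[nm]]$comp
    if (length(cc)) comp[nm, names(cc)] <- cc
  }
  structure(list(
    species = data.frame(
      name = sp_names,
      role = vapply(env$species, `[[`, "", "role"),
      init = vapply(env$species, `[[`, 0, "init"),
      row.names = NULL),
    reactions = rxns,
    S = S,
    k = vapply(rxns, `[[`, 0, "k"),
    labels = vapply(rxns, `[[`, "", "label"),
    react_idx = react_idx,
    comp = comp,
    observable = if ("fluor_free" %in% sp_names) "fluor_free" else NA_character_,
    circuit_name = circuit$name,
    condition = cond,
    params = params
  ), class = "reaction_network")
}

#' Build a mass-action network directly from species and reactions
#'
#' Lower-level companion to [compile_network()] for ad-hoc kinetics (test
#' oracles, textbook systems): supply species with initial concentrations
#' and mass-action reactions with rate constants.
#'
#' @param species Data frame with columns `name`, `init` (uM) and optionally
#'   `role`.
#' @param reactions List of `list(reactants =, products =, k =, label =)`,
#'   where reactants/products are named multiplicity vectors over species
#'   names.
#' @param comp Optional named list mapping species to named moiety-count
#'   vectors, enabling [conservation_vectors()].
#' @param observable Optional species name reported by [mef_trace()].
#' @return A `reaction_network`.
#' @examples
#' net <- mass_action_network(
#'   data.frame(name = c("A", "B", "C"), init = c(1, 1, 0)),
#'   list(list(reactants = c(A = 1, B = 1), products = c(C = 1), k = 1,
#'             label = "assoc")))
#' sim <- simulate_network(net, solver_settings(t_grid = 0:10))
#' sim$conc[11, "A"]  # 1/(1 + k*c0*t) = 1/11
#' @export
mass_action_network <- function(species, reactions, comp = list(),
                                observable = NA_character_) {
  env <- new_network_builder()
  for (i in seq_len(nrow(species)))
    nb_species(env, species$name[i],
               role = if ("role" %in% names(species)) species$role[i] else
                 "species",
               init = species$init[i],
               comp = comp[[species$name[i]]] %||% numeric())
  for (r in reactions) {
    unknown <- setdiff(c(names(r$reactants), names(r$products)),
                       species$name)
    if (length(unknown))
      stop("reaction references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    nb_reaction(env, r$reactants, r$products, r$k, r$label %||% "")
  }
  net <- finalize_network(env, list(name = "custom"), NULL, numeric())
  net$observable <- observable
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s: %d species, %d reactions\n",
              x$circuit_name, nrow(x$species), length(x$reactions)))
  if (length(x$condition))
    cat("  condition:", paste(names(x$condition), x$condition, sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Stoichiometry matrix of a network
#'
#' @param net A `reaction_network`.
#' @return Species-by-reaction matrix of net stoichiometric coefficients.
#' @export
stoichiometry_matrix <- function(net) net$S

#' Conserved linear combinations of a network
#'
#' Returns the conservation vectors implied by strand/molecule bookkeeping:
#' total of each DNA template (free + TF-bound), each transcription factor
#' (free + ligand-bound + operator-bound), each ligand, each DNA gate
#' scaffold across its gate/intermediate/waste states, each released output
#' strand across its carriers, and the fluorophore strand (quenched + free).
#' Every returned vector is an exact left-null vector of the stoichiometry
#' matrix; this is asserted at run time.
#'
#' @param net A `reaction_network`.
#' @return Named list of numeric vectors (one entry per species).
#' @export
conservation_vectors <- function(net) {
  out <- list()
  for (m in colnames(net$comp)) {
    w <- net$comp[, m]
    resid <- max(abs(drop(w %*% net$S)))
    if (resid > 1e-12)
      stop("internal error: moiety '", m, "' is not conserved (residual ",
           format(resid), ")", call. = FALSE)
    out[[m]] <- w
  }
  out
}

#' Export the reaction table
#'
#' Flat table of reactions (reactants, products, rate constant, provenance
#' label) for interoperability; optionally written as CSV.
#'
#' @param net A `reaction_network`.
#' @param path Optional CSV path.
#' @return A data.frame (invisibly if `path` is given).
#' @export
network_reactions <- function(net, path = NULL) {
  side <- function(x) paste(ifelse(x > 1, paste0(x, " "), ""),
                            names(x), sep = "", collapse = " + ")
  df <- data.frame(
    reactants = vapply(net$reactions, function(r) side(r$reactants), ""),
    products = vapply(net$reactions, function(r) side(r$products), ""),
    rate_constant = net$k,
    label = net$labels
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
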