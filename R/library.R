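# Packaged circuit library.
#
# The twelve logic circuits pair a tetracycline-responsive TetR sensor with a
# zinc-responsive SmtB sensor; the sensor entries cover the aTc-induced TetR
# reporter and the graded zinc sensor the ADC designer thresholds.
#
# Shared working concentrations: 50 nM regulated invader templates, 25 nM
# unregulated invader templates, 350 nM RNA NOT-gate templates (inverter
# production must outrun the invader it sequesters), 5 uM DNA gates, 5 uM TF
# dimer (1.2 uM for the graded zinc sensor). Toeholds: 8 nt on reporter,
# translator and threshold gates (saturated displacement), 4 nt on the
# ADC reporter it must outpace, 5 nt on the AND-gate capture step so that
# NOT-gate sequestration can outcompete it.

lib_tetR <- function(ligand = "tetracycline", dimer = 5) {
  # aTc/tetracycline binding is sub-nM and effectively irreversible over 2 h;
  # single-site occupancy of the dimer suffices to release the operator.
  tf_spec("TetR", operator_id = "tetO", dimer_total = dimer,
          ligand_name = ligand, ligand_stoichiometry = 1)
}

lib_smtB <- function(dimer = 5) {
  # micromolar effective zinc affinity gives the graded dose-response the
  # thermometer ADC reads out
  tf_spec("SmtB", operator_id = "smtO", dimer_total = dimer,
          ligand_name = "zinc", ligand_stoichiometry = 1,
          k_on_lig = 1, k_off_lig = 1)
}

signal_gate <- function(invaders, mismatch = FALSE, toehold = 8, conc = 5) {
  gate_spec("SignalGate", "signal", concentration = conc,
            toehold_nt = toehold, invader_names = invaders,
            invader_mismatch = mismatch)
}

lib_sensor_circuits <- function() {
  list(
    unregulated_sensor = circuit_spec(
      "unregulated_sensor",
      templates = list(template_spec("T_u", "InvadeR_u", concentration_nM = 50)),
      gates = list(signal_gate("InvadeR_u"))
    ),
    aTc_sensor = circuit_spec(
      "aTc_sensor",
      templates = list(template_spec("T_tet", "InvadeR_tet",
                                     operator_id = "tetO")),
      tfs = list(lib_tetR(ligand = "aTc")),
      gates = list(signal_gate("InvadeR_tet")),
      ligand_names = "aTc",
      intended_logic = list(label = "BUFFER", inputs = "aTc")
    ),
    zinc_sensor = circuit_spec(
      "zinc_sensor",
      templates = list(template_spec("T_zn", "InvadeR_zn",
                                     operator_id = "smtO")),
      tfs = list(lib_smtB(dimer = 1.2)),
      gates = list(signal_gate("InvadeR_zn", toehold = 4)),
      ligand_names = "zinc",
      intended_logic = list(label = "BUFFER", inputs = "zinc")
    ),
    comparator_base = circuit_spec(
      "comparator_base",
      templates = list(template_spec("T_u", "InvadeR_u", concentration_nM = 50)),
      # 1 uM slow reporter mirrors the threshold-titration experiments, so
      # 0-8x threshold ratios activate within the 2 h window
      gates = list(signal_gate("InvadeR_u", toehold = 4, conc = 1))
    )
  )
}

lib_logic_circuits <- function() {
  tet <- "tetracycline"; zn <- "zinc"

  t_reg_tet <- function() template_spec("T_tet", "InvadeR_tet",
                                        operator_id = "tetO")
  t_reg_zn  <- function() template_spec("T_zn", "InvadeR_zn",
                                        operator_id = "smtO")
  t_unreg   <- function(nm = "T_u", tr = "InvadeR_u")
    template_spec(nm, tr, concentration_nM = 25)
  t_not     <- function(op, nm, tr)
    template_spec(nm, tr, operator_id = op, concentration_nM = 350)
  not_gate  <- function(nm, invader)
    gate_spec(nm, "not_rna", invader_names = invader, toehold_nt = 8)
  or_gate   <- function(nm, invader, out, mismatch = FALSE)
    gate_spec(nm, "or_gate", concentration = 5, toehold_nt = 8,
              invader_names = invader, invader_mismatch = mismatch,
              output_name = out)
  and_gate  <- function(invaders, out = "Out_and")
    gate_spec("ANDGate", "and_gate", concentration = 5, toehold_nt = 5,
              clamp_bp = 7, invader_names = invaders, output_name = out)

  not_circuit <- function(name, op, not_tpl, lig) circuit_spec(
    name,
    templates = list(t_unreg(), t_not(op, not_tpl, "NOTGate")),
    tfs = list(if (op == "tetO") lib_tetR() else lib_smtB()),
    gates = list(not_gate("NOTGate", "InvadeR_u"),
                 signal_gate("InvadeR_u", mismatch = TRUE)),
    ligand_names = lig,
    intended_logic = list(label = "NOT", inputs = lig)
  )

  # A IMPLY B: OFF only when A present and B absent. The B-induced branch
  # feeds the reporter through a translator (or directly, in the no-OR
  # variants) with a clean duplex; the constitutive invader carries the
  # engineered reporter mismatch and is sequestered by the A-induced RNA
  # NOT gate.
  imply_circuit <- function(name, a, b, use_or) {
    a_op <- if (a == tet) "tetO" else "smtO"
    b_tpl <- if (b == tet) t_reg_tet() else t_reg_zn()
    b_inv <- if (b == tet) "InvadeR_tet" else "InvadeR_zn"
    tfs <- list(lib_tetR(), lib_smtB())
    gates <- list(not_gate("NOTGate", "InvadeR_u"))
    if (use_or) {
      gates <- c(gates, list(or_gate("ORGate", b_inv, "Out_or"),
                             signal_gate(c("InvadeR_u", "Out_or"),
                                         mismatch = c(TRUE, FALSE))))
    } else {
      gates <- c(gates, list(signal_gate(c("InvadeR_u", b_inv),
                                         mismatch = c(TRUE, FALSE))))
    }
    circuit_spec(
      name,
      templates = list(t_unreg(), t_not(a_op, "T_not", "NOTGate"), b_tpl),
      tfs = tfs, gates = gates,
      ligand_names = c(tet, zn),
      intended_logic = list(label = "IMPLY", inputs = c(a, b))
    )
  }

  # A NIMPLY B: ON only when A present and B absent. An AND gate pairs the
  # A-induced invader with a constitutive invader that the B-induced RNA NOT
  # gate sequesters.
  nimply_circuit <- function(name, a, b) {
    a_tpl <- if (a == tet) t_reg_tet() else t_reg_zn()
    a_inv <- if (a == tet) "InvadeR_tet" else "InvadeR_zn"
    b_op <- if (b == tet) "tetO" else "smtO"
    circuit_spec(
      name,
      templates = list(t_unreg(), a_tpl, t_not(b_op, "T_not", "NOTGate")),
      tfs = list(lib_tetR(), lib_smtB()),
      gates = list(not_gate("NOTGate", "InvadeR_u"),
                   and_gate(c("InvadeR_u", a_inv)),
                   signal_gate("Out_and")),
      ligand_names = c(tet, zn),
      intended_logic = list(label = "NIMPLY", inputs = c(a, b))
    )
  }

  list(
    NOT_tet = not_circuit("NOT_tet", "tetO", "T_not_tet", tet),
    NOT_zn  = not_circuit("NOT_zn", "smtO", "T_not_zn", zn),
    OR_tet_zn = circuit_spec(
      "OR_tet_zn",
      templates = list(t_reg_tet(), t_reg_zn()),
      tfs = list(lib_tetR(), lib_smtB()),
      gates = list(or_gate("ORGate1", "InvadeR_tet", "Out1"),
                   or_gate("ORGate2", "InvadeR_zn", "Out2"),
                   signal_gate(c("Out1", "Out2"))),
      ligand_names = c(tet, zn),
      intended_logic = list(label = "OR", inputs = c(tet, zn))
    ),
    AND_tet_zn = circuit_spec(
      "AND_tet_zn",
      templates = list(t_reg_tet(), t_reg_zn()),
      tfs = list(lib_tetR(), lib_smtB()),
      gates = list(and_gate(c("InvadeR_tet", "InvadeR_zn")),
                   signal_gate("Out_and")),
      ligand_names = c(tet, zn),
      intended_logic = list(label = "AND", inputs = c(tet, zn))
    ),
    NOR_tet_zn = circuit_spec(
      "NOR_tet_zn",
      templates = list(t_unreg(), t_not("tetO", "T_not_tet", "NOTGate_tet"),
                       t_not("smtO", "T_not_zn", "NOTGate_zn")),
      tfs = list(lib_tetR(), lib_smtB()),
      gates = list(not_gate("NOTGate_tet", "InvadeR_u"),
                   not_gate("NOTGate_zn", "InvadeR_u"),
                   signal_gate("InvadeR_u", mismatch = TRUE)),
      ligand_names = c(tet, zn),
      intended_logic = list(label = "NOR", inputs = c(tet, zn))
    ),
    NAND_tet_zn = circuit_spec(
      "NAND_tet_zn",
      templates = list(t_unreg("T_u1", "InvadeR_u1"),
                       t_unreg("T_u2", "InvadeR_u2"),
                       t_not("tetO", "T_not_tet", "NOTGate_tet"),
                       t_not("smtO", "T_not_zn", "NOTGate_zn")),
      tfs = list(lib_tetR(), lib_smtB()),
      gates = list(not_gate("NOTGate_tet", "InvadeR_u1"),
                   not_gate("NOTGate_zn", "InvadeR_u2"),
                   # thermodynamic drivers on the NOT gates bias sequestration
                   # over translation; modeled as the mismatch penalty on the
                   # competing translator path
                   or_gate("ORGate1", "InvadeR_u1", "Out1", mismatch = TRUE),
                   or_gate("ORGate2", "InvadeR_u2", "Out2", mismatch = TRUE),
                   signal_gate(c("Out1", "Out2"))),
      ligand_names = c(tet, zn),
      intended_logic = list(label = "NAND", inputs = c(tet, zn))
    ),
    IMPLY_zn_tet = imply_circuit("IMPLY_zn_tet", zn, tet, use_or = TRUE),
    IMPLY_tet_zn = imply_circuit("IMPLY_tet_zn", tet, zn, use_or = TRUE),
    IMPLY_zn_tet_noOR = imply_circuit("IMPLY_zn_tet_noOR", zn, tet,
                                      use_or = FALSE),
    IMPLY_tet_zn_noOR = imply_circuit("IMPLY_tet_zn_noOR", tet, zn,
                                      use_or = FALSE),
    NIMPLY_tet_zn = nimply_circuit("NIMPLY_tet_zn", tet, zn),
    NIMPLY_zn_tet = nimply_circuit("NIMPLY_zn_tet", zn, tet)
  )
}

#' The packaged circuit library
#'
#' `circuit_library()` summarizes every packaged circuit;
#' `logic_circuit_names()` gives the names of the twelve logic circuits;
#' `library_circuit(name)` retrieves one circuit.
#'
#' @return `circuit_library()` returns a data.frame with columns `name`,
#'   `logic` (intended-logic label or NA) and `is_logic`;
#'   `library_circuit()` returns a [circuit_spec()].
#' @examples
#' circuit_library()
#' library_circuit("AND_tet_zn")
#' @export
circuit_library <- function() {
  logic <- lib_logic_circuits()
  sensors <- lib_sensor_circuits()
  all <- c(logic, sensors)
  data.frame(
    name = names(all),
    logic = vapply(all, function(s)
      if (is.null(s$intended_logic)) NA_character_ else s$intended_logic$label,
      character(1)),
    is_logic = names(all) %in% names(logic),
    row.names = NULL
  )
}

#' @rdname circuit_library
#' @export
logic_circuit_names <- function() names(lib_logic_circuits())

#' @rdname circuit_library
#' @param name A circuit name from `circuit_library()$name`.
#' @export
library_circuit <- function(name) {
  all <- c(lib_logic_circuits(), lib_sensor_circuits())
  if (!name %in% names(all))
    stop("unknown circuit '", name, "'; available: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  all[[name]]
}
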