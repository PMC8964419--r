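test_that("constructors enforce field invariants with field paths", {
  expect_error(ligand_input("aTc", -1), "concentration")
  expect_error(tf_spec("TetR", "tetO", -1, "aTc"), "dimer_total")
  expect_error(tf_spec("TetR", "tetO", 5, "aTc", ligand_stoichiometry = 3),
               "stoichiometry")
  expect_error(template_spec("T", "I", concentration_nM = -5), "concentration")
  expect_error(template_spec("T", "I", tx_efficiency_factor = 0),
               "tx_efficiency")
  expect_error(gate_spec("G", "wobble", 5, invader_names = "I"),
               "unknown gate kind 'wobble'")
  expect_error(gate_spec("G", "and_gate", 5, invader_names = "I",
                         output_name = "O"), "exactly 2")
  expect_error(gate_spec("G", "signal", 5, invader_names = "I",
                         toehold_nt = 0), "toehold_nt")
  expect_error(gate_spec("G", "not_rna", concentration = 5,
                         invader_names = "I"), "produced by a template")
})

test_that("template concentrations are normalized from nM to uM", {
  tm <- template_spec("T", "I", concentration_nM = 50)
  expect_equal(tm$concentration_uM, 0.05)
})

test_that("the library holds 12 logic circuits implementing 7 functions", {
  lib <- circuit_library()
  expect_equal(sum(lib$is_logic), 12)
  expect_length(logic_circuit_names(), 12)
  labels <- lib$logic[lib$is_logic]
  expect_setequal(unique(labels),
                  c("NOT", "OR", "AND", "NOR", "NAND", "IMPLY", "NIMPLY"))
  expect_length(unique(labels), 7)
})

test_that("every library circuit validates cleanly and is well-formed", {
  for (nm in circuit_library()$name) {
    ckt <- library_circuit(nm)
    expect_identical(validate_circuit(ckt), character(0), label = nm)
    n_signal <- sum(vapply(ckt$gates, function(g) g$kind == "signal",
                           logical(1)))
    expect_equal(n_signal, 1, label = paste(nm, "signal gates"))
  }
})

test_that("unknown library names list the available circuits", {
  expect_error(library_circuit("XOR"), "available:.*AND_tet_zn")
})

test_that("the NOR circuit layers two RNA NOT gates on one shared invader", {
  nor <- library_circuit("NOR_tet_zn")
  nots <- Filter(function(g) g$kind == "not_rna", nor$gates)
  expect_length(nots, 2)
  expect_equal(unique(unlist(lapply(nots, `[[`, "invader_names"))),
               "InvadeR_u")
  regulated <- Filter(function(tm) !is.null(tm$operator_id), nor$templates)
  expect_length(regulated, 2)
})

test_that("the NAND circuit has 4 templates and 2 translator gates", {
  nand <- library_circuit("NAND_tet_zn")
  expect_length(nand$templates, 4)
  unreg <- Filter(function(tm) is.null(tm$operator_id), nand$templates)
  expect_length(unreg, 2)
  ors <- Filter(function(g) g$kind == "or_gate", nand$gates)
  expect_length(ors, 2)
})

test_that("serialization round-trips every library circuit", {
  for (nm in circuit_library()$name) {
    ckt <- library_circuit(nm)
    back <- parse_circuit(serialize_circuit(ckt))
    expect_equal(back, ckt, label = nm)
  }
})

test_that("YAML documents parse, normalize units and resolve references", {
  minimal <- "
name: mini
ligand_names: []
templates:
  - {name: T1, transcript_name: I1, concentration_nM: 50}
tfs: []
gates:
  - {name: SG, kind: signal, concentration: 5, toehold_nt: 8,
     invader_names: [I1]}
"
  spec <- parse_circuit(minimal)
  expect_length(spec$tfs, 0)
  expect_equal(spec$templates[[1]]$concentration_uM, 0.05)

  two_input_and <- "
name: tet_and_zinc
ligand_names: [tetracycline, zinc]
templates:
  - {name: T_tet, transcript_name: I_tet, operator_id: tetO,
     concentration_nM: 50}
  - {name: T_zn, transcript_name: I_zn, operator_id: smtO,
     concentration_nM: 50}
tfs:
  - {name: TetR, operator_id: tetO, dimer_total: 5,
     ligand_name: tetracycline, ligand_stoichiometry: 1}
  - {name: SmtB, operator_id: smtO, dimer_total: 5, ligand_name: zinc,
     ligand_stoichiometry: 1}
gates:
  - {name: AG, kind: and_gate, concentration: 5, toehold_nt: 5, clamp_bp: 7,
     invader_names: [I_tet, I_zn], output_name: Out}
  - {name: SG, kind: signal, concentration: 5, toehold_nt: 8,
     invader_names: [Out]}
"
  spec <- parse_circuit(two_input_and)
  expect_length(spec$tfs, 2)
  kinds <- vapply(spec$gates, `[[`, "", "kind")
  expect_equal(sort(kinds), c("and_gate", "signal"))

  dangling <- sub("invader_names: \\[I1\\]", "invader_names: [I_missing]",
                  minimal)
  expect_error(parse_circuit(dangling), "I_missing")
})

test_that("condition enumeration is canonical binary order", {
  two <- enumerate_conditions(library_circuit("AND_tet_zn"), on_level = 10)
  expect_equal(nrow(two), 4)
  expect_equal(two$tetracycline, c(0, 0, 10, 10))
  expect_equal(two$zinc, c(0, 10, 0, 10))
  one <- enumerate_conditions(library_circuit("aTc_sensor"), on_level = 2)
  expect_equal(one$aTc, c(0, 2))
  none <- enumerate_conditions(library_circuit("unregulated_sensor"), 1)
  expect_equal(nrow(none), 1)
  expect_equal(ncol(none), 0)
  expect_error(enumerate_conditions(library_circuit("aTc_sensor"), 0),
               "on_level")
})

test_that("validation reports dangling and duplicate references", {
  ckt <- library_circuit("unregulated_sensor")
  ckt$gates[[1]]$invader_names <- "nope"
  expect_match(validate_circuit(ckt), "invader 'nope'", all = FALSE)

  ckt2 <- library_circuit("aTc_sensor")
  ckt2$tfs <- list()
  expect_match(validate_circuit(ckt2), "operator 'tetO'", all = FALSE)

  ckt3 <- library_circuit("OR_tet_zn")
  ckt3$gates[[2]]$output_name <- "Out1"
  expect_match(validate_circuit(ckt3), "more than one", all = FALSE)
})
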