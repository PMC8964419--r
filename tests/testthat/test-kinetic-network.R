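test_that("toehold rate law saturates and spans decades", {
  p <- default_params
  expect_equal(toehold_rate(p$n_sat, p), p$k_tmsd_max)
  expect_equal(toehold_rate(10, p), p$k_tmsd_max)
  # the 8-nt threshold gate outpaces the 4-nt signal gate 100-fold
  expect_equal(toehold_rate(8, p) / toehold_rate(4, p), 100)
  p0 <- kinetic_params(decade_per_nt = 0)
  expect_equal(toehold_rate(4, p0), p0$k_tmsd_max)
  expect_error(toehold_rate(0, p), "toehold_nt")
})

test_that("toehold rate is monotone non-decreasing for random parameters", {
  set.seed(42)
  for (i in 1:20) {
    p <- kinetic_params(k_tmsd_max = stats::runif(1, 1, 100),
                        decade_per_nt = stats::runif(1, 0, 2),
                        n_sat = sample(1:10, 1))
    rates <- toehold_rate(1:12, p)
    expect_true(all(diff(rates) >= 0))
  }
})

test_that("the minimal unregulated sensor compiles to two reactions", {
  net <- compile_network(library_circuit("unregulated_sensor"))
  expect_length(net$reactions, 2)
  expect_setequal(sub(":.*", "", net$labels), c("transcription", "signal_tmsd"))
  vecs <- conservation_vectors(net)
  expect_true("fluor:SignalGate" %in% names(vecs))
  expect_true("template:T_u" %in% names(vecs))
})

test_that("repressed sensor matches the TF-operator binding quadratic", {
  p <- default_params
  ckt <- library_circuit("aTc_sensor")
  net <- compile_network(ckt, p, condition = c(aTc = 0))
  sim <- simulate_network(net, solver_settings(t_grid = seq(0, 120, 2)))
  Tt <- 0.05; Ft <- 5; K <- p$k_off_op / p$k_on_op
  b <- Tt + Ft + K
  bound_eq <- (b - sqrt(b^2 - 4 * Tt * Ft)) / 2
  bound_sim <- unname(sim$conc[nrow(sim$conc), "template_T_tet_bound"])
  expect_equal(bound_sim, bound_eq, tolerance = 1e-4)
  expect_gt(bound_sim / Tt, 0.99)
})

test_that("AND circuits carry one reversible exchange and one labeled leak", {
  net <- compile_network(library_circuit("AND_tet_zn"))
  expect_equal(sum(net$labels == "and_capture:ANDGate"), 1)
  expect_equal(sum(net$labels == "and_capture_rev:ANDGate"), 1)
  leaks <- net$labels[startsWith(net$labels, "and_leak")]
  expect_equal(leaks, "and_leak:ANDGate")
  # 7-bp clamp suppresses the leak by the configured decade law
  k_leak <- net$k[net$labels == "and_leak:ANDGate"]
  expect_equal(k_leak, default_params$clamp_leak0 *
                 10^(-default_params$clamp_decay_per_bp * 7))
})

test_that("conservation vectors are exact left-null vectors for all circuits", {
  for (nm in circuit_library()$name) {
    net <- compile_network(library_circuit(nm))
    S <- stoichiometry_matrix(net)
    vecs <- conservation_vectors(net)
    expect_gt(length(vecs), 0)
    for (m in names(vecs))
      expect_lt(max(abs(drop(vecs[[m]] %*% S))), 1e-12,
                label = paste(nm, m))
  }
})

test_that("DNA totals are catalytic in transcription and transcripts are only produced", {
  for (nm in c("NAND_tet_zn", "NIMPLY_zn_tet", "OR_tet_zn")) {
    net <- compile_network(library_circuit(nm))
    S <- stoichiometry_matrix(net)
    tx_cols <- startsWith(net$labels, "transcription")
    # templates unchanged by every reaction (transcription is catalytic)
    tpl <- net$species$role %in% c("template", "template_TF_complex")
    expect_true(all(S[tpl, tx_cols] == 0))
    # transcript species gain mass only through transcription (or release
    # from the reversible AND-gate capture they previously entered)
    src_cols <- tx_cols | startsWith(net$labels, "and_capture_rev")
    tr <- net$species$role %in% c("transcript", "rna_gate")
    expect_true(all(S[tr, !src_cols] <= 0))
    expect_true(all(S[tr, tx_cols] >= 0))
  }
})

test_that("ideal parameters reduce every gate to ideal irreversible TMSD", {
  p <- kinetic_params(mismatch_penalty = 1, clamp_leak0 = 0,
                      structure_penalty = 1)
  for (nm in c("NOT_tet", "NAND_tet_zn", "AND_tet_zn", "IMPLY_zn_tet")) {
    net <- compile_network(library_circuit(nm), p)
    leak <- net$k[startsWith(net$labels, "and_leak")]
    expect_true(all(leak == 0), label = nm)
    tmsd <- grepl("^(signal|or)_tmsd|^sequestration|^threshold_tmsd",
                  net$labels)
    # every displacement runs at the bare toehold-law rate (a power of 10
    # times the saturated constant)
    decades <- log10(p$k_tmsd_max / net$k[tmsd])
    expect_equal(decades, round(decades), tolerance = 1e-12, label = nm)
  }
})

test_that("parameter files round-trip through JSON with units metadata", {
  p <- kinetic_params(k_tx = 1.5, mismatch_penalty = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$units$concentration, "uM")
  expect_equal(read_params(path), p)
})

test_that("network reaction tables export reactants, products and rates", {
  net <- compile_network(library_circuit("unregulated_sensor"))
  df <- network_reactions(net)
  expect_equal(nrow(df), 2)
  expect_true(any(grepl("fluor_free", df$products)))
  path <- withr::local_tempfile(fileext = ".csv")
  network_reactions(net, path)
  expect_equal(nrow(utils::read.csv(path)), 2)
})
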