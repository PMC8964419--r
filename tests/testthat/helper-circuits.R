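# Shared fixtures: calibrated defaults and a coarse solver grid that keeps
# multi-circuit sweeps fast without visible loss of endpoint accuracy.
default_params <- kinetic_params()

coarse_grid <- function(t_end = 120, by = 2)
  solver_settings(t_grid = seq(0, t_end, by = by))

endpoint_mef <- function(circuit, params = default_params, condition = NULL,
                         t_end = 120, by = 2) {
  sim <- simulate_network(compile_network(circuit, params, condition),
                          coarse_grid(t_end, by))
  tr <- mef_trace(sim)
  tr$mef[length(tr$mef)]
}

# A + B -> C at unit rate, as a direct mass-action construction
bimolecular_net <- function(a0, b0, k = 1) {
  mass_action_network(
    data.frame(name = c("A", "B", "C"), init = c(a0, b0, 0)),
    list(list(reactants = c(A = 1, B = 1), products = c(C = 1), k = k,
              label = "assoc")))
}
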