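# Shared fixtures: small gate sequences, decays and phantoms built in code.

gates30 <- gate_sequence()                       # 500 ps / 200 ps / 30 gates
gates10 <- gate_sequence(n_gates = 10L)

# amplitude rate giving a target peak gate count for a single exponential
peak_rate <- function(peak, tau, w = 0.5) peak / (tau * (1 - exp(-w / tau)))

# small widefield config used across tests (fast)
small_wf <- function(...) {
  widefield_config(n_row = 32L, n_col = 32L, tumor_radius = 7, ...)
}

# coarse tomography phantom for fast tests (2 mm voxels)
coarse_tomo <- function() generate_tomo_phantom(tomo_config(voxel_mm = 2))

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)), tol)
}
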