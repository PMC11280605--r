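# Shared fixtures, built in code.

brain_scene <- function(n = 32L) build_phantom("simulated_brain",
                                               shape = c(n, n))

# A single-compartment water-only scene on a small grid, handy for exact
# symmetry checks.
water_scene <- function(n = 16L, depth = 0.8, gamma = 200^2, s0 = 1) {
  build_phantom(list(
    shape = c(n, n),
    grid = list(offsets_hz = seq(-1250, 1250, by = 50), ref_index = 1,
                water_offset_hz = 0, pool_offsets_hz = numeric(0)),
    phase_coef = c(0.2, 0.5, -0.4),
    compartments = list(
      list(name = "water", geometry = list(type = "background"), s0 = s0,
           zspec = list(a = depth * gamma, gamma = gamma)))))
}

# Reference LG parameters used across fitting tests (the brain CEST insert).
ref_lg_params <- function() {
  zspec_params(a = 0.9 * 200^2, gamma = 200^2,
               pools = data.frame(center_hz = 450, b = 0.10, sigma = 120),
               model = "LG")
}

grid51 <- function() freq_grid(seq(-1250, 1250, by = 50), ref_index = 1,
                               water_offset_hz = 0, pool_offsets_hz = 450)
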