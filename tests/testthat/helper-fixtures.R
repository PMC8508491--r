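## Deterministic fixtures built in code.

# Collinear equidistant protonatable sites along x (spacing in Angstrom).
collinear_sites <- function(n, spacing = 5) {
  site_table(seq_len(n), rep("K", n), spacing * (seq_len(n) - 1),
             rep(0, n), rep(0, n))
}

# Tiny fixed geometry with a known type mix, for energy bookkeeping tests.
tiny_sites <- function() {
  site_table(1:6, c("R", "K", "K", "H", "R", "N-terminus"),
             x = c(0, 10, 20, 0, 10, 20),
             y = c(0, 0, 0, 15, 15, 15),
             z = c(0, 0, 0, 0, 0, 0))
}

# Charge-series assignment table sampled exactly from a Gaussian envelope.
gaussian_assignments <- function(mass = 13708.2, charges = 5:9, amp = 100,
                                 center_charge = 7, sigma = 250) {
  mz <- expected_mz(mass, charges)
  mu <- expected_mz(mass, center_charge)
  data.frame(species = "complex", charge = charges, expected_mz = mz,
             matched_mz = mz, height = amp * exp(-(mz - mu)^2 / (2 * sigma^2)))
}

# Envelope-fit stub with a given apex intensity.
envelope_stub <- function(intensity, species = "x") {
  structure(list(species = species, apex_intensity = intensity,
                 apex_mz = 1000, sigma = 1, mean_charge = 7,
                 points_used = 3L, degenerate = FALSE,
                 absent = intensity == 0),
            class = "envelope_fit")
}

# Default RNase-S-like species definitions used by pipeline tests.
default_species_defs <- function() lapply(default_species_plan(), `[[`, "def")
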