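# Small fixtures shared across test files. Everything is generated in
# code; transport fixtures use short-range beams on coarse lattices so
# single tests stay in the sub-second range.

tiny_phantom <- function(dims_cm = c(10, 6, 6), voxel_mm = 4) {
  build_rect_phantom(dims_cm, voxel_mm)
}

tiny_beam <- function(energy = 80, n = 2000, shift = c(0, 0),
                      width = 0.8, mode = "pencil") {
  beam_spec(energy, shift_cm = shift, width_cm = width, mode = mode,
            n_protons = n)
}

fast_cfg <- function(...) transport_config(...)

# independent transcription of the Bethe-Bloch stopping power used as a
# cross-check oracle (coded from the standard formula, separately from
# the package implementation)
oracle_bethe_bloch <- function(E_mev, rho, z_over_a, I_ev) {
  me <- 0.51099895; mp <- 938.2720882; K <- 0.307075
  g <- E_mev / mp + 1
  b2 <- 1 - g^-2
  bg2 <- b2 * g^2
  s <- me / mp
  tmax <- 2 * me * bg2 / (1 + 2 * g * s + s^2)
  I <- I_ev * 1e-6
  K * z_over_a * rho / b2 * (0.5 * log(2 * me * bg2 * tmax / I^2) - b2)
}

# independent transcription of the Highland multiple-scattering sigma
oracle_highland <- function(E_mev, x_cm, X0_cm) {
  mp <- 938.2720882
  pc <- sqrt(E_mev * (E_mev + 2 * mp))
  beta <- pc / (E_mev + mp)
  13.6 / (beta * pc) * sqrt(x_cm / X0_cm) *
    (1 + 0.038 * log(x_cm / X0_cm))
}

# tiny family-A-like dataset for reconstruction tests (coarse lattice,
# low statistics, deterministic under the caller's seed)
tiny_dataset <- function(n = 8, family = "A", n_protons = 1500) {
  ov <- if (family %in% c("A", "B"))
    list(dims_cm = c(12, 8, 8), voxel_mm = 4, energy = c(70, 110))
  else
    list(radius_cm = 6, height_cm = 12, voxel_mm = 10,
         energy = c(70, 110), shift_y = c(-2, 2), shift_z = c(-2, 2),
         width = c(1, 2))
  generate_dataset(family, n, n_protons, overrides = ov)
}
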