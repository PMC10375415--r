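#' Beam specification
#'
#' A proton source entering the phantom along +x: mono-energetic, with a
#' uniform circular entry spot of diameter `width_cm` centred at the
#' transverse shift `shift_cm = (y, z)` relative to the phantom's
#' transverse center. `"wobbler"` mode additionally rotates the spot
#' center on a circle of radius `wobble_radius_cm` with a uniform phase
#' per proton, emulating a beam swept transversely during irradiation.
#'
#' @param energy_mev Kinetic energy, MeV.
#' @param shift_cm Length-2 transverse shift (y, z), cm.
#' @param width_cm Beam spot diameter, cm.
#' @param mode `"pencil"` or `"wobbler"`.
#' @param n_protons Number of primaries.
#' @param wobble_radius_cm Wobble circle radius; default 1.5x the beam
#'   radius (0 degenerates to a pencil beam).
#' @return Object of class `beam_spec`.
#' @export
beam_spec <- function(energy_mev, shift_cm = c(0, 0), width_cm = 1,
                      mode = c("pencil", "wobbler"), n_protons = 1e5,
                      wobble_radius_cm = NULL) {
  mode <- match.arg(mode)
  stopifnot(energy_mev > 0, width_cm > 0, n_protons >= 0,
            length(shift_cm) == 2L)
  if (is.null(wobble_radius_cm))
    wobble_radius_cm <- if (mode == "wobbler") 0.75 * width_cm else 0
  structure(list(energy_mev = energy_mev, shift_cm = as.numeric(shift_cm),
                 width_cm = width_cm, mode = mode,
                 n_protons = as.integer(n_protons),
                 wobble_radius_cm = wobble_radius_cm),
            class = "beam_spec")
}

#' Sample initial proton states for a beam
#'
#' Entry points on the upstream (x = min) phantom face, direction +x.
#' Pencil: uniform on the beam disc; wobbler: the disc center is first
#' displaced by the wobble radius at a uniform phase.
#'
#' @param b A `beam_spec`.
#' @param p A `voxel_phantom` (fixes the upstream face and the transverse
#'   center).
#' @param n Number of protons (defaults to `b$n_protons`).
#' @return data.frame: `x`, `y`, `z` (mm), `dx`, `dy`, `dz`, `energy`.
#' @export
sample_initial_proton <- function(b, p, n = b$n_protons) {
  stopifnot(inherits(b, "beam_spec"), inherits(p, "voxel_phantom"))
  ext <- phantom_extent_mm(p)
  cy <- p$origin_mm[2] + ext[2] / 2 + b$shift_cm[1] * 10
  cz <- p$origin_mm[3] + ext[3] / 2 + b$shift_cm[2] * 10
  r <- b$width_cm * 10 / 2
  u <- stats::runif(n); v <- stats::runif(n)
  rad <- r * sqrt(u); ang <- 2 * pi * v
  y <- cy + rad * cos(ang); z <- cz + rad * sin(ang)
  if (b$mode == "wobbler" && b$wobble_radius_cm > 0) {
    ph <- stats::runif(n, 0, 2 * pi)
    y <- y + b$wobble_radius_cm * 10 * cos(ph)
    z <- z + b$wobble_radius_cm * 10 * sin(ph)
  }
  data.frame(x = p$origin_mm[1] + 1e-9, y = y, z = z,
             dx = 1, dy = 0, dz = 0, energy = b$energy_mev)
}
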