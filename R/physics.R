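#' Linear stopping power of protons (Bethe-Bloch)
#'
#' Electronic stopping power -dE/dx in MeV/cm for a proton of kinetic
#' energy `E` in a registry material, using the standard Bethe-Bloch form
#' with the beta^2 correction and the full maximum-energy-transfer term,
#' no density-effect or shell corrections (they are negligible above a few
#' MeV, the regime the transport operates in).
#'
#' @param E Kinetic energy in MeV (vectorized).
#' @param material Material name or registry row.
#' @return Stopping power, MeV/cm; scales linearly with mass density.
#' @export
stopping_power <- function(E, material) {
  if (any(!is.finite(E)) || any(E <= 0))
    stop("kinetic energy must be positive and finite", call. = FALSE)
  m <- get_material(material)
  pc <- physics_constants()
  gamma <- 1 + E / pc$mp_mev
  beta2 <- 1 - 1 / gamma^2
  bg2 <- beta2 * gamma^2
  r <- pc$me_mev / pc$mp_mev
  tmax <- 2 * pc$me_mev * bg2 / (1 + 2 * gamma * r + r^2)
  I_mev <- m$I * 1e-6
  arg <- 2 * pc$me_mev * bg2 * tmax / I_mev^2
  bracket <- 0.5 * log(arg) - beta2
  bracket <- pmax(bracket, 1e-6)  # guard far below the validity range
  pc$K_bb * (m$Z / m$A) * m$density / beta2 * bracket
}

#' CSDA range of a proton
#'
#' Continuous-slowing-down range in cm: the integral of 1/S(E) from a
#' low-energy cutoff up to the initial energy `E0`. The sub-cutoff residual
#' range (tens of micrometres at the 1 MeV default) is neglected.
#'
#' @param E0 Initial kinetic energy, MeV (vectorized).
#' @param material Material name or registry row.
#' @param cutoff Lower integration limit, MeV.
#' @return Range in cm.
#' @export
csda_range <- function(E0, material, cutoff = 1.0) {
  if (any(!is.finite(E0)) || any(E0 <= 0))
    stop("initial energy must be positive and finite", call. = FALSE)
  m <- get_material(material)
  vapply(E0, function(e) {
    if (e <= cutoff) return(0)
    out <- stats::integrate(function(x) 1 / stopping_power(x, m),
                            lower = cutoff, upper = e,
                            rel.tol = 1e-8, subdivisions = 400L)
    if (out$message != "OK")
      stop("range integration failed: ", out$message, call. = FALSE)
    out$value
  }, numeric(1))
}

#' Rutherford differential cross-section (relative)
#'
#' Hard single-scatter angular weight (Z e^2 / 4E)^2 / sin^4(theta), as
#' used by the forward model; the `"sin4halftheta"` convention replaces the
#' denominator with the classical sin^4(theta/2). Units are fm^2/sr up to
#' the overall normalization, which the transport model calibrates
#' separately, so values should be read as relative.
#'
#' @param E Proton kinetic energy, MeV.
#' @param Z Atomic number of the scattering material.
#' @param theta Polar scattering angle, rad, in (0, pi].
#' @param convention `"sin4theta"` (default) or `"sin4halftheta"`.
#' @return Relative differential cross-section (vectorized over any
#'   argument).
#' @export
rutherford_dcs <- function(E, Z, theta,
                           convention = c("sin4theta", "sin4halftheta")) {
  convention <- match.arg(convention)
  if (any(E <= 0)) stop("E must be positive", call. = FALSE)
  if (any(theta <= 0) || any(theta > pi))
    stop("theta must lie in (0, pi]; theta = 0 is singular", call. = FALSE)
  pc <- physics_constants()
  s <- if (convention == "sin4theta") sin(theta) else sin(theta / 2)
  if (any(s == 0))
    stop("theta = pi is singular under the sin^4(theta) convention",
         call. = FALSE)
  (Z * pc$e2_mevfm / (4 * E))^2 / s^4
}

# Angular support of the hard-scatter density: the printed sin^4(theta)
# form diverges at both 0 and pi, so its support is truncated
# symmetrically; the classical form only diverges at 0.
scatter_support <- function(theta_min, convention) {
  if (!is.finite(theta_min) || theta_min <= 0 || theta_min >= pi / 2)
    stop("theta_min must lie in (0, pi/2)", call. = FALSE)
  if (convention == "sin4theta") c(theta_min, pi - theta_min)
  else c(theta_min, pi)
}

# Tabulated CDF of theta under p(theta) ~ sin(theta) * dcs(theta) on the
# truncated support; used both for inverse-CDF sampling and for the
# solid-angle normalization of the expected-value current estimator.
scatter_theta_table <- function(theta_min, convention = "sin4theta",
                                n = 4096L) {
  sup <- scatter_support(theta_min, convention)
  th <- seq(sup[1], sup[2], length.out = n)
  s <- if (convention == "sin4theta") sin(th) else sin(th / 2)
  f <- sin(th) / s^4
  cdf <- cumsum(c(0, (f[-1] + f[-n]) / 2 * diff(th)))
  norm_omega <- 2 * pi * cdf[n]   # integral of dcs-shape over solid angle
  list(theta = th, cdf = cdf / cdf[n], pdf = f / cdf[n],
       norm_omega = norm_omega, support = sup)
}

#' Sample hard-scatter events
#'
#' Draws polar angles from the Rutherford angular density restricted to
#' angles above `theta_min` (inverse-CDF on a dense tabulation) and
#' azimuths uniformly on `[0, 2pi)`. Under the `"sin4theta"` convention the
#' support is `[theta_min, pi - theta_min]`; under `"sin4halftheta"` it is
#' `[theta_min, pi]`. The angular shape does not depend on `E` or on the
#' material; both are accepted for interface symmetry with the rest of the
#' physics layer.
#'
#' @param n Number of events.
#' @param E Proton kinetic energy, MeV (shape-irrelevant).
#' @param material Material name or registry row (shape-irrelevant).
#' @param theta_min Minimum polar angle, rad, in (0, pi/2).
#' @param convention See [rutherford_dcs()].
#' @return data.frame with columns `theta`, `phi`.
#' @export
sample_hard_scatter <- function(n, E = 200, material = "water",
                                theta_min = 2 * pi / 180,
                                convention = c("sin4theta",
                                               "sin4halftheta")) {
  convention <- match.arg(convention)
  get_material(material)
  if (any(E <= 0)) stop("E must be positive", call. = FALSE)
  tab <- scatter_theta_table(theta_min, convention)
  u <- stats::runif(n)
  theta <- stats::approx(tab$cdf, tab$theta, xout = u, ties = "ordered")$y
  phi <- stats::runif(n, 0, 2 * pi)
  data.frame(theta = theta, phi = phi)
}

#' Radiation length of a registry material
#'
#' Tsai-style closed-form estimate from the effective (Z, A):
#' X0 = 716.4 A / (Z (Z + 1) ln(287 / sqrt(Z))) g/cm^2.
#'
#' @param material Material name or registry row.
#' @return List with `gcm2` (g/cm^2) and `cm` (divided by density).
#' @export
radiation_length <- function(material) {
  m <- get_material(material)
  x0 <- 716.4 * m$A / (m$Z * (m$Z + 1) * log(287 / sqrt(m$Z)))
  list(gcm2 = x0, cm = x0 / m$density)
}

#' Highland multiple-scattering angle
#'
#' Standard deviation (rad) of the projected multiple-Coulomb-scattering
#' angle accumulated over a path `step_cm` in a material, from the Highland
#' parameterization 13.6 MeV / (beta c p) sqrt(x/X0) (1 + 0.038 ln(x/X0)),
#' with the logarithmic factor floored at 0.1 for very thin steps.
#'
#' @param E Proton kinetic energy, MeV (vectorized).
#' @param step_cm Path length, cm.
#' @param material Material name or registry row.
#' @return Projected scattering sigma, rad.
#' @export
highland_sigma <- function(E, step_cm, material) {
  if (any(step_cm <= 0)) stop("step must be positive", call. = FALSE)
  if (any(E <= 0)) stop("E must be positive", call. = FALSE)
  m <- get_material(material)
  pc <- physics_constants()
  x0 <- radiation_length(m)$cm
  pcc <- sqrt(E * (E + 2 * pc$mp_mev))        # momentum * c, MeV
  beta <- pcc / (E + pc$mp_mev)
  t <- step_cm / x0
  corr <- pmax(1 + 0.038 * log(t), 0.1)
  13.6 / (beta * pcc) * sqrt(t) * corr
}

#' Calibrate the hard-scatter normalization constant
#'
#' The macroscopic hard-scatter cross-section is modelled as
#' Sigma(E, m) = C rho Z^2 / A / E^2 per cm. `C` is fixed once so that a
#' proton of `E_ref` MeV traversing `depth_cm` of water undergoes at least
#' one hard scatter with probability `p_target` (default 0.5%), with the
#' energy loss along the path taken from the CSDA slowing-down curve.
#'
#' @param p_target Target probability of >= 1 hard scatter.
#' @param E_ref Reference beam energy, MeV.
#' @param depth_cm Reference water depth, cm.
#' @param cutoff Transport cutoff energy, MeV.
#' @return The scalar constant C (cm^-1 MeV^2 per (g/cm^3 Z^2/A)).
#' @export
calibrate_hard_scatter <- function(p_target = 0.005, E_ref = 200,
                                   depth_cm = 20, cutoff = 1.0) {
  stopifnot(p_target > 0, p_target < 1)
  w <- get_material("water")
  # E after depth_cm of water (or cutoff if the proton stops earlier)
  rng <- csda_range(E_ref, w, cutoff = cutoff)
  e_exit <- if (rng <= depth_cm) cutoff else {
    stats::uniroot(function(e) rng - csda_range(e, w, cutoff = cutoff) -
                     depth_cm,
                   interval = c(cutoff, E_ref), tol = 1e-6)$root
  }
  # integral of E^-2 dx = integral of E^-2 / S(E) dE over the slab
  out <- stats::integrate(function(e) 1 / (e^2 * stopping_power(e, w)),
                          lower = e_exit, upper = E_ref, rel.tol = 1e-8)
  n_expected_unit <- w$density * w$Z^2 / w$A * out$value
  -log(1 - p_target) / n_expected_unit
}

#' Macroscopic hard-scatter cross-section
#'
#' Sigma(E) = C rho Z^2/A / E^2 in cm^-1 for a material, given the
#' calibration constant from [calibrate_hard_scatter()].
#'
#' @param E Kinetic energy, MeV (vectorized).
#' @param material Material name or registry row.
#' @param C Calibration constant.
#' @return Interaction probability per cm.
#' @export
hard_scatter_sigma <- function(E, material, C) {
  m <- get_material(material)
  C * m$density * m$Z^2 / m$A / E^2
}

# Fraction of kinetic energy retained by a proton elastically scattered by
# theta off a nucleus of mass number A (non-relativistic two-body
# kinematics; exact enough at therapy energies).
scatter_energy_fraction <- function(theta, A) {
  pc <- physics_constants()
  m <- pc$mp_mev
  M <- A * pc$amu_mev
  pmax(1 - 4 * m * M / (m + M)^2 * sin(theta / 2)^2, 0)
}
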