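.protorec_cache <- new.env(parent = emptyenv())

#' Transport configuration
#'
#' Numerical settings of the condensed-history transport. The step length
#' defaults to half the phantom voxel; protons below `cutoff_mev` deposit
#' their remaining energy locally (the Bragg peak). Detector currents use
#' either the expected-value next-event estimator (`"nee"`, default): at
#' every `nee_step`-th transport step of every `nee_stride`-th primary the
#' analytic probability of hard-scattering into each detector -- Rutherford
#' angular density times subtended solid angle times survival over the
#' remaining water-equivalent path -- is tallied; or the analog estimator
#' (`"analog"`): escaped protons are ray-traced to the detector boxes and
#' deposit the plastic-scintillator stopping power over the chord.
#'
#' @param step_mm Step length, mm (`NULL`: voxel/2 at simulation time).
#' @param cutoff_mev Transport cutoff energy, MeV.
#' @param theta_min_deg Lower hard-scatter angle bound, degrees.
#' @param convention Rutherford angle convention, see [rutherford_dcs()].
#' @param hs_p_target Calibration target for the hard-scatter rate, see
#'   [calibrate_hard_scatter()].
#' @param current_estimator `"nee"` or `"analog"`.
#' @param nee_protons Primaries used by the next-event estimator.
#' @param nee_step Transport-step thinning of the next-event tally.
#' @param ms_on,straggle_on,hs_on Toggles for multiple scattering, energy
#'   straggling and hard scattering.
#' @param deflect_every Sub-stepping of direction deflection and energy
#'   straggling, in transport steps (variance-scaled; 2 applies both once
#'   per voxel at the default step of voxel/2).
#' @return Object of class `transport_config`.
#' @export
transport_config <- function(step_mm = NULL, cutoff_mev = 1.0,
                             theta_min_deg = 2,
                             convention = c("sin4theta", "sin4halftheta"),
                             hs_p_target = 0.005,
                             current_estimator = c("nee", "analog"),
                             nee_protons = 250, nee_step = 4,
                             ms_on = TRUE, straggle_on = TRUE,
                             hs_on = TRUE, deflect_every = 2L) {
  convention <- match.arg(convention)
  current_estimator <- match.arg(current_estimator)
  stopifnot(cutoff_mev > 0, theta_min_deg > 0, theta_min_deg < 90,
            deflect_every >= 1)
  structure(list(step_mm = step_mm, cutoff_mev = cutoff_mev,
                 theta_min_deg = theta_min_deg, convention = convention,
                 hs_p_target = hs_p_target,
                 current_estimator = current_estimator,
                 nee_protons = nee_protons, nee_step = nee_step,
                 ms_on = ms_on, straggle_on = straggle_on, hs_on = hs_on,
                 deflect_every = as.integer(deflect_every)),
            class = "transport_config")
}

# Physics lookup tables for the C++ stepper, per registry material, on a
# shared log-energy grid. Cached per (step, theta_min, convention,
# cutoff, hs target).
physics_tables <- function(registry, step_mm, cfg) {
  key <- paste(step_mm, cfg$theta_min_deg, cfg$convention,
               cfg$cutoff_mev, cfg$hs_p_target, cfg$deflect_every,
               paste(registry$name, collapse = ","), sep = "|")
  hit <- .protorec_cache[[key]]
  if (!is.null(hit)) return(hit)

  nE <- 512L
  egrid <- exp(seq(log(0.5), log(300), length.out = nE))
  nmat <- nrow(registry)
  S <- ms <- sig <- matrix(0, nE, nmat)
  C <- calibrate_hard_scatter(p_target = cfg$hs_p_target,
                              cutoff = cfg$cutoff_mev)
  for (i in seq_len(nmat)) {
    m <- registry[i, , drop = FALSE]
    S[, i] <- stopping_power(egrid, m)
    ms[, i] <- highland_sigma(egrid, step_mm * cfg$deflect_every / 10, m)
    sig[, i] <- hard_scatter_sigma(egrid, m, C)
  }
  pc <- physics_constants()
  straggling <- pc$bohr_straggling * registry$density *
    registry$Z / registry$A
  w <- get_material("water", registry)
  relstop <- as.numeric(S[which.min(abs(egrid - 100)), ] /
                          S[which.min(abs(egrid - 100)),
                            match("water", registry$name)])
  # water range-energy by cumulative trapezoid on a fine grid
  efine <- exp(seq(log(cfg$cutoff_mev), log(300), length.out = 4096))
  invS <- 1 / stopping_power(efine, w)
  rfine <- cumsum(c(0, (invS[-1] + invS[-4096]) / 2 * diff(efine)))
  range_water <- stats::approx(efine, rfine, xout = egrid, rule = 2)$y
  range_max <- max(rfine)
  nr <- 2048L
  rgrid <- seq(0, range_max, length.out = nr)
  e_of_range <- stats::approx(rfine, efine, xout = rgrid, rule = 2)$y
  # inverse CDF of the hard-scatter polar angle, on uniform quantiles
  tab <- scatter_theta_table(cfg$theta_min_deg * pi / 180,
                             cfg$convention)
  nq <- 1024L
  qs <- seq(0, 1, length.out = nq)
  thq <- stats::approx(tab$cdf, tab$theta, xout = qs,
                       ties = "ordered")$y
  out <- list(egrid = egrid, S = S, sigma_ms = ms, sigma_hs = sig,
              straggling = straggling, A = registry$A,
              relstop = relstop,
              s_plastic = S[, match("scintillator", registry$name),
                            drop = TRUE],
              range_water = range_water, e_of_range = e_of_range,
              range_max = range_max,
              theta_quantiles = thq,
              theta_lo = tab$support[1], theta_hi = tab$support[2],
              norm_omega = tab$norm_omega,
              convention = if (cfg$convention == "sin4theta") 0L else 1L,
              hs_constant = C)
  .protorec_cache[[key]] <- out
  out
}

detector_payload <- function(d) {
  if (is.null(d) || nrow(d) == 0L) {
    z <- matrix(numeric(0), 0, 3)
    return(list(centers = z, normals = z, t1 = z, t2 = z))
  }
  list(centers = cbind(d$cx, d$cy, d$cz),
       normals = cbind(d$nx, d$ny, d$nz),
       t1 = cbind(d$t1x, d$t1y, d$t1z),
       t2 = cbind(d$t2x, d$t2y, d$t2z))
}

beam_payload <- function(b, p, n_protons) {
  ext <- phantom_extent_mm(p)
  list(n_protons = as.integer(n_protons),
       energy_mev = b$energy_mev,
       center_y_mm = p$origin_mm[2] + ext[2] / 2 + b$shift_cm[1] * 10,
       center_z_mm = p$origin_mm[3] + ext[3] / 2 + b$shift_cm[2] * 10,
       radius_mm = b$width_cm * 10 / 2,
       wobble_mm = if (b$mode == "wobbler") b$wobble_radius_cm * 10
                   else 0)
}

cfg_payload <- function(cfg, p, n_protons) {
  step <- if (is.null(cfg$step_mm)) p$voxel_mm / 2 else cfg$step_mm
  if (step > p$voxel_mm / 2 + 1e-9)
    stop("step must not exceed half the voxel size", call. = FALSE)
  list(step_mm = step, cutoff_mev = cfg$cutoff_mev,
       ms_on = cfg$ms_on, straggle_on = cfg$straggle_on,
       hs_on = cfg$hs_on, current_estimator = cfg$current_estimator,
       nee_stride = max(1L, as.integer(floor(n_protons /
                                               cfg$nee_protons))),
       nee_step = as.integer(cfg$nee_step),
       deflect_every = cfg$deflect_every,
       seed = floor(stats::runif(1) * 2^31))
}

#' Irradiate a phantom and score dose and detector currents
#'
#' Monte Carlo forward model: transports `b$n_protons` primaries through
#' the phantom (Bethe-Bloch slowing down with Bohr straggling, Highland
#' multiple scattering, Rutherford hard scatters), scoring the deposited
#' energy per voxel and the per-detector current (deposited energy, MeV).
#' Reproducible given the R random seed.
#'
#' @param p A `voxel_phantom`.
#' @param b A `beam_spec`.
#' @param d A `detector_array`, or `NULL` for no detectors.
#' @param cfg A `transport_config`.
#' @return Object of class `simulation_result`: `dose` (3D array, MeV per
#'   voxel, lattice attributes attached), `currents` (named per detector
#'   id; excluded detectors read 0), `ledger` (energy bookkeeping) and
#'   `meta`.
#' @export
simulate_irradiation <- function(p, b, d = NULL,
                                 cfg = transport_config()) {
  stopifnot(inherits(p, "voxel_phantom"), inherits(b, "beam_spec"))
  step <- if (is.null(cfg$step_mm)) p$voxel_mm / 2 else cfg$step_mm
  tabs <- physics_tables(p$registry, step, cfg)
  dims <- dim(p$density)
  res <- cpp_simulate(as.numeric(p$density),
                      as.integer(p$material_id) - 1L,
                      as.integer(dims), p$voxel_mm,
                      as.numeric(p$origin_mm),
                      tabs, detector_payload(d),
                      beam_payload(b, p, b$n_protons),
                      cfg_payload(cfg, p, b$n_protons))
  dose <- array(res$dose, dim = dims)
  attr(dose, "voxel_mm") <- p$voxel_mm
  attr(dose, "origin_mm") <- p$origin_mm
  currents <- if (cfg$current_estimator == "nee") res$currents_nee
              else res$currents_analog
  if (!is.null(d) && nrow(d)) {
    currents[d$excluded] <- 0
    names(currents) <- paste(d$col, d$row, sep = ":")
  }
  e_in <- b$n_protons * b$energy_mev
  ledger <- list(
    beam_energy_mev = e_in,
    dose_mev = sum(res$dose),
    escaped_mev = res$escaped_mev,
    detector_analog_mev = res$detector_analog_mev,
    nee_current_mev = res$nee_total_mev,
    closure = (sum(res$dose) + res$escaped_mev +
                 res$detector_analog_mev) / max(e_in, 1e-300),
    n_absorbed = res$n_absorbed, n_escaped = res$n_escaped,
    n_detected = res$n_detected, n_hard_scatters = res$n_hard_scatters)
  structure(list(dose = dose, currents = currents, ledger = ledger,
                 meta = list(beam = b, cfg = cfg,
                             voxel_mm = p$voxel_mm,
                             origin_mm = p$origin_mm)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "simulation result: %g MeV beam energy, ledger closure %.4f\n",
    x$ledger$beam_energy_mev, x$ledger$closure))
  cat(sprintf("  dose %.3g MeV over %d voxels; %d detectors\n",
              x$ledger$dose_mev, length(x$dose), length(x$currents)))
  invisible(x)
}

#' Transport a single proton
#'
#' Steps one proton through the phantom and returns its per-voxel energy
#' deposits plus the exit state (or absorption).
#'
#' @param state Named list/vector: `x`, `y`, `z` (mm), `dx`, `dy`, `dz`
#'   (unit direction), `energy` (MeV); e.g. one row of
#'   [sample_initial_proton()].
#' @param p A `voxel_phantom`.
#' @param cfg A `transport_config`.
#' @return List: `status` ("absorbed"/"escaped"), `deposits` (data.frame
#'   voxel index + MeV), `dose` (3D array), exit position/direction/energy.
#' @export
transport_proton <- function(state, p, cfg = transport_config()) {
  stopifnot(inherits(p, "voxel_phantom"))
  dirv <- as.numeric(c(state$dx, state$dy, state$dz))
  if (abs(sqrt(sum(dirv^2)) - 1) > 1e-6)
    stop("direction must be a unit vector", call. = FALSE)
  step <- if (is.null(cfg$step_mm)) p$voxel_mm / 2 else cfg$step_mm
  tabs <- physics_tables(p$registry, step, cfg)
  dims <- dim(p$density)
  res <- cpp_transport_one(as.numeric(p$density),
                           as.integer(p$material_id) - 1L,
                           as.integer(dims), p$voxel_mm,
                           as.numeric(p$origin_mm),
                           tabs, detector_payload(NULL),
                           as.numeric(c(state$x, state$y, state$z)),
                           dirv, as.numeric(state$energy),
                           cfg_payload(cfg, p, 1L))
  dose <- array(res$dose, dim = dims)
  attr(dose, "voxel_mm") <- p$voxel_mm
  attr(dose, "origin_mm") <- p$origin_mm
  list(status = res$status,
       deposits = data.frame(voxel = res$voxel + 1L,
                             deposit_mev = res$deposit_mev),
       dose = dose,
       exit_position = res$exit_position,
       exit_direction = res$exit_direction,
       exit_energy = res$exit_energy)
}

#' Depth-dose profile of a dose grid
#'
#' Sums the dose over the two transverse axes, yielding the 1D profile
#' along the chosen axis (default: x, the beam direction).
#'
#' @param r A `simulation_result` or a 3D dose array.
#' @param axis Axis index (1 = x).
#' @return Numeric vector; sums to the total dose.
#' @export
depth_dose_profile <- function(r, axis = 1L) {
  dose <- if (inherits(r, "simulation_result")) r$dose else r
  stopifnot(length(dim(dose)) == 3L, axis %in% 1:3)
  apply(dose, axis, sum)
}

#' Persist a simulation result (dose NRRD + currents CSV + ledger JSON)
#'
#' @param r A `simulation_result`.
#' @param prefix Path prefix; writes `<prefix>_dose.nrrd`,
#'   `<prefix>_currents.csv`, `<prefix>_ledger.json`.
#' @return The three paths, invisibly.
#' @export
write_simulation_result <- function(r, prefix) {
  stopifnot(inherits(r, "simulation_result"))
  paths <- paste0(prefix, c("_dose.nrrd", "_currents.csv",
                            "_ledger.json"))
  write_nrrd(r$dose, paths[1])
  utils::write.csv(data.frame(id = names(r$currents),
                              energy_mev = as.numeric(r$currents)),
                   paths[2], row.names = FALSE)
  jsonlite::write_json(r$ledger, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
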