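grid_meta <- function(d, voxel_mm = NULL, origin_mm = NULL) {
  if (is.null(voxel_mm)) voxel_mm <- attr(d, "voxel_mm")
  if (is.null(voxel_mm)) voxel_mm <- 1
  nd <- length(dim(d))
  if (is.null(origin_mm)) origin_mm <- attr(d, "origin_mm")
  if (is.null(origin_mm)) origin_mm <- numeric(nd)
  list(voxel_mm = voxel_mm, origin_mm = origin_mm[seq_len(nd)])
}

#' Bragg-peak position of a dose grid
#'
#' Center coordinates (mm) of the voxel with maximal dose; ties resolve
#' to the smallest flat (column-major) index, so results are stable
#' across runs. Works on 2D slabs and 3D grids.
#'
#' @param d Dose array (2D or 3D), optionally with `voxel_mm` /
#'   `origin_mm` attributes.
#' @param voxel_mm,origin_mm Lattice metadata overrides.
#' @return Numeric vector of per-axis peak coordinates, mm.
#' @export
peak_position <- function(d, voxel_mm = NULL, origin_mm = NULL) {
  if (length(d) == 0 || all(d == 0) || all(!is.finite(d)))
    stop("dose grid is empty or all-zero", call. = FALSE)
  g <- grid_meta(d, voxel_mm, origin_mm)
  idx <- arrayInd(which.max(d), dim(d))[1, ]
  g$origin_mm + (idx - 0.5) * g$voxel_mm
}

#' Per-axis Bragg-peak position errors
#'
#' Absolute differences of [peak_position()] between the Monte Carlo
#' reference dose and the estimated dose, per axis, in mm.
#'
#' @param mc,dl Dose arrays on the same lattice.
#' @param voxel_mm Lattice constant override.
#' @return Named vector (`dx`, `dy`[, `dz`]), mm.
#' @export
peak_errors <- function(mc, dl, voxel_mm = NULL) {
  if (!identical(dim(mc), dim(dl)))
    stop("dose grids are on different lattices", call. = FALSE)
  g <- grid_meta(mc, voxel_mm)
  e <- abs(peak_position(mc, g$voxel_mm, g$origin_mm) -
             peak_position(dl, g$voxel_mm, g$origin_mm))
  names(e) <- c("dx", "dy", "dz")[seq_along(e)]
  e
}

#' Root-sum-squared dose error on a 100 Gy normalization
#'
#' Both grids are scaled by the single factor that normalizes the total
#' Monte Carlo dose to 100 Gy; the statistic is the square root of the
#' sum of squared voxel differences. Invariant under a common positive
#' rescaling of both inputs.
#'
#' @param mc Monte Carlo reference dose (any positive total).
#' @param dl Estimated dose on the same lattice.
#' @return Delta_dose in Gy (per 100 Gy total reference dose).
#' @export
delta_dose <- function(mc, dl) {
  if (!identical(dim(mc), dim(dl)))
    stop("dose grids are on different lattices", call. = FALSE)
  tot <- sum(mc)
  if (tot <= 0) stop("reference dose total is zero", call. = FALSE)
  s <- 100 / tot
  sqrt(sum((s * mc - s * dl)^2))
}

#' Gamma-analysis criteria
#'
#' @param dose_pct Dose-difference tolerance, percent of the global
#'   maximum of the normalized reference (global gamma).
#' @param dist_mm Distance-to-agreement tolerance, mm.
#' @return Object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_pct = 3, dist_mm = 3) {
  stopifnot(dose_pct > 0, dist_mm > 0)
  structure(list(dose_pct = dose_pct, dist_mm = dist_mm),
            class = "gamma_criteria")
}

#' Gamma-index map between a reference and an evaluated dose
#'
#' Discrete gamma analysis at voxel centers: for every reference voxel,
#' the minimum over evaluated voxels of
#' sqrt(dose_diff^2 / dD^2 + distance^2 / dd^2). Both grids are first
#' scaled so the reference totals 100 Gy; dD is `dose_pct` percent of the
#' normalized reference's global maximum (global gamma). The search is
#' restricted to distances <= 2 dd, where the distance term alone already
#' exceeds gamma = 2; within the sub-2 range this is exact (verified
#' against unrestricted brute force in the tests). Argument order
#' matters: the reference (first) is the Monte Carlo dose.
#'
#' @param ref Reference dose grid (2D or 3D).
#' @param eval Evaluated dose grid, same lattice.
#' @param criteria A [gamma_criteria()].
#' @param voxel_mm Lattice constant override.
#' @return Gamma array, same shape as `ref`.
#' @export
gamma_map <- function(ref, eval, criteria = gamma_criteria(),
                      voxel_mm = NULL) {
  if (!identical(dim(ref), dim(eval)))
    stop("dose grids are on different lattices", call. = FALSE)
  g <- grid_meta(ref, voxel_mm)
  tot <- sum(ref)
  if (tot <= 0) stop("reference dose total is zero", call. = FALSE)
  s <- 100 / tot
  r <- s * ref; e <- s * eval
  dD <- criteria$dose_pct / 100 * max(r)
  dims <- dim(r)
  dims3 <- c(dims, rep(1L, 3 - length(dims)))
  gm <- cpp_gamma_map(as.numeric(r), as.numeric(e),
                      as.integer(dims3), g$voxel_mm, dD,
                      criteria$dist_mm, 2 * criteria$dist_mm)
  dim(gm) <- dims
  gm
}

#' Gamma passing rate
#'
#' Percentage of voxels with gamma strictly below 1 (a voxel at exactly
#' gamma = 1 fails).
#'
#' @param g Gamma array from [gamma_map()].
#' @param mask Optional logical array restricting the evaluation.
#' @return Passing rate, percent.
#' @export
gamma_passing_rate <- function(g, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(g) else {
    if (!any(mask)) stop("mask selects no voxels", call. = FALSE)
    as.numeric(g)[as.logical(mask)]
  }
  100 * mean(v < 1)
}

#' Evaluate a trained model on held-out samples
#'
#' Runs the model on every test sample and computes the per-sample peak
#' position errors, Delta_dose and gamma passing rate against the Monte
#' Carlo dose, plus mean/std/min/max aggregates.
#'
#' @param model A trained `dose_model`.
#' @param ds The `dose_dataset`.
#' @param idx Test indices (held-out; do not pass training samples).
#' @param criteria A [gamma_criteria()].
#' @return Object of class `eval_report`: `per_sample` data.frame and
#'   `summary` data.frame (rows mean/std/min/max).
#' @export
evaluate_testset <- function(model, ds, idx,
                             criteria = gamma_criteria()) {
  stopifnot(inherits(ds, "dose_dataset"), length(idx) >= 1)
  rows <- lapply(idx, function(i) {
    s <- ds$samples[[i]]
    dl <- predict(model, s$currents, s$ct)
    pe <- peak_errors(s$target, dl,
                      voxel_mm = attr(s$target, "voxel_mm"))
    gm <- gamma_map(s$target, dl, criteria,
                    voxel_mm = attr(s$target, "voxel_mm"))
    out <- data.frame(sample = i,
                      dx_peak = pe[["dx"]], dy_peak = pe[["dy"]],
                      dz_peak = if (length(pe) > 2) pe[["dz"]]
                                else NA_real_,
                      delta_dose = delta_dose(s$target, dl),
                      gamma_pass = gamma_passing_rate(gm))
    out
  })
  per <- do.call(rbind, rows)
  agg <- function(v) if (all(is.na(v))) rep(NA_real_, 4) else
    c(mean(v), stats::sd(v), min(v), max(v))
  metrics <- c("dx_peak", "dy_peak", "dz_peak", "delta_dose",
               "gamma_pass")
  summ <- as.data.frame(lapply(per[metrics], agg))
  summ <- cbind(stat = c("mean", "std", "min", "max"), summ)
  structure(list(per_sample = per, summary = summ,
                 criteria = criteria),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("evaluation over", nrow(x$per_sample), "held-out samples\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Persist / reload an evaluation report (per-sample CSV + summary JSON)
#'
#' @param report An `eval_report`.
#' @param prefix Path prefix; writes `<prefix>_per_sample.csv` and
#'   `<prefix>_summary.json`.
#' @param x Prefix previously passed to [write_eval_report()].
#' @return Paths invisibly / the reconstructed report.
#' @export
write_eval_report <- function(report, prefix) {
  stopifnot(inherits(report, "eval_report"))
  paths <- paste0(prefix, c("_per_sample.csv", "_summary.json"))
  utils::write.csv(report$per_sample, paths[1], row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            criteria = unclass(report$criteria)),
                       paths[2], digits = NA)
  invisible(paths)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(x) {
  per <- utils::read.csv(paste0(x, "_per_sample.csv"))
  js <- jsonlite::read_json(paste0(x, "_summary.json"),
                            simplifyVector = TRUE)
  structure(list(per_sample = per, summary = js$summary,
                 criteria = do.call(gamma_criteria,
                                    as.list(js$criteria))),
            class = "eval_report")
}
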