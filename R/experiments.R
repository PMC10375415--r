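#' Current-change experiment under phantom material substitution
#'
#' Repeats the irradiation of a base phantom and of variants where an
#' axis-aligned region is substituted by another material (typically air
#' and lead), over independent random seeds, and tests each detector for
#' a significant current change (Welch t-test, Benjamini-Hochberg control
#' at `fdr` across detectors). Regions are classified automatically as
#' `"front"` (fully upstream of the unperturbed Bragg depth) or
#' `"around-peak"` from the beam's CSDA range: front substitutions change
#' the observed currents, around-peak substitutions leave them consistent
#' within error because the protons there are too slow to escape.
#'
#' @param p Base `voxel_phantom`.
#' @param b A `beam_spec`.
#' @param d A `detector_array`.
#' @param regions Named list of boxes (`c(x0,x1,y0,y1,z0,z1)` mm).
#' @param materials Substitution materials.
#' @param n_seeds Repeated simulations per variant.
#' @param cfg A `transport_config`.
#' @param fdr Benjamini-Hochberg level.
#' @return Object of class `substitution_report`: per-variant detector
#'   means/sds, adjusted p-values, significant detector counts and the
#'   region classification.
#' @export
run_substitution_experiment <- function(p, b, d, regions,
                                        materials = c("air", "lead"),
                                        n_seeds = 10,
                                        cfg = transport_config(),
                                        fdr = 0.05) {
  stopifnot(inherits(p, "voxel_phantom"), length(regions) >= 1)
  bragg_mm <- p$origin_mm[1] + csda_range(b$energy_mev, "water") * 10
  sim_currents <- function(ph) {
    t(vapply(seq_len(n_seeds), function(s) {
      as.numeric(simulate_irradiation(ph, b, d, cfg)$currents)
    }, numeric(nrow(d))))
  }
  base_cur <- sim_currents(p)
  variants <- list()
  for (rn in names(regions)) {
    box <- regions[[rn]]
    if (any(box[1:2] < p$origin_mm[1]) &&
        all(box[1:2] < p$origin_mm[1]))
      stop("region outside phantom", call. = FALSE)
    cls <- if (max(box[1:2]) < bragg_mm - 5) "front" else "around-peak"
    for (m in materials) {
      ph <- substitute_region(p, box, m)
      cur <- sim_currents(ph)
      pv <- vapply(seq_len(ncol(cur)), function(j) {
        a <- base_cur[, j]; bb <- cur[, j]
        if (stats::sd(a) == 0 && stats::sd(bb) == 0)
          return(if (isTRUE(all.equal(mean(a), mean(bb)))) 1 else 0)
        tryCatch(stats::t.test(a, bb)$p.value, error = function(e) 1)
      }, numeric(1))
      padj <- stats::p.adjust(pv, "BH")
      variants[[paste(rn, m, sep = ":")]] <- list(
        region = rn, material = m, class = cls,
        mean = colMeans(cur), sd = apply(cur, 2, stats::sd),
        p_adjusted = padj, n_significant = sum(padj < fdr))
    }
  }
  structure(list(baseline_mean = colMeans(base_cur),
                 baseline_sd = apply(base_cur, 2, stats::sd),
                 variants = variants, bragg_depth_mm = bragg_mm,
                 n_seeds = n_seeds, fdr = fdr),
            class = "substitution_report")
}

#' @export
print.substitution_report <- function(x, ...) {
  cat(sprintf("substitution experiment (%d seeds, FDR %.2g)\n",
              x$n_seeds, x$fdr))
  for (nm in names(x$variants)) {
    v <- x$variants[[nm]]
    cat(sprintf("  %-24s [%s] significant detectors: %d\n",
                nm, v$class, v$n_significant))
  }
  invisible(x)
}

# dataset with the currents restricted to a detector subset
restrict_dataset <- function(ds, columns = NULL, rows = NULL) {
  sub <- select_subset(ds$detectors, columns, rows)
  keep <- which(ds$detectors$col %in% unique(sub$col) &
                  ds$detectors$row %in% unique(sub$row))
  ds$samples <- lapply(ds$samples, function(s) {
    s$currents <- s$currents[keep]
    s
  })
  ds$detectors <- sub
  ds
}

#' Estimation error versus detector count
#'
#' For each detector subset in the schedule, retrains the current-to-dose
#' estimator `n_repeats` times (independent seeds) on the restricted
#' currents and reports the mean and standard deviation of the test-split
#' depth peak error. The default schedule halves the ring columns
#' (36 to 18) and the rows (12 to 6) by alternating decimation.
#'
#' @param ds A family-C style `dose_dataset`.
#' @param split Split from [split_dataset()].
#' @param schedule Named list; each element `list(columns=, rows=)`
#'   (NULL = all).
#' @param n_repeats Training repetitions per subset.
#' @param model_cfg A `model_config`.
#' @param with_ct Condition on the density grid.
#' @param base_seed Seed offset for the repetitions.
#' @return data.frame: subset, n_detectors, repeat, mean dx/dy/dz peak
#'   errors, plus a `summary` attribute with per-subset mean +/- sd.
#' @export
run_detector_reduction <- function(ds, split, schedule = NULL,
                                   n_repeats = 3,
                                   model_cfg = model_config(),
                                   with_ct = FALSE, base_seed = 1) {
  if (is.null(schedule)) {
    nc <- attr(ds$detectors, "layout")$n_columns
    nr <- attr(ds$detectors, "layout")$n_rows
    schedule <- list(
      full = list(columns = NULL, rows = NULL),
      half_columns = list(columns = seq(1, nc, by = 2), rows = NULL),
      half_rows = list(columns = NULL, rows = seq(1, nr, by = 2)))
  }
  rows_out <- list()
  for (nm in names(schedule)) {
    sub <- schedule[[nm]]
    if (!is.null(sub$columns) && !length(sub$columns))
      stop("empty detector subset", call. = FALSE)
    dsub <- restrict_dataset(ds, sub$columns, sub$rows)
    for (r in seq_len(n_repeats)) {
      set.seed(base_seed + 1000 * r)
      # alternating-row subsets break the z mirror; augment with y only
      tr <- augment_flips(dsub, split$train, mode = "y")
      va <- augment_flips(dsub, split$val, mode = "y")
      s1 <- dsub$samples[[1]]
      model <- build_model(model_cfg, length(s1$currents),
                           length(s1$target), dim(s1$target),
                           with_ct = with_ct,
                           ct_dim = if (with_ct)
                             length(pool_grid(s1$ct,
                                              model_cfg$ct_pool)))
      model <- train_model(model, tr, va)
      rep_ <- evaluate_testset(model, dsub, split$test)
      m <- rep_$summary[rep_$summary$stat == "mean", ]
      rows_out[[length(rows_out) + 1]] <- data.frame(
        subset = nm, n_detectors = nrow(dsub$detectors),
        rep = r, dx_peak = m$dx_peak, dy_peak = m$dy_peak,
        dz_peak = m$dz_peak)
    }
  }
  out <- do.call(rbind, rows_out)
  summ <- do.call(rbind, lapply(split(out, out$subset), function(g)
    data.frame(subset = g$subset[1], n_detectors = g$n_detectors[1],
               dx_mean = mean(g$dx_peak), dx_sd = stats::sd(g$dx_peak),
               dy_mean = mean(g$dy_peak), dy_sd = stats::sd(g$dy_peak))))
  attr(out, "summary") <- summ
  out
}

#' Paired with/without-CT ablation
#'
#' Trains the dose estimator with and without the density-grid input on
#' identical splits and seeds and compares the test-split depth peak
#' error and Delta_dose per sample, over one or more seeds.
#'
#' @param ds A family-C style `dose_dataset` (samples carry `ct`).
#' @param split Split from [split_dataset()].
#' @param model_cfg A `model_config`.
#' @param seeds Training seeds.
#' @return List: `arms` (per-seed eval reports for `no_ct` / `with_ct`),
#'   `paired` data.frame and per-arm mean depth errors.
#' @export
run_ct_ablation <- function(ds, split, model_cfg = model_config(),
                            seeds = 1) {
  s1 <- ds$samples[[1]]
  if (is.null(s1$ct)) stop("dataset has no density grids", call. = FALSE)
  arms <- list(no_ct = list(), with_ct = list())
  paired <- list()
  for (sd_ in seeds) {
    for (arm in c("no_ct", "with_ct")) {
      set.seed(sd_)
      tr <- augment_flips(ds, split$train)
      va <- augment_flips(ds, split$val)
      wc <- arm == "with_ct"
      model <- build_model(model_cfg, length(s1$currents),
                           length(s1$target), dim(s1$target),
                           with_ct = wc,
                           ct_dim = if (wc)
                             length(pool_grid(s1$ct,
                                              model_cfg$ct_pool)))
      model <- train_model(model, tr, va)
      arms[[arm]][[as.character(sd_)]] <-
        evaluate_testset(model, ds, split$test)
    }
    a <- arms$no_ct[[as.character(sd_)]]$per_sample
    b <- arms$with_ct[[as.character(sd_)]]$per_sample
    paired[[length(paired) + 1]] <- data.frame(
      seed = sd_, sample = a$sample,
      dx_no_ct = a$dx_peak, dx_with_ct = b$dx_peak,
      ddose_no_ct = a$delta_dose, ddose_with_ct = b$delta_dose)
  }
  paired <- do.call(rbind, paired)
  list(arms = arms, paired = paired,
       mean_dx_no_ct = mean(paired$dx_no_ct),
       mean_dx_with_ct = mean(paired$dx_with_ct))
}
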