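family_defaults <- function(family) {
  switch(family,
    A = list(dims_cm = c(32, 20, 20), voxel_mm = 2,
             energy = c(180, 220), shift_y = c(-4, 4),
             shift_z = c(0, 0), width = c(1, 1), mode = "pencil",
             sides = c("+y", "-y"), n_per_side = 24, air_layer = FALSE,
             slab_y_half_mm = 60),
    B = list(dims_cm = c(36, 20, 20), voxel_mm = 2,
             energy = c(180, 220), shift_y = c(-4, 4),
             shift_z = c(0, 0), width = c(1, 1), mode = "pencil",
             sides = c("+y", "-y", "+z", "-z"), n_per_side = 24,
             air_layer = TRUE, slab_y_half_mm = 60),
    C = list(radius_cm = 20, height_cm = 40, voxel_mm = 10,
             energy = c(120, 180), shift_y = c(-16, 16),
             shift_z = c(-16, 16), width = c(1, 4), mode = "wobbler",
             angular_step = 10, n_rows = 12),
    stop("family must be A, B or C", call. = FALSE))
}

# Beam-plane slab: dose summed over the voxel layers around the beam
# plane -- the 2D reconstruction target of the rectangular families.
# The default half-width of 4 layers (16 mm at 2 mm voxels) captures the
# full envelope of a 1 cm beam, so the Bragg peak keeps its contrast
# over the entrance channel in the 2D image. `y_half_mm` windows the
# slab to the irradiated corridor around the transverse center (the
# beam shift range plus lateral spread); the window is symmetric, so
# the y-flip augmentation maps it onto itself.
beam_plane_slab <- function(dose, p, half_layers = 4L,
                            y_half_mm = NULL) {
  nz <- dim(dose)[3]
  k <- nz %/% 2
  sel <- max(1L, k - half_layers + 1L):min(nz, k + half_layers)
  sl <- apply(dose[, , sel, drop = FALSE], c(1, 2), sum)
  v <- attr(dose, "voxel_mm")
  oy <- attr(dose, "origin_mm")[2]
  if (!is.null(y_half_mm)) {
    ny <- dim(sl)[2]
    yc <- oy + (seq_len(ny) - 0.5) * v
    ymid <- oy + ny * v / 2
    keep <- which(abs(yc - ymid) <= y_half_mm)
    sl <- sl[, keep, drop = FALSE]
    oy <- oy + (keep[1] - 1) * v
  }
  attr(sl, "voxel_mm") <- v
  attr(sl, "origin_mm") <- c(attr(dose, "origin_mm")[1], oy)
  sl
}

#' Generate a reconstruction dataset for one study family
#'
#' Draws beam parameters uniformly from the family's ranges, builds the
#' phantom (family A: homogeneous rectangular water; B: with a random air
#' slab; C: cylinder with 3--6 random internal structures), runs the
#' Monte Carlo forward model, and stores per sample the detector currents,
#' the dose target (families A/B: the 2D beam-plane slab; C: the full 3D
#' grid), the density grid for C, and the ground-truth metadata.
#' Fully reproducible from the R random seed set by the caller.
#'
#' @param family `"A"`, `"B"` or `"C"`.
#' @param n_samples Number of samples.
#' @param n_protons Primaries per sample.
#' @param cfg A `transport_config`.
#' @param overrides Named list overriding the family defaults (parameter
#'   ranges, voxel size, geometry).
#' @param progress Print a dot every 25 samples.
#' @return Object of class `dose_dataset`.
#' @export
generate_dataset <- function(family, n_samples, n_protons = 5e4,
                             cfg = transport_config(),
                             overrides = list(), progress = FALSE) {
  def <- family_defaults(family)
  def[names(overrides)] <- overrides
  samples <- vector("list", n_samples)
  detectors <- NULL
  for (i in seq_len(n_samples)) {
    energy <- stats::runif(1, def$energy[1], def$energy[2])
    sy <- stats::runif(1, def$shift_y[1], def$shift_y[2])
    sz <- stats::runif(1, def$shift_z[1], def$shift_z[2])
    w <- stats::runif(1, def$width[1], def$width[2])
    b <- beam_spec(energy, shift_cm = c(sy, sz), width_cm = w,
                   mode = def$mode, n_protons = n_protons)
    meta <- list(energy = energy, shift = c(sy, sz), width = w)
    if (family %in% c("A", "B")) {
      p <- build_rect_phantom(def$dims_cm, def$voxel_mm)
      if (def$air_layer) {
        al <- insert_air_layer(p)
        p <- al$phantom
        meta$air_layer_mm <- al$layer
      }
      d <- place_detectors_rect(p, def$n_per_side, def$sides)
      r <- simulate_irradiation(p, b, d, cfg)
      target <- beam_plane_slab(r$dose, p,
                                y_half_mm = def$slab_y_half_mm)
      ct <- NULL
    } else {
      cp <- build_cylinder_phantom(def$radius_cm, def$height_cm,
                                   def$voxel_mm)
      p <- cp$phantom
      meta$n_structures <- nrow(cp$structures)
      d <- place_detectors_cyl(p, b, def$angular_step, def$n_rows,
                               radius_cm = def$radius_cm)
      r <- simulate_irradiation(p, b, d, cfg)
      target <- r$dose
      ct <- export_ct(p)
    }
    if (is.null(detectors)) detectors <- d
    samples[[i]] <- list(currents = as.numeric(r$currents),
                         target = target, ct = ct, meta = meta)
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(family = family, samples = samples,
                 detectors = detectors, params = def,
                 n_protons = n_protons),
            class = "dose_dataset")
}

#' @export
print.dose_dataset <- function(x, ...) {
  cat(sprintf("dose dataset, family %s: %d samples, %d detectors\n",
              x$family, length(x$samples), nrow(x$detectors)))
  invisible(x)
}

#' Save / load a dataset
#'
#' Runtime persistence of generated datasets (single-file RDS container).
#'
#' @param ds A `dose_dataset`.
#' @param path File path.
#' @return `path` invisibly / the dataset.
#' @export
save_dataset <- function(ds, path) {
  saveRDS(ds, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

#' Split a dataset into train / validation / test index sets
#'
#' Random partition into 64% / 16% / 20% (train and validation sizes are
#' rounded to the nearest integer, the test set takes the remainder).
#' Uses the current R random state; call after `set.seed()` for a
#' reproducible partition.
#'
#' @param n Number of samples (or a `dose_dataset`).
#' @param fractions Length-3 split fractions summing to 1.
#' @return List of integer vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(n, fractions = c(0.64, 0.16, 0.20)) {
  if (inherits(n, "dose_dataset")) n <- length(n$samples)
  stopifnot(n >= 5, abs(sum(fractions) - 1) < 1e-9)
  idx <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  list(train = sort(idx[seq_len(n_tr)]),
       val = sort(idx[n_tr + seq_len(n_va)]),
       test = sort(idx[(n_tr + n_va + 1):n]))
}

# flip one sample along "y" or "z": permute currents, mirror target/ct
flip_sample <- function(s, detectors, axis, family) {
  perm <- flip_permutation(detectors, axis)
  s$currents <- s$currents[perm]
  if (family %in% c("A", "B")) {
    # 2D beam-plane slab target: y-flip mirrors dim 2, z-flip is the
    # slab's own symmetry (the slab straddles the beam plane)
    if (axis == "y") s$target <- s$target[, rev(seq_len(ncol(s$target)))]
  } else {
    idx <- lapply(dim(s$target), seq_len)
    a <- if (axis == "y") 2L else 3L
    idx[[a]] <- rev(idx[[a]])
    s$target <- s$target[idx[[1]], idx[[2]], idx[[3]]]
    if (!is.null(s$ct))
      s$ct <- s$ct[idx[[1]], idx[[2]], idx[[3]]]
  }
  s$meta$flipped <- c(s$meta$flipped, axis)
  if (axis == "y") s$meta$shift[1] <- -s$meta$shift[1]
  else s$meta$shift[2] <- -s$meta$shift[2]
  s
}

#' Flip-augment the training and validation samples
#'
#' Family A doubles the selected samples with their y-mirrored copies;
#' families B and C add y-flips, z-flips and (for C) the combined flip,
#' remapping the detector currents by the layout's mirror permutation and
#' mirroring target, density grid and metadata consistently. Test samples
#' must not be passed in (augment after splitting).
#'
#' @param ds A `dose_dataset`.
#' @param idx Indices of the samples to augment (train + validation).
#' @param mode `"y"` (x2), `"yz"` (x3: adds y- and z-flips) or `"yz+"`
#'   (x4: adds the combined flip). Default by family: A `"y"`, B `"yz"`,
#'   C `"yz+"`.
#' @return List of samples: the originals at `idx` followed by their
#'   flipped copies.
#' @export
augment_flips <- function(ds, idx, mode = NULL) {
  stopifnot(inherits(ds, "dose_dataset"))
  if (is.null(mode))
    mode <- switch(ds$family, A = "y", B = "yz", C = "yz+")
  base <- ds$samples[idx]
  out <- base
  add <- function(axis_seq) {
    lapply(base, function(s) {
      for (a in axis_seq) s <- flip_sample(s, ds$detectors, a, ds$family)
      s
    })
  }
  out <- c(out, add("y"))
  if (mode %in% c("yz", "yz+")) out <- c(out, add("z"))
  if (mode == "yz+") out <- c(out, add(c("y", "z")))
  out
}

# design matrices + normalization constants (train statistics only)
dataset_matrices <- function(samples, with_ct = FALSE,
                             ct_pool = 2L) {
  X <- do.call(rbind, lapply(samples, function(s) s$currents))
  Y <- do.call(rbind, lapply(samples, function(s) as.numeric(s$target)))
  XCT <- NULL
  if (with_ct) {
    XCT <- do.call(rbind, lapply(samples, function(s)
      as.numeric(pool_grid(s$ct, ct_pool))))
  }
  list(X = X, Y = Y, XCT = XCT)
}

# block-average pooling of a 3D grid by an integer factor
pool_grid <- function(g, f = 2L) {
  if (f == 1L) return(g)
  d <- dim(g)
  dn <- d %/% f
  g <- g[seq_len(dn[1] * f), seq_len(dn[2] * f), seq_len(dn[3] * f)]
  dim(g) <- c(f, dn[1], f, dn[2], f, dn[3])
  g <- aperm(g, c(2, 4, 6, 1, 3, 5))
  dim(g) <- c(prod(dn), f^3)
  array(rowMeans(g), dn)
}

#' Fit input/target normalization on training samples
#'
#' Currents are scaled by the training-set 99th-percentile current;
#' targets are mapped to `[-1, 1]` (tanh range) by the training-set
#' maximum dose; the density grid is scaled by its training maximum.
#'
#' @param mats Output of the internal design-matrix builder (train rows).
#' @return Named list of scale constants.
#' @keywords internal
fit_normalization <- function(mats) {
  cs <- stats::quantile(mats$X, 0.99, names = FALSE)
  if (cs <= 0) cs <- 1
  dm <- max(mats$Y)
  if (dm <= 0) dm <- 1
  ctm <- if (!is.null(mats$XCT)) max(mats$XCT) else 1
  list(current_scale = cs, dose_max = dm, ct_scale = max(ctm, 1e-12))
}

# "scale": divide by the train p99; "log": additionally compress the
# dynamic range (currents span orders of magnitude across detectors)
normalize_inputs <- function(X, norms, transform = "scale") {
  X <- X / norms$current_scale
  if (identical(transform, "log")) X <- log1p(100 * X) / log1p(100)
  X
}
normalize_targets <- function(Y, norms) 2 * Y / norms$dose_max - 1
denormalize_targets <- function(T, norms)
  pmax((T + 1) / 2 * norms$dose_max, 0)
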