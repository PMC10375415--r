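#' Voxel phantom constructor (internal)
#'
#' A voxel phantom is a pair of congruent 3D grids -- mass density (g/cm^3)
#' and material id (index into a registry) -- on an isotropic lattice.
#' Axis convention: x (dim 1) is the beam direction, y (dim 2) horizontal,
#' z (dim 3) vertical. The density of every voxel always equals its
#' material's registry density.
#'
#' @param material_id Integer 3D array of registry row indices.
#' @param voxel_mm Isotropic voxel edge, mm.
#' @param origin_mm Coordinates of the grid corner (mm), length 3.
#' @param registry Material registry data.frame.
#' @return Object of class `voxel_phantom`.
#' @keywords internal
new_voxel_phantom <- function(material_id, voxel_mm, origin_mm, registry) {
  stopifnot(length(dim(material_id)) == 3L, voxel_mm > 0,
            length(origin_mm) == 3L)
  density <- array(registry$density[material_id], dim = dim(material_id))
  structure(list(density = density,
                 material_id = material_id,
                 voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm),
                 registry = registry),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("voxel phantom: %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], x$voxel_mm))
  cat("materials present:",
      paste(x$registry$name[sort(unique(as.vector(x$material_id)))],
            collapse = ", "), "\n")
  invisible(x)
}

# voxel-center coordinates along one axis (mm)
voxel_centers <- function(p, axis) {
  n <- dim(p$density)[axis]
  p$origin_mm[axis] + (seq_len(n) - 0.5) * p$voxel_mm
}

phantom_extent_mm <- function(p) dim(p$density) * p$voxel_mm

#' Build a homogeneous rectangular water phantom
#'
#' @param dims_cm Length-3 phantom extents (x, y, z), cm.
#' @param voxel_mm Isotropic voxel size, mm.
#' @param registry Material registry.
#' @return A `voxel_phantom`, all water, with the grid corner at the
#'   origin; grid shape is `ceiling(dims / voxel)` per axis.
#' @export
build_rect_phantom <- function(dims_cm = c(30, 20, 20), voxel_mm = 2,
                               registry = material_registry()) {
  stopifnot(length(dims_cm) == 3L, all(dims_cm > 0), voxel_mm > 0)
  if (voxel_mm > min(dims_cm) * 10)
    stop("voxel size exceeds a phantom dimension", call. = FALSE)
  n <- as.integer(ceiling(dims_cm * 10 / voxel_mm))
  water <- match("water", registry$name)
  mid <- array(water, dim = n)
  new_voxel_phantom(mid, voxel_mm, c(0, 0, 0), registry)
}

#' Insert a random air slab into a rectangular water phantom
#'
#' Replaces an axis-aligned full-cross-section slab of water with air.
#' Thickness is drawn uniformly from `thickness_cm` and the slab is placed
#' uniformly inside the middle `middle_frac` of the x extent, so that it
#' sometimes intersects the Bragg peak.
#'
#' @param p Rectangular water `voxel_phantom`.
#' @param thickness_cm Length-2 range of slab thickness, cm.
#' @param middle_frac Fraction of the x extent the slab must lie within.
#' @return List with the modified phantom (`phantom`) and a `layer` record
#'   `c(x0_mm, x1_mm)` for ground truth.
#' @export
insert_air_layer <- function(p, thickness_cm = c(1, 5), middle_frac = 0.8) {
  stopifnot(inherits(p, "voxel_phantom"))
  lx <- phantom_extent_mm(p)[1]
  thick <- stats::runif(1, thickness_cm[1], thickness_cm[2]) * 10
  lo <- lx * (1 - middle_frac) / 2
  hi <- lx - lo - thick
  if (hi <= lo)
    stop("air layer does not fit inside the phantom", call. = FALSE)
  x0 <- stats::runif(1, lo, hi)
  air <- match("air", p$registry$name)
  xc <- voxel_centers(p, 1)
  sel <- xc >= x0 & xc < x0 + thick
  p$material_id[sel, , ] <- air
  p$density <- array(p$registry$density[p$material_id],
                     dim = dim(p$material_id))
  list(phantom = p, layer = c(x0, x0 + thick))
}

#' Build a cylindrical body-like phantom with random internal structures
#'
#' Water cylinder (axis along z) inside an air bounding box, with 3--6
#' internal structures of hydroxyapatite or glass. Each structure's shape
#' is drawn from ellipsoid / rectangular box / z-axis cylinder, each
#' principal extent uniformly from `size_cm`, the center uniformly inside
#' the cylinder; structures are clipped to the cylinder.
#'
#' @param radius_cm Cylinder radius, cm.
#' @param height_cm Cylinder height, cm.
#' @param voxel_mm Voxel size, mm.
#' @param n_structures Candidate structure counts (sampled uniformly).
#' @param size_cm Range of structure extents, cm.
#' @param margin_cm Extra air margin of the bounding box beyond the
#'   cylinder radius, per side, cm.
#' @param registry Material registry.
#' @return List with `phantom` and `structures` (data.frame of specs).
#' @export
build_cylinder_phantom <- function(radius_cm = 20, height_cm = 40,
                                   voxel_mm = 10, n_structures = 3:6,
                                   size_cm = c(5, 20), margin_cm = 0,
                                   registry = material_registry()) {
  stopifnot(radius_cm > 0, height_cm > 0, voxel_mm > 0)
  r_mm <- radius_cm * 10
  half_xy <- r_mm + margin_cm * 10
  n_xy <- as.integer(ceiling(2 * half_xy / voxel_mm))
  n_z <- as.integer(ceiling(height_cm * 10 / voxel_mm))
  air <- match("air", registry$name)
  water <- match("water", registry$name)
  mid <- array(air, dim = c(n_xy, n_xy, n_z))
  origin <- c(-half_xy, -half_xy, 0)
  xc <- origin[1] + (seq_len(n_xy) - 0.5) * voxel_mm
  yc <- origin[2] + (seq_len(n_xy) - 0.5) * voxel_mm
  zc <- origin[3] + (seq_len(n_z) - 0.5) * voxel_mm
  in_cyl <- outer(xc^2, yc^2, "+") <= r_mm^2
  mid[rep(in_cyl, times = n_z)] <- water
  dim(mid) <- c(n_xy, n_xy, n_z)

  k <- sample(n_structures, 1)
  shapes <- sample(c("ellipsoid", "box", "cylinder"), k, replace = TRUE)
  mats <- sample(c("hydroxyapatite", "glass"), k, replace = TRUE)
  specs <- data.frame(shape = shapes, material = mats,
                      ex = stats::runif(k, size_cm[1], size_cm[2]) * 10,
                      ey = stats::runif(k, size_cm[1], size_cm[2]) * 10,
                      ez = stats::runif(k, size_cm[1], size_cm[2]) * 10,
                      cx = NA_real_, cy = NA_real_, cz = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    repeat {
      cx <- stats::runif(1, -r_mm, r_mm)
      cy <- stats::runif(1, -r_mm, r_mm)
      if (cx^2 + cy^2 <= r_mm^2) break
    }
    cz <- stats::runif(1, 0, height_cm * 10)
    specs$cx[i] <- cx; specs$cy[i] <- cy; specs$cz[i] <- cz
    mat_i <- match(mats[i], registry$name)
    hx <- specs$ex[i] / 2; hy <- specs$ey[i] / 2; hz <- specs$ez[i] / 2
    ix <- which(abs(xc - cx) <= hx)
    iy <- which(abs(yc - cy) <= hy)
    iz <- which(abs(zc - cz) <= hz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    sub <- mid[ix, iy, iz, drop = FALSE]
    dx <- (xc[ix] - cx) / hx; dy <- (yc[iy] - cy) / hy
    dz <- (zc[iz] - cz) / hz
    inside <- switch(
      shapes[i],
      box = array(TRUE, dim = dim(sub)),
      ellipsoid = outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1,
      cylinder = array(rep(outer(dx^2, dy^2, "+") <= 1, length(iz)),
                       dim = dim(sub))
    )
    inside <- inside & (sub != air)   # clip to the water cylinder
    sub[inside] <- mat_i
    mid[ix, iy, iz] <- sub
  }
  p <- new_voxel_phantom(mid, voxel_mm, origin, registry)
  list(phantom = p, structures = specs)
}

#' Substitute an axis-aligned region with another material
#'
#' Reassigns every voxel whose center lies inside `box_mm` to `material`,
#' returning a modified copy (the input is untouched).
#'
#' @param p A `voxel_phantom`.
#' @param box_mm 2x3 matrix (rows: lower, upper corners) or length-6
#'   vector `c(x0, x1, y0, y1, z0, z1)` in mm.
#' @param material Material name present in the phantom's registry.
#' @return Modified `voxel_phantom`.
#' @export
substitute_region <- function(p, box_mm, material) {
  stopifnot(inherits(p, "voxel_phantom"))
  mat_i <- match(get_material(material, p$registry)$name, p$registry$name)
  if (length(box_mm) == 6L) box_mm <- matrix(box_mm, 2, 3)
  stopifnot(all(dim(box_mm) == c(2, 3)))
  sel <- lapply(1:3, function(a) {
    cc <- voxel_centers(p, a)
    which(cc >= box_mm[1, a] & cc <= box_mm[2, a])
  })
  if (any(lengths(sel) == 0L))
    stop("box does not intersect the phantom", call. = FALSE)
  p$material_id[sel[[1]], sel[[2]], sel[[3]]] <- mat_i
  p$density <- array(p$registry$density[p$material_id],
                     dim = dim(p$material_id))
  p
}

#' Export the density grid ("CT") of a phantom
#'
#' The phantom's CT is its mass-density distribution: the returned 3D
#' array shares lattice, shape and axes with dose grids.
#'
#' @param p A `voxel_phantom`.
#' @return 3D numeric array of densities with attributes `voxel_mm` and
#'   `origin_mm`.
#' @export
export_ct <- function(p) {
  stopifnot(inherits(p, "voxel_phantom"))
  ct <- p$density
  attr(ct, "voxel_mm") <- p$voxel_mm
  attr(ct, "origin_mm") <- p$origin_mm
  ct
}

#' Flip a phantom along an axis
#'
#' @param p A `voxel_phantom`.
#' @param axis 2 (y) or 3 (z).
#' @return Flipped phantom (lattice unchanged).
#' @export
flip_phantom <- function(p, axis = 2L) {
  stopifnot(inherits(p, "voxel_phantom"), axis %in% c(2L, 3L))
  idx <- lapply(dim(p$material_id), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  p$material_id <- p$material_id[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  p$density <- p$density[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  p
}
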