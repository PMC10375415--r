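DET_FACE_MM <- 10   # square scintillator face
DET_THICK_MM <- 3   # thickness along the inward normal
DET_STANDOFF_MM <- 10

# assemble a detector_array data.frame with orientation vectors
new_detector_array <- function(df, layout) {
  n <- sqrt(df$nx^2 + df$ny^2 + df$nz^2)
  df$nx <- df$nx / n; df$ny <- df$ny / n; df$nz <- df$nz / n
  # t1: pick a lattice axis not parallel to the normal; t2 = n x t1
  t1 <- t(vapply(seq_len(nrow(df)), function(i) {
    nv <- c(df$nx[i], df$ny[i], df$nz[i])
    a <- if (abs(nv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- a - sum(a * nv) * nv
    v / sqrt(sum(v^2))
  }, numeric(3)))
  df$t1x <- t1[, 1]; df$t1y <- t1[, 2]; df$t1z <- t1[, 3]
  df$t2x <- df$ny * df$t1z - df$nz * df$t1y
  df$t2y <- df$nz * df$t1x - df$nx * df$t1z
  df$t2z <- df$nx * df$t1y - df$ny * df$t1x
  if (anyDuplicated(df[, c("col", "row")]))
    stop("duplicate detector ids", call. = FALSE)
  structure(df, class = c("detector_array", "data.frame"),
            layout = layout)
}

#' Place scintillation detectors on the sides of a rectangular phantom
#'
#' `n_per_side` detectors per selected side, evenly spaced along x so they
#' span the full x extent, centred transversely, with centers 10 mm
#' outside the phantom surface and inward normals. Detector id is
#' (column = x index, row = side index).
#'
#' @param p Rectangular `voxel_phantom`.
#' @param n_per_side Detectors per side.
#' @param sides Subset of `c("+y", "-y", "+z", "-z")`.
#' @return A `detector_array` (data.frame of centers and orientations, one
#'   10 x 10 x 3 mm detector per row).
#' @export
place_detectors_rect <- function(p, n_per_side = 24,
                                 sides = c("+y", "-y")) {
  stopifnot(inherits(p, "voxel_phantom"), n_per_side >= 1)
  sides <- match.arg(sides, c("+y", "-y", "+z", "-z"), several.ok = TRUE)
  if (!length(sides)) stop("sides must not be empty", call. = FALSE)
  ext <- phantom_extent_mm(p)
  xs <- p$origin_mm[1] + (seq_len(n_per_side) - 0.5) * ext[1] / n_per_side
  ymid <- p$origin_mm[2] + ext[2] / 2
  zmid <- p$origin_mm[3] + ext[3] / 2
  rows <- lapply(seq_along(sides), function(si) {
    s <- sides[si]
    ctr <- switch(s,
      "+y" = cbind(xs, p$origin_mm[2] + ext[2] + DET_STANDOFF_MM, zmid),
      "-y" = cbind(xs, p$origin_mm[2] - DET_STANDOFF_MM, zmid),
      "+z" = cbind(xs, ymid, p$origin_mm[3] + ext[3] + DET_STANDOFF_MM),
      "-z" = cbind(xs, ymid, p$origin_mm[3] - DET_STANDOFF_MM))
    nrm <- switch(s, "+y" = c(0, -1, 0), "-y" = c(0, 1, 0),
                  "+z" = c(0, 0, -1), "-z" = c(0, 0, 1))
    data.frame(col = seq_len(n_per_side), row = si, side = s,
               cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
               nx = nrm[1], ny = nrm[2], nz = nrm[3],
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  new_detector_array(do.call(rbind, rows),
                     layout = list(kind = "rect", sides = sides,
                                   n_per_side = n_per_side,
                                   center_yz = c(ymid, zmid)))
}

#' Place a detector ring around a cylindrical phantom
#'
#' Columns at `angular_step` degree intervals on a cylinder 10 mm outside
#' the phantom surface, `n_rows` rows stacked contiguously (10 mm pitch)
#' along z centred on the phantom mid-plane -- a fixed instrument, so the
#' vertical beam position stays encoded in the row-current ratios.
#' Detectors whose center lies within `exclusion_cm` of the
#' irradiated-beam envelope (cylinder around the beam axis of radius
#' beam width/2, plus the wobble radius in wobbler mode) are flagged
#' `excluded`: they are removed from the readout but keep their id so
#' layouts stay comparable across samples.
#'
#' @param p Cylindrical `voxel_phantom` (from [build_cylinder_phantom()]).
#' @param beam A `beam_spec` (fixes the beam plane and the exclusion
#'   envelope).
#' @param angular_step Column spacing in degrees; must divide 360.
#' @param n_rows Number of z rows.
#' @param radius_cm Phantom cylinder radius; inferred from the grid extent
#'   when `NULL`.
#' @param exclusion_cm Beam-edge clearance, cm.
#' @return A `detector_array`.
#' @export
place_detectors_cyl <- function(p, beam, angular_step = 10, n_rows = 12,
                                radius_cm = NULL, exclusion_cm = 2) {
  stopifnot(inherits(p, "voxel_phantom"), inherits(beam, "beam_spec"))
  if (360 %% angular_step != 0)
    stop("angular_step must divide 360", call. = FALSE)
  ext <- phantom_extent_mm(p)
  if (is.null(radius_cm)) radius_cm <- min(ext[1], ext[2]) / 2 / 10
  r_det <- radius_cm * 10 + DET_STANDOFF_MM
  ang <- seq(0, 360 - angular_step, by = angular_step) * pi / 180
  z_beam <- p$origin_mm[3] + ext[3] / 2 + beam$shift_cm[2] * 10
  y_beam <- p$origin_mm[2] + ext[2] / 2 + beam$shift_cm[1] * 10
  z_mid <- p$origin_mm[3] + ext[3] / 2
  zs <- z_mid + (seq_len(n_rows) - (n_rows + 1) / 2) * DET_FACE_MM
  g <- expand.grid(col = seq_along(ang), row = seq_len(n_rows))
  cx <- r_det * cos(ang[g$col])
  cy <- r_det * sin(ang[g$col]) + p$origin_mm[2] + ext[2] / 2
  cz <- zs[g$row]
  r_env <- beam$width_cm * 10 / 2 +
    (if (beam$mode == "wobbler") beam$wobble_radius_cm * 10 else 0)
  d_axis <- sqrt((cy - y_beam)^2 + (cz - z_beam)^2)
  df <- data.frame(col = g$col, row = g$row,
                   angle_deg = ang[g$col] * 180 / pi,
                   cx = cx, cy = cy, cz = cz,
                   nx = -cos(ang[g$col]), ny = -sin(ang[g$col]), nz = 0,
                   excluded = d_axis < r_env + exclusion_cm * 10,
                   stringsAsFactors = FALSE)
  new_detector_array(df, layout = list(kind = "cylinder",
                                       angular_step = angular_step,
                                       n_columns = length(ang),
                                       n_rows = n_rows,
                                       radius_cm = radius_cm,
                                       center_yz = c(
                                         p$origin_mm[2] + ext[2] / 2,
                                         z_mid)))
}

#' Select a sub-array of detectors by column / row id
#'
#' @param a A `detector_array`.
#' @param columns,rows Id vectors to keep (default: all).
#' @return A `detector_array` preserving the original order.
#' @export
select_subset <- function(a, columns = NULL, rows = NULL) {
  stopifnot(inherits(a, "detector_array"))
  if (is.null(columns)) columns <- unique(a$col)
  if (is.null(rows)) rows <- unique(a$row)
  if (!all(columns %in% a$col) || !all(rows %in% a$row))
    stop("unknown detector id in subset", call. = FALSE)
  keep <- a$col %in% columns & a$row %in% rows
  new_detector_array(as.data.frame(a)[keep, , drop = FALSE],
                     layout = c(attr(a, "layout"), list(subset = TRUE)))
}

#' Detector permutation under a phantom/beam mirror flip
#'
#' Index permutation `perm` such that `currents[perm]` is the readout of
#' the mirrored experiment: for rectangular layouts a y-(z-)flip swaps the
#' +y/-y (+z/-z) sides; for the cylindrical ring a y-flip maps column
#' angle a to -a and a z-flip reverses the row order.
#'
#' @param a A `detector_array`.
#' @param axis `"y"` or `"z"`.
#' @return Integer permutation of `seq_len(nrow(a))`.
#' @export
flip_permutation <- function(a, axis = c("y", "z")) {
  axis <- match.arg(axis)
  layout <- attr(a, "layout")
  key <- if (layout$kind == "rect") {
    side2 <- a$side
    if (axis == "y") {
      side2[a$side == "+y"] <- "-y"; side2[a$side == "-y"] <- "+y"
    } else {
      side2[a$side == "+z"] <- "-z"; side2[a$side == "-z"] <- "+z"
    }
    paste(a$col, side2)
  } else {
    nc <- layout$n_columns; nr <- layout$n_rows
    if (axis == "y") paste((nc - a$col + 1L) %% nc + 1L, a$row)
    else paste(a$col, nr - a$row + 1L)
  }
  ref <- if (layout$kind == "rect") paste(a$col, a$side)
         else paste(a$col, a$row)
  perm <- match(key, ref)
  if (anyNA(perm))
    stop("layout has no flip-symmetric counterpart along ", axis,
         call. = FALSE)
  perm
}

#' Serialize a detector layout to JSON
#'
#' @param a A `detector_array`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detector_layout <- function(a, path) {
  jsonlite::write_json(
    list(layout = attr(a, "layout"),
         detectors = as.data.frame(a)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
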