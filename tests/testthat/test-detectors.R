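test_that("rectangular side arrays have the stated counts and standoff", {
  p <- build_rect_phantom(c(30, 20, 20), voxel_mm = 5)
  a2 <- place_detectors_rect(p, 24, c("+y", "-y"))
  a4 <- place_detectors_rect(p, 24, c("+y", "-y", "+z", "-z"))
  expect_equal(nrow(a2), 48)
  expect_equal(nrow(a4), 96)
  # every center sits exactly 10 mm outside the nearest phantom face
  ext <- dim(p$density) * p$voxel_mm
  d_y <- pmin(abs(a4$cy - (ext[2] + 10)), abs(a4$cy + 10))
  d_z <- pmin(abs(a4$cz - (ext[3] + 10)), abs(a4$cz + 10))
  expect_true(all(pmin(d_y, d_z) < 1e-9))
  # inward normals are unit and point at the phantom
  expect_equal(a4$nx^2 + a4$ny^2 + a4$nz^2, rep(1, 96))
  expect_true(all(a4$ny[a4$side == "+y"] == -1))
  expect_error(place_detectors_rect(p, 24, character(0)), "empty|arg")
})

test_that("detector boxes never intersect the phantom", {
  p <- build_rect_phantom(c(30, 20, 20), voxel_mm = 5)
  a <- place_detectors_rect(p, 24, c("+y", "-y", "+z", "-z"))
  ext <- dim(p$density) * p$voxel_mm
  # closest approach of each box to the phantom surface is
  # standoff - half thickness = 8.5 mm > 0
  inside <- a$cy > -8.6 & a$cy < ext[2] + 8.6 &
    a$cz > -8.6 & a$cz < ext[3] + 8.6
  expect_false(any(inside))
})

test_that("cylindrical ring: 36 columns, contiguous rows, beam exclusion", {
  set.seed(1)
  cp <- build_cylinder_phantom(20, 40, voxel_mm = 10)
  b <- beam_spec(150, shift_cm = c(0, 0), width_cm = 1, mode = "pencil")
  a <- place_detectors_cyl(cp$phantom, b, angular_step = 10,
                           n_rows = 12, radius_cm = 20)
  expect_equal(length(unique(a$col)), 36)
  expect_equal(nrow(a), 36 * 12)
  # rows stack without gaps: 12 faces of 10 mm = 120 mm of z coverage
  zs <- sort(unique(a$cz))
  expect_equal(diff(zs), rep(10, 11))
  expect_equal(max(zs) - min(zs) + 10, 120)
  # geometric exclusion oracle: center-to-beam-axis distance below
  # envelope + clearance
  ext <- dim(cp$phantom$density) * 10
  yb <- cp$phantom$origin_mm[2] + ext[2] / 2
  zb <- cp$phantom$origin_mm[3] + ext[3] / 2
  d_axis <- sqrt((a$cy - yb)^2 + (a$cz - zb)^2)
  expect_identical(a$excluded, d_axis < 5 + 20)
  expect_true(any(a$excluded))
  # excluded columns sit symmetrically about the beam axis
  exc <- sort(unique(a$col[a$excluded]))
  mirrored <- sort(unique(as.integer((36 - a$col[a$excluded] + 1L) %%
                                       36 + 1L)))
  expect_identical(exc, mirrored)
  expect_error(place_detectors_cyl(cp$phantom, b, angular_step = 7),
               "divide")
})

test_that("subset selection preserves order and validates ids", {
  p <- build_rect_phantom(c(30, 20, 20), voxel_mm = 5)
  a <- place_detectors_rect(p, 24, c("+y", "-y"))
  expect_equal(nrow(select_subset(a)), nrow(a))
  half <- select_subset(a, columns = seq(1, 24, by = 2))
  expect_equal(nrow(half), 24)
  expect_true(all(diff(match(paste(half$col, half$row),
                             paste(a$col, a$row))) > 0))
  expect_error(select_subset(a, columns = 99), "unknown")
  # ring: 36 -> 18 columns and 12 -> 6 rows by alternating decimation
  set.seed(1)
  cp <- build_cylinder_phantom(20, 40, voxel_mm = 10)
  b <- beam_spec(150, width_cm = 1)
  ring <- place_detectors_cyl(cp$phantom, b, radius_cm = 20)
  expect_equal(length(unique(select_subset(
    ring, columns = seq(1, 36, by = 2))$col)), 18)
  expect_equal(length(unique(select_subset(
    ring, rows = seq(1, 12, by = 2))$row)), 6)
})

test_that("flip permutations mirror detector geometry and are involutions", {
  p <- build_rect_phantom(c(30, 20, 20), voxel_mm = 5)
  a <- place_detectors_rect(p, 24, c("+y", "-y", "+z", "-z"))
  ext <- dim(p$density) * p$voxel_mm
  for (ax in c("y", "z")) {
    perm <- flip_permutation(a, ax)
    expect_identical(perm[perm], seq_len(nrow(a)))
    # mirrored centers coincide with the permuted detector's center
    cc <- if (ax == "y") a$cy else a$cz
    mirrored <- ext[if (ax == "y") 2 else 3] - cc
    expect_equal(mirrored, cc[perm], tolerance = 1e-9)
  }
  set.seed(1)
  cp <- build_cylinder_phantom(20, 40, voxel_mm = 10)
  ring <- place_detectors_cyl(cp$phantom, beam_spec(150, width_cm = 1),
                              radius_cm = 20)
  for (ax in c("y", "z")) {
    perm <- flip_permutation(ring, ax)
    expect_identical(perm[perm], seq_len(nrow(ring)))
  }
  yc <- cp$phantom$origin_mm[2] + dim(cp$phantom$density)[2] * 10 / 2
  py <- flip_permutation(ring, "y")
  expect_equal(ring$cy[py] - yc, -(ring$cy - yc), tolerance = 1e-9)
})

test_that("beam sampling honors spot geometry and the wobbler degenerate case", {
  p <- build_rect_phantom(c(30, 20, 20), voxel_mm = 5)
  b <- beam_spec(200, shift_cm = c(2, 0), width_cm = 1,
                 n_protons = 5000)
  set.seed(8)
  s <- sample_initial_proton(b, p)
  r <- sqrt((s$y - 120)^2 + (s$z - 100)^2)
  expect_true(all(r <= 5 + 1e-9))
  # Monte Carlo mean entry point within 3 sigma of the configured center
  se <- 5 / 2 / sqrt(5000)  # sd of a uniform disc radius ~ r/2
  expect_lt(abs(mean(s$y) - 120), 3 * se * 2)
  expect_lt(abs(mean(s$z) - 100), 3 * se * 2)
  # wobbler with zero wobble radius degenerates to the pencil beam
  bw <- beam_spec(200, shift_cm = c(2, 0), width_cm = 1,
                  mode = "wobbler", n_protons = 5000,
                  wobble_radius_cm = 0)
  set.seed(8)
  sw <- sample_initial_proton(bw, p)
  expect_equal(sw[, c("y", "z")], s[, c("y", "z")])
  # a true wobbler spreads entries beyond the pencil disc
  bw2 <- beam_spec(200, width_cm = 1, mode = "wobbler",
                   n_protons = 2000)
  set.seed(8)
  s2 <- sample_initial_proton(bw2, p)
  expect_gt(max(sqrt((s2$y - 100)^2 + (s2$z - 100)^2)), 5)
})
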