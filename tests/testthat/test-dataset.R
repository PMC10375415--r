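test_that("split fractions land on 64/16/20 with documented rounding", {
  set.seed(1)
  s100 <- split_dataset(100)
  expect_equal(lengths(s100)[c("train", "val", "test")],
               c(train = 64, val = 16, test = 20))
  s10 <- split_dataset(10)
  expect_equal(unname(lengths(s10)), c(6, 2, 2))
  # disjoint and exhaustive
  all_idx <- sort(c(s100$train, s100$val, s100$test))
  expect_identical(all_idx, 1:100)
  set.seed(77); a <- split_dataset(50)
  set.seed(77); b <- split_dataset(50)
  expect_identical(a, b)
  expect_error(split_dataset(3), "n >= 5")
})

test_that("dataset generation is reproducible and respects parameter ranges", {
  set.seed(5)
  d1 <- tiny_dataset(n = 3)
  set.seed(5)
  d2 <- tiny_dataset(n = 3)
  expect_identical(d1$samples, d2$samples)
  en <- vapply(d1$samples, function(s) s$meta$energy, numeric(1))
  expect_true(all(en >= 70 & en <= 110))
  set.seed(6)
  dc <- tiny_dataset(n = 2, family = "C")
  wd <- vapply(dc$samples, function(s) s$meta$width, numeric(1))
  expect_true(all(wd >= 1 & wd <= 2))
  expect_false(is.null(dc$samples[[1]]$ct))
  ns <- vapply(dc$samples, function(s) s$meta$n_structures, numeric(1))
  expect_true(all(ns %in% 3:6))
  # currents are non-negative and fixed-length across samples
  lens <- vapply(d1$samples, function(s) length(s$currents), numeric(1))
  expect_true(all(lens == lens[1]))
  expect_true(all(vapply(d1$samples,
                         function(s) all(s$currents >= 0), logical(1))))
  # runtime persistence round-trip
  path <- tempfile(fileext = ".rds")
  save_dataset(d1, path)
  expect_identical(load_dataset(path)$samples, d1$samples)
  unlink(path)
})

test_that("flip augmentation doubles family A and permutes currents exactly", {
  set.seed(9)
  ds <- tiny_dataset(n = 4)
  aug <- augment_flips(ds, 1:3)
  expect_length(aug, 6)
  perm <- flip_permutation(ds$detectors, "y")
  for (i in 1:3) {
    expect_equal(aug[[i + 3]]$currents, aug[[i]]$currents[perm])
    expect_equal(aug[[i + 3]]$target,
                 aug[[i]]$target[, rev(seq_len(ncol(aug[[i]]$target)))],
                 ignore_attr = TRUE)
    expect_equal(aug[[i + 3]]$meta$shift[1], -aug[[i]]$meta$shift[1])
  }
  # flipping twice restores the original sample
  tw <- protorec:::flip_sample(
    protorec:::flip_sample(ds$samples[[1]], ds$detectors, "y", "A"),
    ds$detectors, "y", "A")
  expect_equal(tw$currents, ds$samples[[1]]$currents)
  expect_equal(tw$target, ds$samples[[1]]$target, ignore_attr = TRUE)
})

test_that("families B and C gain y, z and combined flips as configured", {
  set.seed(10)
  db <- tiny_dataset(n = 2, family = "B")
  expect_length(augment_flips(db, 1:2), 6)          # y + z
  expect_length(augment_flips(db, 1:2, "y"), 4)
  set.seed(11)
  dc <- tiny_dataset(n = 2, family = "C")
  aug <- augment_flips(dc, 1:2)                      # y + z + yz
  expect_length(aug, 8)
  # 3D targets and density grids mirror together
  zflip <- aug[[5]]                                  # z-flip of sample 1
  d3 <- dim(dc$samples[[1]]$target)
  expect_equal(as.numeric(zflip$target),
               as.numeric(dc$samples[[1]]$target[, , d3[3]:1]))
  expect_equal(as.numeric(zflip$ct),
               as.numeric(dc$samples[[1]]$ct[, , d3[3]:1]))
  # test samples passed explicitly are the only ones augmented
  expect_length(augment_flips(dc, 1L), 4)
})

test_that("augmentation never leaks into a held-out index set", {
  set.seed(3)
  ds <- tiny_dataset(n = 6)
  sp <- split_dataset(length(ds$samples))
  aug <- augment_flips(ds, c(sp$train, sp$val))
  test_currents <- lapply(ds$samples[sp$test], function(s) s$currents)
  for (a in aug)
    for (tc in test_currents)
      expect_false(isTRUE(all.equal(a$currents, tc)))
})

test_that("normalization constants come from training statistics only", {
  set.seed(4)
  ds <- tiny_dataset(n = 5)
  mats <- protorec:::dataset_matrices(ds$samples[1:3])
  norms <- protorec:::fit_normalization(mats)
  expect_equal(norms$current_scale,
               unname(quantile(mats$X, 0.99)))
  expect_equal(norms$dose_max, max(mats$Y))
  # targets map into [-1, 1] and invert exactly
  Tn <- protorec:::normalize_targets(mats$Y, norms)
  expect_true(all(Tn >= -1 & Tn <= 1))
  expect_equal(protorec:::denormalize_targets(Tn, norms), mats$Y,
               tolerance = 1e-12)
})

test_that("grid pooling averages non-overlapping blocks", {
  g <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  pg <- protorec:::pool_grid(g, 2L)
  expect_equal(dim(pg), c(2, 2, 1))
  expect_equal(pg[1, 1, 1], mean(g[1:2, 1:2, 1:2]))
  expect_identical(protorec:::pool_grid(g, 1L), g)
})
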