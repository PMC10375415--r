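test_that("peak position: delta grids, mirror symmetry, tie breaking", {
  g <- array(0, c(5, 4, 3))
  g[4, 2, 3] <- 7
  expect_equal(peak_position(g, voxel_mm = 5), c(17.5, 7.5, 12.5))
  # y-flip mirrors the y coordinate
  gf <- g[, 4:1, ]
  expect_equal(peak_position(gf, voxel_mm = 5)[2], 4 * 5 - 7.5)
  # two-way tie resolves to the smaller flat index, stably
  t2 <- array(0, c(4, 4, 1))
  t2[2, 2, 1] <- 1; t2[3, 3, 1] <- 1
  for (i in 1:3)
    expect_equal(peak_position(t2, voxel_mm = 1), c(1.5, 1.5, 0.5))
  expect_error(peak_position(array(0, c(2, 2, 2))), "all-zero")
})

test_that("peak errors match a brute-force argmax scan", {
  expect_equal(unname(peak_errors(array(1:24, c(4, 3, 2)),
                                  array(1:24, c(4, 3, 2)),
                                  voxel_mm = 2)), c(0, 0, 0))
  a <- array(0, c(10, 6, 1)); a[3, 4, 1] <- 1
  b <- array(0, c(10, 6, 1)); b[5, 4, 1] <- 1
  expect_equal(peak_errors(a, b, voxel_mm = 5)[["dx"]], 10)
  expect_equal(peak_errors(a, b, voxel_mm = 5)[["dy"]], 0)
  set.seed(31)
  for (k in 1:20) {
    mc <- array(stats::runif(60), c(5, 4, 3))
    dl <- array(stats::runif(60), c(5, 4, 3))
    i1 <- arrayInd(order(-as.numeric(mc))[1], dim(mc))
    i2 <- arrayInd(order(-as.numeric(dl))[1], dim(dl))
    expect_equal(unname(peak_errors(mc, dl, voxel_mm = 3)),
                 abs(as.numeric(i1 - i2)) * 3)
  }
  expect_error(peak_errors(array(1, c(2, 2)), array(1, c(3, 3))),
               "lattice")
})

test_that("delta_dose: normalization, single-voxel case, brute force", {
  mc <- array(stats::runif(48) + 0.5, c(4, 4, 3))
  expect_equal(delta_dose(mc, mc), 0)
  # after normalization, a one-voxel 1 Gy difference gives exactly 1
  mcn <- mc * (100 / sum(mc))
  dln <- mcn; dln[2, 3, 1] <- dln[2, 3, 1] + 1
  expect_equal(delta_dose(mcn, dln), 1)
  # independent double-loop accumulation oracle
  set.seed(17)
  dl <- array(stats::runif(48), c(4, 4, 3))
  acc <- 0
  s <- 100 / sum(mc)
  for (i in 1:4) for (j in 1:4) for (k in 1:3)
    acc <- acc + (s * mc[i, j, k] - s * dl[i, j, k])^2
  expect_equal(delta_dose(mc, dl), sqrt(acc), tolerance = 1e-10)
  # invariant under a common positive rescaling of both inputs
  expect_equal(delta_dose(3.7 * mc, 3.7 * dl), delta_dose(mc, dl))
  expect_error(delta_dose(mc * 0, dl), "zero")
})

# unrestricted brute-force gamma for the oracle comparisons
brute_gamma <- function(ref, eval, voxel, dose_pct, dist_mm) {
  s <- 100 / sum(ref)
  r <- s * ref; e <- s * eval
  dD <- dose_pct / 100 * max(r)
  d3 <- c(dim(ref), rep(1, 3 - length(dim(ref))))
  idx <- as.matrix(expand.grid(x = seq_len(d3[1]), y = seq_len(d3[2]),
                               z = seq_len(d3[3])))
  ev <- as.numeric(e)
  out <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    d2 <- colSums((t(idx) - idx[i, ])^2) * voxel^2
    out[i] <- sqrt(min((ev - as.numeric(r)[i])^2 / dD^2 +
                         d2 / dist_mm^2))
  }
  array(out, dim(ref))
}

test_that("gamma map equals unrestricted brute-force minimization", {
  set.seed(23)
  for (rep in 1:3) {
    ref <- array(stats::runif(7^3), c(7, 7, 7))
    ev <- ref * (1 + stats::rnorm(7^3, sd = 0.05)) +
      stats::runif(7^3, 0, 0.02)
    g1 <- gamma_map(ref, ev, gamma_criteria(3, 3), voxel_mm = 2)
    g2 <- brute_gamma(ref, ev, 2, 3, 3)
    expect_equal(as.numeric(g1), pmin(as.numeric(g2), g1),
                 tolerance = 1e-12)
    # identical wherever gamma < 2 (the passing decision region)
    sel <- g2 < 2
    expect_equal(as.numeric(g1)[sel], as.numeric(g2)[sel],
                 tolerance = 1e-12)
    expect_identical(as.numeric(g1) < 1, as.numeric(g2) < 1)
  }
  # 2D slabs follow the same contract
  ref2 <- matrix(stats::runif(9 * 9) + 0.2, 9, 9)
  ev2 <- ref2 + stats::rnorm(81, sd = 0.03)
  g1 <- gamma_map(ref2, ev2, gamma_criteria(3, 3), voxel_mm = 2)
  g2 <- brute_gamma(ref2, ev2, 2, 3, 3)
  sel <- g2 < 2
  expect_equal(as.numeric(g1)[sel], as.numeric(g2)[sel],
               tolerance = 1e-12)
})

test_that("gamma criteria semantics: offsets, strictness, asymmetry", {
  ref <- array(1, c(6, 6, 1)) + array(stats::runif(36, 0, 1e-9), c(6, 6, 1))
  ref[3, 3, 1] <- 2    # peak voxel fixes the global maximum
  expect_true(all(gamma_map(ref, ref) == 0))
  expect_equal(gamma_passing_rate(gamma_map(ref, ref)), 100)
  # uniform 2.9%-of-max offset on flat fields: every neighbour carries
  # the same dose, so the minimum is the pure dose term 2.9/3
  flat <- array(1, c(5, 5, 1))
  up <- flat * (1 + 0.029)
  gg <- gamma_map(flat, up, gamma_criteria(3, 3), voxel_mm = 5)
  expect_equal(max(gg), 0.029 / 0.03, tolerance = 1e-9)
  expect_equal(gamma_passing_rate(gg), 100)
  # exactly 3% offset sits at gamma = 1 and fails the strict test
  up3 <- flat * 1.03
  g3 <- gamma_map(flat, up3, gamma_criteria(3, 3), voxel_mm = 5)
  expect_equal(min(g3), 1, tolerance = 1e-12)
  expect_equal(gamma_passing_rate(g3), 0)
  # gamma is not symmetric in (reference, evaluated)
  a <- array(stats::runif(27, 1, 2), c(3, 3, 3))
  b <- a; b[1, 1, 1] <- 4
  expect_false(isTRUE(all.equal(gamma_map(a, b), gamma_map(b, a))))
  expect_error(gamma_passing_rate(gamma_map(a, b),
                                  mask = array(FALSE, c(3, 3, 3))),
               "mask")
})

test_that("evaluation reports aggregate per-sample metrics consistently", {
  set.seed(12)
  ds <- tiny_dataset(n = 6)
  sp <- split_dataset(ds, c(0.5, 0.2, 0.3))
  s1 <- ds$samples[[1]]
  m <- build_model(model_config(encoder_hidden = 16, latent = 16,
                                decoder_hidden = 16, epochs = 3),
                   length(s1$currents), length(s1$target),
                   dim(s1$target))
  m <- train_model(m, ds$samples[sp$train], ds$samples[sp$val])
  rep <- evaluate_testset(m, ds, sp$test)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$per_sample), length(sp$test))
  # aggregates recomputed from the per-sample table match the summary
  expect_equal(rep$summary$dx_peak,
               c(mean(rep$per_sample$dx_peak),
                 stats::sd(rep$per_sample$dx_peak),
                 min(rep$per_sample$dx_peak),
                 max(rep$per_sample$dx_peak)))
  # report round-trips through CSV/JSON
  prefix <- file.path(tempdir(), "report")
  write_eval_report(rep, prefix)
  back <- read_eval_report(prefix)
  expect_equal(back$per_sample$gamma_pass, rep$per_sample$gamma_pass)
  expect_equal(back$summary$dx_peak, rep$summary$dx_peak)
  unlink(paste0(prefix, c("_per_sample.csv", "_summary.json")))
})
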