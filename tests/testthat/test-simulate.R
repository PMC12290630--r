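test_that("truth maps encode the variance-ratio ICC", {
  tb <- simulate_dataset(simulation_spec(n_subjects = 10, grid_dims = c(4, 4, 4),
                                         sigma2_between = 1, sigma2_within = 1,
                                         seed = 1))
  expect_equal(unique(na.omit(as.vector(tb$true_icc3))), 0.5)
  expect_equal(unique(na.omit(as.vector(tb$true_bs))), 1)
  expect_equal(unique(na.omit(as.vector(tb$true_ws))), 1)
})

test_that("zero noise makes occasions identical up to bias, ICC(3,1) = 1", {
  tb <- simulate_dataset(simulation_spec(n_subjects = 8, grid_dims = c(3, 3, 3),
                                         sigma2_within = 0,
                                         occasion_bias = c(0, 2), seed = 2))
  diff <- tb$volumes$occasions[[2]] - tb$volumes$occasions[[1]]
  expect_equal(unique(round(as.vector(diff), 10)), 2)
  maps <- voxelwise_icc(tb$volumes, tb$mask, "icc_3")
  expect_equal(as.vector(maps$estimate), rep(1, 27))
})

test_that("masked-median ICC(3,1) recovers the generative ratio at n = 200", {
  tb <- simulate_dataset(simulation_spec(n_subjects = 200, grid_dims = c(6, 6, 6),
                                         sigma2_between = 3, sigma2_within = 2,
                                         seed = 31))
  maps <- voxelwise_icc(tb$volumes, tb$mask, "icc_3")
  expect_lt(abs(masked_median(maps$estimate, tb$mask) - 0.6), 0.05)
})

test_that("datasets are deterministic given the seed", {
  s <- simulation_spec(n_subjects = 6, grid_dims = c(3, 3, 3), seed = 123)
  t1 <- simulate_dataset(s)
  t2 <- simulate_dataset(s)
  expect_identical(t1$volumes$occasions, t2$volumes$occasions)
  expect_identical(unclass(t1$supra_mask), unclass(t2$supra_mask))
})

test_that("occasion bias lowers agreement but not consistency", {
  base <- simulation_spec(n_subjects = 80, grid_dims = c(4, 4, 4),
                          sigma2_between = 1, sigma2_within = 1, seed = 55)
  biased <- simulation_spec(n_subjects = 80, grid_dims = c(4, 4, 4),
                            sigma2_between = 1, sigma2_within = 1,
                            occasion_bias = c(0, 3), seed = 55)
  m0 <- voxelwise_icc(simulate_dataset(base)$volumes, full_mask(c(4, 4, 4)), "icc_3")
  m1 <- voxelwise_icc(simulate_dataset(biased)$volumes, full_mask(c(4, 4, 4)), "icc_3")
  # same seed => same fields; consistency unchanged by the shift
  expect_equal(m1$estimate, m0$estimate, tolerance = 1e-9)
  a0 <- voxelwise_icc(simulate_dataset(base)$volumes, full_mask(c(4, 4, 4)), "icc_2")
  a1 <- voxelwise_icc(simulate_dataset(biased)$volumes, full_mask(c(4, 4, 4)), "icc_2")
  expect_lt(masked_median(a1$estimate, full_mask(c(4, 4, 4))),
            masked_median(a0$estimate, full_mask(c(4, 4, 4))))
})

test_that("make_masks produces disjoint, covering, reproducible masks", {
  mk <- make_masks(c(10, 10, 10), supra_fraction = 0.25, seed = 6)
  expect_equal(sum(mk$supra), 250)
  expect_equal(sum(mk$sub), 750)
  expect_false(any(mk$supra & mk$sub))
  expect_true(all(mk$supra | mk$sub))
  mk2 <- make_masks(c(10, 10, 10), supra_fraction = 0.25, seed = 6)
  expect_identical(unclass(mk$supra), unclass(mk2$supra))
  expect_error(make_masks(c(4, 4, 4), supra_fraction = 1), "strictly between")
})

test_that("worked-example volume set matches the printed vectors", {
  vs <- worked_example_volumes(c(4, 4, 4))
  expect_equal(vs_dims <- vs$grid$dims, c(4L, 4L, 4L))
  expect_equal(relimap:::vs_n_subjects(vs), 5L)
  expect_equal(relimap:::vs_k_occasions(vs), 2L)
  expect_equal(voxel_matrix(vs, 1)[, 1], c(1, 3, 6, 9, 12))
  expect_equal(voxel_matrix(vs, 1)[, 2], 3 * c(1, 3, 6, 9, 12))
  # occasion means across subjects correlate perfectly
  o1 <- sapply(1:5, function(i) mean(vs$occasions[[1]][, , , i]))
  o2 <- sapply(1:5, function(i) mean(vs$occasions[[2]][, , , i]))
  expect_equal(pearson_r(o1, o2), 1.0)
})

test_that("spatial smoothing approximately preserves marginal variances", {
  tb <- simulate_dataset(simulation_spec(n_subjects = 150, grid_dims = c(8, 8, 8),
                                         sigma2_between = 2, sigma2_within = 1,
                                         smooth_fwhm = 2, seed = 14))
  maps <- voxelwise_icc(tb$volumes, tb$mask, "icc_3")
  med_bs <- masked_median(maps$between_subject_var, tb$mask)
  med_ws <- masked_median(maps$within_subject_var, tb$mask)
  # smoothing correlates voxels but the per-voxel variances stay near truth
  expect_lt(abs(med_bs - 2) / 2, 0.25)
  expect_lt(abs(med_ws - 1) / 1, 0.25)
})

test_that("invalid specifications are rejected", {
  expect_error(simulation_spec(n_subjects = 1), "at least 2")
  expect_error(simulation_spec(grid_dims = c(4, 4)), "3 integers")
  expect_error(simulation_spec(sigma2_between = -1), ">= 0")
  expect_error(simulation_spec(mask_fraction = 0), "\\(0, 1\\]")
  expect_error(simulation_spec(occasion_bias = c(0, 0, 0)), "per occasion")
})
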