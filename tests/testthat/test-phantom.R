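test_that("identical spec and seed reproduce the phantom bit-identically", {
  spec <- phantom_spec(grid_shape = c(64L, 64L, 64L), n_vessel_trees = 1L,
                       n_adipocytes = 5L, adipocyte_diameter_mean_um = 20,
                       adipocyte_diameter_sd_um = 2, seed = 12L)
  g1 <- generate_cect_phantom(spec)
  g2 <- generate_cect_phantom(spec)
  expect_identical(g1$volume$data, g2$volume$data)
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$truth, g2$truth)
})

test_that("rasterized roles are pairwise disjoint and volumes consistent", {
  spec <- phantom_spec(grid_shape = c(80L, 80L, 80L), n_vessel_trees = 1L,
                       n_adipocytes = 8L, seed = 3L)
  g <- generate_cect_phantom(spec)
  lab <- g$labels
  # label codes partition the grid by construction; verify the counts
  expect_equal(sum(lab == 2L) * 8, g$truth$true_vessel_volume_um3)
  expect_equal(sum(lab == 3L) * 8, g$truth$true_adipocyte_volume_um3)
  expect_equal(sum(lab == 1L) * 8, g$truth$true_bone_volume_um3)
  expect_equal((length(lab) - sum(lab == 1L)) * 8,
               g$truth$true_marrow_volume_um3)
})

test_that("an empty phantom is pure marrow with zero vessel volume", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 32L), n_vessel_trees = 0L,
                       n_adipocytes = 0L, scaffold_fraction = 0.2, seed = 1L)
  g <- generate_cect_phantom(spec)
  expect_equal(g$truth$true_vessel_volume_um3, 0)
  expect_equal(g$truth$true_branch_count, 0L)
  expect_true(all(g$labels %in% c(0L, 1L)))
})

test_that("a straight tube rasterizes to the analytic capsule voxel count", {
  g <- generate_cect_phantom(straight_tube_spec())
  # brute-force membership in the capsule from (15,40,40) to (65,40,40), r = 5
  a <- array(FALSE, c(80, 80, 80))
  xs <- slice.index(a, 1); ys <- slice.index(a, 2); zs <- slice.index(a, 3)
  t <- pmin(pmax((xs - 15) / 50, 0), 1)
  d2 <- (xs - (15 + 50 * t))^2 + (ys - 40)^2 + (zs - 40)^2
  expect_identical(g$labels == 2L, array(d2 <= 25 + 1e-9, dim(a)))
  expect_identical(g$truth$true_branch_count, 1L)
  expect_identical(g$truth$true_junction_count, 0L)
})

test_that("rasterized sphere volumes approach the analytic volume", {
  for (dvox in c(10, 14, 20)) {
    lab <- array(0L, c(dvox + 8L, dvox + 8L, dvox + 8L))
    n <- osteovasc:::cpp_fill_sphere(lab, dim(lab),
                                     rep((dvox + 8) / 2, 3), dvox / 2, 1L, 0L)
    analytic <- 4 / 3 * pi * (dvox / 2)^3
    expect_lt(abs(n - analytic) / analytic, 0.05)
  }
})

test_that("infeasible adipocyte packing fails naming the achieved count", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 32L), n_vessel_trees = 0L,
                       scaffold_fraction = 0, n_adipocytes = 60L,
                       adipocyte_diameter_mean_um = 30,
                       adipocyte_diameter_sd_um = 1, seed = 2L)
  expect_error(generate_cect_phantom(spec), "placed \\d+ of 60")
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(vessel_radius_range_um = c(1, 10)),
               "below one voxel")
  bad <- c(background = 1, marrow = 1, adipocyte_interior = 5,
           adipocyte_rim = 4, vessel = 3, bone = 9)
  expect_error(phantom_spec(intensity_levels = bad), "contrast ordering")
})

test_that("IF sections paint the requested overlap with exact ground truth", {
  r <- generate_if_section(overlap_fraction = 0.4, snr = 10, seed = 5)
  tr <- r$truth
  # pixel-exact bookkeeping on the noiseless label masks
  roi <- osteovasc:::.roi_mask(r$section)
  expect_equal(sum(tr$cd31_label & tr$emcn_label & roi) / sum(roi),
               tr$true_if_overlap_fraction)
  # within one blob of the target
  expect_gte(tr$true_if_overlap_fraction, 0.4)
  expect_lt(tr$true_if_overlap_fraction, 0.4 + pi * 18^2 / tr$roi_area_px)
  # identity and empty-intersection extremes
  full <- generate_if_section(overlap_fraction = 1, snr = 10, seed = 5)
  expect_identical(full$truth$cd31_label, full$truth$emcn_label)
  none <- generate_if_section(overlap_fraction = 0, snr = 10, seed = 5)
  expect_equal(sum(none$truth$cd31_label & none$truth$emcn_label), 0)
  expect_error(generate_if_section(snr = 0), "snr")
})

test_that("LDF traces carry the prescribed slope and baseline", {
  flat <- generate_ldf_trace(30, 32, 10, 0, 0, seed = 1)
  expect_true(all(flat$perfusion_pu == 10))
  ramp <- generate_ldf_trace(1800, 2, 10, 1, 0, seed = 1)
  expect_equal(tail(ramp$perfusion_pu, 1) - ramp$perfusion_pu[1],
               (1800 - 0.5) / 60, tolerance = 1e-9)
  noisy <- generate_ldf_trace(1800, 4, 40, -0.5, 0.2, seed = 3)
  sl <- trace_slope(noisy)
  expect_lt(abs(sl$slope_pu_per_min - (-0.5)), 3 * sl$se_pu_per_min)
  expect_error(generate_ldf_trace(0, 10, 10), "duration_s")
})
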