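test_that("volume fractions are exact set arithmetic", {
  marrow <- binary_mask(array(TRUE, c(10, 10, 10)), 2, "marrow")
  expect_equal(volume_fraction(marrow, marrow), 100)
  empty <- binary_mask(array(FALSE, c(10, 10, 10)), 2, "vessel")
  expect_equal(volume_fraction(empty, marrow), 0)
  expect_error(volume_fraction(marrow, empty), "empty marrow")
})

test_that("component census counts, densities and equivalent diameters", {
  # one voxel at 2 um: d = (6 * 8 / pi)^(1/3)
  a <- array(FALSE, c(8, 8, 8)); a[4, 4, 4] <- TRUE
  cen <- component_census(binary_mask(a, 2, "adipocyte"), 1)
  expect_equal(cen$equivalent_diameters_um, (6 * 8 / pi)^(1 / 3))
  # 20 disjoint single-voxel components in 4 mm^3 -> 5 per mm^3
  b <- array(FALSE, c(41, 41, 41))
  b[seq(1, 39, 2), 1, 1] <- TRUE
  cen2 <- component_census(binary_mask(b, 2, "adipocyte"), 4)
  expect_equal(cen2$count, 20)
  expect_equal(cen2$density_per_mm3, 5)
  # merged touching spheres count once, diameter from summed volume
  cc <- array(FALSE, c(30, 20, 20))
  xs <- slice.index(cc, 1); ys <- slice.index(cc, 2); zs <- slice.index(cc, 3)
  s1 <- (xs - 10)^2 + (ys - 10)^2 + (zs - 10)^2 <= 16
  s2 <- (xs - 17)^2 + (ys - 10)^2 + (zs - 10)^2 <= 16
  cc <- s1 | s2
  cen3 <- component_census(binary_mask(cc, 2, "adipocyte"), 1)
  expect_equal(cen3$count, length(igraph_components(cc)))
  expect_equal(cen3$equivalent_diameters_um,
               (6 * sum(cc) * 8 / pi)^(1 / 3))
})

test_that("local thickness of slabs is exactly the slab width", {
  for (w in c(3, 4, 7, 10)) {
    a <- array(FALSE, c(24, 24, w + 10))
    a[, , 6:(5 + w)] <- TRUE
    tm <- local_thickness(binary_mask(a, 2))
    interior <- tm$data[8:16, 8:16, 6:(5 + w)]
    expect_equal(unique(as.numeric(interior)), w * 2)   # um at 2 um voxels
  }
})

test_that("local thickness matches the exhaustive inscribed-sphere oracle", {
  set.seed(13)
  a <- array(FALSE, c(12, 12, 12))
  a[3:9, 3:9, 4:8] <- TRUE
  a[5:7, 5:7, 8:10] <- TRUE         # a blocky protrusion
  tm <- local_thickness(binary_mask(a, 1))
  oracle <- bf_local_thickness(a)
  expect_equal(tm$data, oracle, tolerance = 1e-6)
})

test_that("dilating a mask never decreases local thickness", {
  gen <- tree_phantom(2, grid = 64L)
  v <- vessel_mask_from(gen)
  t1 <- local_thickness(v)
  t2 <- local_thickness(ball_dilate(v, 1))
  fg <- v$data
  expect_true(all(t2$data[fg] >= t1$data[fg] - 1e-9))
})

test_that("thickness histograms follow the printed bin conventions", {
  # a cylinder of 24 um modal thickness lands in the [22,26) bin
  cyl <- make_cylinder(6, 30)
  tm <- local_thickness(cyl)
  h <- thickness_histogram(tm)
  modal_bin <- which.max(h$weight_pct)
  expect_equal(h$lower_um[modal_bin], 22)
  expect_equal(sum(h$weight_pct), 100)
  # refinement consistency: merging adjacent bins sums their weights
  h2 <- thickness_histogram(tm, c(seq(2, 66, by = 8), Inf))
  merged <- sapply(seq(1, 16, by = 2), function(i)
    h$weight_pct[i] + h$weight_pct[i + 1])
  expect_equal(h2$weight_pct[1:8], merged)
  expect_error(thickness_histogram(tm, c(10, 5)), "ascending")
})

test_that("two equal-volume thickness populations split 50/50", {
  # modal thicknesses of an 8-um and a 70-um cylinder, weighted equally
  modal <- function(tm) {
    v <- round(tm$data[tm$data > 0], 6)
    as.numeric(names(sort(table(v), decreasing = TRUE))[1])
  }
  m8 <- modal(local_thickness(make_cylinder(2, 30)))
  m70 <- modal(local_thickness(make_cylinder(17.5, 44)))
  h <- thickness_histogram(c(rep(m8, 600), rep(m70, 600)))
  expect_equal(h$weight_pct[h$lower_um == 6], 50)
  expect_equal(h$weight_pct[h$lower_um == 66], 50)
})

test_that("thickness is invariant under axis permutation", {
  gen <- tree_phantom(3, grid = 64L)
  a <- gen$labels == 2L
  t1 <- local_thickness(binary_mask(a, 2))
  t2 <- local_thickness(binary_mask(aperm(a, c(3, 1, 2)), 2))
  expect_equal(sort(t1$data[t1$data > 0]), sort(t2$data[t2$data > 0]))
})

test_that("mean vessel thickness equals the volume-weighted map mean", {
  gen <- tree_phantom(4, grid = 64L)
  v <- vessel_mask_from(gen)
  marrow <- binary_mask(array(TRUE, dim(v$data)), 2, "marrow")
  adip <- binary_mask(array(FALSE, dim(v$data)), 2, "adipocyte")
  m <- morphometry(marrow, adip, v)
  tm <- local_thickness(v)
  expect_equal(m$mean_vessel_thickness_um, mean(tm$data[tm$data > 0]))
})
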