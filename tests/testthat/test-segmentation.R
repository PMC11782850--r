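test_that("VOI selection crops the exact slice range", {
  vol <- image_volume(array(0, c(4, 4, 1000)), 2)
  v <- select_voi(vol, voi_spec(100, 1600))
  expect_equal(dim(v$data)[3], 800)                 # 1.6 mm at 2 um voxels
  v2 <- select_voi(vol, voi_spec(1, 2000))
  expect_equal(dim(v2$data)[3], 1000)               # identity crop
  v3 <- select_voi(vol, voi_spec(1, 10))
  expect_equal(dim(v3$data)[3], 5)                  # 10 um -> 5 slices
  expect_error(select_voi(vol, voi_spec(900, 1600)), "out of bounds")
})

test_that("Otsu threshold separates well-separated modes and matches EBImage", {
  set.seed(21)
  x <- c(rnorm(4000, 20000, 500), rnorm(1000, 60000, 500))
  thr <- otsu_threshold(x)
  expect_gt(thr, 25000)
  expect_lt(thr, 55000)
  expect_error(otsu_threshold(rep(5, 100)), "degenerate")
  skip_if_not_installed("EBImage")
  # overlapping modes give a unique criterion maximum for both implementations
  set.seed(22)
  y <- c(rnorm(6000, 0.3, 0.08), rnorm(2000, 0.75, 0.08))
  y <- pmin(pmax(y, 0), 1)
  img <- matrix(y, 80, 100)
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  mine <- otsu_threshold(img, 256)
  expect_lt(abs(mine - ref), 2 / 256)   # within one histogram bin
})

test_that("bone segmentation recovers a noiseless scaffold exactly", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L), n_vessel_trees = 0L,
                       n_adipocytes = 0L, scaffold_fraction = 0.25,
                       blur_sigma_um = 0, noise_sd = 0,
                       recon_filter_sigma_um = 0, seed = 4L)
  g <- generate_cect_phantom(spec)
  seg <- segment_bone(g$volume)
  expect_identical(seg$bone$data, g$labels == 1L)
  expect_identical(seg$marrow$data, !(g$labels == 1L))
  expect_false(any(seg$bone$data & seg$marrow$data))
  expect_gt(seg$threshold, 18000)
  expect_lt(seg$threshold, 58000)
})

test_that("an all-marrow volume triggers the degenerate-histogram warning", {
  set.seed(8)
  vol <- image_volume(array(rnorm(32^3, 20000, 500), c(32, 32, 32)), 2)
  expect_warning(segment_bone(vol), "bone mode|splitting noise")
})

test_that("adipocyte segmentation recovers noiseless sphere counts exactly", {
  spec <- phantom_spec(grid_shape = c(96L, 96L, 96L), n_vessel_trees = 0L,
                       n_adipocytes = 15L, scaffold_fraction = 0,
                       adipocyte_diameter_mean_um = 28,
                       adipocyte_diameter_sd_um = 2,
                       blur_sigma_um = 0, noise_sd = 0,
                       recon_filter_sigma_um = 0, seed = 6L)
  g <- generate_cect_phantom(spec)
  # scaffold-free: the whole grid is marrow (Otsu would warn, rightly)
  marrow <- binary_mask(array(TRUE, dim(g$labels)), 2, "marrow")
  thr <- phantom_thresholds(spec)
  par <- morpho_params(adipocyte_threshold = thr$adipocyte)
  adip <- segment_adipocytes(g$volume, marrow, par)
  lab <- label_components(adip)
  expect_equal(max(lab), 15)
  # noiseless: the mask matches the painted cells up to the opening's
  # single-voxel surface smoothing
  truth <- g$labels == 3L
  expect_lt(sum(xor(adip$data, truth)) / sum(truth), 0.02)
  expect_gt(sum(adip$data & truth) / sum(truth), 0.98)
})

test_that("a 500-voxel blob is removed by the 650-voxel despeckle", {
  vol <- array(18000, c(40, 40, 40))
  xs <- slice.index(vol, 1); ys <- slice.index(vol, 2); zs <- slice.index(vol, 3)
  blob <- (xs - 20)^2 + (ys - 20)^2 + (zs - 20)^2 <= 4.9^2   # < 650 voxels
  expect_lt(sum(blob), 650)
  vol[blob] <- 5000
  v <- image_volume(vol, 2)
  marrow <- binary_mask(array(TRUE, dim(vol)), 2, "marrow")
  m <- segment_adipocytes(v, marrow, morpho_params(adipocyte_threshold = 15000))
  expect_equal(sum(m$data), 0)
})

test_that("empty marrow gives an empty adipocyte mask", {
  vol <- image_volume(array(c(5000, rep(18000, 8^3 - 1)), c(8, 8, 8)), 2)
  marrow <- binary_mask(array(FALSE, c(8, 8, 8)), 2, "marrow")
  m <- segment_adipocytes(vol, marrow, morpho_params(adipocyte_threshold = 15000))
  expect_equal(sum(m$data), 0)
})

test_that("edge suppression re-levels exactly the dilated ball", {
  vol0 <- array(18000, c(40, 40, 40))
  xs <- slice.index(vol0, 1); ys <- slice.index(vol0, 2); zs <- slice.index(vol0, 3)
  cell <- (xs - 20)^2 + (ys - 20)^2 + (zs - 20)^2 <= 10^2
  rim <- !cell & (xs - 20)^2 + (ys - 20)^2 + (zs - 20)^2 <= 12^2
  vol0[cell] <- 5000
  vol0[rim] <- 27000
  v <- image_volume(vol0, 2)
  adip <- binary_mask(cell, 2, "adipocyte")
  out <- suppress_adipocyte_edges(v, adip, morpho_params())
  region <- bf_dilate(cell, 5)                       # ball-membership oracle
  expect_true(all(out$data[region] == out$data[which(region)[1]]))
  expect_identical(out$data[!region], v$data[!region])
  # empty mask leaves the volume untouched
  none <- binary_mask(array(FALSE, dim(vol0)), 2, "adipocyte")
  expect_identical(suppress_adipocyte_edges(v, none, morpho_params())$data,
                   v$data)
})

test_that("edge suppression prevents false vessels at bright adipocyte rims", {
  # scaffold-free phantom: the whole grid is marrow (no Otsu stage)
  spec <- phantom_spec(grid_shape = c(96L, 96L, 96L), n_vessel_trees = 0L,
                       n_adipocytes = 10L, scaffold_fraction = 0,
                       blur_sigma_um = 2, noise_sd = 0,
                       recon_filter_sigma_um = 0, seed = 9L)
  g <- generate_cect_phantom(spec)
  marrow <- binary_mask(array(TRUE, dim(g$labels)), 2, "marrow")
  thr <- phantom_thresholds(spec)
  par <- morpho_params(adipocyte_threshold = thr$adipocyte,
                       vessel_threshold = thr$vessel,
                       vessel_despeckle1_vox = 1, vessel_despeckle2_vox = 1)
  adip <- segment_adipocytes(g$volume, marrow, par)
  with_supp <- suppressWarnings(segment_vessels(
    suppress_adipocyte_edges(g$volume, adip, par, marrow),
    marrow, par, adip))
  without <- segment_vessels(g$volume, marrow, par, adip)
  expect_gt(max(label_components(without$data)), 0)   # rims misread as vessels
  expect_equal(sum(with_supp$data), 0)                # suppression removes them
})

test_that("vessel despeckle volumes act at the printed cuts", {
  mk <- function(nvox) {
    # a compact blob of exactly nvox voxels (flood-grown cube-ish shape)
    a <- array(FALSE, c(40, 40, 40))
    k <- ceiling(nvox^(1 / 3))
    a[1:k, 1:k, 1:k] <- TRUE
    idx <- which(a)
    a[idx[seq_len(sum(a) - nvox)]] <- FALSE
    a
  }
  vol <- array(18000, c(40, 40, 40))
  vol[mk(1000)] <- 28000
  v <- image_volume(vol, 2)
  marrow <- binary_mask(array(TRUE, dim(vol)), 2, "marrow")
  par <- morpho_params(vessel_threshold = 23000,
                       vessel_close_r1 = 0, vessel_close_r2 = 0)
  expect_equal(sum(segment_vessels(v, marrow, par)$data), 0)    # 1000 < 1050
  vol2 <- array(18000, c(40, 40, 40)); vol2[mk(5000)] <- 28000
  m2 <- segment_vessels(image_volume(vol2, 2), marrow, par)
  expect_equal(sum(m2$data), 0)                                  # 5000 < 5500
  vol3 <- array(18000, c(40, 40, 40)); vol3[mk(5600)] <- 28000
  m3 <- segment_vessels(image_volume(vol3, 2), marrow, par)
  expect_equal(sum(m3$data), 5600)                               # survives
})

test_that("degenerate thresholds error or warn by direction", {
  vol <- image_volume(array(runif(8^3, 10000, 20000), c(8, 8, 8)), 2)
  marrow <- binary_mask(array(TRUE, c(8, 8, 8)), 2, "marrow")
  # selecting the entire volume is an operator error
  expect_error(segment_vessels(vol, marrow,
                               morpho_params(vessel_threshold = 5000)),
               "entire volume")
  expect_error(segment_adipocytes(vol, marrow,
                                  morpho_params(adipocyte_threshold = 25000)),
               "entire volume")
  # selecting nothing is a meaningful empty result, with a warning
  expect_warning(m <- segment_vessels(vol, marrow,
                                      morpho_params(vessel_threshold = 90000)),
                 "empty mask")
  expect_equal(sum(m$data), 0)
  expect_error(segment_vessels(vol, marrow, morpho_params()), "manual")
})
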