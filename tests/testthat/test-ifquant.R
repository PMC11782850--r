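make_section <- function(img, margin = 2) {
  d <- dim(img)
  roi <- cbind(x = c(margin, d[1] - margin, d[1] - margin, margin) + 0.5,
               y = c(margin, margin, d[2] - margin, d[2] - margin) + 0.5)
  if_section(channels = list(EMCN = img, CD31 = img), pixel_size_um = 0.6,
             roi_polygon = roi)
}

test_that("adaptive EMCN threshold behaves on degenerate inputs", {
  const <- make_section(matrix(0.5, 64, 64))
  expect_equal(sum(emcn_mask(const, 9, offset = 0.01)), 0)
  # an isolated bright pixel is erased by the r = 1 opening
  img <- matrix(0.1, 64, 64); img[30, 30] <- 1
  expect_equal(sum(emcn_mask(make_section(img), 15, offset = 0.05)), 0)
  expect_error(emcn_mask(const, 8), "odd")
  expect_error(emcn_mask(const, 1001), "larger than the image")
})

test_that("a whole-image window reduces to a global mean threshold", {
  set.seed(4)
  img <- matrix(runif(64 * 64), 64, 64)
  lm <- osteovasc:::.local_mean(img, 63)
  expect_equal(as.numeric(lm), rep(mean(img), 64 * 64))
})

test_that("local means match direct window averaging", {
  set.seed(6)
  img <- matrix(rnorm(30 * 20), 30, 20)
  lm <- osteovasc:::.local_mean(img, 2)
  for (p in list(c(5, 5), c(1, 1), c(30, 20), c(15, 2))) {
    xr <- max(1, p[1] - 2):min(30, p[1] + 2)
    yr <- max(1, p[2] - 2):min(20, p[2] + 2)
    expect_equal(lm[p[1], p[2]], mean(img[xr, yr]))
  }
})

test_that("polygon rasterization is exact on rectangles and matches shoelace", {
  sq <- cbind(c(0.5, 10.5, 10.5, 0.5), c(0.5, 0.5, 10.5, 10.5))
  expect_equal(sum(rasterize_polygons(sq, c(20, 20))), 100)
  two <- list(sq, sq + 12)
  expect_equal(sum(rasterize_polygons(two, c(30, 30))), 200)
  # random convex polygon: pixel area within 1.5% of the shoelace area
  set.seed(9)
  ang <- sort(runif(12, 0, 2 * pi))
  poly <- cbind(60 + 52 * cos(ang), 60 + 52 * sin(ang))
  px <- sum(rasterize_polygons(poly, c(120, 120)))
  expect_lt(abs(px - abs(polygon_area(poly))) / abs(polygon_area(poly)), 0.015)
  bow <- cbind(c(1, 10, 10, 1), c(1, 10, 1, 10))
  expect_error(rasterize_polygons(bow, c(12, 12)), "self-intersecting")
})

test_that("type-H is the exact pixel intersection with subset guarantees", {
  set.seed(2)
  cd <- matrix(runif(40 * 40) < 0.3, 40, 40)
  em <- matrix(runif(40 * 40) < 0.4, 40, 40)
  roi <- matrix(TRUE, 40, 40)
  res <- type_h(cd, em, roi)
  expect_identical(res$typeh_mask, cd & em)
  expect_true(all(which(res$typeh_mask) %in% which(cd)))
  expect_true(all(which(res$typeh_mask) %in% which(em)))
  expect_lte(res$typeh_area_pct, min(res$cd31_area_pct, res$emcn_area_pct))
  same <- type_h(cd, cd, roi)
  expect_equal(same$typeh_area_pct, same$cd31_area_pct)
  expect_equal(type_h(cd, !cd, roi)$typeh_area_pct, 0)
  expect_error(type_h(cd, em, matrix(FALSE, 40, 40)), "empty ROI")
})

test_that("the painted overlap is recovered through the full IF chain", {
  for (case in list(c(0.4, 10, 21), c(0.25, 5, 33))) {
    r <- generate_if_section(overlap_fraction = case[1], snr = case[2],
                             seed = case[3])
    res <- quantify_if_section(r$section, r$traces)
    expect_lt(abs(res$typeh_area_pct / 100 - r$truth$true_if_overlap_fraction) /
                r$truth$true_if_overlap_fraction, 0.10)
  }
})

test_that("results are invariant to joint intensity and offset rescaling", {
  r <- generate_if_section(overlap_fraction = 0.3, snr = 8, seed = 7)
  s1 <- r$section
  s2 <- s1
  s2$channels <- lapply(s1$channels, function(m) m * 3.7)
  m1 <- emcn_mask(s1, 21, offset = 0.05)
  m2 <- emcn_mask(s2, 21, offset = 0.05 * 3.7)
  expect_identical(m1, m2)
})

test_that("section averaging is the per-field arithmetic mean", {
  roi <- matrix(TRUE, 10, 10)
  a <- type_h(matrix(TRUE, 10, 10), matrix(TRUE, 10, 10), roi)   # 100%
  b <- type_h(matrix(FALSE, 10, 10), matrix(TRUE, 10, 10), roi)  # 0% typeh
  avg <- average_sections(list(a, b))
  expect_equal(avg$typeh_area_pct, 50)
  expect_equal(avg$n_sections_averaged, 2L)
  expect_identical(average_sections(list(a))$typeh_area_pct, a$typeh_area_pct)
  expect_error(average_sections(list()), "no section")
  # independent accumulation oracle for k results
  ks <- lapply(1:4, function(i) type_h(matrix(i %% 2 == 0, 10, 10),
                                       matrix(TRUE, 10, 10), roi))
  expect_equal(average_sections(ks)$typeh_area_pct,
               Reduce(`+`, lapply(ks, `[[`, "typeh_area_pct")) / 4)
})
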