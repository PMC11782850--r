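test_that("surface voxels follow the 6-adjacency definition", {
  a <- array(FALSE, c(5, 5, 5)); a[2:4, 2:4, 2:4] <- TRUE
  sv <- surface_voxels(binary_mask(a, 2))
  expect_equal(sum(sv$data), 26)                 # all but the center
  b <- array(FALSE, c(5, 5, 5)); b[3, 3, 3] <- TRUE
  expect_equal(which(surface_voxels(binary_mask(b, 2))$data), which(b))
  # sphere: matches a neighborhood-scan oracle and ~4*pi*r^2
  s <- array(FALSE, c(25, 25, 25))
  xs <- slice.index(s, 1); ys <- slice.index(s, 2); zs <- slice.index(s, 3)
  s[] <- (xs - 13)^2 + (ys - 13)^2 + (zs - 13)^2 <= 100
  sv2 <- surface_voxels(binary_mask(s, 2))
  scan <- array(FALSE, dim(s))
  for (x in 2:24) for (y in 2:24) for (z in 2:24)
    if (s[x, y, z] && (!s[x - 1, y, z] || !s[x + 1, y, z] || !s[x, y - 1, z] ||
                       !s[x, y + 1, z] || !s[x, y, z - 1] || !s[x, y, z + 1]))
      scan[x, y, z] <- TRUE
  expect_identical(sv2$data, scan)
  expect_lt(abs(sum(sv2$data) - 4 * pi * 100) / (4 * pi * 100), 0.35)
})

test_that("geodesic distances are zero at seeds and bound Euclidean from above", {
  bone <- array(FALSE, c(24, 24, 24)); bone[, , 1:3] <- TRUE
  dm <- geodesic_from_bone(binary_mask(bone, 2, "bone"))
  seeds <- dm$data == 0
  expect_true(any(seeds[, , 4]))
  expect_true(all(is.na(dm$data[, , 1:3])))
  # obstacle-free: geodesic >= Euclidean distance to the seed plane
  for (z in 5:24) {
    eu <- (z - 4) * 2
    expect_true(all(dm$data[, , z] >= eu - 1e-9))
    # quasi-Euclidean overestimate stays below ~8%
    expect_true(all(dm$data[, , z] <= eu * 1.09 + 2))
  }
})

test_that("geodesic routes around a wall and matches the Dijkstra oracle", {
  bone <- array(FALSE, c(20, 20, 8)); bone[, 1:2, ] <- TRUE
  wall <- array(FALSE, c(20, 20, 8)); wall[2:19, 8:9, ] <- TRUE
  # the wall is an obstacle outside the traversable domain, not a seed source
  dom_mask <- binary_mask(!wall, 2, "generic")
  dm <- geodesic_from_bone(binary_mask(bone, 2, "bone"), domain = dom_mask)
  dom <- !bone & !wall
  seeds <- dom & osteovasc:::.six_adjacent(bone)
  oracle <- igraph_geodesic(dom, seeds, 2)
  got <- dm$data
  expect_lt(max(abs(got[dom] - oracle[dom]), na.rm = TRUE), 1e-6)
  # behind the wall, the path is longer than the straight-line distance
  behind <- c(10, 15, 4)
  straight <- (behind[2] - 3) * 2
  expect_gt(got[behind[1], behind[2], behind[3]], straight)
})

test_that("adding bone (more seeds) never increases distances", {
  set.seed(17)
  bone1 <- array(runif(18^3) < 0.05, c(18, 18, 18))
  bone2 <- bone1; bone2[9, 9, 9] <- TRUE; bone2[3, 14, 8] <- TRUE
  d1 <- geodesic_from_bone(binary_mask(bone1, 2, "bone"))
  d2 <- geodesic_from_bone(binary_mask(bone2, 2, "bone"))
  dom <- !bone2
  expect_true(all(d2$data[dom] <= d1$data[dom] + 1e-9, na.rm = TRUE))
})

test_that("the distance distribution is invariant under 90-degree rotation", {
  bone <- array(FALSE, c(24, 24, 24)); bone[, , 1:3] <- TRUE
  ves <- array(FALSE, c(24, 24, 24)); ves[8:16, 8:16, 10:14] <- TRUE
  d1 <- vessel_bone_distance_distribution(
    geodesic_from_bone(binary_mask(bone, 2, "bone")), binary_mask(ves, 2, "vessel"))
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3))
  d2 <- vessel_bone_distance_distribution(
    geodesic_from_bone(binary_mask(rot(bone), 2, "bone")),
    binary_mask(rot(ves), 2, "vessel"))
  expect_equal(d1$weight_pct, d2$weight_pct)
})

test_that("a sheath touching bone everywhere sits fully in the first bin", {
  bone <- array(FALSE, c(16, 16, 16)); bone[, , 1:4] <- TRUE
  ves <- array(FALSE, c(16, 16, 16)); ves[, , 5] <- TRUE
  h <- vessel_bone_distance_distribution(
    geodesic_from_bone(binary_mask(bone, 2, "bone")),
    binary_mask(ves, 2, "vessel"))
  expect_equal(h$weight_pct[1], 100)
})

test_that("two thin tubes at 2 um and 60 um clearance split 50/50", {
  d <- c(40, 40, 72)
  bone <- array(FALSE, d); bone[, , 1:10] <- TRUE
  ves <- array(FALSE, d)
  ves[5:36, 20, 12] <- TRUE    # one step from the seed layer: 2 um
  ves[5:36, 20, 41] <- TRUE    # 30 steps: 60 um
  dm <- geodesic_from_bone(binary_mask(bone, 2, "bone"))
  h <- vessel_bone_distance_distribution(dm, binary_mask(ves, 2, "vessel"))
  expect_equal(h$weight_pct[h$lower_um == 0], 50, tolerance = 0.04)
  expect_equal(h$weight_pct[h$lower_um == 52], 50, tolerance = 0.04)
})

test_that("degenerate proximity inputs raise errors", {
  nobone <- binary_mask(array(FALSE, c(6, 6, 6)), 2, "bone")
  expect_error(geodesic_from_bone(nobone), "seed|bone")
  bone <- array(FALSE, c(6, 6, 6)); bone[, , 1] <- TRUE
  dm <- geodesic_from_bone(binary_mask(bone, 2, "bone"))
  noves <- binary_mask(array(FALSE, c(6, 6, 6)), 2, "vessel")
  expect_error(vessel_bone_distance_distribution(dm, noves), "empty|surface")
})
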