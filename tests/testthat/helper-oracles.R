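# Independent oracles used across the suite. These deliberately use different
# code paths (plain R loops, igraph) than the package internals.

# brute-force Euclidean ball dilation on a small logical array
bf_dilate <- function(a, r) {
  d <- dim(a)
  out <- array(FALSE, d)
  fg <- which(a, arr.ind = TRUE)
  if (nrow(fg) == 0) return(out)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    dd <- (fg[, 1] - x)^2 + (fg[, 2] - y)^2 + (fg[, 3] - z)^2
    if (any(dd <= r^2 + 1e-9)) out[x, y, z] <- TRUE
  }
  out
}

# brute-force connected labeling via igraph on the voxel adjacency graph
igraph_components <- function(a, connectivity = 26) {
  d <- dim(a)
  n <- prod(d)
  ids <- array(seq_len(n), d)
  ef <- c(); et <- c()
  for (dz in 0:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) next
    m <- abs(dx) + abs(dy) + abs(dz)
    if (connectivity == 6 && m > 1) next
    if (connectivity == 18 && m > 2) next
    xr <- max(1, 1 - dx):min(d[1], d[1] - dx)
    yr <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zr <- max(1, 1 - dz):min(d[3], d[3] - dz)
    A <- ids[xr, yr, zr]; B <- ids[xr + dx, yr + dy, zr + dz]
    sel <- a[A] & a[B]
    ef <- c(ef, A[sel]); et <- c(et, B[sel])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, rbind(ef, et))
  memb <- igraph::components(g)$membership
  memb[!a] <- NA
  # sizes of foreground components
  table(memb[a])
}

# Dijkstra oracle on the lattice via igraph, quasi-Euclidean weights
igraph_geodesic <- function(dom, seeds, vox) {
  d <- dim(dom); n <- prod(d)
  ids <- array(seq_len(n), d)
  ef <- c(); et <- c(); ew <- c()
  for (dz in 0:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) next
    xr <- max(1, 1 - dx):min(d[1], d[1] - dx)
    yr <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zr <- max(1, 1 - dz):min(d[3], d[3] - dz)
    A <- ids[xr, yr, zr]; B <- ids[xr + dx, yr + dy, zr + dz]
    sel <- dom[A] & dom[B]
    ef <- c(ef, A[sel]); et <- c(et, B[sel])
    ew <- c(ew, rep(sqrt(dx^2 + dy^2 + dz^2), sum(sel)))
  }
  g <- igraph::make_empty_graph(n + 1, directed = FALSE)
  sid <- which(seeds)
  g <- igraph::add_edges(g, rbind(c(ef, rep(n + 1, length(sid))), c(et, sid)))
  igraph::E(g)$weight <- c(ew, rep(0, length(sid)))
  as.numeric(igraph::distances(g, v = n + 1,
                               weights = igraph::E(g)$weight))[1:n] * vox
}

# exhaustive inscribed-sphere thickness on a small padded mask, under the
# package's stated convention: voxel centers carry the classic digital
# radius (distance to the nearest background voxel center minus half a
# voxel); face midpoints carry the exact distance to the nearest background
# voxel cube; thickness = 2 * max radius over covering spheres
bf_local_thickness <- function(a) {
  d <- dim(a)
  bg <- which(!a, arr.ind = TRUE)
  fgi <- which(a, arr.ind = TRUE)
  out <- array(0, d)
  cx <- seq(min(fgi[, 1]), max(fgi[, 1]), by = 0.5)
  cy <- seq(min(fgi[, 2]), max(fgi[, 2]), by = 0.5)
  cz <- seq(min(fgi[, 3]), max(fgi[, 3]), by = 0.5)
  for (x in cx) for (y in cy) for (z in cz) {
    nhalf <- sum(c(x, y, z) %% 1 != 0)
    if (nhalf > 1) next
    if (nhalf == 0) {
      r <- sqrt(min((bg[, 1] - x)^2 + (bg[, 2] - y)^2 + (bg[, 3] - z)^2)) - 0.5
    } else {
      dx <- pmax(abs(bg[, 1] - x) - 0.5, 0)
      dy <- pmax(abs(bg[, 2] - y) - 0.5, 0)
      dz <- pmax(abs(bg[, 3] - z) - 0.5, 0)
      r <- sqrt(min(dx^2 + dy^2 + dz^2))
    }
    if (r <= 0) next
    cov <- (fgi[, 1] - x)^2 + (fgi[, 2] - y)^2 + (fgi[, 3] - z)^2 <=
      r^2 + 1e-9
    if (any(cov)) {
      sel <- fgi[cov, , drop = FALSE]
      v <- out[sel]
      out[sel] <- pmax(v, 2 * r)
    }
  }
  out
}

# digitized solid cylinder along z
make_cylinder <- function(r_vox, length_vox, pad = 4, voxel_um = 2) {
  n <- 2 * (r_vox + pad) + 1
  a <- array(FALSE, c(n, n, length_vox + 2 * pad))
  c0 <- r_vox + pad + 1
  xs <- slice.index(a, 1); ys <- slice.index(a, 2); zs <- slice.index(a, 3)
  a[] <- (xs - c0)^2 + (ys - c0)^2 <= r_vox^2 &
    zs > pad & zs <= pad + length_vox
  binary_mask(a, voxel_um, "vessel")
}

# fixed straight-tube / Y-tube phantom specs
straight_tube_spec <- function(radius_um = 10, noiseless = TRUE) {
  tr <- list(nodes = rbind(c(15, 40, 40), c(30, 40, 40), c(45, 40, 40),
                           c(65, 40, 40)),
             radii_um = rep(radius_um, 4),
             edges = rbind(c(1, 2), c(2, 3), c(3, 4)))
  phantom_spec(grid_shape = c(80L, 80L, 80L), n_vessel_trees = 0L,
               scaffold_fraction = 0, n_adipocytes = 0L,
               blur_sigma_um = if (noiseless) 0 else 2,
               noise_sd = if (noiseless) 0 else 1000,
               recon_filter_sigma_um = 0,
               fixed_trees = list(tr), seed = 2L)
}

y_tube_spec <- function() {
  tr <- list(nodes = rbind(c(15, 40, 40), c(38, 40, 40), c(58, 52, 40),
                           c(58, 28, 40)),
             radii_um = rep(8, 4),
             edges = rbind(c(1, 2), c(2, 3), c(2, 4)))
  phantom_spec(grid_shape = c(80L, 80L, 80L), n_vessel_trees = 0L,
               scaffold_fraction = 0, n_adipocytes = 0L, blur_sigma_um = 0,
               noise_sd = 0, recon_filter_sigma_um = 0,
               fixed_trees = list(tr), seed = 2L)
}

# small random-tree phantom used by network tests
tree_phantom <- function(seed, grid = 96L) {
  generate_cect_phantom(phantom_spec(
    grid_shape = rep(grid, 3), n_vessel_trees = 2L, scaffold_fraction = 0,
    n_adipocytes = 0L, blur_sigma_um = 0, noise_sd = 0,
    recon_filter_sigma_um = 0, seed = seed))
}

vessel_mask_from <- function(gen) {
  binary_mask(gen$labels == 2L, gen$truth$voxel_size_um, "vessel")
}

expect_census_equal <- function(stats, truth) {
  expect_identical(stats$n_branches, truth$true_branch_count)
  expect_identical(stats$n_junctions, truth$true_junction_count)
  expect_identical(stats$n_triple_points, truth$true_triple_count)
  expect_identical(stats$n_quadruple_points, truth$true_quadruple_count)
}
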