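#' Specification for a synthetic CE-CT phantom
#'
#' Describes a marrow volume containing a trabecular scaffold, tubular vessel
#' trees with controlled radius spectrum and branch topology, and spherical
#' adipocytes, rendered to grayscale with the contrast ordering of a
#' hafnium-polyoxometalate-stained scan (bone densest, stained vessels and
#' adipocyte rim halos intermediate, unstained fat darkest), then degraded by
#' Gaussian blur (partial-volume surrogate) and additive Gaussian noise.
#'
#' Default degradation matches the validation conditions used throughout the
#' package: blur sigma of one voxel and noise standard deviation equal to 10%
#' of the marrow-vessel contrast.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size_um isotropic voxel size, um.
#' @param scaffold_fraction target bone volume fraction of the VOI (0-0.5).
#' @param n_vessel_trees number of independent vessel trees.
#' @param vessel_radius_range_um (min, max) vessel radius in um; the minimum
#'   must be at least one voxel.
#' @param branching_prob per-step probability that a growing branch splits.
#' @param trifurcation_prob probability that a split spawns three children
#'   (a quadruple junction) rather than two (a triple junction).
#' @param n_adipocytes number of adipocytes to place.
#' @param adipocyte_diameter_mean_um,adipocyte_diameter_sd_um diameter
#'   distribution, um.
#' @param intensity_levels named mean grayscale per role: `background`,
#'   `marrow`, `adipocyte_interior`, `adipocyte_rim`, `vessel`, `bone`.
#' @param blur_sigma_um Gaussian PSF sigma, um.
#' @param noise_sd additive Gaussian noise SD, grayscale units (added before
#'   the reconstruction filter, as detector noise precedes reconstruction).
#' @param recon_filter_sigma_um sigma of the reconstruction-side Gaussian
#'   filter applied after noise, emulating the smoothing filter of the
#'   scanner's reconstruction software; 0 disables it.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param fixed_trees optional list of prescribed vessel trees, each a list
#'   with `nodes` (m x 3 matrix, 1-based voxel coordinates), `radii_um`
#'   (length m) and `edges` (2-column matrix of node indices); overrides the
#'   random grower.
#' @return an object of class `PhantomSpec`.
#' @export
phantom_spec <- function(grid_shape = c(160L, 160L, 160L),
                         voxel_size_um = 2,
                         scaffold_fraction = 0.2,
                         n_vessel_trees = 3L,
                         vessel_radius_range_um = c(6, 20),
                         branching_prob = 0.08,
                         trifurcation_prob = 0.2,
                         n_adipocytes = 30L,
                         adipocyte_diameter_mean_um = 32,
                         adipocyte_diameter_sd_um = 6,
                         intensity_levels = c(background = 18000,
                                              marrow = 18000,
                                              adipocyte_interior = 5000,
                                              adipocyte_rim = 25000,
                                              vessel = 28000,
                                              bone = 58000),
                         blur_sigma_um = 2,
                         noise_sd = 1000,
                         recon_filter_sigma_um = 1.2,
                         seed = 1L,
                         fixed_trees = NULL) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            all(grid_shape <= 512), voxel_size_um > 0,
            scaffold_fraction >= 0, scaffold_fraction <= 0.5,
            n_vessel_trees >= 0, branching_prob >= 0, branching_prob <= 1,
            trifurcation_prob >= 0, trifurcation_prob <= 1,
            n_adipocytes >= 0, adipocyte_diameter_mean_um > 0,
            adipocyte_diameter_sd_um >= 0, blur_sigma_um >= 0, noise_sd >= 0,
            recon_filter_sigma_um >= 0)
  need <- c("background", "marrow", "adipocyte_interior", "adipocyte_rim",
            "vessel", "bone")
  if (!all(need %in% names(intensity_levels)))
    stop("intensity_levels must name: ", paste(need, collapse = ", "))
  if (vessel_radius_range_um[1] < voxel_size_um)
    stop("minimum vessel radius is below one voxel")
  if (!(intensity_levels["adipocyte_interior"] < intensity_levels["vessel"] &&
        intensity_levels["vessel"] < intensity_levels["bone"]))
    stop("contrast ordering violated: need adipocyte interior < vessel < bone")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_um = voxel_size_um,
                 scaffold_fraction = scaffold_fraction,
                 n_vessel_trees = as.integer(n_vessel_trees),
                 vessel_radius_range_um = vessel_radius_range_um,
                 branching_prob = branching_prob,
                 trifurcation_prob = trifurcation_prob,
                 n_adipocytes = as.integer(n_adipocytes),
                 adipocyte_diameter_mean_um = adipocyte_diameter_mean_um,
                 adipocyte_diameter_sd_um = adipocyte_diameter_sd_um,
                 intensity_levels = intensity_levels,
                 blur_sigma_um = blur_sigma_um,
                 noise_sd = noise_sd,
                 recon_filter_sigma_um = recon_filter_sigma_um,
                 seed = as.integer(seed),
                 fixed_trees = fixed_trees),
            class = "PhantomSpec")
}

#' Midpoint segmentation thresholds for a phantom
#'
#' For a blurred step edge between two intensity modes the 50% level sits at
#' the true boundary, so the mode midpoint is the unbiased global threshold.
#'
#' @param spec a [phantom_spec()].
#' @return list with `adipocyte` and `vessel` thresholds.
#' @export
phantom_thresholds <- function(spec) {
  lv <- spec$intensity_levels
  # the adipocyte boundary is a fat-to-halo edge (the cell is wrapped by its
  # bright partial-volume rim), so its midpoint uses the rim level
  list(adipocyte = unname((lv["adipocyte_interior"] + lv["adipocyte_rim"]) / 2),
       vessel = unname((lv["marrow"] + lv["vessel"]) / 2))
}

# unit vector
.unit <- function(v) v / sqrt(sum(v^2))

# orthonormal basis perpendicular to unit vector d
.perp_basis <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross(a, d))
  v <- .cross(d, u)
  list(u = u, v = v)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Stochastic branching random walk, one tree at a time, with shared
# collision geometry so tubes of different trees (and non-adjacent branches
# of one tree) keep a clearance and never merge. A tree whose total tube
# volume comes out below `min_tree_vox` is discarded and regrown elsewhere
# (small isolated trees would be erased by the vessel despeckling steps,
# which expect one large connected network per tree). Returns a forest:
# list(nodes, radii, edges, tree_id) with 1-based voxel coordinates.
# Collision exclusions are relationship-based: a branch ignores its own
# recent nodes (the tube continues through them), and nodes of its parent
# and sibling branches that sit near the shared junction.
.grow_forest <- function(dims, n_trees, r_range_vox, branching_prob,
                         trifurcation_prob, step = 4, clearance = 2,
                         max_nodes = 4000, min_tree_vox = NULL) {
  # minimum tube volume per tree scales with the grid so trees stay well
  # above the protocol despeckle volumes without overcrowding small grids
  if (is.null(min_tree_vox))
    min_tree_vox <- max(3000, min(12000, round(0.0025 * prod(dims))))
  margin <- r_range_vox[2] + 4
  lo <- margin + 1
  hi <- dims - margin
  if (any(hi <= lo)) stop("grid too small for the requested vessel radii")
  nodes <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  node_branch <- integer(0)
  node_step <- integer(0)   # step count along the node's branch
  tree_id <- integer(0)
  br_parent <- integer(0)   # parent branch id (0 = trunk)
  br_start <- matrix(numeric(0), ncol = 3)  # junction position per branch
  br_startnode <- integer(0)
  all_edges <- matrix(integer(0), ncol = 2)
  min_len <- function(r) 16 + 2 * r  # radius-scaled minimum branch length
  for (tr in seq_len(n_trees)) {
    for (attempt in 1:5) {
      # snapshot for rollback if the tree comes out too small
      snap <- list(n = nrow(nodes), nb = length(br_parent),
                   ne = nrow(all_edges))
      root <- NULL
      r0 <- runif(1, 0.8 * r_range_vox[2], r_range_vox[2])
      for (try in 1:100) {
        cand <- runif(3, lo, hi)
        if (nrow(nodes) == 0 ||
            all(sqrt(colSums((t(nodes) - cand)^2)) >
                  r0 + radii + clearance + 4 * step)) {
          root <- cand
          break
        }
      }
      if (is.null(root)) break  # no room for another tree at all
      nodes <- rbind(nodes, root)
      radii <- c(radii, r0)
      nb <- length(br_parent) + 1L
      node_branch <- c(node_branch, nb)
      node_step <- c(node_step, 0L)
      tree_id <- c(tree_id, tr)
      br_parent <- c(br_parent, 0L)
      br_start <- rbind(br_start, root)
      br_startnode <- c(br_startnode, nrow(nodes))
      tips <- list(list(node = nrow(nodes), dir = .unit(rnorm(3)),
                        r = r0, len = 0, branch = nb, tree = tr,
                        nstep = 0L))
      tube_vol <- 0
      while (length(tips) > 0 && nrow(nodes) < max_nodes) {
    tip <- tips[[1]]
    tips <- tips[-1]
    pos <- nodes[tip$node, ]
    dir <- .unit(tip$dir + 0.25 * rnorm(3))
    newpos <- pos + dir * step
    if (any(newpos < lo) || any(newpos > hi)) next  # branch ends at margin
    b <- tip$branch
    lim <- tip$r + radii + clearance
    dc <- sqrt(colSums((t(nodes) - newpos)^2))
    same_recent <- node_branch == b &
      (tip$nstep - node_step) <= ceiling(max(lim) / step) + 1L
    parent_b <- if (br_startnode[b] <= length(node_branch))
      node_branch[br_startnode[b]] else b
    related <- node_branch == b | node_branch == parent_b |
      br_startnode[node_branch] == br_startnode[b]
    near_junction <- sqrt(colSums((t(nodes) - br_start[b, ])^2)) <
      lim + 2 * step
    excluded <- same_recent | (related & near_junction)
    if (any(dc < lim & !excluded)) next  # would collide: terminate branch
    nodes <- rbind(nodes, newpos)
    radii <- c(radii, tip$r)
    node_branch <- c(node_branch, b)
    node_step <- c(node_step, tip$nstep + 1L)
    tree_id <- c(tree_id, tip$tree)
    nid <- nrow(nodes)
    all_edges <- rbind(all_edges, c(tip$node, nid))
    tube_vol <- tube_vol + pi * tip$r^2 * step
    newlen <- tip$len + step
    if (newlen >= min_len(tip$r) && runif(1) < branching_prob) {
      k <- if (runif(1) < trifurcation_prob) 3L else 2L
      basis <- .perp_basis(dir)
      phi0 <- runif(1, 0, 2 * pi)
      theta0 <- if (k == 3L) runif(1, 45, 60) else runif(1, 35, 55)
      jit <- if (k == 3L) 10 else 20
      for (i in seq_len(k)) {
        phi <- phi0 + (i - 1) * 2 * pi / k + runif(1, -jit, jit) * pi / 180
        cdir <- .unit(cos(theta0 * pi / 180) * dir +
                        sin(theta0 * pi / 180) *
                          (cos(phi) * basis$u + sin(phi) * basis$v))
        cr <- max(r_range_vox[1], tip$r * runif(1, 0.75, 0.92))
        nb <- length(br_parent) + 1L
        br_parent <- c(br_parent, b)
        br_start <- rbind(br_start, newpos)
        br_startnode <- c(br_startnode, nid)
        tips <- c(tips, list(list(node = nid, dir = cdir, r = cr, len = 0,
                                  branch = nb, tree = tip$tree, nstep = 0L)))
      }
    } else if (runif(1) < 0.02 && newlen >= min_len(tip$r)) {
      # natural termination
    } else {
      tips <- c(tips, list(list(node = nid, dir = dir, r = tip$r,
                                len = newlen, branch = b, tree = tip$tree,
                                nstep = tip$nstep + 1L)))
    }
      }
      if (tube_vol >= min_tree_vox || attempt == 5) break
      # roll back the undersized tree and regrow it elsewhere
      keep <- seq_len(snap$n)
      nodes <- nodes[keep, , drop = FALSE]
      radii <- radii[keep]
      node_branch <- node_branch[keep]
      node_step <- node_step[keep]
      tree_id <- tree_id[keep]
      br_parent <- br_parent[seq_len(snap$nb)]
      br_start <- br_start[seq_len(snap$nb), , drop = FALSE]
      br_startnode <- br_startnode[seq_len(snap$nb)]
      all_edges <- all_edges[seq_len(snap$ne), , drop = FALSE]
    }
  }
  list(nodes = nodes, radii = radii, edges = all_edges, tree_id = tree_id)
}

# Iteratively remove terminal chains shorter than their radius-scaled
# minimum length (so rasterized tubes have no stubby spurs that thinning
# would absorb); the census collapses any degree-2 junction remnants
# automatically.
.prune_tree <- function(tree) {
  repeat {
    n <- nrow(tree$nodes)
    if (n == 0 || nrow(tree$edges) == 0) return(tree)
    elen <- sqrt(rowSums((tree$nodes[tree$edges[, 1], , drop = FALSE] -
                            tree$nodes[tree$edges[, 2], , drop = FALSE])^2))
    cen <- .graph_census(n, tree$edges, elen)
    if (nrow(cen$branches) == 0) return(tree)
    term <- (cen$branches$from == "end") != (cen$branches$to == "end")
    # minimum length scales with tube radius: caps erode about one radius
    deg0 <- tabulate(c(tree$edges), n)
    ch0 <- .chain_membership(list(n = n, edges = tree$edges), deg0)
    chain_r <- rep(0, max(ch0, 1))
    if (any(ch0 > 0)) {
      rr <- tapply(tree$radii[ch0 > 0], ch0[ch0 > 0], mean)
      chain_r[as.integer(names(rr))] <- as.numeric(rr)
    }
    min_len <- 16 + 2 * chain_r[attr(cen$branches, "chain_ids")]
    short <- term & cen$branches$length < min_len
    if (!any(short)) return(tree)
    drop_chains <- attr(cen$branches, "chain_ids")[short]
    keep <- ch0 == 0L | !(ch0 %in% drop_chains)
    remap <- cumsum(keep)
    ek <- keep[tree$edges[, 1]] & keep[tree$edges[, 2]]
    tree <- list(nodes = tree$nodes[keep, , drop = FALSE],
                 radii = tree$radii[keep],
                 edges = cbind(remap[tree$edges[ek, 1]],
                               remap[tree$edges[ek, 2]]),
                 tree_id = tree$tree_id[keep])
  }
}

# Laplacian smoothing of branch interiors (degree-2 nodes only, junctions
# and endpoints fixed): polyline kinks would rasterize to scalloped tubes
# whose crease concavities the closing steps of the segmentation chain would
# fill, so tubes are smoothed to the fidelity of real vessels before
# rasterization. Deviations are well under a voxel, so collision clearances
# are preserved.
.smooth_polylines <- function(tree, iters = 3) {
  n <- nrow(tree$nodes)
  if (n == 0 || nrow(tree$edges) == 0) return(tree)
  deg <- tabulate(c(tree$edges), n)
  nb1 <- integer(n); nb2 <- integer(n)
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges[e, 1]; b <- tree$edges[e, 2]
    if (nb1[a] == 0L) nb1[a] <- b else nb2[a] <- b
    if (nb1[b] == 0L) nb1[b] <- a else nb2[b] <- a
  }
  sel <- deg == 2L
  pts <- tree$nodes
  for (it in seq_len(iters)) {
    pts[sel, ] <- 0.5 * pts[sel, , drop = FALSE] +
      0.25 * pts[nb1[sel], , drop = FALSE] +
      0.25 * pts[nb2[sel], , drop = FALSE]
  }
  tree$nodes <- pts
  tree
}

# split a pruned forest into per-tree polyline objects
.split_forest <- function(forest) {
  trees <- list()
  for (t in sort(unique(forest$tree_id))) {
    keep <- forest$tree_id == t
    if (!any(keep)) next
    remap <- cumsum(keep)
    ek <- keep[forest$edges[, 1]] & keep[forest$edges[, 2]]
    if (!any(ek)) next
    trees[[length(trees) + 1]] <-
      list(nodes = forest$nodes[keep, , drop = FALSE],
           radii = forest$radii[keep],
           edges = cbind(remap[forest$edges[ek, 1]],
                         remap[forest$edges[ek, 2]]))
  }
  trees
}

#' Generate a synthetic CE-CT phantom with known ground truth
#'
#' Builds a labeled volume (vessel trees grown by a stochastic branching
#' random walk, a trabecular scaffold from thresholded smoothed noise,
#' adipocytes placed by overlap-free dart throwing), renders it to grayscale
#' through the specified intensity levels, Gaussian blur and additive noise, and
#' records exact ground truth: voxel volumes counted before blurring, the
#' vessel centerline graph, and its branch/junction census.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [image_volume()]), `truth` (class
#'   `PhantomGroundTruth`) and `labels` (integer array: 0 marrow, 1 bone,
#'   2 vessel, 3 adipocyte interior, 4 adipocyte rim).
#' @export
generate_cect_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  dims <- spec$grid_shape
  vox <- spec$voxel_size_um
  n_total <- prod(dims)
  labels <- array(0L, dims)
  r_range_vox <- spec$vessel_radius_range_um / vox

  # --- vessel trees ---
  trees <- list()
  if (!is.null(spec$fixed_trees)) {
    trees <- lapply(spec$fixed_trees, function(tr) {
      list(nodes = tr$nodes, radii = tr$radii_um / vox,
           edges = tr$edges)
    })
  } else if (spec$n_vessel_trees > 0) {
    forest <- .grow_forest(dims, spec$n_vessel_trees, r_range_vox,
                           spec$branching_prob, spec$trifurcation_prob)
    forest <- .prune_tree(forest)
    trees <- lapply(.split_forest(forest), .smooth_polylines)
  }
  # combined census over all trees
  all_nodes <- do.call(rbind, c(lapply(trees, `[[`, "nodes"),
                                list(matrix(numeric(0), ncol = 3))))
  all_edges <- matrix(integer(0), ncol = 2)
  off <- 0L
  for (tr in trees) {
    if (nrow(tr$edges) > 0)
      all_edges <- rbind(all_edges, tr$edges + off)
    off <- off + nrow(tr$nodes)
  }
  elen <- if (nrow(all_edges) > 0)
    sqrt(rowSums((all_nodes[all_edges[, 1], , drop = FALSE] -
                    all_nodes[all_edges[, 2], , drop = FALSE])^2))
  else numeric(0)
  cen <- .graph_census(nrow(all_nodes), all_edges, elen)
  # rasterize tubes (count unique voxels)
  vessel_vox <- 0L
  for (tr in trees) {
    for (e in seq_len(nrow(tr$edges))) {
      i <- tr$edges[e, 1]; j <- tr$edges[e, 2]
      r <- min(tr$radii[i], tr$radii[j])
      vessel_vox <- vessel_vox +
        cpp_fill_capsule(labels, dims, tr$nodes[i, ] - 1, tr$nodes[j, ] - 1,
                         r, r, 2L, 0L)
    }
  }
  # a union of capsules has no internal cavities; fill any background pocket
  # pinched off by rasterization at wide-angle junctions
  if (vessel_vox > 0) {
    bg <- label_components(labels == 0L, 6L)
    enclosed <- setdiff(seq_len(max(bg)), .border_labels(bg))
    if (length(enclosed)) {
      sel <- array(bg, dims) %in% enclosed
      labels[sel] <- 2L
      vessel_vox <- vessel_vox + sum(sel)
    }
  }

  # --- adipocytes: overlap-free dart throwing ---
  # the cell is the dark lipid sphere (label 3); the bright partial-volume
  # halo (label 4) is an imaging artifact painted as a thin shell AROUND the
  # cell, so the true cell volume is the label-3 voxel count
  adip <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     diameter_um = numeric(0), voxels = integer(0))
  adip_vox <- 0L
  halo <- 2.5  # halo shell thickness, voxels (thick enough to survive the PSF)
  if (spec$n_adipocytes > 0) {
    max_tries <- 300L
    for (i in seq_len(spec$n_adipocytes)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        d_um <- rnorm(1, spec$adipocyte_diameter_mean_um,
                      spec$adipocyte_diameter_sd_um)
        d_um <- min(max(d_um, 3 * vox,
                        spec$adipocyte_diameter_mean_um -
                          3 * spec$adipocyte_diameter_sd_um),
                    spec$adipocyte_diameter_mean_um +
                      3 * spec$adipocyte_diameter_sd_um)
        r_vox <- d_um / 2 / vox
        ctr <- runif(3, r_vox + halo + 3, dims - r_vox - halo - 2)
        if (cpp_region_free(labels, dims, ctr - 1, r_vox + halo + 1, 0L)) {
          cpp_fill_sphere(labels, dims, ctr - 1, r_vox + halo, 4L, 0L)
          n_cell <- cpp_fill_sphere(labels, dims, ctr - 1, r_vox, 3L, 4L)
          adip <- rbind(adip, data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                                         diameter_um = d_um,
                                         voxels = n_cell))
          adip_vox <- adip_vox + n_cell
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(
          "adipocyte packing infeasible: placed %d of %d without overlap",
          i - 1L, spec$n_adipocytes))
    }
  }

  # --- trabecular scaffold: thresholded smoothed noise, order-statistic
  #     calibrated to the target fraction over unoccupied voxels; a 3-voxel
  #     clearance from vessels and adipocytes keeps the perivascular space
  #     open and avoids bone-halo contamination of their surfaces ---
  bone_vox <- 0L
  if (spec$scaffold_fraction > 0) {
    field <- array(cpp_gauss_blur(rnorm(n_total), dims, 3), dims)
    occupied <- labels != 0L
    free <- !array(cpp_ball_dilate(occupied, dims, 3), dims)
    v <- field[free]
    k <- min(round(spec$scaffold_fraction * n_total), length(v))
    if (k > 0) {
      thr <- -sort(-v, partial = k)[k]
      sel <- free & field >= thr
      labels[sel] <- 1L
      bone_vox <- sum(sel)
    }
  }

  # --- render ---
  lv <- spec$intensity_levels
  lut <- c(lv["marrow"], lv["bone"], lv["vessel"],
           lv["adipocyte_interior"], lv["adipocyte_rim"])
  intens <- array(lut[labels + 1L], dims)
  if (spec$blur_sigma_um > 0)
    intens <- array(cpp_gauss_blur(intens, dims, spec$blur_sigma_um / vox),
                    dims)
  if (spec$noise_sd > 0)
    intens <- intens + rnorm(n_total, 0, spec$noise_sd)
  if (spec$recon_filter_sigma_um > 0)
    intens <- array(cpp_gauss_blur(intens, dims,
                                   spec$recon_filter_sigma_um / vox), dims)
  intens[intens < 0] <- 0
  intens[intens > 65535] <- 65535

  truth <- structure(list(
    vessel_centerlines = trees,
    true_branch_count = cen$n_branches,
    true_junction_count = cen$n_junctions,
    true_triple_count = cen$n_triple_points,
    true_quadruple_count = cen$n_quadruple_points,
    true_endpoint_count = cen$n_endpoints,
    adipocytes = adip,
    true_vessel_volume_um3 = vessel_vox * vox^3,
    true_adipocyte_volume_um3 = adip_vox * vox^3,
    true_bone_volume_um3 = bone_vox * vox^3,
    true_marrow_volume_um3 = (n_total - bone_vox) * vox^3,
    voxel_size_um = vox), class = "PhantomGroundTruth")

  list(volume = image_volume(intens, vox), truth = truth, labels = labels)
}

#' @export
print.PhantomGroundTruth <- function(x, ...) {
  cat(sprintf(
    "PhantomGroundTruth: %d branches, %d junctions (%d triple, %d quadruple); %d adipocytes\n",
    x$true_branch_count, x$true_junction_count, x$true_triple_count,
    x$true_quadruple_count, nrow(x$adipocytes)))
  cat(sprintf("  vessel %.3g um^3, adipocyte %.3g um^3, marrow %.3g um^3\n",
              x$true_vessel_volume_um3, x$true_adipocyte_volume_um3,
              x$true_marrow_volume_um3))
  invisible(x)
}

#' Generate a synthetic two-channel immunofluorescence section
#'
#' Paints EMCN- and CD31-positive regions as unions of discs inside a
#' rectangular region of interest so that the painted intersection area over
#' the ROI area reaches `overlap_fraction` (within one disc's area; the
#' achieved pixel-exact fraction is recorded in the ground truth). Channel
#' images are rendered with the requested signal-to-noise ratio; the CD31
#' blobs are additionally exported as "manually traced" outline polygons.
#'
#' @param width,height image size in pixels.
#' @param overlap_fraction target type-H (double-positive) area fraction of
#'   the ROI, 0-1. Values above 0.95 paint both channels over the whole ROI.
#' @param snr signal-to-noise ratio (signal amplitude / noise SD); must be
#'   positive.
#' @param seed RNG seed.
#' @param pixel_size_um pixel size, um.
#' @param n_exclusive number of single-positive discs painted per channel.
#' @param blob_radius_px disc radius range, pixels.
#' @return list with `section` (an [if_section()]), `traces` (list of CD31
#'   polygons), and `truth` (achieved overlap fraction, areas, and the
#'   noiseless label masks).
#' @export
generate_if_section <- function(width = 384L, height = 384L,
                                overlap_fraction = 0.4, snr = 10, seed = 1L,
                                pixel_size_um = 0.62, n_exclusive = 10L,
                                blob_radius_px = c(8, 18)) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (snr <= 0) stop("snr must be positive")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  margin <- 10
  px <- matrix(rep(seq_len(width), height), nrow = width)
  py <- matrix(rep(seq_len(height), each = width), nrow = width)
  roi <- px > margin & px <= width - margin & py > margin & py <= height - margin
  roi_polygon <- cbind(x = c(margin, width - margin, width - margin, margin) + 0.5,
                       y = c(margin, margin, height - margin, height - margin) + 0.5)
  roi_area <- sum(roi)
  cd31 <- matrix(FALSE, width, height)
  emcn <- matrix(FALSE, width, height)
  paint_disc <- function(m, cx, cy, r) {
    xr <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
    yr <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
    sub <- outer(xr, yr, function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
    m[xr, yr] <- m[xr, yr] | sub
    m
  }
  disc_pixels <- function(cx, cy, r) {
    xr <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
    yr <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
    sub <- outer(xr, yr, function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
    cbind(rep(xr, times = length(yr))[c(sub)],
          rep(yr, each = length(xr))[c(sub)])
  }
  traces <- list()
  circle_poly <- function(cx, cy, r, n = 48) {
    a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(x = cx + r * cos(a), y = cy + r * sin(a))
  }
  if (overlap_fraction > 0.95) {
    cd31[roi] <- TRUE
    emcn[roi] <- TRUE
    traces <- list(roi_polygon)
  } else {
    target <- overlap_fraction * roi_area
    tries <- 0L
    while (sum(cd31 & emcn & roi) < target && tries < 5000L) {
      tries <- tries + 1L
      r <- runif(1, blob_radius_px[1], blob_radius_px[2])
      cx <- runif(1, margin + r + 1, width - margin - r)
      cy <- runif(1, margin + r + 1, height - margin - r)
      cd31 <- paint_disc(cd31, cx, cy, r)
      emcn <- paint_disc(emcn, cx, cy, r)
      traces[[length(traces) + 1]] <- circle_poly(cx, cy, r)
    }
    # single-positive discs: must not touch the other channel's mask
    for (ch in c("cd31", "emcn")) {
      other <- if (ch == "cd31") emcn else cd31
      for (i in seq_len(n_exclusive)) {
        for (t in 1:50) {
          r <- runif(1, blob_radius_px[1], blob_radius_px[2])
          cx <- runif(1, margin + r + 1, width - margin - r)
          cy <- runif(1, margin + r + 1, height - margin - r)
          pix <- disc_pixels(cx, cy, r + 2)  # 2-px guard band
          if (!any(other[pix])) {
            if (ch == "cd31") {
              cd31 <- paint_disc(cd31, cx, cy, r)
              traces[[length(traces) + 1]] <- circle_poly(cx, cy, r)
            } else {
              emcn <- paint_disc(emcn, cx, cy, r)
            }
            break
          }
        }
      }
    }
  }
  achieved <- sum(cd31 & emcn & roi) / roi_area
  sig <- 1.0; bg <- 0.15
  noise_sd <- (sig - bg) / snr
  render <- function(m) {
    img <- matrix(bg, width, height)
    img[m] <- sig
    img + matrix(rnorm(width * height, 0, noise_sd), width, height)
  }
  section <- if_section(channels = list(EMCN = render(emcn),
                                        CD31 = render(cd31)),
                        pixel_size_um = pixel_size_um,
                        roi_polygon = roi_polygon)
  truth <- list(true_if_overlap_fraction = achieved,
                cd31_area_px = sum(cd31 & roi),
                emcn_area_px = sum(emcn & roi),
                roi_area_px = roi_area,
                cd31_label = cd31, emcn_label = emcn)
  list(section = section, traces = traces, truth = truth)
}

#' Generate a synthetic laser Doppler flowmetry trace
#'
#' A linear ramp plus Gaussian noise: `perfusion = baseline + slope * t +
#' noise`, with the true slope stored as attribute `true_slope_pu_per_min`.
#'
#' @param duration_s trace duration, seconds.
#' @param sample_rate_hz sampling rate, Hz.
#' @param baseline_pu baseline perfusion, PU.
#' @param slope_pu_per_min linear drift, PU per minute.
#' @param noise_sd additive noise SD, PU.
#' @param seed RNG seed.
#' @param animal,limb,week,segment metadata carried on the trace.
#' @return an [ldf_trace()] data frame.
#' @export
generate_ldf_trace <- function(duration_s, sample_rate_hz, baseline_pu,
                               slope_pu_per_min = 0, noise_sd = 0, seed = 1L,
                               animal = NA, limb = NA, week = NA,
                               segment = NA) {
  stopifnot(duration_s > 0, sample_rate_hz > 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  t <- seq(0, duration_s - 1 / sample_rate_hz, by = 1 / sample_rate_hz)
  pu <- baseline_pu + slope_pu_per_min * t / 60 +
    rnorm(length(t), 0, noise_sd)
  tr <- ldf_trace(time_s = t, perfusion_pu = pu, animal = animal,
                  limb = limb, week = week, segment = segment,
                  check_positive = FALSE)
  attr(tr, "true_slope_pu_per_min") <- slope_pu_per_min
  tr
}
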