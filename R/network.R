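#' Skeletonize a binary mask to its medial curves
#'
#' Topology-preserving 3D thinning: voxels are removed layer by layer (six
#' directional subiterations) when they are simple points and not curve
#' endpoints, until no voxel can be removed. The skeleton is a subset of the
#' mask, one voxel wide along tubes, and has the same number of connected
#' components as the input.
#'
#' @param mask a vessel [binary_mask()].
#' @return skeleton [binary_mask()] with role `"skeleton"`.
#' @export
skeletonize <- function(mask) {
  a <- .mask_array(mask)
  if (!any(a)) stop("empty mask")
  d <- dim(a)
  idx <- which(a, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  sub <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sk <- array(cpp_skeletonize(sub, dim(sub)), dim = dim(sub))
  out <- array(FALSE, dim = d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sk
  binary_mask(out, .mask_voxel(mask), "skeleton")
}

# 26-adjacency edges between TRUE voxels of a logical array.
# Returns list(n, edges = 2-col matrix of vertex ids, len = step lengths in
# voxel units, voxel_index = linear index per vertex).
.adjacency_edges <- function(a) {
  d <- dim(a)
  m <- sum(a)
  id <- array(0L, d)
  id[a] <- seq_len(m)
  from <- list(); to <- list(); len <- list()
  k <- 0L
  for (dz in 0:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) next
    xr <- max(1, 1 - dx):min(d[1], d[1] - dx)
    yr <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zr <- max(1, 1 - dz):min(d[3], d[3] - dz)
    A <- id[xr, yr, zr, drop = FALSE]
    B <- id[xr + dx, yr + dy, zr + dz, drop = FALSE]
    sel <- A > 0L & B > 0L
    if (any(sel)) {
      k <- k + 1L
      from[[k]] <- A[sel]
      to[[k]] <- B[sel]
      len[[k]] <- rep(sqrt(dx^2 + dy^2 + dz^2), sum(sel))
    }
  }
  edges <- if (k > 0L) cbind(unlist(from), unlist(to))
  else matrix(integer(0), ncol = 2)
  list(n = m, edges = edges, len = unlist(len), voxel_index = which(a))
}

# Branch/junction census of a curve graph. Junction vertices (degree >= 3)
# that are adjacent are merged into one junction node; a branch is a maximal
# chain of degree-<=2 vertices together with its attachment edges. Degree-2
# nodes are thereby collapsed. `elen` gives per-edge lengths.
.graph_census <- function(n, edges, elen = NULL) {
  if (is.null(elen)) elen <- rep(1, nrow(edges))
  if (n == 0L)
    return(list(n_branches = 0L, n_junctions = 0L, n_triple_points = 0L,
                n_quadruple_points = 0L, n_endpoints = 0L,
                branches = data.frame(), cluster_degree = integer(0)))
  deg <- tabulate(c(edges), n)
  isJ <- deg >= 3L
  cluster_of <- integer(n)
  n_junctions <- 0L
  if (any(isJ)) {
    Jidx <- which(isJ)
    map <- integer(n); map[Jidx] <- seq_along(Jidx)
    jj <- isJ[edges[, 1]] & isJ[edges[, 2]]
    gj <- igraph::make_empty_graph(length(Jidx), directed = FALSE)
    if (any(jj))
      gj <- igraph::add_edges(gj, rbind(map[edges[jj, 1]], map[edges[jj, 2]]))
    memb <- as.integer(igraph::components(gj)$membership)
    cluster_of[Jidx] <- memb
    n_junctions <- max(memb)
  }
  chain_of <- integer(n)
  n_chains <- 0L
  chain_len <- numeric(0)
  if (any(!isJ)) {
    Ridx <- which(!isJ)
    mapr <- integer(n); mapr[Ridx] <- seq_along(Ridx)
    rr <- !isJ[edges[, 1]] & !isJ[edges[, 2]]
    gr <- igraph::make_empty_graph(length(Ridx), directed = FALSE)
    if (any(rr))
      gr <- igraph::add_edges(gr, rbind(mapr[edges[rr, 1]], mapr[edges[rr, 2]]))
    membr <- as.integer(igraph::components(gr)$membership)
    chain_of[Ridx] <- membr
    n_chains <- max(membr)
    chain_len <- numeric(n_chains)
    if (any(rr)) {
      s <- tapply(elen[rr], chain_of[edges[rr, 1]], sum)
      chain_len[as.integer(names(s))] <- as.numeric(s)
    }
  }
  # attachment incidences: edge with one junction end and one chain end,
  # deduplicated per (chain vertex, cluster)
  mixed <- xor(isJ[edges[, 1]], isJ[edges[, 2]])
  att_u <- integer(0); att_cl <- integer(0); att_len <- numeric(0)
  if (any(mixed)) {
    e1 <- edges[mixed, 1]; e2 <- edges[mixed, 2]; el <- elen[mixed]
    u <- ifelse(isJ[e1], e2, e1)
    cl <- ifelse(isJ[e1], cluster_of[e1], cluster_of[e2])
    key <- paste(u, cl)
    first <- !duplicated(key)
    att_u <- u[first]; att_cl <- cl[first]
    att_len <- as.numeric(tapply(el, key, min)[unique(key)])
  }
  chain_sizes <- if (n_chains > 0) tabulate(chain_of[chain_of > 0L], n_chains) else integer(0)
  att_chain <- chain_of[att_u]
  att_per_chain <- if (n_chains > 0) tabulate(att_chain, n_chains) else integer(0)
  if (length(att_len) && n_chains > 0) {
    s <- tapply(att_len, att_chain, sum)
    chain_len[as.integer(names(s))] <- chain_len[as.integer(names(s))] +
      as.numeric(s)
  }
  # a chain is a branch unless it is a single isolated voxel
  is_branch <- chain_sizes >= 2L | att_per_chain >= 1L
  cluster_degree <- if (n_junctions > 0) tabulate(att_cl, n_junctions) else integer(0)
  # endpoints: degree <= 1 vertices inside branch chains
  n_endpoints <- sum(deg <= 1L & chain_of > 0L &
                       is_branch[pmax(chain_of, 1L)])
  branches <- data.frame()
  if (any(is_branch)) {
    bid <- which(is_branch)
    ends <- vapply(bid, function(ch) {
      cls <- att_cl[att_chain == ch]
      c(if (length(cls) >= 1) sprintf("J%d", cls[1]) else "end",
        if (length(cls) >= 2) sprintf("J%d", cls[2]) else "end")
    }, character(2))
    branches <- data.frame(branch_id = seq_along(bid),
                           from = ends[1, ], to = ends[2, ],
                           length = chain_len[bid],
                           n_voxels = chain_sizes[bid])
    attr(branches, "chain_ids") <- bid
  }
  list(n_branches = as.integer(sum(is_branch)),
       n_junctions = as.integer(n_junctions),
       n_triple_points = as.integer(sum(cluster_degree == 3L)),
       n_quadruple_points = as.integer(sum(cluster_degree == 4L)),
       n_endpoints = as.integer(n_endpoints),
       branches = branches,
       cluster_degree = cluster_degree)
}

#' Branch and junction census of a skeleton
#'
#' Junction voxels are skeleton voxels with three or more skeleton neighbours
#' (26-connectivity); adjacent junction voxels are merged into one junction
#' node before counting. A branch is a vessel segment between junctions or
#' between a junction and an endpoint. Junctions are classified by merged-node
#' degree: triple points have three incident branches, quadruple points four
#' (higher degrees count as junctions but in neither named class).
#'
#' @param skeleton output of [skeletonize()].
#' @param prune_length_um iteratively remove terminal branches shorter than
#'   this length before the census (0 = no pruning, the default).
#' @return list with `stats` (class `SkeletonStats`: `n_branches`,
#'   `n_junctions`, `n_triple_points`, `n_quadruple_points`, `n_endpoints`)
#'   and `graph` (a branch table with end labels and lengths in um).
#' @export
analyze_skeleton <- function(skeleton, prune_length_um = 0) {
  a <- .mask_array(skeleton)
  vox <- .mask_voxel(skeleton)
  if (!any(a)) {
    stats <- structure(list(n_branches = 0L, n_junctions = 0L,
                            n_triple_points = 0L, n_quadruple_points = 0L,
                            n_endpoints = 0L), class = "SkeletonStats")
    return(list(stats = stats, graph = data.frame()))
  }
  repeat {
    g <- .adjacency_edges(a)
    cen <- .graph_census(g$n, g$edges, g$len * vox)
    if (prune_length_um <= 0 || nrow(cen$branches) == 0) break
    term <- cen$branches$from == "end" | cen$branches$to == "end"
    short <- term & cen$branches$length < prune_length_um &
      !(cen$branches$from == "end" & cen$branches$to == "end")
    if (!any(short)) break
    # remove the chain voxels of the short terminal branches
    deg <- tabulate(c(g$edges), g$n)
    chain_of <- .chain_membership(g, deg)
    bid <- which(cen$branches$branch_id %in% cen$branches$branch_id[short])
    drop_chains <- attr(cen$branches, "chain_ids")[bid]
    drop_v <- which(chain_of %in% drop_chains)
    a[g$voxel_index[drop_v]] <- FALSE
  }
  stats <- structure(cen[c("n_branches", "n_junctions", "n_triple_points",
                           "n_quadruple_points", "n_endpoints")],
                     class = "SkeletonStats")
  names(cen$branches)[names(cen$branches) == "length"] <- "length_um"
  list(stats = stats, graph = cen$branches)
}

# chain membership helper used by pruning
.chain_membership <- function(g, deg) {
  n <- g$n
  isJ <- deg >= 3L
  chain_of <- integer(n)
  if (any(!isJ)) {
    Ridx <- which(!isJ)
    mapr <- integer(n); mapr[Ridx] <- seq_along(Ridx)
    rr <- !isJ[g$edges[, 1]] & !isJ[g$edges[, 2]]
    gr <- igraph::make_empty_graph(length(Ridx), directed = FALSE)
    if (any(rr))
      gr <- igraph::add_edges(gr, rbind(mapr[g$edges[rr, 1]],
                                        mapr[g$edges[rr, 2]]))
    chain_of[Ridx] <- as.integer(igraph::components(gr)$membership)
  }
  chain_of
}

#' @export
print.SkeletonStats <- function(x, ...) {
  cat(sprintf(
    "SkeletonStats: %d branches, %d junctions (%d triple, %d quadruple), %d endpoints\n",
    x$n_branches, x$n_junctions, x$n_triple_points, x$n_quadruple_points,
    x$n_endpoints))
  invisible(x)
}
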