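#' Surface voxels of a mask
#'
#' Foreground voxels that are 6-adjacent to observed background. Volume faces
#' are not counted as surface, so structures cut by the VOI boundary do not
#' contribute spurious cut-face surface.
#'
#' @param mask a [binary_mask()].
#' @return surface [binary_mask()] with role `"surface"`.
#' @export
surface_voxels <- function(mask) {
  a <- .mask_array(mask)
  if (!any(a)) stop("empty mask")
  d <- dim(a)
  bg_adj <- array(FALSE, d)
  shift_bg <- function(dx, dy, dz) {
    out <- array(FALSE, d)
    xr <- max(1, 1 + dx):min(d[1], d[1] + dx)
    yr <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zr <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xr, yr, zr] <- !a[xr - dx, yr - dy, zr - dz, drop = FALSE]
    out
  }
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    bg_adj <- bg_adj | shift_bg(o[1], o[2], o[3])
  binary_mask(a & bg_adj, .mask_voxel(mask), "surface")
}

#' Geodesic distance from bone surfaces through non-bone space
#'
#' Shortest-path distance from the bone interface, computed by a
#' priority-queue (Dijkstra) wavefront over the 26-neighbourhood with
#' quasi-Euclidean step weights (1, sqrt(2), sqrt(3) times the voxel size).
#' Seeds are the traversable voxels 6-adjacent to bone, so a distance of 0
#' means "touching bone". By default all non-bone space is traversable
#' (vessel and adipocyte interiors included); set `block_vessels = TRUE` to
#' make vessel interiors opaque while keeping their surface reachable.
#'
#' @param bone bone [binary_mask()] (cortical-inclusive VOI).
#' @param domain optional traversable [binary_mask()]; defaults to non-bone.
#' @param vessels vessel mask, only used when `block_vessels = TRUE`.
#' @param block_vessels make vessel interiors non-traversable.
#' @return an object of class `GeodesicDistanceMap`: list with `data` (array
#'   of distances in micrometres; `Inf` = unreachable, `NA` = outside the
#'   traversable domain) and `voxel_size_um`.
#' @export
geodesic_from_bone <- function(bone, domain = NULL, vessels = NULL,
                               block_vessels = FALSE) {
  b <- .mask_array(bone)
  vox <- .mask_voxel(bone)
  if (!any(b)) stop("no bone voxels: geodesic seed set is empty")
  dom <- if (is.null(domain)) !b else .mask_array(domain) & !b
  if (block_vessels) {
    if (is.null(vessels)) stop("block_vessels = TRUE requires a vessel mask")
    v <- .mask_array(vessels)
    dom <- dom & (!v | .mask_array(surface_voxels(vessels)))
  }
  seeds <- dom & .six_adjacent(b)
  if (!any(seeds)) stop("no traversable voxels adjacent to bone")
  d <- array(cpp_geodesic(dom, seeds, dim(b)), dim = dim(b)) * vox
  structure(list(data = d, voxel_size_um = vox),
            class = "GeodesicDistanceMap")
}

# voxels 6-adjacent to a TRUE voxel of `a`
.six_adjacent <- function(a) {
  d <- dim(a)
  out <- array(FALSE, d)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    xr <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    yr <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zr <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    tmp <- array(FALSE, d)
    tmp[xr, yr, zr] <- a[xr - o[1], yr - o[2], zr - o[3], drop = FALSE]
    out <- out | tmp
  }
  out
}

#' @export
print.GeodesicDistanceMap <- function(x, ...) {
  v <- x$data[is.finite(x$data)]
  cat(sprintf("GeodesicDistanceMap: %d reachable voxels, range %.1f-%.1f um\n",
              length(v), min(v), max(v)))
  invisible(x)
}

#' Vessel-surface-to-bone-surface distance distribution (Ves.S-BS)
#'
#' Samples the geodesic map at the vessel surface voxels and bins the sampled
#' distances with the published convention: 4-um bins from 0 to 52 um plus an
#' open-ended tail. Weights are percent of the reachable sampled voxels and
#' sum to 100; unreachable surface voxels are reported separately.
#'
#' @param dmap a [geodesic_from_bone()] map.
#' @param vessels vessel [binary_mask()] aligned with the map.
#' @param bin_edges_um ascending bin edges, last may be `Inf`.
#' @return an object of class `ProximityDistribution`: data.frame with
#'   `lower_um`, `upper_um`, `weight_pct`, plus attributes
#'   `unreachable_pct` and `n_surface_voxels`.
#' @export
vessel_bone_distance_distribution <- function(dmap, vessels,
                                              bin_edges_um = c(seq(0, 52, by = 4), Inf)) {
  stopifnot(inherits(dmap, "GeodesicDistanceMap"))
  sv <- .mask_array(surface_voxels(vessels))
  if (!identical(dim(sv), dim(dmap$data))) stop("map and vessels are not aligned")
  vals <- dmap$data[sv]
  if (length(vals) == 0) stop("no vessel surface voxels")
  vals[is.na(vals)] <- Inf  # surface voxels outside the domain are unreachable
  reach <- is.finite(vals)
  if (!any(reach)) stop("no vessel surface voxel can reach bone")
  h <- .bin_distribution(vals[reach], bin_edges_um)
  class(h) <- c("ProximityDistribution", class(h))
  attr(h, "unreachable_pct") <- 100 * mean(!reach)
  attr(h, "n_surface_voxels") <- length(vals)
  h
}
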