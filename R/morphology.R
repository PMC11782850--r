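#' Morphological operations with discretized Euclidean balls
#'
#' All structuring elements are discretized Euclidean balls
#' \eqn{\{x : \lVert x \rVert \le r\}} in voxel units, realized exactly through
#' the squared Euclidean distance transform. The image border is handled so
#' that dilation cannot paint outside the volume and erosion only responds to
#' observed background (structures cut by a VOI face keep the cut surface);
#' with these conventions closing and opening are exact morphological duals.
#'
#' @param mask a [binary_mask()] or logical 3D array. 2D images can be passed
#'   as single-slice arrays.
#' @param r ball radius in voxels (`r = 0` is the identity).
#' @return a mask of the same type as the input.
#' @export
ball_dilate <- function(mask, r) {
  a <- .mask_array(mask)
  if (r <= 0) return(mask)
  out <- array(cpp_ball_dilate(a, dim(a), r), dim = dim(a))
  .wrap_like(out, mask)
}

#' @rdname ball_dilate
#' @export
ball_erode <- function(mask, r) {
  a <- .mask_array(mask)
  if (r <= 0) return(mask)
  out <- array(cpp_ball_erode(a, dim(a), r), dim = dim(a))
  .wrap_like(out, mask)
}

#' @rdname ball_dilate
#' @export
ball_open <- function(mask, r) ball_dilate(ball_erode(mask, r), r)

#' @rdname ball_dilate
#' @export
ball_close <- function(mask, r) ball_erode(ball_dilate(mask, r), r)

#' Label connected components of a binary mask
#'
#' @param mask a [binary_mask()] or logical 3D array.
#' @param connectivity voxel adjacency: 6 (faces), 18 (faces+edges) or
#'   26 (faces+edges+corners). Default 26 for foreground.
#' @return integer array of component labels (0 = background), with an
#'   attribute `sizes` giving voxel counts per label.
#' @export
label_components <- function(mask, connectivity = 26L) {
  a <- .mask_array(mask)
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  lab <- array(cpp_label(a, dim(a), as.integer(connectivity)), dim = dim(a))
  n <- max(lab)
  attr(lab, "sizes") <- if (n > 0) tabulate(lab[lab > 0L], n) else integer(0)
  lab
}

#' Remove small speckles from a binary mask
#'
#' White despeckling removes foreground components smaller than `min_voxels`;
#' black despeckling fills enclosed background cavities smaller than
#' `min_voxels` (background components touching the volume border are exempt,
#' since they are not cavities). Components of exactly `min_voxels` voxels
#' survive, i.e. the rule is "remove speckles < min_voxels". The operation is
#' idempotent.
#'
#' @param mask a [binary_mask()] or logical 3D array.
#' @param min_voxels minimum surviving component size (>= 1).
#' @param polarity `"white"` (foreground speckles) or `"black"` (cavities).
#' @param connectivity foreground connectivity; the background cavities use the
#'   complementary connectivity (26 -> 6, 6 -> 26, 18 -> 6).
#' @return a mask of the same type as the input.
#' @export
despeckle <- function(mask, min_voxels, polarity = c("white", "black"),
                      connectivity = 26L) {
  polarity <- match.arg(polarity)
  stopifnot(min_voxels >= 1)
  a <- .mask_array(mask)
  if (polarity == "white") {
    lab <- label_components(a, connectivity)
    sizes <- attr(lab, "sizes")
    if (length(sizes) == 0) return(mask)
    keep <- sizes >= min_voxels
    out <- array(lab > 0L & keep[pmax(lab, 1L)], dim = dim(a))
  } else {
    bg_conn <- if (connectivity == 6L) 26L else 6L
    lab <- label_components(!a, bg_conn)
    sizes <- attr(lab, "sizes")
    if (length(sizes) == 0) return(mask)
    border <- .border_labels(lab)
    fill <- sizes < min_voxels
    fill[border] <- FALSE
    out <- array(a | (lab > 0L & fill[pmax(lab, 1L)]), dim = dim(a))
  }
  .wrap_like(out, mask)
}

# labels present on any face of the array
.border_labels <- function(lab) {
  d <- dim(lab)
  faces <- c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
             lab[, , 1], lab[, , d[3]])
  unique(faces[faces > 0L])
}
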