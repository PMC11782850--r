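#' 3D grayscale image volume
#'
#' Container for a reconstructed CE-CT volume (or any isotropic scalar 3D
#' grid): a numeric array plus its physical voxel size. Slices along the third
#' axis are the tomographic z-stack; `origin_slice` records the growth-plate
#' reference slice used to anchor volumes of interest.
#'
#' @param data numeric 3D array (grayscale).
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @param origin_slice index (1-based) of the anatomical reference slice.
#' @return an object of class `ImageVolume3D`.
#' @export
image_volume <- function(data, voxel_size_um, origin_slice = 1L) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  if (any(dim(data) < 2L))
    stop("volume needs at least 2 voxels per axis")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 origin_slice = as.integer(origin_slice)),
            class = "ImageVolume3D")
}

#' @export
print.ImageVolume3D <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageVolume3D: %d x %d x %d voxels @ %g um (%.0f-%.0f)\n",
              d[1], d[2], d[3], x$voxel_size_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' 3D binary mask
#'
#' Segmentation product aligned to a source volume. `role` records which
#' tissue compartment the mask represents.
#'
#' @param data logical 3D array.
#' @param voxel_size_um voxel size in micrometres.
#' @param role one of `"bone"`, `"marrow"`, `"adipocyte"`, `"vessel"`,
#'   `"skeleton"`, `"surface"`, `"generic"`.
#' @return an object of class `BinaryMask3D`.
#' @export
binary_mask <- function(data, voxel_size_um,
                        role = c("generic", "bone", "marrow", "adipocyte",
                                 "vessel", "skeleton", "surface")) {
  role <- match.arg(role)
  stopifnot(is.array(data), length(dim(data)) == 3L, is.logical(data))
  structure(list(data = data, voxel_size_um = voxel_size_um, role = role),
            class = "BinaryMask3D")
}

#' @export
print.BinaryMask3D <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BinaryMask3D [%s]: %d x %d x %d @ %g um, %d foreground voxels\n",
              x$role, d[1], d[2], d[3], x$voxel_size_um, sum(x$data)))
  invisible(x)
}

# accept either a BinaryMask3D or a bare logical array
.mask_array <- function(m) {
  if (inherits(m, "BinaryMask3D")) m$data
  else if (is.array(m) && is.logical(m)) m
  else stop("expected a BinaryMask3D or a logical array")
}

.mask_voxel <- function(m, default = 1) {
  if (inherits(m, "BinaryMask3D")) m$voxel_size_um else default
}

.same_geometry <- function(a, b) {
  identical(dim(.mask_array(a)), dim(.mask_array(b)))
}

.wrap_like <- function(data, template, role = NULL) {
  if (inherits(template, "BinaryMask3D"))
    binary_mask(data, template$voxel_size_um,
                if (is.null(role)) template$role else role)
  else data
}
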