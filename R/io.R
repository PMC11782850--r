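#' Read and write volumes as multi-page TIFF stacks
#'
#' Volumes are written one page per z-slice as 16-bit grayscale (intensities
#' are stored as value/65535); masks as 8-bit 0/255. Reading restores the
#' numeric scale.
#'
#' @param volume an [image_volume()].
#' @param path file path.
#' @return `write_*` return the path invisibly; `read_volume_tiff` returns an
#'   [image_volume()], `read_mask_tiff` a [binary_mask()].
#' @export
write_volume_tiff <- function(volume, path) {
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[3]), function(z) t(volume$data[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param voxel_size_um voxel size of the stored volume.
#' @export
read_volume_tiff <- function(path, voxel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(d[2], d[1], length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) * 65535
  image_volume(arr, voxel_size_um)
}

#' @rdname write_volume_tiff
#' @param mask a [binary_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  a <- .mask_array(mask)
  d <- dim(a)
  pages <- lapply(seq_len(d[3]), function(z) t(a[, , z]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param role mask role, see [binary_mask()].
#' @export
read_mask_tiff <- function(path, voxel_size_um, role = "generic") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(FALSE, c(d[2], d[1], length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) > 0.5
  binary_mask(arr, voxel_size_um, role)
}

#' Read and write LDF traces as CSV
#'
#' Columns: `time_s`, `perfusion_pu`, plus metadata columns `animal`,
#' `limb`, `week`, `segment`.
#'
#' @param trace an [ldf_trace()].
#' @param path file path.
#' @export
write_ldf_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, perfusion_pu = trace$perfusion_pu,
                   animal = attr(trace, "animal"), limb = attr(trace, "limb"),
                   week = attr(trace, "week"),
                   segment = attr(trace, "segment"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ldf_csv
#' @export
read_ldf_csv <- function(path) {
  df <- read.csv(path)
  ldf_trace(df$time_s, df$perfusion_pu,
            animal = df$animal[1], limb = df$limb[1], week = df$week[1],
            segment = df$segment[1])
}

#' Write polygons (ROI or traces) as JSON
#'
#' Stored as a list of vertex arrays `[[x, y], ...]`.
#'
#' @param polygons matrix or list of matrices.
#' @param path file path.
#' @export
write_polygons_json <- function(polygons, path) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  jsonlite::write_json(lapply(polygons, function(p) unname(as.matrix(p))),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_json
#' @export
read_polygons_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), function(p) {
    m <- as.matrix(p)
    colnames(m) <- c("x", "y")
    m
  })
}
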