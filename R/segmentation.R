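#' Volume-of-interest specification
#'
#' A VOI is an axial crop of the reconstructed volume: it begins at the slice
#' aligned with the proximal edge of the distal growth plate and extends a
#' fixed physical length along the bone axis (1600 um by default, roughly 10%
#' of a mouse femur). Two variants are used per bone: a trabecular VOI
#' excluding cortical bone for marrow morphometry, and a longer,
#' cortical-inclusive VOI for vessel-to-bone proximity.
#'
#' @param start_slice 1-based index of the first slice.
#' @param length_um VOI length along the slice axis, in micrometres.
#' @param include_cortical whether cortical bone is part of the VOI
#'   (provenance flag; the crop itself is identical).
#' @return an object of class `VOISpec`.
#' @export
voi_spec <- function(start_slice, length_um = 1600, include_cortical = FALSE) {
  stopifnot(start_slice >= 1, length_um > 0)
  structure(list(start_slice = as.integer(start_slice),
                 length_um = length_um,
                 include_cortical = isTRUE(include_cortical)),
            class = "VOISpec")
}

#' Crop a volume to a VOI
#'
#' Keeps exactly `round(length_um / voxel_size_um)` slices starting at
#' `start_slice`.
#'
#' @param volume an [image_volume()].
#' @param voi a [voi_spec()].
#' @return the cropped [image_volume()], with the VOI recorded in
#'   attribute `"voi"`.
#' @export
select_voi <- function(volume, voi) {
  stopifnot(inherits(volume, "ImageVolume3D"), inherits(voi, "VOISpec"))
  nz <- dim(volume$data)[3]
  n_slices <- round(voi$length_um / volume$voxel_size_um)
  if (n_slices < 1) stop("VOI shorter than one slice")
  last <- voi$start_slice + n_slices - 1L
  if (voi$start_slice > nz || last > nz) {
    max_len <- (nz - voi$start_slice + 1L) * volume$voxel_size_um
    stop(sprintf(
      "VOI out of bounds: slices %d-%d requested, volume has %d; maximum length from slice %d is %g um",
      voi$start_slice, last, nz, voi$start_slice, max(max_len, 0)))
  }
  out <- image_volume(volume$data[, , voi$start_slice:last, drop = FALSE],
                      volume$voxel_size_um, origin_slice = 1L)
  attr(out, "voi") <- voi
  out
}

#' Otsu threshold of a grayscale sample
#'
#' Maximizes the between-class variance of the intensity histogram.
#'
#' @param x numeric vector or array of intensities.
#' @param levels number of histogram bins.
#' @return the scalar threshold (values strictly above it are "high" class).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  if (diff(r) == 0) stop("degenerate (constant) intensities: no threshold exists")
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  h <- tabulate(bin, levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w1 <- cumsum(as.numeric(h))
  m1 <- cumsum(as.numeric(h) * mids)
  n <- w1[levels]
  mt <- m1[levels]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, levels)
  bcv[valid] <- w1[valid] * w2[valid] *
    (m1[valid] / w1[valid] - (mt - m1[valid]) / w2[valid])^2
  # with empty histogram gaps the criterion plateaus; take the plateau middle
  best <- which(bcv >= max(bcv) * (1 - 1e-12))
  k <- best[ceiling(length(best) / 2)]
  thr <- breaks[k + 1L]
  attr(thr, "separability") <- max(bcv) / (n^2 * stats::var(x))
  thr
}

#' Segment cancellous bone by automatic 3D Otsu thresholding
#'
#' Bone is the high-attenuation class of the full-VOI histogram; the
#' complement is the marrow space (which still contains vessels and
#' adipocytes). A warning is issued when the resulting bone fraction is
#' implausibly extreme, which happens when the volume has no real bone mode
#' and the threshold merely splits noise.
#'
#' @param volume an [image_volume()] (already cropped to the VOI).
#' @param levels histogram bins for the Otsu criterion.
#' @return list with elements `bone` and `marrow` ([binary_mask()]s) and the
#'   scalar `threshold`.
#' @export
segment_bone <- function(volume, levels = 256L) {
  stopifnot(inherits(volume, "ImageVolume3D"))
  thr <- otsu_threshold(volume$data, levels)
  bone <- volume$data > thr
  frac <- mean(bone)
  eta <- attr(thr, "separability")
  if (frac < 0.005 || frac > 0.995 || (!is.na(eta) && eta < 0.75))
    warning(sprintf(
      "bone fraction %.1f%%, class separability %.2f after Otsu: histogram may lack a bone mode (threshold splitting noise)",
      100 * frac, eta))
  list(bone = binary_mask(bone, volume$voxel_size_um, "bone"),
       marrow = binary_mask(!bone, volume$voxel_size_um, "marrow"),
       threshold = as.numeric(thr))
}

#' Morphological segmentation parameters
#'
#' Defaults reproduce the published processing chain for 2-um CE-CT data:
#' adipocytes are cleaned by opening (ball r = 1), closing (ball r = 3) and
#' white+black despeckling below 650 voxels; vessels by closing (r = 4),
#' despeckling below 1050 voxels, closing (r = 6) and despeckling below
#' 5500 voxels. The despeckle volumes are absolute voxel counts and therefore
#' scale with object size: for data at other resolutions, or for phantoms
#' with smaller objects, they should be set to a value below the smallest
#' structure of interest.
#'
#' @param adip_open_r,adip_close_r,adip_dilate_r,vessel_close_r1,vessel_close_r2
#'   ball radii in voxels.
#' @param adip_despeckle_vox,vessel_despeckle1_vox,vessel_despeckle2_vox
#'   despeckle thresholds in voxels.
#' @param bone_dilate_r exclusion radius (voxels) around bone during vessel
#'   thresholding: the blurred marrow-bone interface sweeps through every
#'   intermediate grayscale, so a PSF-scale shell next to bone would
#'   otherwise be misread as vessel (the same partial-volume artifact the
#'   protocol suppresses at adipocyte rims by dilation and subtraction).
#' @param adipocyte_threshold,vessel_threshold global grayscale cuts
#'   (`"manual"` means not yet chosen; numeric values are required before
#'   segmenting). Adipocytes are segmented below their threshold (unstained
#'   fat is dark), vessels above theirs (contrast-stained tissue is bright).
#' @param connectivity foreground connectivity for despeckling and component
#'   counts.
#' @return an object of class `MorphoParams`.
#' @export
morpho_params <- function(adip_open_r = 1, adip_close_r = 3,
                          adip_despeckle_vox = 650, adip_dilate_r = 5,
                          vessel_close_r1 = 4, vessel_despeckle1_vox = 1050,
                          vessel_close_r2 = 6, vessel_despeckle2_vox = 5500,
                          bone_dilate_r = 2,
                          adipocyte_threshold = "manual",
                          vessel_threshold = "manual",
                          connectivity = 26L) {
  stopifnot(adip_open_r >= 0, adip_close_r >= 0, adip_dilate_r >= 0,
            vessel_close_r1 >= 0, vessel_close_r2 >= 0,
            adip_despeckle_vox >= 1, vessel_despeckle1_vox >= 1,
            vessel_despeckle2_vox >= 1, connectivity %in% c(6L, 18L, 26L))
  structure(list(adip_open_r = adip_open_r, adip_close_r = adip_close_r,
                 adip_despeckle_vox = adip_despeckle_vox,
                 adip_dilate_r = adip_dilate_r,
                 vessel_close_r1 = vessel_close_r1,
                 vessel_despeckle1_vox = vessel_despeckle1_vox,
                 vessel_close_r2 = vessel_close_r2,
                 vessel_despeckle2_vox = vessel_despeckle2_vox,
                 bone_dilate_r = bone_dilate_r,
                 adipocyte_threshold = adipocyte_threshold,
                 vessel_threshold = vessel_threshold,
                 connectivity = as.integer(connectivity)),
            class = "MorphoParams")
}

.check_threshold <- function(thr, volume, what, bright) {
  if (!is.numeric(thr))
    stop(sprintf("%s threshold is '%s': a numeric global threshold is required",
                 what, as.character(thr)))
  r <- range(volume$data)
  # a cut past the near end of the range would select the whole volume:
  # certainly an operator error. A cut past the far end selects nothing,
  # which is a meaningful (empty) result, e.g. after rim suppression.
  if ((bright && thr <= r[1]) || (!bright && thr >= r[2]))
    stop(sprintf("%s threshold %g outside the volume's dynamic range [%g, %g]: it would select the entire volume",
                 what, thr, r[1], r[2]))
  if ((bright && thr > r[2]) || (!bright && thr < r[1]))
    warning(sprintf("%s threshold %g beyond the dynamic range [%g, %g]: empty mask",
                    what, thr, r[1], r[2]))
  thr
}

#' Suggest a global threshold at the histogram valley between two modes
#'
#' Convenience for phantom work: finds the minimum of a smoothed histogram
#' between two stated intensity modes. Real scans use operator-chosen values.
#'
#' @param volume an [image_volume()] or numeric array.
#' @param mode_lo,mode_hi the two mode intensities bracketing the valley.
#' @param bins histogram bins across the full range.
#' @return scalar threshold.
#' @export
suggest_threshold <- function(volume, mode_lo, mode_hi, bins = 512L) {
  x <- if (inherits(volume, "ImageVolume3D")) volume$data else volume
  stopifnot(mode_lo < mode_hi)
  breaks <- seq(min(x), max(x), length.out = bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), bins)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  # light smoothing to avoid empty-bin minima
  k <- c(1, 2, 3, 2, 1) / 9
  hs <- as.numeric(stats::filter(h, k, sides = 2))
  hs[is.na(hs)] <- h[is.na(hs)]
  sel <- mids > mode_lo & mids < mode_hi
  if (!any(sel)) stop("no histogram bins between the stated modes")
  mids[sel][which.min(hs[sel])]
}

#' Segment marrow adipocytes
#'
#' Global threshold (adipocytes are the dark, unstained compartment) followed
#' by opening, closing, white despeckling and black despeckling, restricted to
#' the marrow space.
#'
#' @param volume an [image_volume()] (the VOI).
#' @param marrow marrow [binary_mask()] from [segment_bone()].
#' @param params a [morpho_params()] with a numeric `adipocyte_threshold`.
#' @return adipocyte [binary_mask()].
#' @export
segment_adipocytes <- function(volume, marrow, params = morpho_params()) {
  stopifnot(inherits(volume, "ImageVolume3D"))
  thr <- .check_threshold(params$adipocyte_threshold, volume, "adipocyte", bright = FALSE)
  m <- (volume$data <= thr) & .mask_array(marrow)
  m <- .mask_array(ball_open(m, params$adip_open_r))
  m <- .mask_array(ball_close(m, params$adip_close_r))
  m <- .mask_array(despeckle(m, params$adip_despeckle_vox, "white",
                             params$connectivity))
  m <- .mask_array(despeckle(m, params$adip_despeckle_vox, "black",
                             params$connectivity))
  m <- m & .mask_array(marrow)
  binary_mask(m, volume$voxel_size_um, "adipocyte")
}

#' Suppress partial-volume rims around adipocytes
#'
#' The bright halo at adipocyte boundaries (a partial-volume artifact) has
#' grayscale values similar to contrast-stained vessels. Before vessel
#' thresholding, the adipocytes are dilated (ball r = 5 by default) and the
#' dilated region is re-leveled to the marrow background intensity (median of
#' marrow voxels outside the dilated adipocytes), which removes the rims from
#' vessel candidacy deterministically.
#'
#' @param volume an [image_volume()].
#' @param adipocytes adipocyte [binary_mask()].
#' @param params a [morpho_params()] (uses `adip_dilate_r`).
#' @param marrow optional marrow mask used for the background reference;
#'   defaults to the whole volume outside the dilated adipocytes.
#' @return a new [image_volume()] with the rims re-leveled.
#' @export
suppress_adipocyte_edges <- function(volume, adipocytes,
                                     params = morpho_params(),
                                     marrow = NULL) {
  stopifnot(inherits(volume, "ImageVolume3D"))
  adip <- .mask_array(adipocytes)
  if (!any(adip)) return(volume)
  region <- .mask_array(ball_dilate(adip, params$adip_dilate_r))
  outside <- !region
  if (!is.null(marrow)) outside <- outside & .mask_array(marrow)
  ref <- median(volume$data[outside])
  out <- volume
  out$data[region] <- ref
  out
}

#' Segment blood vessels
#'
#' Global threshold (vessels are bright after contrast staining) on the
#' edge-suppressed volume, then closing (r = 4), despeckling (< 1050 voxels),
#' closing (r = 6) and despeckling (< 5500 voxels), restricted to marrow and
#' forced disjoint from the adipocyte mask.
#'
#' @param volume the edge-suppressed [image_volume()]
#'   (see [suppress_adipocyte_edges()]).
#' @param marrow marrow [binary_mask()].
#' @param params a [morpho_params()] with a numeric `vessel_threshold`.
#' @param adipocytes optional adipocyte mask to exclude.
#' @param bone optional bone mask; its `bone_dilate_r` dilation is excluded
#'   from vessel candidacy to suppress the bone partial-volume halo.
#' @return vessel [binary_mask()].
#' @export
segment_vessels <- function(volume, marrow, params = morpho_params(),
                            adipocytes = NULL, bone = NULL) {
  stopifnot(inherits(volume, "ImageVolume3D"))
  thr <- .check_threshold(params$vessel_threshold, volume, "vessel", bright = TRUE)
  m <- (volume$data >= thr) & .mask_array(marrow)
  bone_zone <- NULL
  if (!is.null(bone) && params$bone_dilate_r > 0) {
    bone_zone <- .mask_array(ball_dilate(.mask_array(bone),
                                         params$bone_dilate_r))
    m <- m & !bone_zone
  }
  m <- .mask_array(ball_close(m, params$vessel_close_r1))
  m <- .mask_array(despeckle(m, params$vessel_despeckle1_vox, "white",
                             params$connectivity))
  m <- .mask_array(ball_close(m, params$vessel_close_r2))
  m <- .mask_array(despeckle(m, params$vessel_despeckle2_vox, "white",
                             params$connectivity))
  m <- m & .mask_array(marrow)
  if (!is.null(adipocytes)) m <- m & !.mask_array(adipocytes)
  if (!is.null(bone_zone)) m <- m & !bone_zone  # closings regrow into the halo
  binary_mask(m, volume$voxel_size_um, "vessel")
}
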