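#' Two-channel immunofluorescence section
#'
#' Holds the EMCN and CD31 maximum-intensity-projection channels of one bone
#' section together with the analysis region of interest (a polygon drawn to
#' cover 10% of the tibia length in the original protocol; consumed here as
#' input).
#'
#' @param channels named list with numeric matrices `EMCN` and `CD31` of
#'   identical dimensions (x by y, pixel centers at integer coordinates).
#' @param pixel_size_um pixel size, um.
#' @param roi_polygon closed simple polygon (n x 2 matrix of x,y vertices).
#' @return an object of class `IFSection`.
#' @export
if_section <- function(channels, pixel_size_um, roi_polygon) {
  stopifnot(is.list(channels), all(c("EMCN", "CD31") %in% names(channels)))
  if (!identical(dim(channels$EMCN), dim(channels$CD31)))
    stop("channels must have identical dimensions")
  roi_polygon <- as.matrix(roi_polygon)
  if (nrow(roi_polygon) < 3) stop("ROI polygon needs at least 3 vertices")
  if (.polygon_self_intersects(roi_polygon))
    stop("ROI polygon is self-intersecting")
  if (abs(polygon_area(roi_polygon)) <= 0) stop("ROI polygon has zero area")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 roi_polygon = roi_polygon),
            class = "IFSection")
}

#' Shoelace area of a polygon
#'
#' @param poly n x 2 matrix of vertices.
#' @return signed area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# segment-intersection test for self-intersection of a closed polygon
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  inter <- function(p1, p2, p3, p4)
    ccw(p1, p3, p4) != ccw(p2, p3, p4) && ccw(p1, p2, p3) != ccw(p1, p2, p4)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      s1 <- seg(i); s2 <- seg(j)
      if (inter(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize polygons to a pixel mask (even-odd fill)
#'
#' Scanline rasterization at integer pixel centers; each polygon is filled by
#' the even-odd rule and the results are unioned. Self-intersecting polygons
#' are rejected.
#'
#' @param polygons a single n x 2 matrix or a list of them.
#' @param shape c(width, height) of the target mask.
#' @return logical matrix of dimension `shape`.
#' @export
rasterize_polygons <- function(polygons, shape) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  out <- matrix(FALSE, shape[1], shape[2])
  for (pi in seq_along(polygons)) {
    poly <- as.matrix(polygons[[pi]])
    if (.polygon_self_intersects(poly))
      stop(sprintf("polygon %d is self-intersecting", pi))
    x <- poly[, 1]; y <- poly[, 2]
    n <- nrow(poly)
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    for (row in seq_len(shape[2])) {
      yy <- row
      crosses <- ((y <= yy & yn > yy) | (yn <= yy & y > yy))
      if (!any(crosses)) next
      xs <- sort(x[crosses] + (yy - y[crosses]) *
                   (xn[crosses] - x[crosses]) / (yn[crosses] - y[crosses]))
      for (k in seq(1, length(xs) - 1, by = 2)) {
        cols <- which(seq_len(shape[1]) > xs[k] + 1e-12 &
                        seq_len(shape[1]) <= xs[k + 1] + 1e-12)
        out[cols, row] <- TRUE
      }
    }
  }
  out
}

# ROI polygon -> pixel mask for a section
.roi_mask <- function(section) {
  rasterize_polygons(section$roi_polygon, dim(section$channels$EMCN))
}

#' Binarize the EMCN channel by adaptive thresholding
#'
#' A pixel is positive when its intensity exceeds the local arithmetic mean
#' over a square window plus `offset`; the mask is then refined by opening
#' (disc r = 1) and closing (disc r = 2) and restricted to the ROI. The local
#' mean is computed with an integral image; at the borders the window is
#' clipped to the image. When the window covers the whole image the rule
#' reduces to a global mean threshold.
#'
#' @param section an [if_section()].
#' @param window_px odd window width, >= 3; default: nearest odd integer to
#'   1/8 of the ROI bounding-box width.
#' @param offset added to the local mean before comparison.
#' @return logical matrix (the EMCN mask).
#' @export
emcn_mask <- function(section, window_px = NULL, offset = 0) {
  img <- section$channels$EMCN
  d <- dim(img)
  if (is.null(window_px)) {
    bbw <- diff(range(section$roi_polygon[, 1]))
    window_px <- max(3L, 2L * floor(bbw / 16) + 1L)
  }
  if (window_px < 3 || window_px %% 2 == 0)
    stop("window_px must be odd and >= 3")
  if (window_px > 2 * max(d))
    stop("window larger than the image")
  lm <- .local_mean(img, (window_px - 1L) / 2L)
  m <- img > lm + offset
  m3 <- array(m, c(d, 1L))
  m3 <- .mask_array(ball_close(ball_open(m3, 1), 2))
  m <- m3[, , 1]
  m & .roi_mask(section)
}

# clipped-window local mean via integral image
.local_mean <- function(img, half) {
  d <- dim(img)
  # S[i+1, j+1] = sum(img[1:i, 1:j])
  S <- matrix(0, d[1] + 1L, d[2] + 1L)
  cs <- apply(img, 2, cumsum)            # cumsum down rows (x)
  S[-1, -1] <- t(apply(cs, 1, cumsum))   # then across columns (y)
  x0 <- pmax(seq_len(d[1]) - half, 1L); x1 <- pmin(seq_len(d[1]) + half, d[1])
  y0 <- pmax(seq_len(d[2]) - half, 1L); y1 <- pmin(seq_len(d[2]) + half, d[2])
  A <- S[x1 + 1L, y1 + 1L, drop = FALSE]
  B <- S[x0, y1 + 1L, drop = FALSE]
  C <- S[x1 + 1L, y0, drop = FALSE]
  D <- S[x0, y0, drop = FALSE]
  cnt <- outer(x1 - x0 + 1L, y1 - y0 + 1L)
  (A - B - C + D) / cnt
}

#' Rasterize manually traced CD31 polygons into a mask
#'
#' @param traces list of polygons (n x 2 matrices) as traced by the operator.
#' @param shape c(width, height) of the target mask.
#' @param roi optional ROI mask (logical matrix) to clip against.
#' @return logical matrix (the CD31 mask).
#' @export
cd31_mask_from_roi <- function(traces, shape, roi = NULL) {
  m <- rasterize_polygons(traces, shape)
  if (!is.null(roi)) m <- m & roi
  m
}

#' Type-H area fractions from CD31 and EMCN masks
#'
#' Type-H endothelium is the exact pixel intersection of the CD31 and EMCN
#' masks. Areas are reported as percent of the ROI pixel count.
#'
#' @param cd31,emcn logical matrices.
#' @param roi logical ROI matrix.
#' @return an object of class `CompositionResult` with fields
#'   `emcn_area_pct`, `cd31_area_pct`, `typeh_area_pct`,
#'   `n_sections_averaged`, and the `typeh_mask`.
#' @export
type_h <- function(cd31, emcn, roi) {
  stopifnot(identical(dim(cd31), dim(emcn)), identical(dim(cd31), dim(roi)))
  n <- sum(roi)
  if (n == 0) stop("empty ROI")
  th <- cd31 & emcn & roi
  structure(list(emcn_area_pct = 100 * sum(emcn & roi) / n,
                 cd31_area_pct = 100 * sum(cd31 & roi) / n,
                 typeh_area_pct = 100 * sum(th) / n,
                 n_sections_averaged = 1L,
                 typeh_mask = th),
            class = "CompositionResult")
}

#' @export
print.CompositionResult <- function(x, ...) {
  cat(sprintf(
    "CompositionResult: EMCN %.2f%%, CD31 %.2f%%, type H %.2f%% (n = %d sections)\n",
    x$emcn_area_pct, x$cd31_area_pct, x$typeh_area_pct,
    x$n_sections_averaged))
  invisible(x)
}

#' Average composition results over sections of one bone
#'
#' @param results list of [type_h()] results (typically two sections).
#' @return a `CompositionResult` with per-field arithmetic means.
#' @export
average_sections <- function(results) {
  if (length(results) == 0) stop("no section results to average")
  stopifnot(all(vapply(results, inherits, logical(1), "CompositionResult")))
  structure(list(
    emcn_area_pct = mean(vapply(results, `[[`, numeric(1), "emcn_area_pct")),
    cd31_area_pct = mean(vapply(results, `[[`, numeric(1), "cd31_area_pct")),
    typeh_area_pct = mean(vapply(results, `[[`, numeric(1), "typeh_area_pct")),
    n_sections_averaged = sum(vapply(results, `[[`, integer(1),
                                     "n_sections_averaged")),
    typeh_mask = NULL), class = "CompositionResult")
}

#' Quantify one IF section end to end
#'
#' Convenience wrapper: EMCN mask by adaptive threshold and morphology, CD31
#' mask from traced polygons, type-H intersection, all relative to the ROI.
#'
#' @param section an [if_section()].
#' @param traces CD31 trace polygons.
#' @param window_px,offset passed to [emcn_mask()].
#' @return a `CompositionResult`.
#' @export
quantify_if_section <- function(section, traces, window_px = NULL,
                                offset = 0) {
  roi <- .roi_mask(section)
  em <- emcn_mask(section, window_px, offset)
  cd <- cd31_mask_from_roi(traces, dim(section$channels$CD31), roi)
  type_h(cd, em, roi)
}
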