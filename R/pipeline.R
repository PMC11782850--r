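#' Configuration for a full osteovascular quantification run
#'
#' Either a phantom spec (synthetic input) or a path to a reconstructed TIFF
#' stack, plus the segmentation, morphometry, network and proximity settings.
#'
#' @param phantom optional [phantom_spec()]; mutually exclusive with
#'   `volume_path`.
#' @param volume_path optional path to a multi-page TIFF volume.
#' @param voxel_size_um voxel size of the input volume (required with
#'   `volume_path`).
#' @param voi optional [voi_spec()] for the morphometry VOI (cortical
#'   excluded).
#' @param voi_proximity optional [voi_spec()] for the proximity VOI (cortical
#'   included); defaults to the morphometry VOI.
#' @param params a [morpho_params()]. Thresholds left `"manual"` are filled
#'   from the phantom's intensity-mode midpoints when a phantom is supplied.
#' @param thickness_bins_um,proximity_bins_um histogram bin edges.
#' @param connectivity component connectivity.
#' @param block_vessels make vessel interiors non-traversable for the
#'   geodesic stage.
#' @param compute_thickness compute the local thickness map (may be skipped
#'   for large volumes).
#' @param prune_length_um terminal-branch pruning for the skeleton census
#'   (0 = none).
#' @param if_inputs optional list of IF inputs, each
#'   `list(section = if_section, traces = list of polygons)`.
#' @param ldf_segments optional list of lists of [ldf_trace()]s (repeated
#'   measurements per bone).
#' @param out_dir optional output directory for masks and reports.
#' @param seed RNG seed recorded in the report.
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(phantom = NULL, volume_path = NULL,
                       voxel_size_um = NULL, voi = NULL,
                       voi_proximity = NULL, params = morpho_params(),
                       thickness_bins_um = c(seq(2, 66, by = 4), Inf),
                       proximity_bins_um = c(seq(0, 52, by = 4), Inf),
                       connectivity = 26L, block_vessels = FALSE,
                       compute_thickness = TRUE, prune_length_um = 0,
                       if_inputs = NULL, ldf_segments = NULL,
                       out_dir = NULL, seed = 1L) {
  if (is.null(phantom) == is.null(volume_path))
    stop("supply exactly one of `phantom` or `volume_path`")
  if (!is.null(volume_path)) {
    if (!file.exists(volume_path)) stop("volume_path does not exist: ", volume_path)
    if (is.null(voxel_size_um)) stop("voxel_size_um required with volume_path")
  }
  structure(list(phantom = phantom, volume_path = volume_path,
                 voxel_size_um = voxel_size_um, voi = voi,
                 voi_proximity = voi_proximity, params = params,
                 thickness_bins_um = thickness_bins_um,
                 proximity_bins_um = proximity_bins_um,
                 connectivity = as.integer(connectivity),
                 block_vessels = isTRUE(block_vessels),
                 compute_thickness = isTRUE(compute_thickness),
                 prune_length_um = prune_length_um,
                 if_inputs = if_inputs, ldf_segments = ldf_segments,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Hash of a run configuration
#'
#' MD5 of the deparsed configuration, recorded in every report so results are
#' traceable to their settings. The output directory is excluded: where the
#' results are written does not change what they are.
#'
#' @param config a [run_config()].
#' @return hex string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(cfg, control = "exact"), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full quantification pipeline
#'
#' Stages in the published order: bone removal (Otsu), adipocyte
#' segmentation, partial-volume edge suppression, vessel segmentation, then
#' morphometry, skeleton census and vessel-bone proximity; optional IF and
#' LDF reductions. The report is deterministic for a fixed configuration:
#' rerunning the same config reproduces it bit-identically.
#'
#' @param config a [run_config()].
#' @return an object of class `RunReport`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  chash <- config_hash(config)
  truth <- NULL
  if (!is.null(config$phantom)) {
    gen <- .stage("phantom", generate_cect_phantom(config$phantom))
    vol <- gen$volume
    truth <- gen$truth
  } else {
    vol <- .stage("load", read_volume_tiff(config$volume_path,
                                           config$voxel_size_um))
  }
  if (!is.null(config$voi)) vol <- .stage("voi", select_voi(vol, config$voi))

  params <- config$params
  if (!is.null(config$phantom)) {
    thr <- phantom_thresholds(config$phantom)
    if (!is.numeric(params$adipocyte_threshold))
      params$adipocyte_threshold <- thr$adipocyte
    if (!is.numeric(params$vessel_threshold))
      params$vessel_threshold <- thr$vessel
  }

  seg <- .stage("bone", segment_bone(vol))
  adip <- if (!is.null(config$phantom) && config$phantom$n_adipocytes == 0)
    binary_mask(array(FALSE, dim(vol$data)), vol$voxel_size_um, "adipocyte")
  else
    .stage("adipocytes", segment_adipocytes(vol, seg$marrow, params))
  vol_s <- .stage("edge_suppression",
                  suppress_adipocyte_edges(vol, adip, params, seg$marrow))
  vess <- .stage("vessels",
                 segment_vessels(vol_s, seg$marrow, params, adip, seg$bone))

  morpho <- .stage("morphometry",
                   morphometry(seg$marrow, adip, vess,
                               connectivity = config$connectivity,
                               thickness_bins_um = config$thickness_bins_um,
                               compute_thickness = config$compute_thickness))

  skel_res <- NULL
  if (any(vess$data)) {
    skel <- .stage("skeleton", skeletonize(vess))
    skel_res <- .stage("census",
                       analyze_skeleton(skel, config$prune_length_um))
  }

  prox <- NULL
  if (any(seg$bone$data) && any(vess$data)) {
    vol_p <- if (is.null(config$voi_proximity)) vol else
      .stage("voi_proximity", select_voi(vol, config$voi_proximity))
    dmap <- .stage("geodesic",
                   geodesic_from_bone(seg$bone, vessels = vess,
                                      block_vessels = config$block_vessels))
    prox <- .stage("proximity",
                   vessel_bone_distance_distribution(
                     dmap, vess, config$proximity_bins_um))
  }

  composition <- NULL
  if (!is.null(config$if_inputs)) {
    composition <- .stage("ifquant", average_sections(lapply(
      config$if_inputs, function(inp)
        quantify_if_section(inp$section, inp$traces))))
  }

  perfusion <- NULL
  if (!is.null(config$ldf_segments)) {
    perfusion <- .stage("perfusion",
                        lapply(config$ldf_segments, weighted_mean_perfusion))
  }

  report <- structure(list(
    config_hash = chash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("osteovasc")),
    otsu_threshold = seg$threshold,
    adipocyte_threshold = params$adipocyte_threshold,
    vessel_threshold = params$vessel_threshold,
    morphometry = morpho,
    skeleton = skel_res,
    proximity = prox,
    composition = composition,
    perfusion = perfusion,
    truth = truth), class = "RunReport")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask_tiff(seg$bone, file.path(config$out_dir, "bone.tif"))
    write_mask_tiff(adip, file.path(config$out_dir, "adipocytes.tif"))
    write_mask_tiff(vess, file.path(config$out_dir, "vessels.tif"))
    write_report_json(report, file.path(config$out_dir, "report.json"))
    if (!is.null(skel_res) && nrow(skel_res$graph) > 0)
      write.csv(skel_res$graph, file.path(config$out_dir, "branches.csv"),
                row.names = FALSE)
  }
  report
}

#' Serialize a run report to JSON
#'
#' Numeric values are written at full precision; the serialization is
#' deterministic, so identical reports produce identical files.
#'
#' @param report a [run_pipeline()] report.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$truth <- NULL  # ground truth is phantom metadata, not a measurement
  x$morphometry <- unclass(x$morphometry)
  if (!is.null(x$skeleton)) {
    x$skeleton$stats <- unclass(x$skeleton$stats)
    attr(x$skeleton$graph, "chain_ids") <- NULL
  }
  if (!is.null(x$proximity)) {
    prox <- as.data.frame(x$proximity)
    x$proximity <- list(bins = prox,
                        unreachable_pct = attr(x$proximity, "unreachable_pct"))
  }
  if (!is.null(x$composition)) {
    x$composition <- unclass(x$composition)
    x$composition$typeh_mask <- NULL
  }
  if (!is.null(x$perfusion)) x$perfusion <- lapply(x$perfusion, unclass)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport (config %s)\n", substr(x$config_hash, 1, 8)))
  print(x$morphometry)
  if (!is.null(x$skeleton)) print(x$skeleton$stats)
  if (!is.null(x$proximity)) {
    cat(sprintf("Proximity: %.1f%% of vessel surface within 4 um of bone\n",
                x$proximity$weight_pct[1]))
  }
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}
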