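#' Default pixel scale of the 6 x 6 mm en face grid
#'
#' The en face scans are 6 x 6 mm nominal; at a 1024-pixel raster this gives
#' 6000/1024 = 5.859 um per pixel, consistent with the annotation-protocol
#' constant of 2.5 px corresponding to about 14.65 um. The scale is
#' configurable per image because device rasters differ.
#'
#' @return micrometers per pixel
#' @export
default_pixel_size_um <- function() 6000 / 1024

#' Convert a pixel length to micrometers
#'
#' @param length_px nonnegative length in pixels
#' @param pixel_size_um micrometers per pixel
#' @return length in micrometers
#' @examples
#' px_to_um(2.5)  # ~14.65 um, the annotation-protocol threshold
#' @export
px_to_um <- function(length_px, pixel_size_um = default_pixel_size_um()) {
  if (any(length_px < 0)) parameter_error("length_px must be nonnegative")
  length_px * pixel_size_um
}

#' Run configuration
#'
#' Collects every tunable of the metric pipeline with its default. All
#' lengths are micrometers.
#'
#' @param pixel_size_um raster scale (default 6000/1024)
#' @param min_component_px smallest accepted foreground component
#' @param n_boundary_samples ellipse-boundary samples in the containment
#'   penalty of [fit_inner_ellipse()]
#' @param tol_um containment tolerance of the inner-ellipse fit
#' @param n_restarts multi-starts of the inner-ellipse fit
#' @param n_points boundary samples per shape for the distance metrics
#' @param cd_reduction Chamfer reduction, see [chamfer()]
#' @param convexity_convention see [convexity()]
#' @param seed integer seed
#' @return a list of class `faz_config`
#' @export
faz_config <- function(pixel_size_um = default_pixel_size_um(),
                       min_component_px = 16, n_boundary_samples = 256,
                       tol_um = 0.5, n_restarts = 8, n_points = 512,
                       cd_reduction = "mean_of_directions",
                       convexity_convention = "standard", seed = 1L) {
  cfg <- list(pixel_size_um = pixel_size_um,
              min_component_px = min_component_px,
              n_boundary_samples = n_boundary_samples, tol_um = tol_um,
              n_restarts = n_restarts, n_points = n_points,
              cd_reduction = cd_reduction,
              convexity_convention = convexity_convention,
              seed = as.integer(seed))
  num <- c("pixel_size_um", "min_component_px", "n_boundary_samples",
           "tol_um", "n_restarts", "n_points")
  if (any(vapply(cfg[num], function(v) !is.numeric(v) || v <= 0, logical(1))))
    config_error("numeric config fields must be positive")
  structure(cfg, class = "faz_config")
}

#' Read a binary FAZ mask from PNG or TIFF
#'
#' Nonzero pixels are foreground. Multi-channel images are reduced by "any
#' channel nonzero".
#'
#' @param path file path ending in .png, .tif or .tiff
#' @param pixel_size_um micrometers per pixel
#' @return a `faz_mask`: list with `pixels` (0/1 matrix, `[row, col]`,
#'   top-left origin) and `pixel_size_um`
#' @export
read_faz_mask <- function(path, pixel_size_um = default_pixel_size_um()) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    parameter_error(paste("unsupported mask format:", ext)))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
  structure(list(pixels = (img > 0) * 1L, pixel_size_um = pixel_size_um),
            class = "faz_mask")
}

#' Write a binary FAZ mask as PNG
#'
#' @param mask a `faz_mask` or binary matrix
#' @param path output path
#' @export
write_faz_mask <- function(mask, path) {
  px <- if (inherits(mask, "faz_mask")) mask$pixels else mask
  png::writePNG((px != 0) * 1, path)
  invisible(path)
}

#' Read a QuPath GeoJSON annotation as a FAZ polygon
#'
#' Reads a GeoJSON `FeatureCollection` (or single `Feature`/`Polygon`) as
#' exported by QuPath, takes the first `Polygon` feature's exterior ring,
#' and scales the pixel coordinates to micrometers. The y axis follows the
#' image convention (down-positive), as in QuPath exports.
#'
#' @param path GeoJSON file path
#' @param pixel_size_um micrometers per pixel applied to the coordinates
#' @return a [faz_polygon()]
#' @export
read_qupath_geojson <- function(path, pixel_size_um = default_pixel_size_um()) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(gj$type %||% "",
    FeatureCollection = lapply(gj$features, function(f) f$geometry),
    Feature = list(gj$geometry),
    Polygon = list(gj),
    parameter_error("not a GeoJSON FeatureCollection/Feature/Polygon"))
  geoms <- Filter(function(g) identical(g$type, "Polygon"), geoms)
  if (!length(geoms)) no_foreground_error("no Polygon feature in GeoJSON")
  ring <- geoms[[1]]$coordinates[[1]]
  xy <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  faz_polygon(xy[, 1] * pixel_size_um, xy[, 2] * pixel_size_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute all nine FAZ biomarkers for one polygon
#'
#' @param p a [faz_polygon()] in micrometers
#' @param cfg a [faz_config()]
#' @return a one-row data.frame with the full metric record and fit
#'   diagnostics
#' @export
compute_metrics <- function(p, cfg = faz_config()) {
  p <- faz_polygon(p)
  cm <- classic_metrics(p, convexity_convention = cfg$convexity_convention)
  fit <- fit_inner_ellipse(p, n_boundary_samples = cfg$n_boundary_samples,
                           tol_um = cfg$tol_um, n_restarts = cfg$n_restarts,
                           seed = cfg$seed)
  dd <- faz_ie_distances(p, fit, n_points = cfg$n_points,
                         cd_reduction = cfg$cd_reduction)
  cbind(cm,
        data.frame(area_mm2 = cm$area_um2 / 1e6,
                   ie_area_um2 = ellipse_area(fit$ellipse),
                   diff_ie_um2 = diff_inner_ellipse(p, fit),
                   hd_um = dd$hd_um, cd_um2 = dd$cd_um2,
                   ie_violation_um = fit$containment_violation_um,
                   ie_converged = fit$converged))
}

#' Batch metric computation over mask and GeoJSON files
#'
#' Processes each input file (PNG/TIFF masks or QuPath GeoJSON polygons),
#' computes the full biomarker record, and optionally writes a CSV plus
#' per-image JSON diagnostics. Failures are logged per file and the run
#' continues; the function errors only when every input fails.
#'
#' @param paths character vector of input files
#' @param cfg a [faz_config()]
#' @param csv_path optional output CSV path (see [write_metrics_csv()])
#' @param diagnostics_dir optional directory for per-image JSON sidecars
#'   with the inner-ellipse fit diagnostics
#' @return a data.frame with one row per successful input: `patient_id`
#'   (file stem), `eye` (parsed from a trailing `_OD`/`_OS` in the stem, else
#'   `NA`), `pixel_size_um`, and the metric columns
#' @export
compute_all <- function(paths, cfg = faz_config(), csv_path = NULL,
                        diagnostics_dir = NULL) {
  rows <- list(); failures <- character(0)
  for (path in paths) {
    rec <- tryCatch({
      ext <- tolower(tools::file_ext(path))
      p <- if (ext %in% c("geojson", "json")) {
        read_qupath_geojson(path, cfg$pixel_size_um)
      } else {
        mask_to_polygon(read_faz_mask(path, cfg$pixel_size_um),
                        min_component_px = cfg$min_component_px)
      }
      m <- compute_metrics(p, cfg)
      stem <- tools::file_path_sans_ext(basename(path))
      eye <- if (grepl("_(OD|OS)$", stem)) sub(".*_(OD|OS)$", "\\1", stem)
             else NA_character_
      if (!is.null(diagnostics_dir)) {
        jsonlite::write_json(
          list(file = basename(path),
               containment_violation_um = m$ie_violation_um,
               n_restarts = cfg$n_restarts, converged = m$ie_converged),
          file.path(diagnostics_dir, paste0(stem, "_ie_fit.json")),
          auto_unbox = TRUE, digits = NA)
      }
      cbind(data.frame(patient_id = stem, eye = eye,
                       pixel_size_um = cfg$pixel_size_um), m)
    }, error = function(e) {
      message(sprintf("fazmetrics: skipping %s: %s", path, conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) failures <- c(failures, path) else rows <- c(rows, list(rec))
  }
  if (!length(rows))
    data_error(sprintf("all %d input(s) failed", length(failures)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(csv_path)) write_metrics_csv(res, csv_path, cfg)
  res
}

#' Write / read the metrics CSV
#'
#' RFC 4180 CSV with `#`-prefixed header comments capturing the
#' configuration for provenance. Numeric values are written with 12
#' significant digits so that a write-read round trip reproduces the file
#' byte-identically.
#'
#' @param records metrics data.frame from [compute_all()]
#' @param path output path
#' @param cfg the [faz_config()] used (recorded in the header)
#' @export
write_metrics_csv <- function(records, path, cfg = faz_config()) {
  hdr <- c("# fazmetrics metrics CSV v1",
           vapply(names(cfg), function(k)
             sprintf("# %s=%s", k, format(cfg[[k]], digits = 12)),
             character(1)))
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.12g", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @return `read_metrics_csv()`: the records data.frame (header comments
#'   skipped)
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
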