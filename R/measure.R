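#' Resolved run configuration
#'
#' All tunable thresholds of the measurement pipeline with their defaults.
#' Zone radii stay at the standard (0.5, 1, 2) disc-diameter breaks unless
#' explicitly overridden.
#'
#' @param ... Overrides of the defaults listed below.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    rgb_tolerance = 0.25,          # RGB input decoding tolerance (0-1)
    min_vessel_fraction = 0.01,    # quality floor for vessel coverage
    zone_breaks = c(A = 0.5, B = 1, C = 2),  # DD from the disc edge
    junction_gap_factor = 1.2,     # junction merge gap, x local width
    spur_min_length_um = 0,        # absolute spur floor
    spur_width_factor = 2,         # spur threshold, x local width
    count_crossings_as_bifurcations = FALSE,
    smooth_window = 5L,            # polyline smoothing (points)
    angle_min_fit_px = 5,          # minimum direction-fit window
    density_region = "image",      # "image" or "2dd"
    box_min_size = 4L,             # smallest box-counting size (px)
    q_range = seq(-3, 3, by = 0.5),
    knudtson_n_largest = 6L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Measure the full parameter panel of one segmentation map
#'
#' Runs the whole pipeline on one eye: disc fit and zone construction,
#' per-class skeletonization, graph extraction and spur pruning, Zone C
#' branching and length statistics, fractal panel on the class centerlines,
#' Zone B Knudtson equivalents, and vessel densities.
#'
#' @param map A [segmentation_map()].
#' @param config A [run_config()].
#' @return List of class `eye_measurement`: `record` (the
#'   [morphometry_record()] row), `annuli`, per-class `graphs`, `caliber`,
#'   `fractal`, and quality `warnings`.
#' @export
measure_map <- function(map, config = run_config()) {
  stopifnot(inherits(map, "segmentation_map"))
  warns <- validate_quality(map, config$min_vessel_fraction)
  disc <- fit_disc(map$disc)
  annuli <- zone_annuli(disc, config$zone_breaks)
  sp <- map$pixel_spacing
  graphs <- list(); skels <- list(); branch <- list(); lenstats <- list()
  for (cls in c("artery", "vein")) {
    mask <- map[[cls]]
    skel <- skeletonize(mask)
    g <- extract_graph(skel, mask, sp, vessel_class = cls,
                       junction_gap_factor = config$junction_gap_factor)
    g <- prune_spurs(g, min_length = config$spur_min_length_um,
                     width_factor = config$spur_width_factor)
    skels[[cls]] <- skel
    graphs[[cls]] <- g
    branch[[cls]] <- zone_c_branch_stats(
      g, annuli, count_crossings = config$count_crossings_as_bifurcations)
    lenstats[[cls]] <- zone_c_length_stats(refine_junctions(g), annuli,
                                           config$smooth_window)
  }
  fr <- fractal_panel(skels$artery, skels$vein,
                      sizes = default_box_sizes(map$height, map$width,
                                                config$box_min_size),
                      q_range = config$q_range)
  cal <- caliber_panel(graphs$artery, graphs$vein, annuli,
                       n_largest = config$knudtson_n_largest)
  dens <- densities(map$artery, map$vein, skels$artery, skels$vein,
                    annuli = annuli, region = config$density_region)
  rec <- morphometry_record(
    avr = cal$avr, crae = cal$crae, crve = cal$crve,
    d0_a = fr$d0_a, d1_a = fr$d1_a, d2_a = fr$d2_a, sl_a = fr$sl_a,
    d0_v = fr$d0_v, d1_v = fr$d1_v, d2_v = fr$d2_v, sl_v = fr$sl_v,
    length_avg_a = lenstats$artery$length_avg,
    length_avg_v = lenstats$vein$length_avg,
    curvature_avg_a = lenstats$artery$curvature_avg,
    curvature_avg_v = lenstats$vein$curvature_avg,
    angle_avg_a = branch$artery$angle_avg,
    angle_avg_v = branch$vein$angle_avg,
    asymmetry_avg_a = branch$artery$asymmetry_avg,
    asymmetry_avg_v = branch$vein$asymmetry_avg,
    branch_avg_a = branch$artery$branch_avg,
    branch_avg_v = branch$vein$branch_avg,
    vessel_length_density = dens$vessel_length_density,
    vessel_density = dens$vessel_density,
    source_id = map$source_id)
  structure(list(record = rec, annuli = annuli, graphs = graphs,
                 caliber = cal, fractal = fr, branch = branch,
                 warnings = warns),
            class = "eye_measurement")
}

#' @export
print.eye_measurement <- function(x, ...) {
  cat("eye_measurement '", x$record$source_id, "'\n", sep = "")
  rec <- x$record
  num <- vapply(rec[, setdiff(names(rec), "source_id")], identity, numeric(1))
  print(round(num, 4))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

# discover <id>_artery/_vein/_disc triplets in a directory
discover_mask_sets <- function(dir) {
  files <- list.files(dir, pattern = "_artery\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  if (length(files) == 0L)
    stop("no '*_artery.png' masks found in ", dir, call. = FALSE)
  lapply(files, function(f) {
    stem <- sub("_artery\\.(png|tif|tiff)$", "", f, ignore.case = TRUE)
    ext <- tools::file_ext(f)
    list(id = stem,
         artery = file.path(dir, f),
         vein = file.path(dir, paste0(stem, "_vein.", ext)),
         disc = file.path(dir, paste0(stem, "_disc.", ext)))
  })
}

#' Batch measurement
#'
#' Measures a list of segmentation maps (or a directory of
#' `<id>_artery/_vein/_disc` raster triplets) and optionally writes the
#' records CSV.  Per-image failures do not abort the batch: the failed image
#' contributes an all-missing row and a `failures` entry.
#'
#' @param maps List of [segmentation_map()]s, or a directory path.
#' @param pixel_spacing Micrometers per pixel (required when `maps` is a
#'   directory).
#' @param out_csv Optional output CSV path.
#' @param config A [run_config()].
#' @return List of class `measure_batch`: `records` (data frame),
#'   `measurements`, `failures` (named character of error messages).
#' @export
measure <- function(maps, pixel_spacing = NULL, out_csv = NULL,
                    config = run_config()) {
  if (is.character(maps) && length(maps) == 1L && dir.exists(maps)) {
    if (is.null(pixel_spacing))
      stop("pixel_spacing is required when reading masks from a directory",
           call. = FALSE)
    sets <- discover_mask_sets(maps)
    maps <- lapply(sets, function(s) {
      tryCatch(read_segmentation(artery = s$artery, vein = s$vein,
                                 disc = s$disc,
                                 pixel_spacing = pixel_spacing,
                                 source_id = s$id,
                                 rgb_tolerance = config$rgb_tolerance),
               error = function(e) structure(list(id = s$id,
                                                  msg = conditionMessage(e)),
                                             class = "load_failure"))
    })
  }
  records <- list(); meas <- list(); failures <- character(0)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (inherits(m, "load_failure")) {
      failures[m$id] <- m$msg
      records[[i]] <- morphometry_record(source_id = m$id)
      next
    }
    res <- tryCatch(measure_map(m, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[m$source_id] <- conditionMessage(res)
      records[[i]] <- morphometry_record(source_id = m$source_id)
    } else {
      records[[i]] <- res$record
      meas[[m$source_id]] <- res
    }
  }
  df <- do.call(rbind, records)
  if (!is.null(out_csv)) write_records_csv(records, out_csv)
  structure(list(records = df, measurements = meas, failures = failures),
            class = "measure_batch")
}

#' @export
print.measure_batch <- function(x, ...) {
  cat("measure_batch:", nrow(x$records), "row(s),",
      length(x$failures), "failure(s)\n")
  invisible(x)
}

#' Write a zone-overlay debug image
#'
#' Renders the vessel masks with the fitted disc circle and the three zone
#' boundaries as rings, as an RGB PNG.
#'
#' @param map A [segmentation_map()].
#' @param annuli A [zone_annuli()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_zone_overlay <- function(map, annuli, path) {
  h <- map$height; w <- map$width
  img <- array(0, c(h, w, 3))
  img[, , 1] <- map$artery
  img[, , 3] <- map$vein
  img[, , 1] <- pmax(img[, , 1], map$disc * 0.8)
  img[, , 2] <- pmax(img[, , 2], map$disc * 0.8)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  d <- sqrt((xs - annuli$disc$center[["x"]])^2 +
            (ys - annuli$disc$center[["y"]])^2)
  for (r in annuli$radii) {
    ring <- abs(d - r) < 0.75
    img[, , 2][ring] <- 1
  }
  png::writePNG(img, path)
  invisible(path)
}
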