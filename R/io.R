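#' Parameter names of a morphometry record
#'
#' Fixed column order of the per-eye parameter vector: caliber equivalents,
#' fractal dimensions, length/branching metrics (artery `_a`, vein `_v`
#' suffixes) and the two density measures, followed by `source_id`.
#'
#' @return Character vector of the 24 column names.
#' @export
record_fields <- function() {
  c("avr", "crae", "crve",
    "d0_a", "d1_a", "d2_a", "sl_a",
    "d0_v", "d1_v", "d2_v", "sl_v",
    "length_avg_a", "length_avg_v",
    "curvature_avg_a", "curvature_avg_v",
    "angle_avg_a", "angle_avg_v",
    "asymmetry_avg_a", "asymmetry_avg_v",
    "branch_avg_a", "branch_avg_v",
    "vessel_length_density", "vessel_density",
    "source_id")
}

#' Construct a segmentation map
#'
#' Bundles binary artery, vein and optic-disc rasters with the physical pixel
#' spacing.  Any nonzero raster value is treated as foreground.
#'
#' @param artery,vein,disc Numeric/logical matrices of identical dimensions.
#' @param pixel_spacing Pixel spacing in micrometers per pixel (positive).
#' @param source_id Free-text image identifier.
#' @return An object of class `segmentation_map` with binary 0/1 integer
#'   matrices `artery`, `vein`, `disc` plus `pixel_spacing` and `source_id`.
#' @export
segmentation_map <- function(artery, vein, disc, pixel_spacing,
                             source_id = "") {
  chans <- list(artery = artery, vein = vein, disc = disc)
  for (nm in names(chans)) {
    if (!is.matrix(chans[[nm]]))
      stop("channel '", nm, "' is not a matrix", call. = FALSE)
  }
  dims <- vapply(chans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- names(chans)[which(dims[1, ] != dims[1, 1] |
                              dims[2, ] != dims[2, 1])[1]]
    stop("dimension mismatch: channel '", bad, "' is ",
         dims[1, bad], "x", dims[2, bad], " but '", names(chans)[1],
         "' is ", dims[1, 1], "x", dims[2, 1], call. = FALSE)
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be a single positive number (um/pixel)",
         call. = FALSE)
  bin <- lapply(chans, function(m) {
    m <- matrix(as.integer(m != 0), nrow(m), ncol(m))
    m
  })
  structure(list(artery = bin$artery, vein = bin$vein, disc = bin$disc,
                 height = nrow(bin$artery), width = ncol(bin$artery),
                 pixel_spacing = as.numeric(pixel_spacing),
                 source_id = as.character(source_id)),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat("segmentation_map",
      if (nzchar(x$source_id)) paste0(" '", x$source_id, "'"),
      "\n  ", x$height, "x", x$width, " px @ ", x$pixel_spacing,
      " um/px\n", sep = "")
  cat(sprintf("  artery: %d px  vein: %d px  disc: %d px\n",
              sum(x$artery), sum(x$vein), sum(x$disc)))
  invisible(x)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' for ", path, call. = FALSE))
  img
}

#' Read a segmentation map from raster files
#'
#' Accepts either three single-channel rasters (`artery`, `vein`, `disc`
#' paths) or a single RGB raster (`rgb` path) with the conventional coloring
#' red = artery, blue = vein, yellow = disc.  Grayscale channels are
#' binarized as value > 0.
#'
#' @param artery,vein,disc Paths to single-channel PNG/TIFF rasters.
#' @param rgb Path to one RGB raster (alternative input dialect).
#' @param pixel_spacing Micrometers per pixel (required, positive).
#' @param source_id Identifier; defaults to the first file name.
#' @param rgb_tolerance Channel tolerance (0-1 scale) used when decoding the
#'   RGB dialect.
#' @return A [segmentation_map()].
#' @export
read_segmentation <- function(artery = NULL, vein = NULL, disc = NULL,
                              rgb = NULL, pixel_spacing,
                              source_id = NULL, rgb_tolerance = 0.25) {
  if (!is.null(rgb)) {
    img <- read_raster(rgb)
    if (length(dim(img)) != 3L || dim(img)[3] < 3L)
      stop("rgb raster must have >= 3 channels: ", rgb, call. = FALSE)
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
    tol <- rgb_tolerance
    a_mask <- r > 1 - tol & g < tol & b < tol
    v_mask <- b > 1 - tol & r < tol & g < tol
    d_mask <- r > 1 - tol & g > 1 - tol & b < tol
    if (is.null(source_id)) source_id <- basename(rgb)
    return(segmentation_map(a_mask, v_mask, d_mask, pixel_spacing, source_id))
  }
  paths <- list(artery = artery, vein = vein, disc = disc)
  if (any(vapply(paths, is.null, logical(1))))
    stop("provide either rgb= or all three of artery=, vein=, disc=",
         call. = FALSE)
  chans <- lapply(paths, function(p) {
    img <- read_raster(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel of gray+alpha
    img
  })
  if (is.null(source_id)) source_id <- basename(paths$artery)
  segmentation_map(chans$artery, chans$vein, chans$disc, pixel_spacing,
                   source_id)
}

#' Write segmentation masks as PNG files
#'
#' Inverse of [read_segmentation()] in the three-raster dialect; writes
#' binary masks as 8-bit grayscale PNGs.
#'
#' @param map A [segmentation_map()].
#' @param artery,vein,disc Output paths.
#' @return Invisibly, the three paths.
#' @export
write_segmentation <- function(map, artery, vein, disc) {
  stopifnot(inherits(map, "segmentation_map"))
  png::writePNG(map$artery + 0, artery)
  png::writePNG(map$vein + 0, vein)
  png::writePNG(map$disc + 0, disc)
  invisible(c(artery = artery, vein = vein, disc = disc))
}

#' Assemble a morphometry record
#'
#' One value per parameter; parameters not supplied are missing (`NA`), which
#' the CSV writer renders as an empty cell.
#'
#' @param ... Named parameter values from [record_fields()].
#' @param source_id Image identifier.
#' @return A one-row data frame of class `morphometry_record` with the fixed
#'   column order.
#' @export
morphometry_record <- function(..., source_id = "") {
  vals <- list(...)
  fields <- record_fields()
  unknown <- setdiff(names(vals), fields)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rec <- as.list(rep(NA_real_, length(fields) - 1L))
  names(rec) <- fields[-length(fields)]
  for (nm in names(vals)) rec[[nm]] <- as.numeric(vals[[nm]])
  rec$source_id <- as.character(source_id)
  out <- as.data.frame(rec, stringsAsFactors = FALSE)
  class(out) <- c("morphometry_record", class(out))
  out
}

#' Write morphometry records to CSV
#'
#' Header uses the fixed parameter names; missing values become empty cells
#' (blank, not the text "NA"/"NaN").
#'
#' @param records A list of records or a data frame of stacked records.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_records_csv <- function(records, path) {
  if (inherits(records, "data.frame")) records <- list(records)
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  df <- do.call(rbind, lapply(records, function(r) {
    r <- as.data.frame(r, stringsAsFactors = FALSE)
    missing_cols <- setdiff(record_fields(), names(r))
    for (m in missing_cols) r[[m]] <- NA_real_
    r[, record_fields(), drop = FALSE]
  }))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a morphometry record CSV
#'
#' @param path CSV written by [write_records_csv()] (or with the same header).
#' @return Data frame with one row per eye; blank cells become `NA`.
#' @export
read_records_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = setNames(
                   c(rep("numeric", length(record_fields()) - 1L), "character"),
                   record_fields()))
  df
}

#' Advisory quality checks for a segmentation map
#'
#' Flags conditions under which downstream zone-based measurement is
#' unreliable: an empty disc mask, a disc touching the image border (zones
#' would be truncated), and a vessel foreground fraction below a floor.
#' Never modifies its input.
#'
#' @param map A [segmentation_map()].
#' @param min_vessel_fraction Warn when (artery | vein) foreground fraction is
#'   below this value.
#' @return Character vector of warnings (length 0 when all checks pass).
#' @export
validate_quality <- function(map, min_vessel_fraction = 0.01) {
  stopifnot(inherits(map, "segmentation_map"))
  warnings <- character(0)
  if (sum(map$disc) == 0) {
    warnings <- c(warnings, "no optic disc: disc mask is empty")
  } else {
    idx <- which(map$disc != 0, arr.ind = TRUE)
    if (any(idx[, 1] == 1L | idx[, 1] == map$height |
            idx[, 2] == 1L | idx[, 2] == map$width))
      warnings <- c(warnings, "optic disc touches the image border")
  }
  vf <- sum(map$artery | map$vein) / (map$height * map$width)
  if (vf < min_vessel_fraction)
    warnings <- c(warnings,
                  sprintf("vessel foreground fraction %.4f below floor %.4f",
                          vf, min_vessel_fraction))
  warnings
}
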