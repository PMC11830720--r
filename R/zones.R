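#' Fit the optic disc as an equivalent-area circle
#'
#' The disc is summarized by the centroid of its mask and the diameter of the
#' circle with the same pixel area, `2*sqrt(area/pi)`.  An elliptical or
#' ragged mask therefore yields a scalar "disc diameter" (DD), the distance
#' unit of the measurement zones.
#'
#' @param disc_mask Binary raster (matrix), nonzero = disc.
#' @return Object of class `optic_disc`: `center` (x, y in pixel units),
#'   `diameter` and `radius` in pixels.
#' @export
fit_disc <- function(disc_mask) {
  idx <- which(disc_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no disc: disc mask is empty", call. = FALSE)
  center <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  area <- nrow(idx)
  diameter <- 2 * sqrt(area / pi)
  structure(list(center = center, diameter = diameter, radius = diameter / 2),
            class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("optic_disc: center (%.1f, %.1f) px, diameter %.1f px\n",
              x$center["x"], x$center["y"], x$diameter))
  invisible(x)
}

#' Annular measurement zones around the optic disc
#'
#' Zones are annuli at fixed multiples of the disc diameter (DD) measured
#' outward from the disc *edge*: Zone A spans (0, 0.5] DD, Zone B (0.5, 1] DD
#' and Zone C (1, 2] DD.  Boundary points belong to the inner zone.
#'
#' @param disc An [fit_disc()] result.
#' @param breaks Outer edges of zones A, B, C in DD from the disc edge.
#' @return Object of class `zone_annuli` with the disc and the absolute
#'   radial break points (pixels from disc center).
#' @export
zone_annuli <- function(disc, breaks = c(A = 0.5, B = 1, C = 2)) {
  stopifnot(inherits(disc, "optic_disc"), length(breaks) == 3L,
            all(diff(c(0, breaks)) > 0))
  radii <- disc$radius + breaks * disc$diameter
  structure(list(disc = disc, breaks_dd = breaks,
                 radii = c(disc = disc$radius, A = radii[[1]],
                           B = radii[[2]], C = radii[[3]])),
            class = "zone_annuli")
}

#' Zone label of a point
#'
#' @param x,y Point coordinates in pixels (vectorized).
#' @param annuli A [zone_annuli()].
#' @return Character vector with values `"disc"`, `"A"`, `"B"`, `"C"` or
#'   `"outside"`.
#' @export
zone_of <- function(x, y, annuli) {
  stopifnot(inherits(annuli, "zone_annuli"))
  ctr <- annuli$disc$center
  d <- sqrt((x - ctr[["x"]])^2 + (y - ctr[["y"]])^2)
  r <- annuli$radii
  out <- rep("outside", length(d))
  out[d <= r[["C"]]] <- "C"
  out[d <= r[["B"]]] <- "B"
  out[d <= r[["A"]]] <- "A"
  out[d <= r[["disc"]]] <- "disc"
  out
}

# Radial distance of polyline points from the disc center (pixels).
radial_dist <- function(poly, disc) {
  sqrt((poly[, 1] - disc$center[["x"]])^2 + (poly[, 2] - disc$center[["y"]])^2)
}

# Split one polyline (with optional widths) into maximal runs whose points all
# lie inside [r_in, r_out] (half-open outward handled by zone_of's caller:
# here membership is r > r_in & r <= r_out, with r_in = 0 meaning no inner
# bound). Returns list of list(polyline, widths).
clip_polyline_annulus <- function(poly, widths, disc, r_in, r_out) {
  d <- radial_dist(poly, disc)
  inside <- d > r_in & d <= r_out
  if (!any(inside)) return(list())
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- list()
  for (k in keep) {
    i <- starts[k]:ends[k]
    if (length(i) < 2L) next  # stubs of a single point dropped
    out[[length(out) + 1L]] <- list(polyline = poly[i, , drop = FALSE],
                                    widths = if (is.null(widths)) NULL
                                             else widths[i])
  }
  out
}

#' Restrict a vessel graph to one zone
#'
#' Segments are truncated at the zone's radial boundaries; pieces shorter
#' than two points are dropped.  Nodes keep their original kinds; a
#' bifurcation belongs to the zone containing its node position.
#'
#' @param graph A `vessel_graph` (see [extract_graph()]).
#' @param annuli A [zone_annuli()].
#' @param zone One of `"A"`, `"B"`, `"C"` (or `"disc"`).
#' @return A `vessel_graph` whose segments are the clipped pieces.  Clipped
#'   pieces carry `tree_id` inherited from their source segment; node/segment
#'   incidence is not preserved across clipping (clipped stubs have no node
#'   ids).
#' @export
clip_to_zone <- function(graph, annuli, zone = "C") {
  stopifnot(inherits(graph, "vessel_graph"), inherits(annuli, "zone_annuli"))
  r <- annuli$radii
  bounds <- switch(zone,
    disc = c(0, r[["disc"]]),
    A = c(r[["disc"]], r[["A"]]),
    B = c(r[["A"]], r[["B"]]),
    C = c(r[["B"]], r[["C"]]),
    stop("unknown zone '", zone, "'", call. = FALSE))
  segs <- list()
  for (s in graph$segments) {
    pieces <- clip_polyline_annulus(s$polyline, s$widths, annuli$disc,
                                    bounds[1], bounds[2])
    for (p in pieces) {
      segs[[length(segs) + 1L]] <- list(
        polyline = p$polyline, widths = p$widths,
        from = NA_integer_, to = NA_integer_,
        tree_id = s$tree_id, vessel_class = s$vessel_class)
    }
  }
  structure(list(nodes = graph$nodes, segments = segs,
                 vessel_class = graph$vessel_class,
                 spacing = graph$spacing, annuli = annuli, zone = zone),
            class = "vessel_graph")
}
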