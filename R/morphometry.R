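#' Angle between two daughter directions
#'
#' The bifurcation angle is the angle subtended by the two daughter branches,
#' each summarized by a unit direction pointing away from the node.
#'
#' @param parent_dir,d1_dir,d2_dir Direction vectors (length 2); only the
#'   daughters enter the angle, the parent is accepted for symmetry of the
#'   interface.
#' @return Angle in degrees, in (0, 180].
#' @export
bifurcation_angle <- function(parent_dir = NULL, d1_dir, d2_dir) {
  for (v in list(d1_dir, d2_dir)) {
    if (sqrt(sum(v^2)) == 0) stop("zero-length direction vector", call. = FALSE)
  }
  u1 <- d1_dir / sqrt(sum(d1_dir^2))
  u2 <- d2_dir / sqrt(sum(d2_dir^2))
  acos(pmin(1, pmax(-1, sum(u1 * u2)))) * 180 / pi
}

#' Squared-caliber branching asymmetry
#'
#' Asymmetry index of the two daughter calibers on a 0-100 scale:
#' `100 * (1 - (min/max)^2)`.  0 means equal daughters.
#'
#' @param w1,w2 Daughter widths (um), positive.
#' @return Asymmetry percent in \[0, 100\].
#' @export
bifurcation_asymmetry <- function(w1, w2) {
  if (any(c(w1, w2) <= 0)) stop("daughter widths must be positive",
                                call. = FALSE)
  r <- min(w1, w2) / max(w1, w2)
  100 * (1 - r^2)
}

#' Arc-chord tortuosity of a polyline
#'
#' Ratio of the centerline arc length to the straight-line distance between
#' its endpoints; 1 for a straight vessel, larger for curved ones.
#'
#' @param polyline n x 2 coordinate matrix, n >= 2.
#' @return Dimensionless ratio >= 1 (up to discretization), or `NA` with a
#'   warning when the endpoints coincide (closed loop).
#' @export
segment_tortuosity <- function(polyline) {
  stopifnot(is.matrix(polyline), nrow(polyline) >= 2L)
  chord <- sqrt(sum((polyline[nrow(polyline), ] - polyline[1, ])^2))
  if (chord < .Machine$double.eps^0.5) {
    warning("coincident endpoints: tortuosity undefined")
    return(NA_real_)
  }
  polyline_arc_px(polyline) / chord
}

# Direction of a polyline away from one end, by least-squares line fit over
# the points whose arc distance from that end lies in (skip_px, skip_px +
# fit_px]; sign oriented away from the end point.  Falls back to the overall
# chord when too few points fall in the window.
direction_at <- function(poly, end = c("start", "end"), skip_px = 0,
                         fit_px = 5) {
  end <- match.arg(end)
  if (end == "end") poly <- poly[nrow(poly):1, , drop = FALSE]
  arc <- c(0, cumsum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)))
  sel <- arc > skip_px & arc <= skip_px + fit_px
  if (sum(sel) < 2L) {
    # short branch: chord from the first point past the skip to the tip
    i0 <- which(arc > skip_px)[1]
    if (is.na(i0) || i0 >= nrow(poly)) i0 <- max(1L, nrow(poly) - 1L)
    v <- poly[nrow(poly), ] - poly[i0, ]
    if (sum(v^2) == 0) v <- poly[nrow(poly), ] - poly[1, ]
    if (sum(v^2) == 0) return(c(NA_real_, NA_real_))
    return(v / sqrt(sum(v^2)))
  }
  w <- poly[sel, , drop = FALSE]
  ctr <- colMeans(w)
  cv <- crossprod(sweep(w, 2, ctr))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (sum(ev * (ctr - poly[1, ])) < 0) ev <- -ev
  ev
}

#' Measure every bifurcation of a vessel graph
#'
#' For each degree-3 node the three incident branches are identified; when
#' zones are supplied the parent is the branch heading back toward the disc
#' (vessel trees are disc-rooted), otherwise the widest branch.  Branch
#' directions are least-squares line fits over a caliber-scaled window away
#' from the node (see `skip_widths`).  Degree-4 nodes are crossing suspects
#' and excluded by default; nodes of degree 5 or more are always excluded.
#'
#' @param graph A `vessel_graph` with width-annotated segments.
#' @param annuli Optional [zone_annuli()]; adds a `zone` column.
#' @param count_crossings Include degree-4 nodes as bifurcations.
#' @param min_fit_px Minimum direction-fit window (pixels).
#' @param skip_widths,fit_widths Direction window placement in units of the
#'   local width: the fit spans arc `(skip_widths * w, skip_widths * w +
#'   max(min_fit_px, fit_widths * w)]` from the node.  The defaults (skip
#'   1.5 widths, fit 4 widths) clear the junction blob -- where the medial
#'   axis of merging strokes is biased -- and average the direction over a
#'   caliber-scaled arc, the scale at which a branch angle is well defined
#'   on a discrete skeleton.
#' @return Data frame: `node`, `x`, `y`, `tree_id`, `angle` (degrees),
#'   `asymmetry` (percent), `parent_width`, `daughter_width_1`,
#'   `daughter_width_2` (um), and `zone` when `annuli` is given.
#' @export
bifurcation_measures <- function(graph, annuli = NULL,
                                 count_crossings = FALSE, min_fit_px = 5,
                                 skip_widths = 1.5, fit_widths = 4) {
  stopifnot(inherits(graph, "vessel_graph"))
  kinds <- c("bifurcation", if (count_crossings) "crossing-suspect")
  n_complex <- sum(graph$nodes$kind == "complex")
  if (n_complex > 0)
    message(n_complex, " node(s) of degree >= 5 excluded from bifurcation ",
            "statistics")
  ids <- graph$nodes$id[graph$nodes$kind %in% kinds]
  sp <- graph$spacing
  rows <- list()
  for (id in ids) {
    inc <- which(vapply(graph$segments, function(s)
      identical(s$from, id) || identical(s$to, id), logical(1)))
    branches <- lapply(graph$segments[inc], function(s) {
      # orient polyline to start at this node
      at_start <- identical(s$from, id)
      poly <- if (at_start) s$polyline
              else s$polyline[nrow(s$polyline):1, , drop = FALSE]
      w <- if (at_start) s$widths else rev(s$widths)
      arc <- c(0, cumsum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)))
      w_loc <- median(w[arc <= max(min_fit_px, arc[length(arc)] / 3)])
      list(poly = poly, widths = w, w_loc = w_loc)
    })
    if (length(branches) < 3L) next
    node <- graph$nodes[graph$nodes$id == id, ]
    all_dirs <- lapply(branches, function(b) {
      w_px <- b$w_loc / sp
      direction_at(smooth_polyline(b$poly), "start",
                   skip_px = skip_widths * w_px,
                   fit_px = max(min_fit_px, fit_widths * w_px))
    })
    if (any(is.na(unlist(all_dirs)))) next
    if (!is.null(annuli)) {
      # parent flows in from the disc: most disc-ward branch direction
      radial <- c(node$x - annuli$disc$center[["x"]],
                  node$y - annuli$disc$center[["y"]])
      radial <- radial / max(sqrt(sum(radial^2)), .Machine$double.eps)
      ord <- order(vapply(all_dirs, function(d) sum(d * radial), numeric(1)))
    } else {
      ord <- order(vapply(branches, `[[`, numeric(1), "w_loc"),
                   decreasing = TRUE)
    }
    parent <- branches[[ord[1]]]
    d1 <- branches[[ord[2]]]; d2 <- branches[[ord[3]]]
    dirs <- all_dirs[ord[2:3]]
    # daughter caliber sampled past the junction shoulder
    dwidth <- vapply(list(d1, d2), function(b) {
      arc <- c(0, cumsum(sqrt(diff(b$poly[, 1])^2 + diff(b$poly[, 2])^2)))
      w_px <- b$w_loc / sp
      sk <- skip_widths * w_px
      sel <- arc > sk & arc <= sk + max(min_fit_px, fit_widths * w_px)
      if (sum(sel) < 1L) b$w_loc else median(b$widths[sel])
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      node = id, x = node$x, y = node$y, tree_id = node$tree_id,
      angle = bifurcation_angle(NULL, dirs[[1]], dirs[[2]]),
      asymmetry = bifurcation_asymmetry(dwidth[1], dwidth[2]),
      parent_width = parent$w_loc,
      daughter_width_1 = dwidth[1], daughter_width_2 = dwidth[2])
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(node = integer(0), x = numeric(0), y = numeric(0),
                         tree_id = integer(0), angle = numeric(0),
                         asymmetry = numeric(0), parent_width = numeric(0),
                         daughter_width_1 = numeric(0),
                         daughter_width_2 = numeric(0))
  if (!is.null(annuli)) out$zone <- if (nrow(out)) zone_of(out$x, out$y, annuli)
                                    else character(0)
  out
}

# tree ids of components "rooted at the disc margin": components with at
# least one node no farther than the Zone A outer edge from the disc center
rooted_tree_ids <- function(graph, annuli) {
  if (nrow(graph$nodes) == 0L) return(integer(0))
  d <- sqrt((graph$nodes$x - annuli$disc$center[["x"]])^2 +
            (graph$nodes$y - annuli$disc$center[["y"]])^2)
  sort(unique(graph$nodes$tree_id[d <= annuli$radii[["A"]]]))
}

#' Zone C branching statistics
#'
#' Mean bifurcation angle, mean asymmetry, and the mean number of Zone C
#' bifurcations per disc-rooted vessel tree.  All three are missing when the
#' class has no Zone C bifurcation (blank-cell rule).
#'
#' @param graph A `vessel_graph` of one vessel class (unclipped).
#' @param annuli A [zone_annuli()].
#' @param count_crossings Treat degree-4 nodes as bifurcations.
#' @return List with `angle_avg`, `asymmetry_avg`, `branch_avg` (all `NA`
#'   when no Zone C bifurcation exists) and the `measures` table.
#' @export
zone_c_branch_stats <- function(graph, annuli, count_crossings = FALSE,
                                ...) {
  meas <- bifurcation_measures(graph, annuli, count_crossings, ...)
  zc <- meas[!is.na(meas$zone) & meas$zone == "C", , drop = FALSE]
  if (nrow(zc) == 0L)
    return(list(angle_avg = NA_real_, asymmetry_avg = NA_real_,
                branch_avg = NA_real_, measures = meas))
  roots <- rooted_tree_ids(graph, annuli)
  branch_avg <- if (length(roots))
    mean(vapply(roots, function(tid) sum(zc$tree_id == tid), numeric(1)))
  else NA_real_
  list(angle_avg = mean(zc$angle), asymmetry_avg = mean(zc$asymmetry),
       branch_avg = branch_avg, measures = meas)
}

#' Zone C segment length and tortuosity
#'
#' Segments are clipped to Zone C; each clipped piece contributes its
#' smoothed arc length (um) and arc-chord tortuosity.  Pieces with undefined
#' tortuosity (coincident endpoints) are excluded from the tortuosity mean.
#'
#' @param graph A `vessel_graph` of one vessel class (unclipped).
#' @param annuli A [zone_annuli()].
#' @param smooth_window Polyline smoothing window (points).
#' @param min_piece_um Clipped pieces shorter than this (boundary-crossing
#'   fragments) are excluded from both averages.
#' @return List with `length_avg` (um), `curvature_avg`, `n_segments`; both
#'   averages `NA` when Zone C holds no segment.
#' @export
zone_c_length_stats <- function(graph, annuli, smooth_window = 5L,
                                min_piece_um = 60) {
  clipped <- clip_to_zone(graph, annuli, "C")
  if (length(clipped$segments) == 0L)
    return(list(length_avg = NA_real_, curvature_avg = NA_real_,
                n_segments = 0L))
  lens <- numeric(0); torts <- numeric(0)
  for (s in clipped$segments) {
    poly <- smooth_polyline(s$polyline, smooth_window)
    arc <- polyline_arc_px(poly) * graph$spacing
    if (arc < min_piece_um) next  # boundary-crossing fragments
    lens <- c(lens, arc)
    torts <- c(torts, suppressWarnings(segment_tortuosity(poly)))
  }
  if (length(lens) == 0L)
    return(list(length_avg = NA_real_, curvature_avg = NA_real_,
                n_segments = 0L))
  list(length_avg = mean(lens),
       curvature_avg = if (any(!is.na(torts))) mean(torts, na.rm = TRUE)
                       else NA_real_,
       n_segments = length(lens))
}

#' Vessel area and length densities
#'
#' `vessel_density` is the fraction of the analysis region covered by the
#' artery-or-vein mask; `vessel_length_density` is the fraction covered by
#' the union of the class skeletons.  By default the analysis region is the
#' full image; it can be restricted to the disc-centered field of radius 2 DD
#' beyond the disc edge.
#'
#' @param artery_mask,vein_mask Binary masks.
#' @param artery_skel,vein_skel Matching skeletons.
#' @param annuli A [zone_annuli()] (needed for `region = "2dd"`).
#' @param region `"image"` or `"2dd"`.
#' @return List with `vessel_length_density` and `vessel_density`, both in
#'   \[0, 1\].
#' @export
densities <- function(artery_mask, vein_mask, artery_skel, vein_skel,
                      annuli = NULL, region = c("image", "2dd")) {
  region <- match.arg(region)
  stopifnot(all(dim(artery_mask) == dim(vein_mask)),
            all(dim(artery_mask) == dim(artery_skel)),
            all(dim(artery_mask) == dim(vein_skel)))
  if (region == "2dd") {
    if (is.null(annuli)) stop("annuli required for region = '2dd'",
                              call. = FALSE)
    nr <- nrow(artery_mask); nc <- ncol(artery_mask)
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), nc), nr, nc)
    keep <- sqrt((xs - annuli$disc$center[["x"]])^2 +
                 (ys - annuli$disc$center[["y"]])^2) <= annuli$radii[["C"]]
  } else {
    keep <- matrix(TRUE, nrow(artery_mask), ncol(artery_mask))
  }
  denom <- sum(keep)
  if (denom == 0L) stop("empty analysis region", call. = FALSE)
  vd <- sum((artery_mask != 0 | vein_mask != 0) & keep) / denom
  vld <- sum((artery_skel != 0 | vein_skel != 0) & keep) / denom
  list(vessel_length_density = vld, vessel_density = vd)
}
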