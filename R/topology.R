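#' Skeletonize a binary mask
#'
#' Topology-preserving thinning (Zhang-Suen) to a one-pixel-wide, 8-connected
#' centerline, followed by a minimality pass that deletes redundant
#' staircase/corner pixels (pixels whose neighbours stay mutually connected
#' without them), so that path pixels have exactly two neighbours and
#' junction pixels three or more.  The skeleton is a subset of the input
#' foreground; an empty mask yields an empty skeleton.
#'
#' @param mask Binary raster (matrix); nonzero = vessel.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  .thin_clean(.zs_thin(m))
}

# 8-neighbour count of every foreground pixel (0 elsewhere).
neighbor_count <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- skel
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc * (skel != 0L)
}

# Arc length of a polyline in pixel units.
polyline_arc_px <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
}

#' Smooth a pixel polyline
#'
#' Centered moving average with a window that shrinks near the ends, so the
#' two endpoints are preserved exactly.  Used before arc-length and direction
#' estimation to suppress the staircase inflation of 8-connected pixel
#' chains (an unsmoothed chain overestimates the length of oblique straight
#' lines by up to ~8%).
#'
#' @param poly n x 2 coordinate matrix.
#' @param window Odd window size in points; `1` disables smoothing.
#' @return Smoothed n x 2 matrix.
#' @export
smooth_polyline <- function(poly, window = 5L) {
  n <- nrow(poly)
  if (window <= 1L || n <= 2L) return(poly)
  h <- (as.integer(window) - 1L) %/% 2L
  out <- poly
  for (j in 1:2) {
    cs <- c(0, cumsum(poly[, j]))
    i <- seq_len(n)
    lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
    k <- pmin(i - lo, hi - i)  # symmetric shrink keeps the mean centered
    lo <- i - k; hi <- i + k
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# -- internal: raw pixel-level trace of a 1px skeleton ------------------------

# Returns list(nodes = data.frame(id, x, y, kind_raw), node_of = int matrix
# mapping pixel -> node id (0 = none), segments = list of (rows matrix, from,
# to)).  Node kinds here are "endpoint"/"junction".
trace_skeleton <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- neighbor_count(skel)
  fg <- skel != 0L
  iso <- fg & deg == 0L
  n_iso <- sum(iso)
  if (n_iso > 0) {
    message("dropping ", n_iso, " isolated skeleton pixel(s)")
    fg[iso] <- FALSE
  }
  is_node_px <- fg & (deg == 1L | deg >= 3L)
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  nbrs_of <- function(r, c) {
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    hit <- fg[cbind(rr, cc)]
    cbind(rr[hit], cc[hit])
  }

  # cluster 8-adjacent junction pixels into nodes
  node_of <- matrix(0L, nr, nc)
  jpx <- which(fg & deg >= 3L, arr.ind = TRUE)
  nid <- 0L
  nodes_x <- numeric(0); nodes_y <- numeric(0); nodes_kind <- character(0)
  if (nrow(jpx) > 0L) {
    jset <- matrix(FALSE, nr, nc); jset[jpx] <- TRUE
    for (i in seq_len(nrow(jpx))) {
      r0 <- jpx[i, 1]; c0 <- jpx[i, 2]
      if (node_of[r0, c0] != 0L) next
      nid <- nid + 1L
      queue <- list(c(r0, c0)); node_of[r0, c0] <- nid
      members <- matrix(c(r0, c0), 1L)
      while (length(queue)) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        nb <- nbrs_of(p[1], p[2])
        if (nrow(nb)) {
          isj <- jset[nb] & node_of[nb] == 0L
          for (k in which(isj)) {
            node_of[nb[k, 1], nb[k, 2]] <- nid
            queue[[length(queue) + 1L]] <- nb[k, ]
            members <- rbind(members, nb[k, ])
          }
        }
      }
      nodes_x <- c(nodes_x, mean(members[, 2]))
      nodes_y <- c(nodes_y, mean(members[, 1]))
      nodes_kind <- c(nodes_kind, "junction")
    }
  }
  epx <- which(fg & deg == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(epx))) {
    nid <- nid + 1L
    node_of[epx[i, 1], epx[i, 2]] <- nid
    nodes_x <- c(nodes_x, epx[i, 2]); nodes_y <- c(nodes_y, epx[i, 1])
    nodes_kind <- c(nodes_kind, "endpoint")
  }

  visited <- matrix(FALSE, nr, nc)  # for path (degree-2) pixels
  segments <- list()
  add_seg <- function(rows, from, to) {
    segments[[length(segments) + 1L]] <<- list(rows = rows, from = from,
                                               to = to)
  }
  node_px <- which(is_node_px, arr.ind = TRUE)
  pid <- function(r, c) (c - 1L) * nr + r
  for (i in seq_len(nrow(node_px))) {
    r0 <- node_px[i, 1]; c0 <- node_px[i, 2]
    nb <- nbrs_of(r0, c0)
    for (k in seq_len(nrow(nb))) {
      r1 <- nb[k, 1]; c1 <- nb[k, 2]
      if (is_node_px[r1, c1]) {
        # direct node-node adjacency; emit once, skip within-cluster contacts
        if (node_of[r0, c0] != node_of[r1, c1] && pid(r0, c0) < pid(r1, c1))
          add_seg(rbind(c(r0, c0), c(r1, c1)),
                  node_of[r0, c0], node_of[r1, c1])
        next
      }
      if (visited[r1, c1]) next
      rows <- rbind(c(r0, c0), c(r1, c1))
      visited[r1, c1] <- TRUE
      prev <- c(r0, c0); cur <- c(r1, c1)
      repeat {
        nb2 <- nbrs_of(cur[1], cur[2])
        nb2 <- nb2[!(nb2[, 1] == prev[1] & nb2[, 2] == prev[2]), ,
                   drop = FALSE]
        if (nrow(nb2) == 0L) break  # dead end without endpoint flag (rare)
        # prefer a node pixel if present (handles diagonal shortcuts)
        j <- which(is_node_px[nb2])
        nxt <- if (length(j)) nb2[j[1], ] else nb2[1, ]
        rows <- rbind(rows, nxt)
        if (is_node_px[nxt[1], nxt[2]]) break
        visited[nxt[1], nxt[2]] <- TRUE
        prev <- cur; cur <- nxt
      }
      last <- rows[nrow(rows), ]
      to <- if (is_node_px[last[1], last[2]]) node_of[last[1], last[2]]
            else NA_integer_
      add_seg(rows, node_of[r0, c0], to)
    }
  }
  # node-free cycles
  leftover <- which(fg & deg == 2L & !visited, arr.ind = TRUE)
  while (nrow(leftover) > 0L) {
    start <- leftover[1, ]
    rows <- rbind(start)
    visited[start[1], start[2]] <- TRUE
    nb <- nbrs_of(start[1], start[2])
    prev <- start; cur <- nb[1, ]
    while (!(cur[1] == start[1] && cur[2] == start[2])) {
      rows <- rbind(rows, cur)
      visited[cur[1], cur[2]] <- TRUE
      nb2 <- nbrs_of(cur[1], cur[2])
      nb2 <- nb2[!(nb2[, 1] == prev[1] & nb2[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nb2) == 0L) break
      prev <- cur; cur <- nb2[1, ]
    }
    rows <- rbind(rows, start)
    add_seg(rows, NA_integer_, NA_integer_)
    leftover <- which(fg & deg == 2L & !visited, arr.ind = TRUE)
  }
  list(nodes = data.frame(id = seq_len(nid), x = nodes_x, y = nodes_y,
                          kind_raw = nodes_kind, stringsAsFactors = FALSE),
       segments = segments)
}

# classify node kinds from current segment incidence and compute degrees
recompute_nodes <- function(nodes, segments) {
  deg <- integer(nrow(nodes))
  for (s in segments) {
    if (!is.na(s$from)) deg[s$from] <- deg[s$from] + 1L
    if (!is.na(s$to)) deg[s$to] <- deg[s$to] + 1L
  }
  kind <- rep("unused", nrow(nodes))
  kind[deg == 1L] <- "endpoint"
  kind[deg == 2L] <- "through"
  kind[deg == 3L] <- "bifurcation"
  kind[deg == 4L] <- "crossing-suspect"
  kind[deg >= 5L] <- "complex"
  nodes$degree <- deg
  nodes$kind <- kind
  nodes
}

# splice segments at degree-2 nodes (joins the two incident polylines)
splice_through_nodes <- function(nodes, segments) {
  repeat {
    nodes <- recompute_nodes(nodes, segments)
    thr <- which(nodes$kind == "through")
    if (length(thr) == 0L) break
    id <- thr[1]
    inc <- which(vapply(segments, function(s)
      identical(s$from, id) + identical(s$to, id) > 0, logical(1)))
    if (length(inc) == 1L) {  # both ends on the same node: becomes a cycle
      segments[[inc]]$from <- NA_integer_
      segments[[inc]]$to <- NA_integer_
      next
    }
    a <- segments[[inc[1]]]; b <- segments[[inc[2]]]
    orient <- function(s, at_end) {
      # return s with polyline ordered so the shared node is at that end
      if (at_end == "last" && identical(s$to, id)) return(s)
      if (at_end == "last" && identical(s$from, id)) {
        s$polyline <- s$polyline[nrow(s$polyline):1, , drop = FALSE]
        s$widths <- rev(s$widths)
        tmp <- s$from; s$from <- s$to; s$to <- tmp
        return(s)
      }
      if (at_end == "first" && identical(s$from, id)) return(s)
      s$polyline <- s$polyline[nrow(s$polyline):1, , drop = FALSE]
      s$widths <- rev(s$widths)
      tmp <- s$from; s$from <- s$to; s$to <- tmp
      s
    }
    a <- orient(a, "last"); b <- orient(b, "first")
    joined <- list(polyline = rbind(a$polyline,
                                    b$polyline[-1, , drop = FALSE]),
                   widths = c(a$widths, b$widths[-1]),
                   from = a$from, to = b$to,
                   tree_id = a$tree_id, vessel_class = a$vessel_class)
    segments[[inc[1]]] <- joined
    segments[[inc[2]]] <- NULL
  }
  list(nodes = nodes, segments = segments)
}

# connected-component labels over nodes using segment incidence (union-find)
component_labels <- function(n_nodes, segments) {
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in segments) {
    if (is.na(s$from) || is.na(s$to)) next
    a <- find(s$from); b <- find(s$to)
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

#' Extract a centerline graph from a skeleton
#'
#' Skeleton pixels with one 8-neighbour become endpoints and pixels with
#' three or more become junction pixels; adjacent junction pixels, and
#' junction nodes connected by a centerline path shorter than a local-width
#' gap, merge into a single node (thinning splits wide Y-junctions into
#' nearby T-junction pairs).  Segments are traced between nodes; the caliber
#' at every centerline point is twice the Euclidean distance transform of the
#' source mask, in micrometers.
#'
#' @param skeleton One-pixel-wide binary skeleton (from [skeletonize()]).
#' @param mask The source binary mask (for widths).
#' @param spacing Micrometers per pixel.
#' @param vessel_class `"artery"` or `"vein"` (annotation only).
#' @param junction_gap_factor Junction pairs closer (along the centerline)
#'   than this multiple of the local mean width are merged; set `0` to merge
#'   only pixel-adjacent junctions.
#' @return Object of class `vessel_graph`: `nodes` data frame (`id`, `x`,
#'   `y`, `degree`, `kind`, `tree_id`), `segments` list (each with
#'   `polyline`, `widths` in um, `from`, `to`, `tree_id`, `vessel_class`),
#'   plus `spacing`.
#' @export
extract_graph <- function(skeleton, mask, spacing, vessel_class = "artery",
                          junction_gap_factor = 1.2) {
  stopifnot(is.matrix(skeleton), is.matrix(mask),
            all(dim(skeleton) == dim(mask)), spacing > 0)
  if (sum(skeleton != 0) == 0L) {
    return(structure(list(nodes = data.frame(id = integer(0), x = numeric(0),
                                             y = numeric(0),
                                             degree = integer(0),
                                             kind = character(0),
                                             tree_id = integer(0)),
                          segments = list(), vessel_class = vessel_class,
                          spacing = spacing),
                     class = "vessel_graph"))
  }
  dt <- EBImage::distmap(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  dt <- as.matrix(dt)
  tr <- trace_skeleton(matrix(as.integer(skeleton != 0),
                              nrow(skeleton), ncol(skeleton)))
  nodes <- tr$nodes
  segments <- lapply(tr$segments, function(s) {
    poly <- cbind(x = s$rows[, 2], y = s$rows[, 1])
    w <- 2 * dt[s$rows] * spacing
    w[w <= 0] <- spacing  # centerline point on mask edge: floor at one pixel
    list(polyline = poly, widths = w, from = s$from, to = s$to,
         tree_id = NA_integer_, vessel_class = vessel_class)
  })

  # merge junction nodes linked by short junction-junction paths
  if (junction_gap_factor > 0 && length(segments)) {
    repeat {
      nodes2 <- recompute_nodes(nodes, segments)
      merged <- FALSE
      incident_width <- function(nid) {
        w <- vapply(segments, function(z) {
          if (identical(z$from, nid) || identical(z$to, nid))
            mean(z$widths) else 0
        }, numeric(1))
        max(w)
      }
      for (si in seq_along(segments)) {
        s <- segments[[si]]
        if (is.na(s$from) || is.na(s$to) || s$from == s$to) next
        if (nodes2$degree[s$from] < 3L || nodes2$degree[s$to] < 3L) next
        # gap scales with the junction caliber: connectors through the
        # crotch of a junction blob are much thinner than the vessels
        w_loc <- max(mean(s$widths),
                     incident_width(s$from), incident_width(s$to))
        gap_px <- max(2, junction_gap_factor * w_loc / spacing)
        if (polyline_arc_px(s$polyline) >= gap_px) next
        keep <- s$from; drop <- s$to
        nodes$x[keep] <- (nodes$x[keep] + nodes$x[drop]) / 2
        nodes$y[keep] <- (nodes$y[keep] + nodes$y[drop]) / 2
        segments[[si]] <- NULL
        segments <- lapply(segments, function(z) {
          if (identical(z$from, drop)) z$from <- keep
          if (identical(z$to, drop)) z$to <- keep
          z
        })
        merged <- TRUE
        break
      }
      if (!merged) break
    }
    # contraction turns junction triangles into short self-loops that would
    # inflate the node degree; drop them (genuine vascular loops are long)
    segments <- Filter(function(s) {
      if (is.na(s$from) || is.na(s$to) || s$from != s$to) return(TRUE)
      polyline_arc_px(s$polyline) >= 3 * mean(s$widths) / spacing
    }, segments)
  }

  nodes <- recompute_nodes(nodes, segments)
  comp <- component_labels(nrow(nodes), segments)
  nodes$tree_id <- match(comp, unique(comp))
  segments <- lapply(segments, function(s) {
    s$tree_id <- if (!is.na(s$from)) nodes$tree_id[s$from]
                 else if (!is.na(s$to)) nodes$tree_id[s$to]
                 else NA_integer_
    s
  })
  structure(list(nodes = nodes, segments = segments,
                 vessel_class = vessel_class, spacing = spacing),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind,
                        levels = c("endpoint", "bifurcation",
                                   "crossing-suspect", "complex", "through",
                                   "unused")))
  cat("vessel_graph (", x$vessel_class, "): ", length(x$segments),
      " segments, ", nrow(x$nodes), " nodes\n", sep = "")
  cat("  ", paste(names(kinds)[kinds > 0], kinds[kinds > 0], sep = ": ",
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Remove terminal spur segments
#'
#' Terminal segments (one end of degree 1) shorter than a threshold are
#' skeletonization artifacts at wide-vessel tips and junction shoulders.
#' Removal is iterated to a fixed point and the surviving segments are
#' spliced through any node left with degree 2, so the operation is
#' idempotent.
#'
#' @param graph A `vessel_graph`.
#' @param min_length Absolute threshold in micrometers (may be 0).
#' @param width_factor Per-segment threshold as a multiple of the segment's
#'   outer-half median caliber; the effective threshold is the larger of the
#'   two.  Genuine thinning spurs run about one local width; anatomical
#'   terminal branches are several widths long, so 2 separates the two.
#' @return The pruned `vessel_graph`.
#' @export
prune_spurs <- function(graph, min_length = 0, width_factor = 2) {
  stopifnot(inherits(graph, "vessel_graph"))
  nodes <- graph$nodes; segments <- graph$segments
  repeat {
    nodes <- recompute_nodes(nodes, segments)
    drop <- integer(0)
    for (si in seq_along(segments)) {
      s <- segments[[si]]
      if (is.na(s$from) || is.na(s$to)) next
      d_from <- nodes$degree[s$from]; d_to <- nodes$degree[s$to]
      if (d_from != 1L && d_to != 1L) next
      if (d_from == 1L && d_to == 1L) next  # isolated path, not a spur
      # caliber from the half away from the junction: the distance transform
      # is junction-inflated near the attached end
      n_pts <- length(s$widths)
      outer_half <- if (d_from == 1L) seq_len(ceiling(n_pts / 2))
                    else seq.int(floor(n_pts / 2) + 1L, n_pts)
      thr_um <- max(min_length, width_factor * median(s$widths[outer_half]))
      if (polyline_arc_px(s$polyline) * graph$spacing < thr_um)
        drop <- c(drop, si)
    }
    if (length(drop) == 0L) break
    segments <- segments[-drop]
  }
  sp <- splice_through_nodes(nodes, segments)
  nodes <- recompute_nodes(sp$nodes, sp$segments)
  segments <- sp$segments
  comp <- component_labels(nrow(nodes), segments)
  nodes$tree_id <- match(comp, unique(comp))
  segments <- lapply(segments, function(s) {
    s$tree_id <- if (!is.na(s$from)) nodes$tree_id[s$from]
                 else if (!is.na(s$to)) nodes$tree_id[s$to]
                 else NA_integer_
    s
  })
  structure(list(nodes = nodes, segments = segments,
                 vessel_class = graph$vessel_class, spacing = graph$spacing),
            class = "vessel_graph")
}

#' Refine junction positions by branch back-extrapolation
#'
#' A thinning skeleton places a junction node at the center of the merged
#' junction blob, displaced outward along the daughters' bisector from the
#' true branching point; segment arc lengths measured from the node inherit
#' that bias.  This pass relocates every junction to the least-squares
#' intersection of the incident branches' direction lines (fitted past the
#' blob) and snaps the incident segment endpoints to it.  Node table
#' positions are updated too.
#'
#' @param graph A `vessel_graph`.
#' @param max_shift_widths Relocation is clamped to this multiple of the
#'   local width (guards degenerate direction fits).
#' @return The refined `vessel_graph`.
#' @export
refine_junctions <- function(graph, max_shift_widths = 1.5) {
  stopifnot(inherits(graph, "vessel_graph"))
  sp <- graph$spacing
  nodes <- graph$nodes
  segments <- graph$segments
  for (id in nodes$id[nodes$degree >= 3L]) {
    inc <- which(vapply(segments, function(s)
      identical(s$from, id) || identical(s$to, id), logical(1)))
    A <- matrix(0, 2, 2); b <- c(0, 0)
    w_max <- 0
    n_used <- 0L
    for (si in inc) {
      s <- segments[[si]]
      at_start <- identical(s$from, id)
      poly <- if (at_start) s$polyline
              else s$polyline[nrow(s$polyline):1, , drop = FALSE]
      w <- if (at_start) s$widths else rev(s$widths)
      arc <- c(0, cumsum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)))
      w_px <- median(w[arc <= max(5, arc[length(arc)] / 3)]) / sp
      w_max <- max(w_max, w_px)
      u <- direction_at(smooth_polyline(poly), "start", skip_px = w_px,
                        fit_px = max(5, 2 * w_px))
      if (any(is.na(u))) next
      i0 <- which(arc > w_px)[1]
      if (is.na(i0)) i0 <- nrow(poly)
      p <- poly[i0, ]
      proj <- diag(2) - tcrossprod(u)
      A <- A + proj
      b <- b + proj %*% p
      n_used <- n_used + 1L
    }
    ni <- which(nodes$id == id)
    node_pos <- c(nodes$x[ni], nodes$y[ni])
    if (n_used < 2L || abs(det(A)) < 1e-8) next
    P <- as.numeric(solve(A, b))
    shift <- P - node_pos
    lim <- max_shift_widths * w_max
    if (sqrt(sum(shift^2)) > lim)
      P <- node_pos + shift * lim / sqrt(sum(shift^2))
    nodes$x[ni] <- P[1]; nodes$y[ni] <- P[2]
    # replace the blob-interior run of each incident segment with a straight
    # step from P, so the refined path carries no artificial corner
    for (si in inc) {
      s <- segments[[si]]
      for (end in c("from", "to")[c(identical(s$from, id),
                                    identical(s$to, id))]) {
        rev_back <- end == "to"
        poly <- if (rev_back) s$polyline[nrow(s$polyline):1, , drop = FALSE]
                else s$polyline
        w <- if (rev_back) rev(s$widths) else s$widths
        arc <- c(0, cumsum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)))
        w_px <- median(w[arc <= max(5, arc[length(arc)] / 3)]) / sp
        i0 <- which(arc > 0.8 * w_px)[1]
        if (is.na(i0)) i0 <- nrow(poly)
        i0 <- min(i0, nrow(poly) - 1L)
        # the straight step from P must continue the branch, not double back
        onward <- poly[min(i0 + 3L, nrow(poly)), ] - poly[i0, ]
        if (sum((poly[i0, ] - P) * onward) <= 0) next
        poly <- rbind(P, poly[i0:nrow(poly), , drop = FALSE])
        w <- c(w[i0], w[i0:length(w)])
        if (rev_back) { poly <- poly[nrow(poly):1, , drop = FALSE]
                        w <- rev(w) }
        s$polyline <- poly
        s$widths <- w
      }
      segments[[si]] <- s
    }
  }
  structure(list(nodes = nodes, segments = segments,
                 vessel_class = graph$vessel_class, spacing = graph$spacing),
            class = "vessel_graph")
}
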