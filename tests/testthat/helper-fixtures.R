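# Geometric rasters and small graph objects used across the test files.
# Everything is generated in code; nothing is read from disk.

blank_raster <- function(n = 64) matrix(0L, n, n)

# horizontal bar of given pixel width centered vertically
bar_mask <- function(n = 128, len = 100, width = 5) {
  m <- matrix(0L, n, n)
  r0 <- n %/% 2 - (width - 1) %/% 2
  m[r0:(r0 + width - 1), 10:(10 + len - 1)] <- 1L
  m
}

filled_disk <- function(n = 64, r = 20, cx = n / 2, cy = n / 2) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 <= r^2), n, n)
}

filled_ellipse <- function(n = 256, a = 40, b = 60, cx = n / 2, cy = n / 2) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  matrix(as.integer(((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1), n, n)
}

# stroke a straight line of the given pixel width into a raster
stroke_line <- function(m, x0, y0, x1, y1, width = 3) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  t <- seq(0, 1, length.out = max(2, ceiling(len * 2)))
  xs <- x0 + t * (x1 - x0); ys <- y0 + t * (y1 - y0)
  r <- max(0.5, width / 2 - 0.5)
  span <- floor(r)
  off <- expand.grid(dy = -span:span, dx = -span:span)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  for (k in seq_along(xs)) {
    px <- round(xs[k]) + off$dx; py <- round(ys[k]) + off$dy
    ok <- px >= 1 & px <= ncol(m) & py >= 1 & py <= nrow(m)
    m[cbind(py[ok], px[ok])] <- 1L
  }
  m
}

# a "Y": one stem splitting into two daughters
y_mask <- function(n = 128, width = 5) {
  m <- matrix(0L, n, n)
  m <- stroke_line(m, 10, 64, 64, 64, width)
  m <- stroke_line(m, 64, 64, 110, 30, width)
  stroke_line(m, 64, 64, 110, 98, width)
}

# an "X": two full strokes crossing at the center
x_mask <- function(n = 128, width = 5) {
  m <- matrix(0L, n, n)
  m <- stroke_line(m, 20, 20, 108, 108, width)
  stroke_line(m, 20, 108, 108, 20, width)
}

# Sierpinski triangle via the Pascal-mod-2 bit trick; side must be 2^k
sierpinski_mask <- function(side = 512) {
  idx <- 0:(side - 1)
  m <- outer(idx, idx, function(i, j) as.integer(bitwAnd(i, j) == 0))
  # upper-left triangle pattern; orientation is irrelevant for box counting
  m
}

# strip multifractal: 1D binomial cascade of total mass `total` over
# 2^levels column strips, all mass on a single row (keeps the measure 1D)
cascade_strips <- function(side = 512, p = 0.7, levels = 5, total = 1e7) {
  counts <- total
  for (l in seq_len(levels)) {
    left <- round(counts * p)
    counts <- as.numeric(rbind(left, counts - left))
  }
  strip <- side / 2^levels
  m <- matrix(0, side, side)
  m[side / 2, seq(1, side, by = strip)] <- counts
  m
}

# closed-form alpha(q) of the 1D binomial cascade (base-e slopes vs log eps)
cascade_alpha <- function(q, p = 0.7) {
  r <- 1 - p
  -(p^q * log(p) + r^q * log(r)) / ((p^q + r^q) * log(2))
}

# hand-built vessel_graph: a disc-rooted chain of degree-3 bifurcations.
# Each bifurcation spec: adv (px from the previous node along the current
# heading), angle (degrees between its two daughters), parent_width (first
# segment only) and daughter_widths (tip, continuation).  The chain continues
# through the second daughter; the last bifurcation gets two tips.
# Disc center (256, 256), radius 40 px assumed.
toy_tree_segments <- function(bif_specs, root_angle = 0, spacing = 10,
                              tree_offset = 0L) {
  ctr <- c(256, 256)
  deg2rad <- pi / 180
  nodes <- list(); segments <- list()
  add_node <- function(x, y) {
    nodes[[length(nodes) + 1L]] <<- c(x = x, y = y)
    length(nodes) + tree_offset
  }
  seg <- function(a, b, from, to, w) {
    t <- seq(0, 1, length.out = max(2, ceiling(sqrt(sum((b - a)^2)))))
    poly <- cbind(x = a[1] + t * (b[1] - a[1]), y = a[2] + t * (b[2] - a[2]))
    segments[[length(segments) + 1L]] <<- list(
      polyline = poly, widths = rep(w, nrow(poly)), from = from, to = to,
      tree_id = 1L + tree_offset, vessel_class = "artery")
  }
  dirv <- function(ang) c(cos(ang * deg2rad), sin(ang * deg2rad))
  cur_pos <- ctr + 41 * dirv(root_angle)
  cur <- add_node(cur_pos[1], cur_pos[2])
  cur_dir <- root_angle
  cur_w <- bif_specs[[1]]$parent_width
  for (i in seq_along(bif_specs)) {
    b <- bif_specs[[i]]
    bif_pos <- cur_pos + b$adv * dirv(cur_dir)
    bif <- add_node(bif_pos[1], bif_pos[2])
    seg(cur_pos, bif_pos, cur, bif, cur_w)
    tip_dir <- cur_dir + b$angle / 2
    cont_dir <- cur_dir - b$angle / 2
    tip <- bif_pos + 35 * dirv(tip_dir)
    tipid <- add_node(tip[1], tip[2])
    seg(bif_pos, tip, bif, tipid, b$daughter_widths[1])
    if (i == length(bif_specs)) {  # terminal: second tip
      tip2 <- bif_pos + 35 * dirv(cont_dir)
      tip2id <- add_node(tip2[1], tip2[2])
      seg(bif_pos, tip2, bif, tip2id, b$daughter_widths[2])
    }
    cur <- bif; cur_pos <- bif_pos
    cur_dir <- cont_dir
    cur_w <- b$daughter_widths[2]
  }
  list(nodes = do.call(rbind, nodes), segments = segments)
}

toy_graph <- function(trees, spacing = 10) {
  nodes <- NULL; segments <- list(); offset <- 0L
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    nd <- data.frame(id = seq_len(nrow(tr$nodes)) + offset,
                     x = tr$nodes[, "x"], y = tr$nodes[, "y"])
    nd$tree_id <- i
    nodes <- rbind(nodes, nd)
    off <- offset
    segments <- c(segments, lapply(tr$segments, function(s) {
      s$tree_id <- i
      s$from <- s$from + off
      s$to <- s$to + off
      s
    }))
    offset <- offset + nrow(tr$nodes)
  }
  g <- structure(list(nodes = nodes, segments = segments,
                      vessel_class = "artery", spacing = spacing),
                 class = "vessel_graph")
  g$nodes <- retinavasc:::recompute_nodes(g$nodes, g$segments)
  g
}

toy_annuli <- function() {
  disc <- structure(list(center = c(x = 256, y = 256), diameter = 80,
                         radius = 40), class = "optic_disc")
  zone_annuli(disc)
}

# cached default synthetic image, shared across test files
.fixture_env <- new.env()
fixture_image <- function(seed = 7) {
  key <- paste0("img", seed)
  if (is.null(.fixture_env[[key]])) {
    tr <- grow_tree(tree_params(), seed = seed)
    map <- rasterize_tree(tr, sprintf("fixture_%d", seed))
    .fixture_env[[key]] <- list(truth = tr, map = map,
                                record = truth_record(tr, map))
  }
  .fixture_env[[key]]
}
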