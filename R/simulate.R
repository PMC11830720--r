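#' Parameters of the synthetic vascular-tree generator
#'
#' Defines a disc-centered 45-degree-style field with binary artery/vein
#' trees growing radially outward from the disc margin.  All physical values
#' are micrometers; per-class values are length-2 vectors named
#' `artery`/`vein`.  Defaults emulate a fundus field scaled to a 512 px
#' canvas at 10 um/px: disc radius 400 um, roots reaching Zone C at the first
#' bifurcation, one further (stochastic) bifurcation level in Zone C, branch
#' angles near 80 degrees, squared-caliber asymmetry near 40, arc-chord
#' tortuosity near 1.10, and Murray cube-law caliber splitting.
#'
#' @param n_trees Trees per vessel class.
#' @param branch_levels Number of branch generations (root = level 0).
#' @param mean_branch_angle,angle_jitter_sd Total daughter-daughter angle
#'   (degrees), truncated to `angle_range`.
#' @param asymmetry_target,asymmetry_jitter_sd Squared-caliber asymmetry
#'   index (percent), truncated to `asymmetry_range`.
#' @param tortuosity_target,tortuosity_jitter_sd Per-branch arc-chord ratio,
#'   truncated to `tortuosity_range`.
#' @param tortuosity_wavelength Wavelength (um) of the sinusoidal centerline
#'   displacement.
#' @param root_width Root caliber per class (um), jitter `root_width_sd`.
#' @param width_taper Extra multiplicative taper applied to both daughters on
#'   top of the cube-law split.
#' @param branch_prob Probability that a level >= 1 branch bifurcates again
#'   (the root always bifurcates when `branch_levels >= 2`).
#' @param root_length,branch_length,terminal_length Mean segment lengths (um)
#'   by level, each with `*_sd` jitter and hard truncation `*_range`.
#' @param disc_radius Optic-disc radius (um).
#' @param canvas_px Square canvas edge (pixels).
#' @param pixel_spacing Micrometers per pixel.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(n_trees = 4L,
                        branch_levels = 3L,
                        mean_branch_angle = c(artery = 88, vein = 77),
                        angle_jitter_sd = 13,
                        angle_range = c(50, 115),
                        asymmetry_target = c(artery = 44, vein = 38),
                        asymmetry_jitter_sd = 12,
                        asymmetry_range = c(8, 70),
                        tortuosity_target = 1.10,
                        tortuosity_jitter_sd = 0.02,
                        tortuosity_range = c(1.03, 1.18),
                        tortuosity_wavelength = 1000,
                        root_width = c(artery = 120, vein = 142),
                        root_width_sd = 7,
                        width_taper = 0.92,
                        branch_prob = c(artery = 0.85, vein = 0.85),
                        root_length = 930, root_length_sd = 30,
                        root_length_range = c(880, 990),
                        branch_length = 420, branch_length_sd = 45,
                        branch_length_range = c(330, 510),
                        terminal_length = 450, terminal_length_sd = 40,
                        terminal_length_range = c(360, 540),
                        disc_radius = 400,
                        canvas_px = 512L,
                        pixel_spacing = 10) {
  per_class <- function(x) {
    if (length(x) == 1L) x <- c(artery = unname(x), vein = unname(x))
    stopifnot(all(c("artery", "vein") %in% names(x)))
    x
  }
  p <- list(n_trees = as.integer(n_trees),
            branch_levels = as.integer(branch_levels),
            mean_branch_angle = per_class(mean_branch_angle),
            angle_jitter_sd = angle_jitter_sd, angle_range = angle_range,
            asymmetry_target = per_class(asymmetry_target),
            asymmetry_jitter_sd = asymmetry_jitter_sd,
            asymmetry_range = asymmetry_range,
            tortuosity_target = tortuosity_target,
            tortuosity_jitter_sd = tortuosity_jitter_sd,
            tortuosity_range = tortuosity_range,
            tortuosity_wavelength = tortuosity_wavelength,
            root_width = per_class(root_width), root_width_sd = root_width_sd,
            width_taper = width_taper,
            branch_prob = per_class(branch_prob),
            root_length = root_length, root_length_sd = root_length_sd,
            root_length_range = root_length_range,
            branch_length = branch_length, branch_length_sd = branch_length_sd,
            branch_length_range = branch_length_range,
            terminal_length = terminal_length,
            terminal_length_sd = terminal_length_sd,
            terminal_length_range = terminal_length_range,
            disc_radius = disc_radius,
            canvas_px = as.integer(canvas_px),
            pixel_spacing = pixel_spacing)
  stopifnot(p$n_trees >= 1L, p$branch_levels >= 1L,
            all(p$mean_branch_angle > 10 & p$mean_branch_angle < 170),
            p$pixel_spacing > 0, p$disc_radius > 0)
  class(p) <- "tree_params"
  p
}

rtrunc_norm <- function(n, mean, sd, range) {
  pmin(pmax(rnorm(n, mean, sd), range[1]), range[2])
}

ang_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

# Sinusoidal centerline displacement with a sin^2 envelope: zero displacement
# and zero slope at both ends, so bifurcation positions and local headings at
# the nodes are unperturbed.  Amplitude is solved by bisection (quadrature of
# the arc integral) to hit the requested arc-chord ratio.
wave_amplitude <- function(length_um, wavelength_um, tortuosity, phase = 0,
                           n_quad = 400L) {
  if (tortuosity <= 1) return(0)
  t <- seq(0, 1, length.out = n_quad)
  dt <- t[2] - t[1]
  kappa <- length_um / wavelength_um
  # d/dt [sin^2(pi t) sin(2 pi kappa t + phase)]
  fp <- pi * sin(2 * pi * t) * sin(2 * pi * kappa * t + phase) +
        2 * pi * kappa * sin(pi * t)^2 * cos(2 * pi * kappa * t + phase)
  arc_ratio <- function(a_rel) mean(sqrt(1 + (a_rel * fp)^2))
  hi <- 0.5
  while (arc_ratio(hi) < tortuosity && hi < 8) hi <- hi * 2
  a_rel <- uniroot(function(a) arc_ratio(a) - tortuosity, c(0, hi),
                   tol = 1e-8)$root
  a_rel * length_um
}

# dense polyline (px units) of one wavy branch; step ~0.5 px
branch_polyline <- function(start_px, heading, length_um, amp_um,
                            wavelength_um, phase, spacing) {
  len_px <- length_um / spacing
  n <- max(8L, ceiling(len_px * 2))
  t <- seq(0, 1, length.out = n + 1L)
  kappa <- length_um / wavelength_um
  u <- (amp_um / spacing) * sin(pi * t)^2 * sin(2 * pi * kappa * t + phase)
  ex <- c(cos(heading), sin(heading))
  en <- c(-sin(heading), cos(heading))
  cbind(x = start_px[1] + t * len_px * ex[1] + u * en[1],
        y = start_px[2] + t * len_px * ex[2] + u * en[2])
}

#' Grow a synthetic vascular forest with ground truth
#'
#' Grows `n_trees` binary trees per vessel class from evenly spaced points on
#' the disc margin, radially outward.  Daughter headings split the sampled
#' total branch angle in proportion to the opposite squared caliber (the
#' narrower daughter deviates more), calibers follow the cube-law split
#' implied by the sampled asymmetry index, and centerlines carry a smoothly
#' enveloped sinusoidal displacement realizing the sampled arc-chord
#' tortuosity.  Each tree owns an angular sector about the disc center and
#' every bifurcation splits its sector between the daughters (headings
#' clamped inside the sub-sector, with a small margin; a branch whose sector
#' is narrower than 40 degrees stops bifurcating), so trees and subtrees
#' never intersect and every junction stays resolvable in the rasterization.
#' Deterministic given `seed`.
#'
#' @param params A [tree_params()].
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: `branches` (per-branch polylines
#'   in px, widths, class, tree, level), `bifurcations` (true position,
#'   angle, asymmetry, widths, radial distance), and `params`.
#' @export
grow_tree <- function(params, seed = 1L) {
  stopifnot(inherits(params, "tree_params"))
  set.seed(seed)
  sp <- params$pixel_spacing
  ctr <- c(params$canvas_px / 2 + 0.5, params$canvas_px / 2 + 0.5)
  r_disc_px <- params$disc_radius / sp
  branches <- list()
  bifs <- list()
  field_radius <- params$canvas_px / 2 - 2

  sample_len <- function(level) {
    if (level == 0L)
      rtrunc_norm(1, params$root_length, params$root_length_sd,
                  params$root_length_range)
    else rtrunc_norm(1, params$branch_length, params$branch_length_sd,
                     params$branch_length_range)
  }

  # Angular bookkeeping is done relative to each tree's radial axis phi0.
  # Every branch owns a wedge (lo, hi) of polar angle about the disc center;
  # daughters receive the sub-wedges on either side of the node's polar
  # angle.  A daughter keeps its sampled heading when its straight course
  # would stay inside its sub-wedge out to just beyond the Zone C outer
  # radius (collisions farther out cannot disturb any zone statistic);
  # otherwise the heading is shrunk toward the local radial direction until
  # the course fits.  Sub-wedges narrower than 25 degrees stop bifurcating.
  min_bif_wedge <- 25 * pi / 180
  wedge_margin <- 2 * pi / 180
  r_protect <- 5 * r_disc_px + 8
  reach_px <- (params$branch_length_range[2] +
               params$terminal_length_range[2]) / sp

  grow_class <- function(cls) {
    phi_offset <- if (cls == "artery") 0 else pi / params$n_trees
    for (k in seq_len(params$n_trees)) {
      phi0 <- 2 * pi * (k - 1) / params$n_trees + phi_offset
      tree_id <- k
      rel_polar <- function(pt) ang_diff(atan2(pt[2] - ctr[2],
                                               pt[1] - ctr[1]), phi0)
      # all random draws and the polyline of one branch, so a bifurcation can
      # pre-draw both daughters and test their clearance before committing
      draw_branch <- function(start_px, heading_rel, level, wedge) {
        len <- sample_len(level)
        will_bif <- (level + 1L) < params$branch_levels &&
          (wedge[2] - wedge[1]) >= min_bif_wedge &&
          (level == 0L || runif(1) < params$branch_prob[[cls]])
        if (level > 0L && !will_bif && level + 1L < params$branch_levels) {
          # non-bifurcating interior branch runs on as its own terminal
          len <- len + rtrunc_norm(1, params$terminal_length,
                                   params$terminal_length_sd,
                                   params$terminal_length_range)
        }
        if (level + 1L == params$branch_levels) {
          len <- rtrunc_norm(1, params$terminal_length,
                             params$terminal_length_sd,
                             params$terminal_length_range)
        }
        tau <- rtrunc_norm(1, params$tortuosity_target,
                           params$tortuosity_jitter_sd,
                           params$tortuosity_range)
        phase <- runif(1, 0, 2 * pi)
        amp <- wave_amplitude(len, params$tortuosity_wavelength, tau, phase)
        poly <- branch_polyline(start_px, phi0 + heading_rel, len, amp,
                                params$tortuosity_wavelength, phase, sp)
        list(poly = poly, tau = tau, will_bif = will_bif)
      }
      # strokes of the two daughters must not touch beyond the junction zone
      clearance_ok <- function(p1, p2, w1_px, w2_px, wp_px) {
        i1 <- seq(1, nrow(p1), by = 4); i2 <- seq(1, nrow(p2), by = 4)
        a1 <- (i1 - 1) / 2; a2 <- (i2 - 1) / 2  # arc in px (0.5 px steps)
        dx <- outer(p1[i1, 1], p2[i2, 1], `-`)
        dy <- outer(p1[i1, 2], p2[i2, 2], `-`)
        d2 <- dx * dx + dy * dy
        allow <- 1.5 * wp_px
        dmin <- (w1_px + w2_px) / 2 + 1
        far <- outer(a1 > allow, a2 > allow, `&`)
        !any(far & d2 < dmin^2)
      }
      grow_branch <- function(start_px, heading_rel, width_um, level,
                              wedge, pre = NULL) {
        if (is.null(pre)) pre <- draw_branch(start_px, heading_rel, level,
                                             wedge)
        poly <- pre$poly
        will_bif <- pre$will_bif
        # truncate at the field of view
        rr <- sqrt((poly[, 1] - ctr[1])^2 + (poly[, 2] - ctr[2])^2)
        if (any(rr > field_radius)) {
          warning("branch truncated at field of view")
          poly <- poly[seq_len(which(rr > field_radius)[1]), , drop = FALSE]
          will_bif <- FALSE
        }
        branches[[length(branches) + 1L]] <<- list(
          id = length(branches) + 1L, vessel_class = cls, tree = tree_id,
          level = level, width_um = width_um, polyline = poly,
          tortuosity_drawn = pre$tau)
        if (!will_bif || nrow(poly) < 2L) return(invisible(NULL))
        end_px <- poly[nrow(poly), ]
        alpha <- rel_polar(end_px)      # node polar angle splits the wedge
        # largest heading (toward h0 from the local radial) whose straight
        # course stays inside the sub-wedge while r <= r_protect
        fit_heading <- function(h0, w) {
          t <- seq(16, reach_px, by = 2)  # daughters share the node early on
          for (s in seq(1, 0, by = -0.1)) {
            h <- alpha + s * (h0 - alpha)
            px <- end_px[1] + t * cos(phi0 + h)
            py <- end_px[2] + t * sin(phi0 + h)
            rr <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
            a <- ang_diff(atan2(py - ctr[2], px - ctr[1]), phi0)
            near <- rr <= r_protect
            if (all(a[near] >= w[1] + wedge_margin &
                    a[near] <= w[2] - wedge_margin)) return(h)
          }
          alpha
        }
        wedge_up <- c(alpha, wedge[2]); wedge_dn <- c(wedge[1], alpha)
        for (try in seq_len(15L)) {
          theta <- rtrunc_norm(1, params$mean_branch_angle[[cls]],
                               params$angle_jitter_sd,
                               params$angle_range) * pi / 180
          asym <- rtrunc_norm(1, params$asymmetry_target[[cls]],
                              params$asymmetry_jitter_sd,
                              params$asymmetry_range)
          rho <- sqrt(1 - asym / 100)            # w_small / w_large
          w_l <- width_um / (1 + rho^3)^(1 / 3)  # cube-law split
          w_s <- rho * w_l
          w_l <- w_l * params$width_taper
          w_s <- w_s * params$width_taper
          share_l <- w_s^2 / (w_l^2 + w_s^2)     # wide daughter hugs the axis
          side <- sample(c(-1, 1), 1)
          h_l <- heading_rel + side * theta * share_l
          h_s <- heading_rel - side * theta * (1 - share_l)
          up_first <- h_l > h_s
          h_l <- fit_heading(h_l, if (up_first) wedge_up else wedge_dn)
          h_s <- fit_heading(h_s, if (up_first) wedge_dn else wedge_up)
          sep <- abs(h_l - h_s)
          if (sep < 35 * pi / 180) {    # keep the junction resolvable
            push <- (35 * pi / 180 - sep) / 2
            if (h_l >= h_s) { h_l <- h_l + push; h_s <- h_s - push }
            else { h_l <- h_l - push; h_s <- h_s + push }
          }
          pre_l <- draw_branch(end_px, h_l, level + 1L,
                               if (up_first) wedge_up else wedge_dn)
          pre_s <- draw_branch(end_px, h_s, level + 1L,
                               if (up_first) wedge_dn else wedge_up)
          if (clearance_ok(pre_l$poly, pre_s$poly, w_l / sp, w_s / sp,
                           width_um / sp)) break
        }
        d_polys <- list()
        for (d in seq_len(2)) {
          hd <- if (d == 1) h_l else h_s
          wd <- if (d == 1) w_l else w_s
          wedge_d <- if ((d == 1) == up_first) wedge_up else wedge_dn
          did <- length(branches) + 1L  # daughter is appended before its kids
          grow_branch(end_px, hd, wd, level + 1L, wedge_d,
                      pre = if (d == 1) pre_l else pre_s)
          d_polys[[d]] <- branches[[did]]$polyline
        }
        # true angle under the measurement convention: caliber-scaled
        # direction window away from the node
        dirs <- lapply(seq_len(2), function(d) {
          wpx <- (if (d == 1) w_l else w_s) / sp
          direction_at(d_polys[[d]], "start", skip_px = 1.5 * wpx,
                       fit_px = max(5, 4 * wpx))
        })
        bifs[[length(bifs) + 1L]] <<- data.frame(
          vessel_class = cls, tree = tree_id, level = level,
          x = end_px[1], y = end_px[2],
          r_px = sqrt(sum((end_px - ctr)^2)),
          angle = bifurcation_angle(NULL, dirs[[1]], dirs[[2]]),
          asymmetry = asym, parent_width = width_um,
          daughter_width_1 = w_l, daughter_width_2 = w_s,
          stringsAsFactors = FALSE)
        invisible(NULL)
      }
      w0 <- max(20, rnorm(1, params$root_width[[cls]], params$root_width_sd))
      start <- ctr + r_disc_px * c(cos(phi0), sin(phi0))
      half <- pi / params$n_trees - 6 * pi / 180  # 6 deg inter-tree margin
      grow_branch(start, 0, w0, 0L, c(-half, half))
    }
  }
  grow_class("artery")
  grow_class("vein")
  structure(list(branches = branches,
                 bifurcations = if (length(bifs)) do.call(rbind, bifs)
                                else NULL,
                 params = params,
                 disc_center_px = ctr, disc_radius_px = r_disc_px,
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth: ", length(x$branches), " branches, ",
      if (is.null(x$bifurcations)) 0 else nrow(x$bifurcations),
      " bifurcations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# stamp filled disks of the given radii (px) at the given centers
stamp_disks <- function(canvas, xs, ys, radii_px) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  rkey <- round(radii_px * 2) / 2
  for (r in unique(rkey)) {
    sel <- which(rkey == r)
    rr <- max(0.5, r - 0.5)  # cover pixels with center within r - 0.5
    span <- floor(rr)
    off <- expand.grid(dy = -span:span, dx = -span:span)
    off <- off[off$dx^2 + off$dy^2 <= rr^2, ]
    cx <- round(xs[sel]); cy <- round(ys[sel])
    px <- outer(off$dx, cx, `+`)
    py <- outer(off$dy, cy, `+`)
    ok <- px >= 1 & px <= nc & py >= 1 & py <= nr
    canvas[cbind(py[ok], px[ok])] <- 1L
  }
  canvas
}

#' Rasterize a synthetic forest to a segmentation map
#'
#' Branch centerlines are stroked with their per-branch width (disk
#' stamping, no anti-aliasing); the optic disc is a filled circle.
#' Overlapping branches of a class union into one mask.
#'
#' @param truth A [grow_tree()] result.
#' @param source_id Identifier carried into the map.
#' @return A [segmentation_map()].
#' @export
rasterize_tree <- function(truth, source_id = "synthetic") {
  p <- truth$params
  n <- p$canvas_px
  masks <- list(artery = matrix(0L, n, n), vein = matrix(0L, n, n))
  for (b in truth$branches) {
    r_px <- (b$width_um / p$pixel_spacing) / 2
    masks[[b$vessel_class]] <- stamp_disks(masks[[b$vessel_class]],
                                           b$polyline[, 1], b$polyline[, 2],
                                           rep(r_px, nrow(b$polyline)))
  }
  disc <- matrix(0L, n, n)
  disc <- stamp_disks(disc, truth$disc_center_px[1], truth$disc_center_px[2],
                      truth$disc_radius_px + 0.5)
  segmentation_map(masks$artery, masks$vein, disc, p$pixel_spacing, source_id)
}

#' Ground-truth parameter record of a synthetic image
#'
#' Recomputes, from the stored continuous geometry and the true disc circle,
#' the same Zone C statistics the measurement pipeline reports: mean
#' bifurcation angle/asymmetry and mean Zone C bifurcation count per tree,
#' clipped segment lengths and tortuosities, trunk-based CRAE/CRVE/AVR and
#' the rasterized densities.
#'
#' @param truth A [grow_tree()] result.
#' @param map Optional matching [rasterize_tree()] output (for the density
#'   entries).
#' @param min_piece_um Zone-clipped pieces shorter than this are ignored,
#'   matching the measurement convention.
#' @return One-row data frame of true parameter values (`NA` where
#'   undefined), using the measurement parameter names.
#' @export
truth_record <- function(truth, map = NULL, min_piece_um = 60) {
  p <- truth$params
  sp <- p$pixel_spacing
  disc <- structure(list(center = c(x = truth$disc_center_px[1],
                                    y = truth$disc_center_px[2]),
                         diameter = 2 * truth$disc_radius_px,
                         radius = truth$disc_radius_px),
                    class = "optic_disc")
  ann <- zone_annuli(disc)
  out <- list()
  for (cls in c("artery", "vein")) {
    sfx <- if (cls == "artery") "_a" else "_v"
    bf <- truth$bifurcations
    if (!is.null(bf)) bf <- bf[bf$vessel_class == cls, , drop = FALSE]
    zoneb <- numeric(0)
    if (!is.null(bf) && nrow(bf)) {
      zl <- zone_of(bf$x, bf$y, ann)
      zc <- bf[zl == "C", , drop = FALSE]
    } else zc <- bf
    if (!is.null(zc) && nrow(zc)) {
      out[[paste0("angle_avg", sfx)]] <- mean(zc$angle)
      out[[paste0("asymmetry_avg", sfx)]] <- mean(zc$asymmetry)
      out[[paste0("branch_avg", sfx)]] <-
        mean(vapply(seq_len(p$n_trees),
                    function(k) sum(zc$tree == k), numeric(1)))
    } else {
      out[[paste0("angle_avg", sfx)]] <- NA_real_
      out[[paste0("asymmetry_avg", sfx)]] <- NA_real_
      out[[paste0("branch_avg", sfx)]] <- NA_real_
    }
    lens <- numeric(0); torts <- numeric(0)
    for (b in truth$branches) {
      if (b$vessel_class != cls) next
      pieces <- clip_polyline_annulus(b$polyline, NULL, disc,
                                      ann$radii[["B"]], ann$radii[["C"]])
      for (pc in pieces) {
        arc <- polyline_arc_px(pc$polyline) * sp
        if (arc < min_piece_um) next
        lens <- c(lens, arc)
        torts <- c(torts,
                   suppressWarnings(segment_tortuosity(pc$polyline)))
      }
      if (b$level == 0L) zoneb <- c(zoneb, b$width_um)
    }
    out[[paste0("length_avg", sfx)]] <- if (length(lens)) mean(lens)
                                        else NA_real_
    out[[paste0("curvature_avg", sfx)]] <-
      if (any(!is.na(torts))) mean(torts, na.rm = TRUE) else NA_real_
    out[[if (cls == "artery") "crae" else "crve"]] <-
      central_equivalent(zoneb, cls)
  }
  out$avr <- out$crae / out$crve
  if (!is.null(map)) {
    npx <- map$height * map$width
    out$vessel_density <- sum(map$artery | map$vein) / npx
    arc_px <- sum(vapply(truth$branches,
                         function(b) polyline_arc_px(b$polyline), numeric(1)))
    out$vessel_length_density <- arc_px / npx
  }
  as.data.frame(out)
}

#' Generate a labeled synthetic cohort
#'
#' One image per row: group-specific parameter overrides are applied to a
#' base [tree_params()], each image gets its own RNG stream seeded from the
#' cohort seed and image index, and the true parameter values are returned
#' as a ground-truth ledger.
#'
#' @param group_specs Named list: for each group, a list of [tree_params()]
#'   argument overrides (e.g. `list(control = list(), npdr = list(branch_prob
#'   = c(artery = 0.8, vein = 0.55)))`).  Defaults define a control group and
#'   an NPDR-like group with longer segments, fewer venous branches, narrower
#'   vessels and lower densities.
#' @param n_per_group Images per group (>= 1).
#' @param seed Cohort seed.
#' @param base_params Base [tree_params()] arguments common to all groups.
#' @return List of class `synthetic_cohort`: `images` (each with `map`,
#'   `truth`, `group`, `source_id`) and `ledger` (data frame of true values
#'   with `group` and `source_id`).
#' @export
generate_cohort <- function(group_specs = default_group_specs(),
                            n_per_group = 10L, seed = 1L,
                            base_params = list()) {
  stopifnot(length(group_specs) >= 2L, n_per_group >= 1L)
  if (is.null(names(group_specs)) || any(!nzchar(names(group_specs))))
    stop("group_specs must be a named list", call. = FALSE)
  images <- list()
  ledger <- list()
  idx <- 0L
  for (g in names(group_specs)) {
    pars <- do.call(tree_params, modifyList(base_params, group_specs[[g]]))
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      img_seed <- (as.integer(seed) %% 100000L) * 20011L + idx
      truth <- grow_tree(pars, seed = img_seed)
      sid <- sprintf("%s_%03d", g, i)
      map <- rasterize_tree(truth, source_id = sid)
      rec <- truth_record(truth, map)
      rec$group <- g
      rec$source_id <- sid
      images[[idx]] <- list(map = map, truth = truth, group = g,
                            source_id = sid)
      ledger[[idx]] <- rec
    }
  }
  structure(list(images = images, ledger = do.call(rbind, ledger),
                 seed = seed),
            class = "synthetic_cohort")
}

#' Default two-group cohort specification
#'
#' A control group and an NPDR-like group whose deltas follow the effect
#' directions reported for mild-to-moderate NPDR: longer Zone C segments,
#' fewer venous branches, smaller venous branching angle and asymmetry, and
#' lower vessel densities (narrower calibers).
#'
#' @return Named list of parameter overrides usable as `group_specs`.
#' @export
default_group_specs <- function() {
  list(
    control = list(),
    npdr = list(branch_prob = c(artery = 0.80, vein = 0.55),
                branch_length = 450,
                branch_length_range = c(360, 540),
                mean_branch_angle = c(artery = 85, vein = 70),
                asymmetry_target = c(artery = 42, vein = 32),
                root_width = c(artery = 111, vein = 131)))
}

#' Write a synthetic cohort to disk
#'
#' Masks as `<id>_artery/_vein/_disc.png`, the ground-truth ledger as
#' `ground_truth.csv`, and the resolved generation parameters as
#' `cohort_config.yaml`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in cohort$images) {
    write_segmentation(img$map,
                       file.path(dir, paste0(img$source_id, "_artery.png")),
                       file.path(dir, paste0(img$source_id, "_vein.png")),
                       file.path(dir, paste0(img$source_id, "_disc.png")))
  }
  write.csv(cohort$ledger, file.path(dir, "ground_truth.csv"),
            row.names = FALSE, na = "")
  cfg <- lapply(cohort$images[!duplicated(vapply(cohort$images, `[[`,
                                                character(1), "group"))],
                function(img) unclass(img$truth$params))
  names(cfg) <- unique(vapply(cohort$images, `[[`, character(1), "group"))
  cfg <- c(list(seed = cohort$seed), cfg)
  writeLines(yaml::as.yaml(cfg), file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}
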