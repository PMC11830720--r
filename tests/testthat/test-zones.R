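test_that("fit_disc returns centroid and equivalent-area diameter", {
  disk <- filled_disk(512, 50, 256, 256)
  d <- fit_disc(disk)
  expect_equal(unname(d$center), c(256, 256), tolerance = 0.01)
  expect_equal(d$diameter, 100, tolerance = 1)

  ell <- filled_ellipse(256, 40, 60)
  de <- fit_disc(ell)
  expect_equal(de$diameter, 2 * sqrt(sum(ell) / pi), tolerance = 1e-9)

  expect_error(fit_disc(blank_raster(32)), "no disc")
})

test_that("zone labels follow distance from the disc edge in DD units", {
  ann <- zone_annuli(fit_disc(filled_disk(512, 40, 256, 256)))
  dd <- ann$disc$diameter
  r0 <- ann$disc$radius
  at_dd <- function(k) zone_of(256 + r0 + k * dd, 256, ann)
  expect_equal(at_dd(0.25), "A")
  expect_equal(at_dd(0.75), "B")
  expect_equal(at_dd(1.5), "C")
  expect_equal(at_dd(2.5), "outside")
  expect_equal(zone_of(256, 256, ann), "disc")
  # boundary points belong to the inner zone (half-open outward)
  expect_equal(at_dd(0.5), "A")
  expect_equal(at_dd(1), "B")
  expect_equal(at_dd(2), "C")
})

test_that("zone labels partition the (0, 2] DD annulus", {
  ann <- toy_annuli()
  set.seed(11)
  th <- runif(300, 0, 2 * pi)
  rr <- runif(300, 0.01, 3.1) * ann$disc$diameter + ann$disc$radius
  z <- zone_of(256 + rr * cos(th), 256 + rr * sin(th), ann)
  expect_true(all(z %in% c("A", "B", "C", "outside")))
  inside <- rr <= ann$radii[["C"]]
  expect_true(all(z[inside] != "outside"))
  expect_true(all(z[!inside] == "outside"))
})

test_that("clip_to_zone truncates segments at the annulus boundaries", {
  # straight radial segment from the disc edge out to 3 DD
  ann <- toy_annuli()
  t <- seq(0, 1, length.out = 500)
  poly <- cbind(x = 256 + (41 + t * (3 * 80)) * 1, y = rep(256, 500))
  g <- structure(list(
    nodes = data.frame(id = 1:2, x = poly[c(1, 500), 1],
                       y = poly[c(1, 500), 2], degree = c(1L, 1L),
                       kind = "endpoint", tree_id = 1L),
    segments = list(list(polyline = poly, widths = rep(50, 500),
                         from = 1L, to = 2L, tree_id = 1L,
                         vessel_class = "artery")),
    vessel_class = "artery", spacing = 10), class = "vessel_graph")
  zc <- clip_to_zone(g, ann, "C")
  expect_length(zc$segments, 1)
  len <- retinavasc:::polyline_arc_px(zc$segments[[1]]$polyline)
  expect_equal(len, 80, tolerance = 1.5)  # exactly one DD of 80 px

  expect_length(clip_to_zone(g, ann, "A")$segments, 1)
  lenA <- retinavasc:::polyline_arc_px(clip_to_zone(g, ann, "A")$segments[[1]]$polyline)
  expect_equal(lenA, 39, tolerance = 1.5)

  # graph entirely inside the disc clips to nothing
  poly2 <- cbind(x = seq(250, 262, length.out = 20), y = rep(256, 20))
  g2 <- g
  g2$segments <- list(list(polyline = poly2, widths = rep(50, 20),
                           from = 1L, to = 2L, tree_id = 1L,
                           vessel_class = "artery"))
  expect_length(clip_to_zone(g2, ann, "C")$segments, 0)
})

test_that("clipped zone lengths add up to the length within 2 DD", {
  img <- fixture_image()
  m <- suppressWarnings(suppressMessages(measure_map(img$map)))
  g <- m$graphs$artery
  ann <- m$annuli
  total_zones <- 0
  for (z in c("A", "B", "C")) {
    cl <- clip_to_zone(g, ann, z)
    total_zones <- total_zones + sum(vapply(cl$segments, function(s)
      retinavasc:::polyline_arc_px(s$polyline), numeric(1)))
  }
  # direct restriction to <= 2 DD beyond the edge (excluding the disc)
  direct <- 0
  for (s in g$segments) {
    d <- sqrt((s$polyline[, 1] - ann$disc$center[["x"]])^2 +
              (s$polyline[, 2] - ann$disc$center[["y"]])^2)
    keep <- d > ann$radii[["disc"]] & d <= ann$radii[["C"]]
    if (sum(keep) >= 2)
      direct <- direct +
        retinavasc:::polyline_arc_px(s$polyline[keep, , drop = FALSE])
  }
  expect_equal(total_zones, direct,
               tolerance = (2 * length(g$segments) + 2) / direct)
})
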