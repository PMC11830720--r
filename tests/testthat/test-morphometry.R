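test_that("bifurcation_angle handles canonical daughter geometries", {
  d <- function(a) c(cos(a * pi / 180), sin(a * pi / 180))
  expect_equal(bifurcation_angle(NULL, d(30), d(-30)), 60, tolerance = 1e-9)
  expect_equal(bifurcation_angle(NULL, d(0), d(90)), 90, tolerance = 1e-9)
  expect_equal(bifurcation_angle(NULL, d(0), d(180)), 180, tolerance = 1e-9)
  # invariant to daughter relabeling and vector scaling
  expect_equal(bifurcation_angle(NULL, d(75), d(-20)),
               bifurcation_angle(NULL, d(-20), 3 * d(75)))
  expect_error(bifurcation_angle(NULL, c(0, 0), d(10)), "zero-length")
})

test_that("bifurcation_asymmetry is the squared-caliber index", {
  expect_equal(bifurcation_asymmetry(7, 7), 0)
  expect_equal(bifurcation_asymmetry(10, 5), 75)   # 100 * (1 - 0.25)
  expect_equal(bifurcation_asymmetry(5, 10), bifurcation_asymmetry(10, 5))
  expect_error(bifurcation_asymmetry(-1, 5), "positive")
})

test_that("segment_tortuosity is arc over chord with degenerate handling", {
  straight <- cbind(x = seq(0, 100, by = 0.5), y = 0)
  expect_equal(segment_tortuosity(straight), 1)

  th <- seq(0, pi, by = pi / 180)
  half_circle <- cbind(x = cos(th), y = sin(th))
  expect_equal(segment_tortuosity(half_circle), pi / 2, tolerance = 1e-3)

  loop <- cbind(x = cos(seq(0, 2 * pi, length.out = 90)),
                y = sin(seq(0, 2 * pi, length.out = 90)))
  expect_warning(v <- segment_tortuosity(loop), "coincident")
  expect_true(is.na(v))
})

test_that("tortuosity is invariant to rotation, translation and scale", {
  set.seed(42)
  for (i in 1:5) {
    t <- seq(0, 1, length.out = 200)
    poly <- cbind(x = 100 * t, y = 8 * sin(2 * pi * t * runif(1, 1, 3)))
    base <- segment_tortuosity(poly)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- sweep(poly %*% R * runif(1, 0.5, 4), 2, c(17, -3), `+`)
    expect_equal(segment_tortuosity(moved), base, tolerance = 1e-9)
  }
})

test_that("zone C branch statistics average the accepted bifurcations", {
  # one tree, 3 Zone C bifurcations with known angles
  tree <- toy_tree_segments(list(
    list(adv = 90, angle = 60, parent_width = 120,
         daughter_widths = c(100, 80)),
    list(adv = 35, angle = 80, daughter_widths = c(85, 70)),
    list(adv = 25, angle = 100, daughter_widths = c(70, 60))))
  g <- toy_graph(list(tree))
  st <- zone_c_branch_stats(g, toy_annuli())
  expect_equal(st$branch_avg, 3)
  expect_equal(st$angle_avg, mean(c(60, 80, 100)), tolerance = 2)
  asym <- function(w) 100 * (1 - (min(w) / max(w))^2)
  expect_equal(st$asymmetry_avg,
               mean(c(asym(c(100, 80)), asym(c(85, 70)), asym(c(70, 60)))),
               tolerance = 1e-6)
})

test_that("branch_avg is the mean count per disc-rooted tree", {
  spec2 <- list(list(adv = 95, angle = 70, parent_width = 120,
                     daughter_widths = c(100, 80)),
                list(adv = 35, angle = 70, daughter_widths = c(85, 70)))
  spec4 <- c(spec2, list(
    list(adv = 22, angle = 75, daughter_widths = c(70, 60)),
    list(adv = 18, angle = 75, daughter_widths = c(60, 50))))
  # two separate trees with 2 and 4 Zone C bifurcations
  t1 <- toy_tree_segments(spec2, root_angle = 0)
  t2 <- toy_tree_segments(spec4, root_angle = 180)
  st <- zone_c_branch_stats(toy_graph(list(t1, t2)), toy_annuli())
  expect_equal(st$branch_avg, 3)  # mean of 2 and 4
})

test_that("branch statistics are missing when Zone C has no bifurcation", {
  tree <- toy_tree_segments(list(
    list(adv = 55, angle = 70, parent_width = 120,  # Zone B only
         daughter_widths = c(100, 80))))
  st <- zone_c_branch_stats(toy_graph(list(tree)), toy_annuli())
  expect_true(is.na(st$angle_avg))
  expect_true(is.na(st$asymmetry_avg))
  expect_true(is.na(st$branch_avg))
})

test_that("zone C length stats average clipped segments", {
  img <- fixture_image()
  m <- suppressWarnings(suppressMessages(measure_map(img$map)))
  expect_gt(m$record$length_avg_a, 0)
  expect_gte(m$record$curvature_avg_a, 1)
  # empty graph yields missing values
  e <- structure(list(nodes = data.frame(), segments = list(),
                      vessel_class = "artery", spacing = 10),
                 class = "vessel_graph")
  st <- zone_c_length_stats(e, toy_annuli())
  expect_true(is.na(st$length_avg))
  expect_true(is.na(st$curvature_avg))
})

test_that("densities are pixel fractions over the analysis region", {
  n <- 100
  all_vessel <- matrix(1L, n, n)
  z <- matrix(0L, n, n)
  d <- densities(all_vessel, z, z, z)
  expect_equal(d$vessel_density, 1)

  d0 <- densities(z, z, z, z)
  expect_equal(d0$vessel_density, 0)
  expect_equal(d0$vessel_length_density, 0)

  line <- matrix(0L, n, n); line[50, 1:100] <- 1L
  dl <- densities(line, z, line, z)
  expect_equal(dl$vessel_density, 0.01)
  expect_equal(dl$vessel_length_density, 0.01)
})

test_that("dilation increases area density but not length density", {
  img <- fixture_image()
  a <- img$map$artery; v <- img$map$vein
  ska <- skeletonize(a); skv <- skeletonize(v)
  base <- densities(a, v, ska, skv)
  ker <- EBImage::makeBrush(3, "box")
  ad <- as.matrix(EBImage::dilate(a, ker))
  vd <- as.matrix(EBImage::dilate(v, ker))
  thick <- densities(ad, vd, ska, skv)
  expect_gt(thick$vessel_density, base$vessel_density)
  expect_equal(thick$vessel_length_density, base$vessel_length_density)
})

test_that("vessel density dominates length density on real masks", {
  img <- fixture_image()
  m <- suppressWarnings(suppressMessages(measure_map(img$map)))
  expect_gt(m$record$vessel_density, m$record$vessel_length_density)
  expect_lt(m$record$vessel_density, 1)
})
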