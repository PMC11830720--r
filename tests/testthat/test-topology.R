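test_that("skeletonize thins shapes to one-pixel centerlines", {
  sk <- skeletonize(bar_mask(128, 100, 5))
  deg <- retinavasc:::neighbor_count(sk)
  # a single 8-connected path: 2 endpoints, rest degree-2, ~100 px long
  expect_equal(sum(sk == 1 & deg == 1), 2)
  expect_equal(sum(sk == 1 & deg > 2), 0)
  expect_gt(sum(sk), 90)
  expect_lt(sum(sk), 105)
  # subset of the input foreground
  expect_true(all(bar_mask(128, 100, 5)[sk == 1] == 1))

  expect_equal(sum(skeletonize(blank_raster(32))), 0)

  disk <- skeletonize(filled_disk(64, 20))
  expect_lt(sum(disk), 25)  # near-point residue of a convex blob
})

test_that("extract_graph classifies Y and X topologies", {
  ym <- y_mask()
  gy <- extract_graph(skeletonize(ym), ym, spacing = 10)
  gy <- prune_spurs(gy)
  expect_equal(sum(gy$nodes$kind == "endpoint"), 3)
  expect_equal(sum(gy$nodes$kind == "bifurcation"), 1)
  expect_equal(length(gy$segments), 3)

  xm <- x_mask()
  gx <- prune_spurs(extract_graph(skeletonize(xm), xm, spacing = 10))
  expect_equal(sum(gx$nodes$kind == "crossing-suspect"), 1)
  expect_equal(sum(gx$nodes$degree == 4), 1)
})

test_that("widths follow twice the distance transform times spacing", {
  m <- bar_mask(128, 100, 6)
  g <- extract_graph(skeletonize(m), m, spacing = 5)
  w <- unlist(lapply(g$segments, `[[`, "widths"))
  # interior of a 6 px bar at 5 um/px: 2 * 3 px * 5 um = 30 um
  expect_equal(median(w), 30, tolerance = 0.2)
})

test_that("segment arc lengths add up to the traced skeleton path length", {
  img <- fixture_image()
  mask <- img$map$artery
  sk <- skeletonize(mask)
  g <- extract_graph(sk, mask, 10)
  total_seg <- sum(vapply(g$segments, function(s)
    retinavasc:::polyline_arc_px(s$polyline), numeric(1)))
  # skeleton pixel count approximates total path length within one pixel
  # per segment plus the diagonal-step excess
  expect_gt(total_seg, sum(sk) * 0.95)
  expect_lt(total_seg, sum(sk) * 1.45)
})

test_that("node kinds always match degrees recomputed from segments", {
  img <- fixture_image()
  for (cls in c("artery", "vein")) {
    mask <- img$map[[cls]]
    g <- prune_spurs(extract_graph(skeletonize(mask), mask, 10, cls))
    recount <- retinavasc:::recompute_nodes(g$nodes, g$segments)
    expect_identical(recount$kind, g$nodes$kind)
    expect_identical(recount$degree, g$nodes$degree)
    expect_true(all(g$nodes$degree[g$nodes$kind == "endpoint"] == 1))
    expect_true(all(g$nodes$degree[g$nodes$kind == "bifurcation"] == 3))
  }
})

test_that("prune_spurs removes short terminals, is idempotent, keeps rest", {
  # Y with one tiny daughter: pruning degenerates it to a single path
  n <- 128
  m <- matrix(0L, n, n)
  m <- stroke_line(m, 10, 64, 70, 64, 5)
  m <- stroke_line(m, 70, 64, 120, 64, 5)
  m <- stroke_line(m, 70, 64, 74, 58, 5)  # 7 px spur
  g <- extract_graph(skeletonize(m), m, spacing = 10)
  p1 <- prune_spurs(g, min_length = 150)
  expect_equal(sum(p1$nodes$kind == "bifurcation"), 0)
  expect_equal(length(p1$segments), 1)

  # graph with no short terminal is unchanged
  ym <- y_mask()
  gy <- prune_spurs(extract_graph(skeletonize(ym), ym, 10))
  gy2 <- prune_spurs(gy)
  expect_equal(length(gy2$segments), length(gy$segments))
  expect_identical(gy2$nodes$kind, gy$nodes$kind)

  # idempotence on a real image graph
  img <- fixture_image()
  g <- extract_graph(skeletonize(img$map$vein), img$map$vein, 10, "vein")
  once <- prune_spurs(g)
  twice <- prune_spurs(once)
  expect_equal(length(twice$segments), length(once$segments))
  expect_identical(twice$nodes$kind, once$nodes$kind)
})

test_that("graph recovers the simulated bifurcation count exactly", {
  img <- fixture_image()
  ann <- toy_annuli()
  for (cls in c("artery", "vein")) {
    mask <- img$map[[cls]]
    g <- prune_spurs(extract_graph(skeletonize(mask), mask, 10, cls))
    truth_n <- sum(img$truth$bifurcations$vessel_class == cls)
    expect_equal(sum(g$nodes$kind == "bifurcation"), truth_n)
  }
})
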