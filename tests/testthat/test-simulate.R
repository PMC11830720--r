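test_that("growth is deterministic given the seed", {
  p <- tree_params()
  t1 <- grow_tree(p, seed = 99)
  t2 <- grow_tree(p, seed = 99)
  expect_identical(t1$branches, t2$branches)
  expect_identical(t1$bifurcations, t2$bifurcations)
  m1 <- rasterize_tree(t1); m2 <- rasterize_tree(t2)
  expect_identical(m1$artery, m2$artery)
  expect_identical(m1$vein, m2$vein)
  t3 <- grow_tree(p, seed = 100)
  expect_false(identical(t1$branches, t3$branches))
})

test_that("zero tortuosity target gives exactly straight branches", {
  p <- tree_params(tortuosity_target = 1, tortuosity_jitter_sd = 0,
                   tortuosity_range = c(1, 1))
  tr <- grow_tree(p, seed = 3)
  for (b in tr$branches)
    expect_equal(segment_tortuosity(b$polyline), 1, tolerance = 1e-9)
})

test_that("zero asymmetry target gives equal daughter widths", {
  p <- tree_params(asymmetry_target = c(artery = 0, vein = 0),
                   asymmetry_jitter_sd = 0, asymmetry_range = c(0, 0))
  tr <- grow_tree(p, seed = 3)
  expect_equal(tr$bifurcations$daughter_width_1,
               tr$bifurcations$daughter_width_2, tolerance = 1e-9)
})

test_that("wave amplitude solver realizes the requested arc-chord ratio", {
  for (tau in c(1.02, 1.1, 1.2)) {
    amp <- retinavasc:::wave_amplitude(400, 1000, tau, phase = 0.7)
    poly <- retinavasc:::branch_polyline(c(0, 0), 0.3, 400, amp, 1000, 0.7, 1)
    expect_equal(segment_tortuosity(poly), tau, tolerance = 5e-3)
  }
  expect_equal(retinavasc:::wave_amplitude(400, 1000, 1), 0)
})

test_that("rasterization covers the stroked area without double counting", {
  p <- tree_params(n_trees = 1, branch_levels = 1, tortuosity_target = 1,
                   tortuosity_jitter_sd = 0, tortuosity_range = c(1, 1),
                   root_width = c(artery = 60, vein = 60), root_width_sd = 0)
  tr <- grow_tree(p, seed = 2)
  map <- rasterize_tree(tr)
  b <- tr$branches[[1]]
  expected <- retinavasc:::polyline_arc_px(b$polyline) * (b$width_um / 10)
  expect_equal(sum(map$artery), expected, tolerance = 0.10 * expected)
  expect_true(all(map$artery %in% 0:1))
  expect_gt(sum(map$disc), 0)

  # empty class stays empty
  p0 <- tree_params(n_trees = 1, branch_levels = 1)
  tr0 <- grow_tree(p0, seed = 2)
  tr0$branches <- Filter(function(b) b$vessel_class == "artery", tr0$branches)
  m0 <- rasterize_tree(tr0)
  expect_equal(sum(m0$vein), 0)
})

test_that("truth records are recomputable and internally consistent", {
  fx <- fixture_image()
  rec <- truth_record(fx$truth, fx$map)
  rec2 <- truth_record(fx$truth, fx$map)
  expect_identical(rec, rec2)
  expect_equal(rec$avr, rec$crae / rec$crve)
  expect_gte(rec$curvature_avg_a, 1)
  expect_true(rec$vessel_density > 0 && rec$vessel_density < 1)
  zc <- zone_of(fx$truth$bifurcations$x, fx$truth$bifurcations$y,
                toy_annuli())
  agg <- table(fx$truth$bifurcations$vessel_class[zc == "C"])
  expect_equal(rec$branch_avg_a * 4, unname(agg[["artery"]]))
  expect_equal(rec$branch_avg_v * 4, unname(agg[["vein"]]))
})

test_that("generate_cohort builds the labeled set reproducibly", {
  co <- generate_cohort(n_per_group = 3, seed = 21)
  expect_length(co$images, 6)
  expect_equal(nrow(co$ledger), 6)
  expect_equal(as.integer(table(co$ledger$group)), c(3L, 3L))

  co2 <- generate_cohort(n_per_group = 3, seed = 21)
  expect_identical(co$ledger, co2$ledger)
  expect_identical(co$images[[5]]$map$artery, co2$images[[5]]$map$artery)

  expect_error(generate_cohort(n_per_group = 0, seed = 1), "n_per_group")
  expect_error(generate_cohort(list(only = list()), 2, 1), "2")
})

test_that("NPDR-like group deltas show in the ground-truth ledger", {
  co <- generate_cohort(n_per_group = 8, seed = 5)
  led <- co$ledger
  ctrl <- led[led$group == "control", ]
  npdr <- led[led$group == "npdr", ]
  expect_lt(mean(npdr$branch_avg_v), mean(ctrl$branch_avg_v))
  expect_lt(mean(npdr$vessel_density), mean(ctrl$vessel_density))
  expect_gt(mean(npdr$length_avg_v), mean(ctrl$length_avg_v))
})

test_that("write_cohort emits masks, ledger and config", {
  tmp <- withr::local_tempdir()
  co <- generate_cohort(n_per_group = 2, seed = 77)
  write_cohort(co, tmp)
  expect_length(list.files(tmp, pattern = "_artery\\.png$"), 4)
  led <- read.csv(file.path(tmp, "ground_truth.csv"))
  expect_equal(nrow(led), 4)
  cfg <- yaml::read_yaml(file.path(tmp, "cohort_config.yaml"))
  expect_equal(cfg$seed, 77)
  expect_true(all(c("control", "npdr") %in% names(cfg)))
})
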