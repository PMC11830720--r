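test_that("box_counts tallies per-box masses on the anchored grid", {
  full <- matrix(1, 64, 64)
  bc <- box_counts(full, sizes = 64)
  expect_equal(as.numeric(bc[["64"]]), 4096)

  single <- matrix(0, 64, 64); single[17, 42] <- 1
  for (e in c(4, 8, 16, 32)) {
    occ <- box_counts(single, sizes = e)[[1]]
    expect_equal(sum(occ > 0), 1)
  }

  line <- matrix(0, 64, 64); line[10, 1:64] <- 1
  expect_equal(sum(box_counts(line, sizes = 8)[["8"]] > 0), 8)

  expect_error(box_counts(matrix(0, 32, 32)), "no foreground")
  expect_error(box_counts(matrix(1, 8, 8), sizes = 16), "exceeds")
})

test_that("adding foreground never decreases occupied box counts", {
  set.seed(3)
  base <- matrix(rbinom(128 * 128, 1, 0.02), 128, 128)
  extra <- pmax(base, matrix(rbinom(128 * 128, 1, 0.02), 128, 128))
  sizes <- default_box_sizes(128, 128)
  b1 <- box_counts(base, sizes); b2 <- box_counts(extra, sizes)
  for (k in seq_along(sizes))
    expect_true(sum(b2[[k]] > 0) >= sum(b1[[k]] > 0))
})

test_that("capacity dimension is invariant to whole-box translation", {
  m <- matrix(0, 256, 256)
  m[64:192, 100] <- 1; m[100, 64:192] <- 1
  d1 <- generalized_dimension(box_counts(m), 0)$dimension
  shifted <- matrix(0, 256, 256)
  shifted[(64:192) + 32, 100 + 32] <- 1; shifted[100 + 32, (64:192) + 32] <- 1
  d2 <- generalized_dimension(box_counts(shifted), 0)$dimension
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("generalized dimensions match analytic values on exact sets", {
  line <- matrix(0, 512, 512); line[256, ] <- 1
  expect_equal(generalized_dimension(box_counts(line), 0)$dimension, 1,
               tolerance = 0.05)

  square <- matrix(1, 512, 512)
  expect_equal(generalized_dimension(box_counts(square), 0)$dimension, 2,
               tolerance = 0.05)

  sier <- sierpinski_mask(512)
  expect_equal(generalized_dimension(box_counts(sier), 0)$dimension,
               log(3) / log(2), tolerance = 0.05)

  expect_error(generalized_dimension(box_counts(line, sizes = c(64, 32)), 0),
               "at least 4")
})

test_that("dimension ordering d0 >= d1 >= d2 holds on exact measures", {
  line <- matrix(0, 512, 512); line[100, 30:500] <- 1
  fixtures <- list(line, matrix(1, 512, 512), sierpinski_mask(512))
  for (m in fixtures) {
    occ <- box_counts(m)
    d0 <- generalized_dimension(occ, 0)$dimension
    d1 <- generalized_dimension(occ, 1)$dimension
    d2 <- generalized_dimension(occ, 2)$dimension
    expect_gte(d0, d1 - 0.02)
    expect_gte(d1, d2 - 0.02)
  }
  # strict ordering on a genuinely multifractal measure, against closed form
  occ <- box_counts(cascade_strips(512), sizes = c(128, 64, 32, 16))
  expect_equal(generalized_dimension(occ, 0)$dimension, 1, tolerance = 0.02)
  p <- 0.7; r <- 0.3
  expect_equal(generalized_dimension(occ, 1)$dimension,
               -(p * log2(p) + r * log2(r)), tolerance = 0.02)
  expect_equal(generalized_dimension(occ, 2)$dimension,
               -log2(p^2 + r^2), tolerance = 0.02)
})

test_that("singularity length vanishes for monofractals", {
  line <- matrix(0, 512, 512); line[256, ] <- 1
  expect_lt(singularity_length(line)$sl, 0.1)
  square <- matrix(1, 256, 256)
  expect_lt(singularity_length(square)$sl, 0.1)
})

test_that("singularity length of a binomial cascade matches the closed form", {
  m <- cascade_strips(512, p = 0.7, levels = 5)
  res <- singularity_length(m, sizes = c(128, 64, 32, 16))
  # analytic spectrum width over the same truncated q range
  expected <- cascade_alpha(min(res$q)) - cascade_alpha(max(res$q))
  expect_equal(res$sl, expected, tolerance = 0.15)
})

test_that("fractal_panel keys both classes and handles empty input", {
  sk <- skeletonize(fixture_image()$map$artery)
  pan <- fractal_panel(sk, sk)
  expect_equal(pan$d0_a, pan$d0_v)
  expect_equal(pan$sl_a, pan$sl_v)
  expect_true(all(is.finite(c(pan$d0_a, pan$d1_a, pan$d2_a))))

  pan2 <- fractal_panel(sk, NULL)
  expect_true(is.na(pan2$d0_v) && is.na(pan2$sl_v))
  expect_false(is.na(pan2$d0_a))

  # superset foreground (both classes together) is more space-filling
  both <- pmax(sk, skeletonize(fixture_image()$map$vein))
  expect_gt(fractal_spectrum(both)$d0, fractal_spectrum(sk)$d0)
})

test_that("regression diagnostics are reported and strong on exact sets", {
  sp <- fractal_spectrum(sierpinski_mask(512))
  expect_true(all(c("size", "n_boxes", "entropy", "sum_p2") %in%
                  names(sp$diagnostics)))
  expect_gte(sp$r2[["d0"]], 0.97)
})
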