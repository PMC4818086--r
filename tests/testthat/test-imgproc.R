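test_that("background subtraction flattens backgrounds but keeps impulses", {
  # constant image: background equals the image, everything removed
  s <- image_stack(array(37, c(4, 40, 40)))
  out <- subtract_background(s, radius = 8)
  expect_true(all(out$data == 0))

  # small bright peak on a flat background survives with its height
  a <- array(10, c(3, 60, 60))
  a[2, 30, 30] <- 150
  out <- subtract_background(image_stack(a), radius = 10)
  expect_equal(out$data[2, 30, 30], 140)
  expect_gte(min(out$data), 0)

  expect_error(subtract_background(s, radius = 30), "larger than the slice")
  expect_error(subtract_background(s, radius = 0), "radius")
})

test_that("rank filters obey order statistics and remove impulse noise", {
  set.seed(2)
  a <- array(runif(16 * 16 * 16, 0, 100), c(16, 16, 16))
  s <- image_stack(a)
  mn <- rank_filter_3d(s, "minimum", 1)$data
  mx <- rank_filter_3d(s, "maximum", 1)$data
  expect_true(all(mn <= a + 1e-12))
  expect_true(all(a <= mx + 1e-12))

  # constant stack has zero variance everywhere
  v <- rank_filter_3d(image_stack(array(5, c(6, 6, 6))), "variance", 1)
  expect_true(all(v$data == 0))

  # single-voxel impulse is removed by a radius-1 median
  b <- array(0, c(9, 9, 9)); b[5, 5, 5] <- 255
  med <- rank_filter_3d(image_stack(b), "median", 1)$data
  expect_equal(max(med), 0)

  expect_error(rank_filter_3d(s, "mean", 1))
})

test_that("min/max filters are idempotent at fixed radius", {
  set.seed(3)
  s <- image_stack(array(runif(1000, 0, 9), c(10, 10, 10)))
  mn1 <- rank_filter_3d(s, "minimum", 1)
  expect_equal(rank_filter_3d(mn1, "minimum", 1)$data,
               rank_filter_3d(s, "minimum", 2)$data, tolerance = 1e-12)
})

test_that("gaussian blur preserves mass and has exact trivial cases", {
  a <- array(0, c(15, 15, 15)); a[8, 8, 8] <- 1000
  s <- image_stack(a)
  expect_identical(gaussian_blur_3d(s, 0)$data, a)
  const <- gaussian_blur_3d(image_stack(array(7, c(8, 8, 8))), 1)
  expect_equal(const$data, array(7, c(8, 8, 8)), tolerance = 1e-9)
  bl <- gaussian_blur_3d(s, 1)
  expect_equal(sum(bl$data), 1000, tolerance = 0.01)
  # centred impulse reproduces the separable kernel profile
  expect_equal(bl$data[8, 8, 8], max(bl$data))
})

test_that("anisotropic spacing widens the blur along the coarse axis", {
  a <- array(0, c(21, 21, 21)); a[11, 11, 11] <- 1
  iso <- gaussian_blur_3d(image_stack(a), 2)$data
  aniso <- gaussian_blur_3d(image_stack(a, spacing = c(2, 1, 1)), 2)$data
  # with dz = 2 the kernel is narrower in z voxels
  expect_lt(iso[11, 11, 11], aniso[11, 11, 11])
  expect_gt(iso[14, 11, 11], aniso[14, 11, 11] - 1e-12)
})

# running mean over {i-1, i, i+1} truncated at the ends
roll_mean3 <- function(m) {
  n <- length(m)
  vapply(seq_len(n), function(i) mean(m[max(1, i - 1):min(n, i + 1)]), 0)
}

test_that("depth compensation recovers uniform luminosity", {
  set.seed(4)
  base <- array(rep(100 * runif(32 * 32), each = 16), c(16, 32, 32))
  s <- image_stack(base)
  # luminosity-uniform stack: gains identically 1
  out <- compensate_depth(s)
  expect_equal(attr(out, "gains"), rep(1, 16))
  expect_equal(out$data, base)

  # geometric decay: the gains follow the closed form exactly, and away
  # from the truncated end windows the compensated slice maxima are flat
  dec <- apply_artifacts(s, 0, 0.9)
  cmp <- compensate_depth(dec)
  mx <- apply(cmp$data, 1, max)
  m_true <- max(base) * 0.9^(0:15)
  r_true <- roll_mean3(m_true)
  g_true <- max(r_true) / r_true
  expect_equal(as.numeric(attr(cmp, "gains")), g_true, tolerance = 1e-6)
  mid <- mx[2:15]
  expect_lt(diff(range(mid)) / max(mid), 1e-6)

  # truncated window at the ends: first slice gain uses slices 1:2 only
  m <- vapply(seq_len(16), function(i) quantile(dec$data[i, , ], 0.999,
                                                names = FALSE), 0)
  r1 <- mean(m[1:2])
  expect_equal(attr(cmp, "gains")[1], max(roll_mean3(m)) / r1,
               tolerance = 1e-9)
})

test_that("near-empty slices are gain-capped with a warning", {
  a <- array(0, c(6, 16, 16))
  a[3:6, 5:12, 5:12] <- 200
  expect_warning(out <- compensate_depth(image_stack(a)), "capped")
  expect_true(all(attr(out, "gains") <= 10))
})

test_that("2D hole filling fills enclosed regions only, idempotently", {
  a <- array(FALSE, c(3, 21, 21))
  # slice 2: annulus
  for (y in 1:21) for (x in 1:21) {
    r <- sqrt((y - 11)^2 + (x - 11)^2)
    a[2, y, x] <- r >= 5 && r <= 8
  }
  f <- fill_holes_2d(a)
  expect_true(all(f[2, , ][sqrt(outer(1:21 - 11, rep(0, 21), "+")^2 +
                                  outer(rep(0, 21), 1:21 - 11, "+")^2) <= 8]))
  expect_identical(f, fill_holes_2d(f))
  # solid disk unchanged
  solid <- a; solid[2, , ] <- FALSE
  for (y in 1:21) for (x in 1:21) {
    solid[2, y, x] <- sqrt((y - 11)^2 + (x - 11)^2) <= 8
  }
  expect_identical(fill_holes_2d(solid), solid)
  # "C" shape open to the border stays open
  cshape <- array(FALSE, c(1, 15, 15))
  cshape[1, 3:13, 3:13] <- TRUE
  cshape[1, 6:10, 6:15] <- FALSE  # slot reaching the border
  expect_identical(fill_holes_2d(cshape), cshape)
})

test_that("gradient separation splits touching structures, fixes nothing else", {
  # constant stack unchanged
  s <- image_stack(array(40, c(8, 8, 8)))
  expect_equal(gradient_separation(s)$data, s$data)

  # two spheres joined by a 1-voxel-wide bright neck: after separation and
  # re-threshold the two components reappear
  g <- c(24L, 48L, 24L)
  m <- array(0, g)
  m[rasterize_ellipsoid(c(12, 15, 12), c(7, 7, 7), diag(3), g)] <- 200
  m[rasterize_ellipsoid(c(12, 33, 12), c(7, 7, 7), diag(3), g)] <- 200
  m[12, 22:26, 12] <- 200
  before <- oracle_component_count(m > 100, 26L)
  expect_equal(before, 1)
  sep <- gradient_separation(image_stack(m))
  after <- oracle_component_count(sep$data > 100, 26L)
  expect_equal(after, 2)
  # deep interior voxels unchanged
  expect_equal(sep$data[12, 15, 12], 200)
})

test_that("tier-1 composes its stages as configured", {
  ps <- generate_stack(small_spec(), seed = 21)
  cfg <- tier1_config(background_radius = 12, median_radius = 0,
                      lumen_median_radius = 0, sigma = 0, compensate = FALSE)
  t1 <- run_tier1(ps$stack, cfg)
  # with all optional stages off both branches equal the background-subtracted
  # input
  expect_equal(t1$morphometrics$data,
               subtract_background(ps$stack, 12)$data)
  expect_equal(t1$lumen$data, t1$morphometrics$data)

  # denoise hook runs in sequence
  cfg2 <- tier1_config(background_radius = 12, median_radius = 0,
                       lumen_median_radius = 0, sigma = 0, compensate = FALSE,
                       denoise = function(s) restacked <- image_stack(
                         s$data * 0 + 1, s$spacing, s$bit_depth))
  t2 <- suppressWarnings(run_tier1(ps$stack, cfg2))
  expect_true(all(t2$morphometrics$data == 1))

  # stage failures carry the stage name
  bad <- tier1_config(background_radius = 200)
  expect_error(run_tier1(ps$stack, bad), "subtract_background")
})

test_that("tier-1 preserves grid shape and spacing metadata", {
  ps <- generate_stack(small_spec(), seed = 22)
  ps$stack$spacing <- c(2, 0.5, 0.5)
  t1 <- run_tier1(ps$stack, tier1_config(background_radius = 12))
  expect_identical(dim(t1$morphometrics$data), dim(ps$stack$data))
  expect_identical(t1$morphometrics$spacing, c(2, 0.5, 0.5))
  expect_identical(t1$lumen$spacing, c(2, 0.5, 0.5))
  expect_identical(dim(t1$mask), dim(ps$stack$data))
})
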