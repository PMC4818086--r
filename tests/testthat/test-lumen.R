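# hollow ellipsoid phantom in a small grid: shell bright, cavity dark
hollow_fixture <- function(outer = c(9, 8, 7), frac = 0.5,
                           grid = c(28, 28, 28), fg = 200, bg = 20) {
  center <- (grid + 1) / 2
  shell <- rasterize_ellipsoid(center, outer, diag(3), grid)
  cavity <- rasterize_ellipsoid(center, frac * outer, diag(3), grid)
  a <- array(bg, grid)
  a[shell] <- fg
  a[cavity] <- bg
  list(stack = image_stack(a), mask = a > 100,
       cavity_voxels = nrow(cavity), total_voxels = nrow(shell))
}

test_that("a hollow ellipsoid yields exactly one lumen of the right size", {
  h <- hollow_fixture()
  lum <- segment_lumena(h$mask, h$stack, lumen_threshold = 100)
  expect_equal(attr(lum, "n_labels"), 1L)
  expect_lt(abs(sum(lum > 0) - h$cavity_voxels) / h$cavity_voxels, 0.1)
})

test_that("a solid ellipsoid yields no lumen", {
  g <- c(24, 24, 24)
  a <- array(20, g)
  a[rasterize_ellipsoid(c(12, 12, 12), c(8, 7, 6), diag(3), g)] <- 200
  lum <- segment_lumena(a > 100, image_stack(a), lumen_threshold = 100)
  expect_equal(attr(lum, "n_labels"), 0L)
})

test_that("every structure of a clean reference phantom has its lumen found", {
  ps <- generate_stack(small_spec(), seed = 31)
  mask <- ps$structure_labels > 0 & ps$lumen_labels == 0
  lum <- segment_lumena(mask, ps$stack, lumen_threshold = 100)
  expect_equal(attr(lum, "n_labels"), nrow(ps$truth))
})

test_that("lumen threshold outside the intensity range errors", {
  h <- hollow_fixture()
  expect_error(segment_lumena(h$mask, h$stack, lumen_threshold = 999),
               "outside")
})

test_that("lumena are assigned to the containing structure", {
  ps <- generate_stack(small_spec(), seed = 32)
  mask <- ps$structure_labels > 0 & ps$lumen_labels == 0
  labs <- label_components(fill_holes_2d(mask), min_voxels = 64)
  lum <- segment_lumena(mask, ps$stack, lumen_threshold = 100)
  as <- assign_lumena(lum, labs)
  expect_true(all(!as$flagged))
  # each assigned parent contains the lumen centroid
  for (i in seq_len(nrow(as))) {
    cz <- round(as$centroid_z[i]) + 1
    cy <- round(as$centroid_y[i]) + 1
    cx <- round(as$centroid_x[i]) + 1
    expect_equal(labs[cz, cy, cx], as$parent[i])
  }
})

test_that("two cavities in one structure both assign to it; strays flag", {
  g <- c(30, 44, 30)
  a <- array(20, g)
  a[rasterize_ellipsoid(c(15, 22, 15), c(10, 18, 10), diag(3), g)] <- 200
  a[rasterize_ellipsoid(c(15, 13, 15), c(4, 4, 4), diag(3), g)] <- 20
  a[rasterize_ellipsoid(c(15, 31, 15), c(4, 4, 4), diag(3), g)] <- 20
  mask <- a > 100
  labs <- label_components(fill_holes_2d(mask), min_voxels = 64)
  lum <- segment_lumena(mask, image_stack(a), lumen_threshold = 100)
  expect_equal(attr(lum, "n_labels"), 2L)
  as <- assign_lumena(lum, labs)
  expect_equal(as$parent, c(1L, 1L))

  lm <- lumen_metrics(measure_structures(labs), as)
  expect_equal(lm$structures$n_lumena, 2L)
  expect_equal(lm$lumen_fraction, 1)

  # a dark speck far outside every structure is a flagged orphan; build an
  # artificial lumen label volume containing it
  stray <- array(FALSE, g)
  stray[2:5, 2:5, 2:5] <- TRUE
  stray_lab <- label_components(stray, min_voxels = 1)
  expect_message(as2 <- assign_lumena(stray_lab, labs), "could not be assigned")
  expect_true(all(as2$flagged))
})

test_that("relative lumen volume matches constructed voxel counts", {
  # cuboid structure (10 x 10 x 10 = 1000 voxels filled) with an enclosed
  # cavity of exactly 5 x 8 x 5 = 200 voxels: RLV = 0.2 by construction
  g <- c(14, 14, 14)
  a <- array(20, g)
  a[3:12, 3:12, 3:12] <- 200
  a[5:9, 4:11, 5:9] <- 20
  mask <- a > 100
  filled <- fill_holes_2d(mask)
  labs <- label_components(filled, min_voxels = 64)
  lum <- segment_lumena(mask, image_stack(a), lumen_threshold = 100)
  expect_equal(attr(lum, "n_labels"), 1L)
  expect_equal(sum(lum > 0), 200L)
  as <- assign_lumena(lum, labs)
  lm <- lumen_metrics(measure_structures(labs), as)
  expect_equal(lm$structures$rlv, 0.2, tolerance = 1e-9)
})

test_that("no lumena anywhere gives RLV 0 and L 0", {
  g <- c(20, 20, 20)
  a <- array(20, g)
  a[rasterize_ellipsoid(c(10, 10, 10), c(6, 6, 6), diag(3), g)] <- 200
  labs <- label_components(a > 100, min_voxels = 64)
  lum <- segment_lumena(a > 100, image_stack(a), lumen_threshold = 100)
  as <- assign_lumena(lum, labs)
  lm <- lumen_metrics(measure_structures(labs), as)
  expect_equal(lm$structures$rlv, 0)
  expect_equal(lm$structures$n_lumena, 0L)
  expect_equal(lm$lumen_fraction, 0)
})

test_that("RLV stays in [0, 1) and lumen voxels stay inside filled masks", {
  for (s in 1:3) {
    ps <- generate_stack(small_spec(), seed = 40 + s)
    mask <- ps$structure_labels > 0 & ps$lumen_labels == 0
    filled <- fill_holes_2d(mask)
    labs <- label_components(filled, min_voxels = 64)
    lum <- segment_lumena(mask, ps$stack, lumen_threshold = 100)
    as <- assign_lumena(lum, labs)
    lm <- lumen_metrics(measure_structures(labs), as)
    expect_true(all(lm$structures$rlv >= 0 & lm$structures$rlv < 1))
    # cavity voxels are disjoint from the shell and inside the filled mask
    expect_true(all(!mask[lum > 0]))
    expect_true(all(filled[lum > 0]))
    expect_gte(lm$lumen_fraction, 0)
    expect_lte(lm$lumen_fraction, 1)
  }
})

test_that("detected lumen counts on half-probability phantoms are binomial", {
  # generator truth and detection agree: on clean stacks the cavity is exact,
  # so detected lumen-bearing structures across seeds follow
  # Binomial(n, 0.5)
  spec <- small_spec(lumen_probability = 0.5, n_structures = 8L)
  hits <- 0L; n <- 0L
  for (s in 1:20) {
    ps <- generate_stack(spec, seed = 300 + s)
    mask <- ps$structure_labels > 0 & ps$lumen_labels == 0
    labs <- label_components(fill_holes_2d(mask), min_voxels = 64)
    lum <- segment_lumena(mask, ps$stack, lumen_threshold = 100)
    as <- assign_lumena(lum, labs)
    lm <- lumen_metrics(measure_structures(labs), as)
    hits <- hits + sum(lm$structures$has_lumen)
    n <- n + nrow(lm$structures)
  }
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})
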