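line_mask <- function(n = 21, grid = c(9, 9, 27)) {
  m <- array(FALSE, grid)
  m[5, 5, 4:(3 + n)] <- TRUE
  m
}

test_that("a 1-voxel-wide line is already minimal and keeps its length", {
  m <- line_mask(21)
  sk <- skeletonize_3d(m)
  expect_identical(sk, m)
  g <- skeleton_graph(sk, spacing = c(1, 1, 1), prune_length = 0)
  expect_equal(g$n_branches, 1L)
  expect_equal(g$total_length, 20)
})

test_that("skeletons stay inside the mask and preserve component count", {
  set.seed(8)
  for (i in 1:4) {
    ax <- runif(3, 4, 9)
    m <- ellipsoid_mask(ax, grid = c(26, 26, 26))
    m[2:4, 2:4, 2:4] <- TRUE  # second small component
    sk <- skeletonize_3d(m)
    expect_true(all(m[sk]))
    expect_equal(oracle_component_count(sk, 26L),
                 oracle_component_count(m, 26L))
  }
})

test_that("a solid cylinder thins to its centreline", {
  g <- c(48, 15, 15)
  m <- array(FALSE, g)
  for (z in 5:44) {
    m[z, , ][(outer(1:15 - 8, rep(0, 15), "+")^2 +
                outer(rep(0, 15), 1:15 - 8, "+")^2) <= 16] <- TRUE
  }
  sk <- skeletonize_3d(m)
  expect_equal(oracle_component_count(sk, 26L), 1L)
  # a thin curve: far fewer voxels than the solid, spanning most of its length
  expect_lt(sum(sk), sum(m) / 20)
  zr <- range(which(apply(sk, 1, any)))
  expect_gt(diff(zr), 25)
  g1 <- skeleton_graph(sk, prune_length = 2)
  expect_equal(g1$n_branches, 1L)
})

test_that("a solid ball collapses to a small interior remnant", {
  m <- ellipsoid_mask(c(10, 10, 10))
  sk <- skeletonize_3d(m)
  # far fewer voxels than the solid, spanning at most one radius
  expect_lt(sum(sk), sum(m) / 100)
  cc <- which(sk, arr.ind = TRUE)
  expect_lte(max(apply(cc, 2, function(v) diff(range(v)))), 10)
  expect_true(all(m[sk]))
})

test_that("I and Y fixtures give 1 and 3 branches", {
  # "I": straight duct
  gi <- skeleton_graph(line_mask(15), prune_length = 0)
  expect_equal(gi$n_branches, 1L)
  expect_false(gi$has_multiple_branches)

  # "Y": three arms meeting at one junction
  m <- array(FALSE, c(5, 40, 40))
  m[3, 20, 20] <- TRUE
  m[3, 21:32, 20] <- TRUE                       # stem
  for (k in 1:12) m[3, 20 - k, 20 - k] <- TRUE  # arm 1
  for (k in 1:12) m[3, 20 - k, 20 + k] <- TRUE  # arm 2
  gy <- skeleton_graph(m, prune_length = 0)
  expect_equal(gy$n_branches, 3L)
  expect_true(gy$has_multiple_branches)
  expect_equal(sum(gy$nodes$type == "junction"), 1L)
  # the cumulated length is the sum of the three arms
  expect_equal(gy$total_length, 12 + 12 * sqrt(2) + 12 * sqrt(2))
  # and the branched shape is longer, hence more complex, than the duct
  expect_gt(gy$total_length, gi$total_length)
})

test_that("empty and single-voxel skeletons are handled", {
  e <- skeleton_graph(array(FALSE, c(4, 4, 4)))
  expect_equal(e$n_branches, 0L)
  expect_equal(e$total_length, 0)
  expect_false(e$has_multiple_branches)

  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  iso <- skeleton_graph(m)
  expect_equal(iso$n_branches, 1L)
  expect_equal(iso$total_length, 0)
})

test_that("branch lengths scale exactly with voxel spacing", {
  m <- array(FALSE, c(5, 30, 30))
  m[3, 5:25, 5] <- TRUE
  for (k in 0:10) m[3, 25, 5 + k] <- TRUE
  g1 <- skeleton_graph(m, spacing = c(1, 1, 1), prune_length = 0)
  g2 <- skeleton_graph(m, spacing = c(2, 2, 2), prune_length = 0)
  expect_equal(g2$total_length, 2 * g1$total_length)
})

test_that("every skeleton voxel is covered exactly once by the graph", {
  set.seed(9)
  for (i in 1:3) {
    m <- ellipsoid_mask(runif(3, 5, 9), grid = c(26, 26, 26),
                        orientation = rot3(rnorm(3), runif(1, 0, pi)))
    sk <- skeletonize_3d(m)
    g <- skeleton_graph(sk, prune_length = 0)
    interior <- unlist(lapply(seq_along(g$branch_voxels), function(b) {
      bb <- g$branches[b, ]
      setdiff(g$branch_voxels[[b]], c(bb$from, bb$to))
    }))
    expect_false(any(duplicated(interior)))
    covered <- sort(unique(c(interior,
                             unlist(g$branches[c("from", "to")]))))
    expect_equal(covered, seq_len(nrow(g$coords)))
  }
})

test_that("a closed ring is one branch of its perimeter length", {
  # diamond ring: every voxel has exactly two neighbours (diagonal steps)
  m <- array(FALSE, c(5, 15, 15))
  for (y in 1:15) for (x in 1:15) {
    m[3, y, x] <- (abs(y - 8) + abs(x - 8)) == 4
  }
  g <- skeleton_graph(m, prune_length = 0)
  expect_equal(g$n_branches, 1L)
  expect_equal(g$total_length, 16 * sqrt(2))
})

test_that("short spurs are pruned; a rasterized ellipsoid reports 1 branch", {
  # diagonal line with a single-voxel diagonal spur off its middle: the
  # spur attaches to exactly one line voxel, a clean 3-branch junction
  m <- array(FALSE, c(5, 24, 24))
  for (k in 3:19) m[3, k, k] <- TRUE
  m[3, 12, 10] <- TRUE
  g0 <- skeleton_graph(m, prune_length = 0)
  expect_equal(g0$n_branches, 3L)
  g2 <- skeleton_graph(m, prune_length = 2)
  expect_equal(g2$n_branches, 1L)

  set.seed(10)
  for (i in 1:3) {
    m <- ellipsoid_mask(runif(3, 6, 12), grid = c(32, 32, 32),
                        orientation = rot3(rnorm(3), runif(1, 0, pi)))
    g <- skeleton_graph(skeletonize_3d(m), prune_length = 2)
    expect_equal(g$n_branches, 1L)
  }
})

test_that("per-structure complexity separates pairs from single ellipsoids", {
  set.seed(12)
  ps1 <- generate_stack(small_spec(n_structures = 5L), seed = 51)
  ps4 <- generate_stack(small_spec(n_structures = 5L,
                                   perpendicular_pair = TRUE,
                                   grid_shape = c(48L, 112L, 112L)),
                        seed = 51)
  lab1 <- label_components(fill_holes_2d(ps1$structure_labels > 0 &
                                           ps1$lumen_labels == 0))
  lab4 <- label_components(fill_holes_2d(ps4$structure_labels > 0 &
                                           ps4$lumen_labels == 0))
  c1 <- measure_complexity(lab1)
  c4 <- measure_complexity(lab4)
  expect_gt(mean(c4$total_length), mean(c1$total_length))
  expect_gte(mean(c4$n_branches), mean(c1$n_branches))
})
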