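# Shared fixtures and independent oracles.  Everything is generated in code;
# oracles are deliberately naive (brute force) and independent of the
# implementation paths they check.

# small, fast phantom spec for module tests; overrides replace defaults
small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_structures = 6L, grid_shape = c(40L, 96L, 96L),
         semi_axis_range = c(5, 9)),
    list(...)
  )
  do.call(phantom_spec, args)
}

# solid rasterized ellipsoid mask in its own little grid
ellipsoid_mask <- function(semi_axes, grid = NULL, orientation = diag(3)) {
  if (is.null(grid)) grid <- rep(2L * ceiling(max(semi_axes)) + 9L, 3L)
  center <- (grid + 1) / 2
  co <- rasterize_ellipsoid(center, semi_axes, orientation, grid)
  m <- array(FALSE, grid)
  m[co] <- TRUE
  m
}

# axis-angle rotation matrix (independent of the package's internal helper)
rot3 <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# oracle: plain-R flood-fill connected-component count (26- or 6-conn)
oracle_component_count <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  nlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- cc + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nlab
          queue <- c(queue, (p[1]) + d[1] * ((p[2] - 1L) + d[2] * (p[3] - 1L)))
        }
      }
    }
  }
  nlab
}

# oracle: exhaustive between-class-variance scan for a threshold, on the
# raw values (256 candidate cuts between min and max)
oracle_otsu <- function(v) {
  v <- as.numeric(v)
  cuts <- seq(min(v), max(v), length.out = 258)[2:257]
  bcv <- vapply(cuts, function(t) {
    w1 <- mean(v <= t)
    if (w1 == 0 || w1 == 1) return(-Inf)
    (w1 * (1 - w1)) * (mean(v[v <= t]) - mean(v[v > t]))^2
  }, 0)
  cuts[which.max(bcv)]
}

# oracle: brute-force two-sided Wilcoxon p by enumerating group labelings
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  combs <- utils::combn(length(r), n)
  Ws <- apply(combs, 2, function(i) sum(r[i]))
  W <- sum(r[seq_len(n)])
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# per-stack means of one parameter, split by condition
stack_means <- function(study, parameter, conditions) {
  sub <- study[study$condition %in% conditions, ]
  agg <- tapply(as.numeric(sub[[parameter]]),
                list(sub$condition, sub$stack_id), mean)
  lapply(conditions, function(cn) as.numeric(stats::na.omit(agg[cn, ])))
}
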