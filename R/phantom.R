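#' Phantom specification
#'
#' Describes a computer-generated validation stack: a population of randomly
#' placed, randomly oriented, randomly sized solid ellipsoids (mimicking
#' epithelial structures), each optionally hollowed by a smaller concentric
#' ellipsoidal lumen.  Four named conditions ([phantom_condition_spec()])
#' reproduce the validation design: a reference population (C1), a population
#' elongated along one body axis (C2), a population where only half the
#' structures carry a lumen (C3), and a population of perpendicular ellipsoid
#' pairs (C4).
#'
#' Defaults: 40 structures on a 64 x 256 x 256 voxel grid with unit spacing;
#' semi-axes uniform in \[6, 12\] voxels; foreground (shell) intensity 200 and
#' background 20 on an 8-bit-like scale; lumen semi-axes a single uniform
#' fraction in \[0.35, 0.6\] of the parent's semi-axes, so lumena are strictly
#' interior.  Stacks are clean by default; imaging artifacts (Gaussian noise,
#' per-slice depth decay) are opt-in via `noise_sd` / `depth_decay` so the
#' preprocessing stages can be exercised.
#'
#' @param n_structures number of structures per stack (> 0).
#' @param grid_shape integer length-3 voxel grid `(z, y, x)`.
#' @param semi_axis_range length-2 positive interval (voxels) each principal
#'   semi-axis is drawn from.
#' @param axis_elongation_factor multiplier applied to the sampling maximum of
#'   the first (designated) semi-axis; 2 gives the elongated condition.
#' @param lumen_probability probability in `[0, 1]` that a structure carries
#'   a lumen.
#' @param lumen_radius_fraction_range length-2 interval inside `(0, 1)`; one
#'   fraction per lumen scales all three parent semi-axes.
#' @param perpendicular_pair if `TRUE` each structure is the union of two
#'   perpendicular duct-like ellipsoids: each part's designated (long)
#'   semi-axis is drawn from the widened interval (factor
#'   `max(2, axis_elongation_factor)`), the second part is rotated 90
#'   degrees about a random axis orthogonal to the first's designated
#'   direction, and it is centred at the tip of the first's designated
#'   semi-axis, forming a T junction of crossing ducts.
#' @param clearance minimum empty-voxel gap enforced between structures by
#'   rejection sampling.  Count recovery presumes separable structures: the
#'   default of 4 voxels keeps neighbours separated through the pipeline's
#'   radius-2 median (a 5-cube box that can bridge narrower gaps seen from
#'   both sides) and the 1-voxel Gaussian blur.
#' @param n_stacks stacks per condition (used by study-level helpers).
#' @param foreground,background mean shell / background intensities.
#' @param noise_sd additive Gaussian noise SD (0 = clean).
#' @param depth_decay per-slice multiplicative luminosity decay in `(0, 1]`
#'   (1 = none).
#' @param seed optional integer seed recorded in the spec.
#' @return a `phantom_spec` list.
#' @seealso [phantom_condition_spec()], [generate_stack()]
#' @export
phantom_spec <- function(n_structures = 40L,
                         grid_shape = c(64L, 256L, 256L),
                         semi_axis_range = c(6, 12),
                         axis_elongation_factor = 1,
                         lumen_probability = 1,
                         lumen_radius_fraction_range = c(0.35, 0.6),
                         perpendicular_pair = FALSE,
                         clearance = 4L,
                         n_stacks = 6L,
                         foreground = 200,
                         background = 20,
                         noise_sd = 0,
                         depth_decay = 1,
                         seed = NULL) {
  spec <- list(
    n_structures = as.integer(n_structures),
    grid_shape = as.integer(grid_shape),
    semi_axis_range = as.numeric(semi_axis_range),
    axis_elongation_factor = as.numeric(axis_elongation_factor),
    lumen_probability = as.numeric(lumen_probability),
    lumen_radius_fraction_range = as.numeric(lumen_radius_fraction_range),
    perpendicular_pair = isTRUE(perpendicular_pair),
    clearance = as.integer(clearance),
    n_stacks = as.integer(n_stacks),
    foreground = as.numeric(foreground),
    background = as.numeric(background),
    noise_sd = as.numeric(noise_sd),
    depth_decay = as.numeric(depth_decay),
    seed = seed
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_structures <= 0L) stop("n_structures must be > 0", call. = FALSE)
    if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
      stop("grid_shape must be three voxel counts of at least 8", call. = FALSE)
    }
    if (length(semi_axis_range) != 2L || any(semi_axis_range <= 0) ||
        diff(semi_axis_range) < 0) {
      stop("semi_axis_range must be a positive, non-decreasing interval",
           call. = FALSE)
    }
    if (axis_elongation_factor < 1) {
      stop("axis_elongation_factor must be >= 1", call. = FALSE)
    }
    if (lumen_probability < 0 || lumen_probability > 1) {
      stop("lumen_probability must lie in [0, 1]", call. = FALSE)
    }
    if (length(lumen_radius_fraction_range) != 2L ||
        min(lumen_radius_fraction_range) <= 0 ||
        max(lumen_radius_fraction_range) >= 1 ||
        diff(lumen_radius_fraction_range) < 0) {
      stop("lumen_radius_fraction_range must lie strictly inside (0, 1)",
           call. = FALSE)
    }
    if (clearance < 0L) stop("clearance must be >= 0", call. = FALSE)
    if (n_stacks <= 0L) stop("n_stacks must be > 0", call. = FALSE)
    if (foreground <= background) {
      stop("foreground intensity must exceed background", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (depth_decay <= 0 || depth_decay > 1) {
      stop("depth_decay must lie in (0, 1]", call. = FALSE)
    }
  })
  structure(spec, class = "phantom_spec")
}

#' Named validation conditions
#'
#' Builds the [phantom_spec()] for one of the four validation conditions:
#' * `C1` — reference: 40 ellipsoids, isotropic size distribution, every
#'   structure carries a lumen;
#' * `C2` — as C1 but the sampling maximum of the designated semi-axis is
#'   doubled (more elongated structures);
#' * `C3` — as C1 but each structure has only a 50% chance of a lumen;
#' * `C4` — as C1 but each structure is a perpendicular T-junction pair of
#'   duct-like ellipsoids (more complex, branched shapes).
#'
#' @param condition one of `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @param ... named [phantom_spec()] fields overriding the condition defaults.
#' @return a `phantom_spec`.
#' @examples
#' phantom_condition_spec("C3")$lumen_probability
#' @export
phantom_condition_spec <- function(condition = c("C1", "C2", "C3", "C4"),
                                   ...) {
  condition <- match.arg(condition)
  args <- switch(condition,
    C1 = list(),
    C2 = list(axis_elongation_factor = 2),
    C3 = list(lumen_probability = 0.5),
    C4 = list(perpendicular_pair = TRUE)
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(phantom_spec, args)
}

# uniform random rotation matrix (via a uniform unit quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# rotation by `angle` about unit axis `u` (Rodrigues)
rotation_about <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rasterize an ellipsoid onto a voxel grid
#'
#' A voxel belongs to the ellipsoid when its centre satisfies the rotated
#' ellipsoid inequality `sum((R^T (v - c) / s)^2) <= 1`; the result is clipped
#' at the grid bounds.
#'
#' @param center numeric length-3 centre `(z, y, x)` in voxel coordinates
#'   (1-based), inside the grid.
#' @param semi_axes numeric length-3 strictly positive semi-axes (voxels).
#' @param orientation 3x3 rotation matrix; columns are the ellipsoid's
#'   principal directions in grid coordinates.
#' @param grid_shape integer length-3 grid dimensions `(z, y, x)`.
#' @return integer matrix of included voxel coordinates, one row per voxel,
#'   columns `(z, y, x)`, 1-based.
#' @examples
#' nrow(rasterize_ellipsoid(c(16, 16, 16), c(10, 10, 10), diag(3),
#'                          c(32, 32, 32))) # ~ 4/3 pi 10^3
#' @export
rasterize_ellipsoid <- function(center, semi_axes, orientation = diag(3),
                                grid_shape) {
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  grid_shape <- as.integer(grid_shape)
  if (length(center) != 3L || length(semi_axes) != 3L) {
    stop("center and semi_axes must have length 3", call. = FALSE)
  }
  if (any(semi_axes <= 0)) {
    stop("semi-axes must be strictly positive", call. = FALSE)
  }
  if (any(center < 1) || any(center > grid_shape)) {
    stop("center must lie inside the grid", call. = FALSE)
  }
  r <- max(semi_axes)
  lo <- pmax(1, floor(center - r))
  hi <- pmin(grid_shape, ceiling(center + r))
  pts <- as.matrix(expand.grid(
    z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3],
    KEEP.OUT.ATTRS = FALSE
  ))
  d <- sweep(pts, 2, center)
  b <- d %*% orientation  # body-frame coordinates
  q <- (b[, 1] / semi_axes[1])^2 + (b[, 2] / semi_axes[2])^2 +
    (b[, 3] / semi_axes[3])^2
  m <- pts[q <= 1, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

coords_to_index <- function(coords, dim) {
  (coords[, 1]) + dim[1] * ((coords[, 2] - 1L) + dim[2] * (coords[, 3] - 1L))
}

#' Generate one phantom stack with ground truth
#'
#' Places `spec$n_structures` non-overlapping structures by rejection
#' sampling, enforcing a clearance of at least 2 voxels between structures so
#' the generated count is recoverable by segmentation.  Each structure draws
#' its lumen with `spec$lumen_probability`; lumen voxels are set to the
#' background intensity (a dark hole), shell voxels to the foreground
#' intensity.  Fully reproducible from `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (defaults to `spec$seed`); `NULL` uses the
#'   current RNG state.
#' @return a `phantom_stack` list: `stack` ([image_stack()]),
#'   `structure_labels` and `lumen_labels` (integer label arrays of the filled
#'   structures and of the cavities), and `truth`, a tibble with one row per
#'   structure (label, centre, first-part semi-axes sorted long/middle/short,
#'   part count, lumen presence and voxel counts).
#' @export
generate_stack <- function(spec, seed = spec$seed) {
  spec <- validate_phantom_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  dims <- spec$grid_shape
  vol <- array(spec$background, dims)
  slab <- array(0L, dims)
  lumen_lab <- array(0L, dims)
  forbidden <- array(FALSE, dims)

  rows <- vector("list", spec$n_structures)
  n_lumena <- 0L
  max_tries <- 300L

  for (k in seq_len(spec$n_structures)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      parts <- sample_parts(spec)
      # exact per-axis extent of the union: |offset_k| plus the rotated
      # ellipsoid's half-extent along axis k
      margin <- apply(vapply(parts, function(p) {
        abs(p$offset) +
          sqrt(colSums((p$semi_axes * t(p$orientation))^2))
      }, numeric(3)), 1, max) + 1
      lo <- 1 + margin
      hi <- dims - margin
      if (any(hi <= lo)) {
        if (try == max_tries) {
          stop("structures do not fit: use a larger grid or smaller semi-axes",
               call. = FALSE)
        }
        next  # this orientation/size draw cannot fit; redraw
      }
      center <- lo + runif(3) * (hi - lo)
      coords <- do.call(rbind, lapply(parts, function(p) {
        rasterize_ellipsoid(center + p$offset, p$semi_axes, p$orientation,
                            dims)
      }))
      coords <- unique(coords)
      idx <- coords_to_index(coords, dims)
      if (!any(forbidden[idx])) {
        forbidden <- cpp_mark_dilated(forbidden, dims, coords,
                                      spec$clearance)
        vol[idx] <- spec$foreground
        slab[idx] <- k
        has_lumen <- runif(1) < spec$lumen_probability
        lumen_voxels <- 0L
        lumen_fraction <- NA_real_
        if (has_lumen) {
          lumen_fraction <- runif(1, spec$lumen_radius_fraction_range[1],
                                  spec$lumen_radius_fraction_range[2])
          lc <- rasterize_ellipsoid(center,
                                    lumen_fraction * parts[[1]]$semi_axes,
                                    parts[[1]]$orientation, dims)
          li <- coords_to_index(lc, dims)
          n_lumena <- n_lumena + 1L
          vol[li] <- spec$background
          lumen_lab[li] <- n_lumena
          lumen_voxels <- length(li)
        }
        ax <- sort(parts[[1]]$semi_axes, decreasing = TRUE)
        rows[[k]] <- tibble::tibble(
          label = k,
          center_z = center[1], center_y = center[2], center_x = center[3],
          axis_long = ax[1], axis_middle = ax[2], axis_short = ax[3],
          n_parts = length(parts),
          n_voxels = length(idx),
          has_lumen = has_lumen,
          lumen_label = if (has_lumen) n_lumena else NA_integer_,
          lumen_fraction = lumen_fraction,
          lumen_voxels = lumen_voxels
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "could not place structure %d after %d tries; use a larger grid or fewer/smaller structures",
        k, max_tries
      ), call. = FALSE)
    }
  }

  stack <- image_stack(vol, spacing = c(1, 1, 1), bit_depth = 16L)
  if (spec$noise_sd > 0 || spec$depth_decay < 1) {
    stack <- apply_artifacts(stack, spec$noise_sd, spec$depth_decay)
  }
  structure(
    list(
      stack = stack,
      structure_labels = slab,
      lumen_labels = lumen_lab,
      truth = dplyr::bind_rows(rows),
      spec = spec
    ),
    class = "phantom_stack"
  )
}

# sample the ellipsoid part(s) of one structure; each part carries a centre
# offset relative to the structure centre (zero for single ellipsoids)
sample_parts <- function(spec) {
  lohi <- spec$semi_axis_range
  axes <- runif(3, lohi[1], lohi[2])
  if (spec$axis_elongation_factor > 1) {
    # designated (first) body axis drawn from a widened interval
    axes[1] <- runif(1, lohi[1], lohi[2] * spec$axis_elongation_factor)
  }
  rot <- random_rotation()
  if (spec$perpendicular_pair) {
    # the paired condition crosses two duct-like ellipsoids: each part's
    # designated (long) axis is drawn from the widened interval also used
    # by the elongated condition, because "positioned perpendicularly"
    # refers to the ducts' axes and near-spherical parts simply merge into
    # a rounder blob with no measurable extra complexity
    duct <- max(2, spec$axis_elongation_factor)
    axes[1] <- runif(1, lohi[1], lohi[2] * duct)
    axes2 <- c(runif(1, lohi[1], lohi[2] * duct), runif(2, lohi[1], lohi[2]))
    # the second duct is perpendicular to the first: its orientation is the
    # first's rotated 90 degrees about a random axis orthogonal to the
    # designated direction, and it is centred at the tip of the first's
    # designated semi-axis, forming a T junction (a concentric union is
    # merely a rounder blob and carries no extra complexity)
    a1 <- rot[, 1]
    v <- rnorm(3)
    v <- v - sum(v * a1) * a1
    while (sqrt(sum(v^2)) < 1e-8) {
      v <- rnorm(3)
      v <- v - sum(v * a1) * a1
    }
    rot2 <- rotation_about(v, pi / 2) %*% rot
    return(list(
      list(semi_axes = axes, orientation = rot, offset = c(0, 0, 0)),
      list(semi_axes = axes2, orientation = rot2, offset = axes[1] * a1)
    ))
  }
  list(list(semi_axes = axes, orientation = rot, offset = c(0, 0, 0)))
}

#' Apply imaging artifacts to a stack
#'
#' Emulates depth-dependent luminosity loss and detector noise: slice `i`
#' (0-based) is multiplied by `depth_decay^i`, then independent Gaussian
#' noise of standard deviation `noise_sd` is added, and the result is clipped
#' to the stack's declared intensity range.
#'
#' @param stack an [image_stack()].
#' @param noise_sd Gaussian noise SD, `>= 0`.
#' @param depth_decay per-slice decay in `(0, 1]`.
#' @return the degraded `image_stack`.
#' @export
apply_artifacts <- function(stack, noise_sd = 0, depth_decay = 1) {
  stack <- as_image_stack(stack)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (depth_decay <= 0 || depth_decay > 1) {
    stop("depth_decay must lie in (0, 1]", call. = FALSE)
  }
  d <- dim(stack$data)
  out <- stack$data * depth_decay^(rep(seq_len(d[1]), times = d[2] * d[3]) - 1)
  if (noise_sd > 0) out <- out + rnorm(length(out), sd = noise_sd)
  dim(out) <- d
  restack(stack, clamp(out, 0, intensity_max(stack)))
}

#' Generate a multi-condition phantom study in memory
#'
#' Convenience wrapper used for small studies and tests: generates
#' `n_stacks` stacks for each condition from a single seed and returns them
#' with a manifest mapping stack ids to condition and replicate.  Large
#' studies are better run with [run_validation_study()], which processes each
#' stack as it is generated instead of holding them all.
#'
#' @param conditions character vector of condition names.
#' @param n_stacks stacks per condition.
#' @param seed integer seed for the whole study.
#' @param ... [phantom_spec()] overrides applied to every condition.
#' @return list with `stacks` (named list of `phantom_stack`) and `manifest`
#'   (tibble: stack_id, condition, replicate).
#' @export
generate_phantom_study <- function(conditions = c("C1", "C2", "C3", "C4"),
                                   n_stacks = 6L, seed = 1L, ...) {
  set.seed(seed)
  stacks <- list()
  manifest <- list()
  for (cond in conditions) {
    spec <- phantom_condition_spec(cond, ...)
    for (s in seq_len(n_stacks)) {
      id <- sprintf("%s_%d", cond, s)
      stacks[[id]] <- generate_stack(spec, seed = NULL)
      manifest[[id]] <- tibble::tibble(
        stack_id = id, condition = cond, replicate = sprintf("r%d", s)
      )
    }
  }
  list(stacks = stacks, manifest = dplyr::bind_rows(manifest))
}

#' Write a phantom study to disk
#'
#' Writes, per stack, the 16-bit intensity TIFF plus ground-truth label TIFFs
#' for structures and lumena, and a CSV manifest with one row per generated
#' structure (stack id, condition, replicate and the truth columns of
#' [generate_stack()]).
#'
#' @param dir output directory (created if missing).
#' @param conditions,n_stacks,seed,... as in [generate_phantom_study()].
#' @return invisibly, the manifest tibble.
#' @export
write_phantom_study <- function(dir, conditions = c("C1", "C2", "C3", "C4"),
                                n_stacks = 6L, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  manifest <- list()
  for (cond in conditions) {
    spec <- phantom_condition_spec(cond, ...)
    for (s in seq_len(n_stacks)) {
      id <- sprintf("%s_%d", cond, s)
      ps <- generate_stack(spec, seed = NULL)
      write_stack(ps$stack, file.path(dir, paste0(id, ".tif")))
      write_labels(ps$structure_labels,
                   file.path(dir, paste0(id, "_structures.tif")))
      write_labels(ps$lumen_labels, file.path(dir, paste0(id, "_lumena.tif")))
      manifest[[id]] <- dplyr::mutate(
        ps$truth, stack_id = id, condition = cond,
        replicate = sprintf("r%d", s), .before = 1
      )
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
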