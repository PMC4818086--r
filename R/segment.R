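#' Otsu threshold of a volume
#'
#' Exhaustively maximises the between-class variance over a 256-bin
#' histogram of the intensity range.
#'
#' @param x numeric vector, array or [image_stack()].
#' @return the threshold intensity (a bin edge).
#' @export
otsu_threshold <- function(x) {
  if (inherits(x, "image_stack")) x <- x$data
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - lo) / (hi - lo) * nb)), nbins = nb)
  p <- h / sum(h)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  bcv <- (mu_t * w - mu)^2 / (w * (1 - w))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-nb])
  lo + k * (hi - lo) / nb  # upper edge of the optimal bin
}

#' Threshold a stack
#'
#' A voxel is foreground when its intensity is strictly above the threshold.
#' With `threshold = "otsu"` the threshold is chosen automatically by
#' [otsu_threshold()]; the value actually applied is recorded in the
#' `"threshold"` attribute of the result.  An empty foreground is a warning,
#' not an error.
#'
#' @param stack an [image_stack()] (or numeric 3D array).
#' @param threshold numeric intensity within the stack's range, or `"otsu"`.
#' @return logical array with attribute `"threshold"`.
#' @export
binarize <- function(stack, threshold = "otsu") {
  stack <- as_image_stack(stack)
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(stack)
  } else {
    threshold <- as.numeric(threshold)
    rng <- range(stack$data)
    if (threshold < rng[1] - 1e-9 || threshold > rng[2] + 1e-9) {
      stop(sprintf("threshold %g outside the intensity range [%g, %g]",
                   threshold, rng[1], rng[2]), call. = FALSE)
    }
  }
  out <- stack$data > threshold
  if (!any(out)) warning("empty foreground after thresholding")
  structure(out, threshold = threshold)
}

#' Label 3D connected components
#'
#' Labels the 26-connected foreground components of a binary volume,
#' removes components smaller than `min_voxels` (specks that cannot be
#' measured reliably), and renumbers the survivors `1..K` by decreasing
#' voxel count.
#'
#' @param mask binary 3D array.
#' @param min_voxels minimum component size kept (default 64, roughly
#'   structures at least 4 voxels across).
#' @param spacing voxel spacing carried to the measurements.
#' @param connectivity 26 (default) or 6.
#' @return a `label_volume`: integer array with attributes `spacing` and
#'   `n_labels`; 0 is background.
#' @export
label_components <- function(mask, min_voxels = 64L, spacing = c(1, 1, 1),
                             connectivity = 26L) {
  m <- as_mask(mask)
  d <- dim(m)
  if (!connectivity %in% c(6L, 26L)) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  lab <- cpp_label_components(as.vector(m), d, as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  out <- integer(length(lab))
  if (length(keep)) {
    remap <- integer(length(sizes))
    remap[keep[order(sizes[keep], decreasing = TRUE)]] <- seq_along(keep)
    pos <- lab > 0L
    out[pos] <- remap[lab[pos]]
  }
  dim(out) <- d
  structure(out, spacing = as.numeric(spacing), n_labels = length(keep),
            class = c("label_volume", class(out)))
}

#' Repair each labeled structure's mask in isolation
#'
#' A structure whose lumen sits close beneath the surface can breach its
#' shell after smoothing and thresholding; the broken hollow shell defeats
#' per-slice hole filling, shrinks the measured volume and turns the
#' skeleton into a mesh of spurious branches.  This step crops each
#' structure, applies a binary closing (a maximum filter followed by a
#' minimum filter, sealing channels narrower than the window) and per-slice
#' hole filling to that structure alone, and merges the repaired voxels
#' back under the structure's label.  Because every structure is repaired
#' in isolation, neighbouring structures can never be bridged and the
#' component count is untouched.
#'
#' @param labels a [label_components()] result.
#' @param close_radius box half-width of the closing; 0 skips closing and
#'   only re-fills.
#' @return the repaired `label_volume` (same labels, possibly more voxels).
#' @export
solidify_labels <- function(labels, close_radius = 2L) {
  k <- attr(labels, "n_labels") %||% max(labels)
  if (k == 0L) return(labels)
  d <- dim(labels)
  idx <- which(labels > 0L)
  coords <- arrayInd(idx, d)
  ids <- labels[idx]
  pad <- as.integer(close_radius) + 1L
  out <- labels
  for (i in seq_len(k)) {
    cc <- coords[ids == i, , drop = FALSE]
    lo <- pmax(apply(cc, 2, min) - pad, 1L)
    hi <- pmin(apply(cc, 2, max) + pad, d)
    dd <- hi - lo + 1L
    m <- array(FALSE, dd)
    m[(cc[, 1] - lo[1] + 1L) +
        dd[1] * ((cc[, 2] - lo[2]) + dd[2] * (cc[, 3] - lo[3]))] <- TRUE
    rep_m <- m
    if (close_radius > 0) rep_m <- binary_close(rep_m, close_radius)
    rep_m <- fill_holes_2d(rep_m)
    add <- which(rep_m & !m)
    if (length(add)) {
      ac <- arrayInd(add, dd)
      gi <- (ac[, 1] + lo[1] - 1L) +
        d[1] * ((ac[, 2] + lo[2] - 2L) + d[2] * (ac[, 3] + lo[3] - 2L))
      free <- out[gi] == 0L
      out[gi[free]] <- i
    }
  }
  out
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d labeled structure(s)\n",
              d[1], d[2], d[3], attr(x, "n_labels")))
  invisible(x)
}

# surface area of a binary mask by the co-area estimator: the mask is
# smoothed with a 1-voxel Gaussian and the integral of the gradient
# magnitude (physical units) over the volume approximates the boundary
# area -- unlike raw voxel-face counting, this is unbiased enough that a
# rasterized sphere scores sphericity ~ 1
surface_area_mask <- function(coords, spacing) {
  lo <- apply(coords, 2, min) - 4L
  hi <- apply(coords, 2, max) + 4L
  d <- hi - lo + 1L
  m <- array(0, d)
  idx <- (coords[, 1] - lo[1] + 1L) +
    d[1] * ((coords[, 2] - lo[2] + 1L) - 1L +
              d[2] * ((coords[, 3] - lo[3] + 1L) - 1L))
  m[idx] <- 1
  k <- gaussian_kernel(1)
  sm <- cpp_convolve_sep(as.vector(m), d, k, k, k)
  dim(sm) <- d
  gz <- (sm[c(2:d[1], d[1]), , ] - sm[c(1, 1:(d[1] - 1)), , ]) /
    (2 * spacing[1])
  gy <- (sm[, c(2:d[2], d[2]), ] - sm[, c(1, 1:(d[2] - 1)), ]) /
    (2 * spacing[2])
  gx <- (sm[, , c(2:d[3], d[3])] - sm[, , c(1, 1:(d[3] - 1))]) /
    (2 * spacing[3])
  # one-sided differences at the crop border (the pad keeps the surface away)
  sum(sqrt(gz^2 + gy^2 + gx^2)) * prod(spacing)
}

measure_one <- function(coords, spacing, label_id) {
  n <- nrow(coords)
  if (n < 4L) {
    stop(sprintf(
      "label %d has %d voxel(s); at least 4 are needed for moments",
      label_id, n
    ), call. = FALSE)
  }
  voxvol <- prod(spacing)
  phys <- sweep(coords, 2, spacing, `*`)
  centroid <- colMeans(phys)
  cc <- sweep(phys, 2, centroid)
  cov <- crossprod(cc) / n
  # half-voxel correction: voxel centres under-disperse a solid body by the
  # within-voxel variance spacing^2 / 12 per axis
  cov <- cov + diag(spacing^2 / 12)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  semi <- sqrt(5 * pmax(ev, 0))  # moment-matched ellipsoid semi-axes
  volume <- n * voxvol
  area <- surface_area_mask(coords, spacing)
  sphericity <- (36 * pi * volume^2 / area^3)^(1 / 3)
  ell_vol <- 4 / 3 * pi * prod(semi)
  tibble::tibble(
    label = label_id,
    n_voxels = n,
    volume = volume,
    surface_area = area,
    centroid_z = centroid[1] / spacing[1],
    centroid_y = centroid[2] / spacing[2],
    centroid_x = centroid[3] / spacing[3],
    axis_long = semi[1],
    axis_middle = semi[2],
    axis_short = semi[3],
    elon1 = semi[1] / semi[2],
    elon2 = semi[2] / semi[3],
    sphericity = sphericity,
    ellipsoid_volume = ell_vol,
    rve = volume / ell_vol
  )
}

#' Measure every labeled structure
#'
#' Computes, per structure: physical volume (voxel count times voxel
#' volume); principal semi-axis lengths from the eigen-decomposition of the
#' spacing-aware second-moment matrix of its voxel centres
#' (`semi_axis = sqrt(5 * lambda)`, the moment-matched solid ellipsoid, with
#' a half-voxel discretization correction); elongation `Elon1 = long/middle`
#' and flatness `Elon2 = middle/short`; surface area (smoothed-gradient
#' co-area estimator); sphericity `S = ((36 pi V^2) / A^3)^(1/3)`; the
#' moment-fitted ellipsoid volume `4/3 pi L M S`; and the ratio volume
#' ellipsoid `RVE = V / V_ellipsoid` (1 for a perfect ellipsoid, towards 0
#' for branched structures).  Centroids are reported in 0-based voxel
#' coordinates `(z, y, x)`.
#'
#' Measurements run on the hole-filled mask, so `volume` includes the lumen
#' cavity.
#'
#' @param labels a [label_components()] result.
#' @param spacing voxel spacing (defaults to the label volume's).
#' @return a tibble with one row per structure.
#' @export
measure_structures <- function(labels, spacing = attr(labels, "spacing")) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  k <- max(0L, attr(labels, "n_labels") %||% max(labels))
  if (k == 0L) return(measure_one_empty())
  idx <- which(labels > 0L)
  coords <- arrayInd(idx, dim(labels))
  ids <- labels[idx]
  out <- lapply(seq_len(k), function(i) {
    measure_one(coords[ids == i, , drop = FALSE], spacing, i)
  })
  out <- dplyr::bind_rows(out)
  out$centroid_z <- out$centroid_z - 1
  out$centroid_y <- out$centroid_y - 1
  out$centroid_x <- out$centroid_x - 1
  out
}

measure_one_empty <- function() {
  tibble::tibble(
    label = integer(), n_voxels = integer(), volume = numeric(),
    surface_area = numeric(), centroid_z = numeric(), centroid_y = numeric(),
    centroid_x = numeric(), axis_long = numeric(), axis_middle = numeric(),
    axis_short = numeric(), elon1 = numeric(), elon2 = numeric(),
    sphericity = numeric(), ellipsoid_volume = numeric(), rve = numeric()
  )
}

#' Measure a single structure
#'
#' @param labels a [label_components()] result.
#' @param label_id the structure label to measure.
#' @param spacing voxel spacing.
#' @return a one-row tibble (see [measure_structures()]).
#' @export
measure_structure <- function(labels, label_id,
                              spacing = attr(labels, "spacing")) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  idx <- which(labels == label_id)
  if (length(idx) == 0L) {
    stop(sprintf("label %s does not exist", label_id), call. = FALSE)
  }
  out <- measure_one(arrayInd(idx, dim(labels)), spacing, label_id)
  out$centroid_z <- out$centroid_z - 1
  out$centroid_y <- out$centroid_y - 1
  out$centroid_x <- out$centroid_x - 1
  out
}

#' Structure quality
#'
#' `Q = Elon1 - Elon2 + 5 * RLV`.  Positive values indicate elongated,
#' lumen-bearing ("normal") structures; negative values indicate flat
#' structures (`Elon2 > Elon1`).
#'
#' @param elon1 elongation (long/middle axis ratio), `>= 1`.
#' @param elon2 flatness (middle/short axis ratio), `>= 1`.
#' @param rlv relative lumen volume in `[0, 1)`.
#' @return numeric quality score (vectorised).
#' @export
quality <- function(elon1, elon2, rlv) {
  elon1 - elon2 + 5 * rlv
}

`%||%` <- function(a, b) if (is.null(a)) b else a
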