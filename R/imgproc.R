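#' Remove the local slice background
#'
#' Estimates a per-slice local background by grayscale opening (a minimum
#' filter followed by a maximum filter with the same large window) and
#' subtracts it, clamping at zero.  Objects narrower than the window are
#' removed from the background estimate and therefore survive subtraction;
#' the window must be wider than the largest structure cross-section.
#'
#' @param stack an [image_stack()].
#' @param radius window half-width in voxels (window = `2 * radius + 1`);
#'   must be at least 1 and smaller than the slice.
#' @return the background-subtracted `image_stack`.
#' @export
subtract_background <- function(stack, radius = 25L) {
  stack <- as_image_stack(stack)
  d <- dim(stack$data)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1 voxel", call. = FALSE)
  if (2L * radius + 1L > min(d[2], d[3])) {
    stop("background radius larger than the slice", call. = FALSE)
  }
  r2d <- c(0L, radius, radius)  # per-slice (no z extent)
  bg <- cpp_rank_filter(as.vector(stack$data), d, r2d, 0L)  # minimum
  bg <- cpp_rank_filter(bg, d, r2d, 1L)                     # then maximum
  out <- pmax(as.vector(stack$data) - bg, 0)
  dim(out) <- d
  restack(stack, out)
}

#' 3D rank filters
#'
#' Replaces each voxel by an order statistic (median, minimum, maximum) or
#' the variance over its cubic box neighbourhood of half-width `radius`.
#' Edges are handled by mirror reflection.  The box (rather than ball)
#' neighbourhood is a documented choice: it is separable for min/max and
#' marginally different from a ball for the small radii used here.
#'
#' @param stack an [image_stack()].
#' @param kind one of `"median"`, `"minimum"`, `"maximum"`, `"variance"`.
#' @param radius box half-width in voxels, `>= 1`.
#' @return the filtered `image_stack`.
#' @export
rank_filter_3d <- function(stack, kind = c("median", "minimum", "maximum",
                                           "variance"), radius = 1L) {
  stack <- as_image_stack(stack)
  kind <- match.arg(kind)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1 voxel", call. = FALSE)
  code <- c(minimum = 0L, maximum = 1L, median = 2L, variance = 3L)[[kind]]
  d <- dim(stack$data)
  out <- cpp_rank_filter(as.vector(stack$data), d, rep(radius, 3L), code)
  dim(out) <- d
  restack(stack, out)
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' 3D Gaussian blur
#'
#' Separable Gaussian convolution smoothing the structure surfaces by
#' normalising each voxel against its neighbourhood.  `sigma` is given in
#' physical units and converted per axis through the voxel spacing, so
#' anisotropic stacks are smoothed isotropically in physical space.
#'
#' @param stack an [image_stack()].
#' @param sigma Gaussian SD in physical units; scalar or length-3
#'   `(z, y, x)`.  `sigma = 0` is the identity.
#' @return the blurred `image_stack`.
#' @export
gaussian_blur_3d <- function(stack, sigma = 1) {
  stack <- as_image_stack(stack)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  sigma <- rep(as.numeric(sigma), length.out = 3L)
  if (all(sigma == 0)) return(stack)
  sv <- sigma / stack$spacing
  d <- dim(stack$data)
  out <- cpp_convolve_sep(as.vector(stack$data), d,
                          gaussian_kernel(sv[1]), gaussian_kernel(sv[2]),
                          gaussian_kernel(sv[3]))
  dim(out) <- d
  restack(stack, out)
}

#' Compensate depth-dependent luminosity loss
#'
#' Slices farther from the objective are dimmer.  For slice `i` the robust
#' slice maximum `m_i` (by default the 99.9th percentile, resistant to hot
#' pixels; set `probs = 1` for the exact maximum) is smoothed by a running
#' mean over the window `{i - 1, i, i + 1}` (truncated at the stack ends)
#' giving `r_i`; each slice is then scaled by `gain_i = R / r_i`, where `R`
#' is the largest `r_i`, and clipped to the declared intensity range.  Gains
#' are capped (default 10x) so near-empty slices are not amplified into pure
#' noise; a capped or degenerate slice triggers a warning.
#'
#' @param stack an [image_stack()].
#' @param probs quantile used as the robust slice maximum.
#' @param gain_cap maximum allowed per-slice gain.
#' @return the compensated `image_stack`, with the per-slice gains attached
#'   as attribute `"gains"`.
#' @export
compensate_depth <- function(stack, probs = 0.999, gain_cap = 10) {
  stack <- as_image_stack(stack)
  d <- dim(stack$data)
  nz <- d[1]
  m <- vapply(seq_len(nz), function(i) {
    quantile(stack$data[i, , ], probs = probs, names = FALSE)
  }, 0)
  r <- vapply(seq_len(nz), function(i) {
    w <- max(1L, i - 1L):min(nz, i + 1L)
    mean(m[w])
  }, 0)
  R <- max(r)
  if (R <= 0) {
    warning("stack has no signal; depth compensation left it unchanged")
    return(structure(stack, gains = rep(1, nz)))
  }
  gains <- ifelse(r > 0, R / r, Inf)
  if (any(gains > gain_cap)) {
    warning(sprintf("%d slice gain(s) capped at %gx (near-empty slices)",
                    sum(gains > gain_cap), gain_cap))
    gains <- pmin(gains, gain_cap)
  }
  out <- stack$data * gains[rep(seq_len(nz), times = d[2] * d[3])]
  dim(out) <- d
  out <- clamp(out, 0, intensity_max(stack))
  structure(restack(stack, out), gains = gains)
}

#' Fill holes slice by slice
#'
#' Per-slice (2D) hole filling: any background region of a slice not
#' connected to the slice border becomes foreground.  Used to fill the lumen
#' cavity before morphometric measurement so the lumen does not interfere
#' with shape and volume, and to delimit the region cavities are searched in.
#' Idempotent.
#'
#' @param mask binary 3D array `(z, y, x)` (logical or 0/1).
#' @return logical array of the same shape.
#' @export
fill_holes_2d <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  # EBImage fills per frame; frames run along the 3rd dimension
  perm <- aperm(m, c(2, 3, 1)) * 1
  filled <- EBImage::fillHull(EBImage::Image(perm))
  out <- aperm(as.array(filled) > 0.5, c(3, 1, 2))
  dim(out) <- d
  out
}

# binary morphological closing: 3D maximum then minimum filter (box radius
# r); seals dark gaps narrower than the window without moving surfaces at
# larger scales
binary_close <- function(mask, radius = 2L) {
  m <- as_mask(mask)
  d <- dim(m)
  v <- cpp_rank_filter(as.numeric(m), d, rep(as.integer(radius), 3L), 1L)
  v <- cpp_rank_filter(v, d, rep(as.integer(radius), 3L), 0L)
  out <- v > 0.5
  dim(out) <- d
  out
}

# 3D hole filling: background 6-components not touching the volume border
fill_holes_3d <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  bg <- cpp_label_components(as.vector(!m), d, 6L)
  dim(bg) <- d
  border <- unique(c(
    bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]
  ))
  border <- border[border > 0]
  out <- m | !(bg %in% c(0L, border))
  dim(out) <- d
  out
}

#' Separate touching structures with a morphological gradient
#'
#' Computes the 3D morphological gradient (maximum filter minus minimum
#' filter, radius 1), which demarcates structure edges, and subtracts it from
#' the image, clamping at zero.  Thin bright necks between conjoined
#' structures sit entirely on an edge and are removed, so a subsequent
#' threshold separates the structures; interior voxels at least 2 voxels from
#' a boundary are unchanged.  Optional: only needed for crowded images.
#'
#' @param stack an [image_stack()].
#' @return the edge-suppressed `image_stack`.
#' @export
gradient_separation <- function(stack) {
  stack <- as_image_stack(stack)
  d <- dim(stack$data)
  v <- as.vector(stack$data)
  grad <- cpp_rank_filter(v, d, rep(1L, 3L), 1L) -
    cpp_rank_filter(v, d, rep(1L, 3L), 0L)
  out <- pmax(v - grad, 0)
  dim(out) <- d
  restack(stack, out)
}

#' Tier-1 configuration
#'
#' Stage toggles and parameters for [run_tier1()].  Defaults are the
#' smallest radii that suppress single-voxel noise without eroding the
#' smallest (about 6-voxel) structures.  The lumen branch uses a gentler
#' median (radius 1) than the morphometrics branch (radius 2) so small dark
#' cavities are not filled in by the filter.
#'
#' @param background_radius half-width of the background opening window.
#' @param denoise optional hook, a `function(image_stack) -> image_stack`
#'   run right after background subtraction (e.g. an external wavelet or
#'   bilateral denoiser); `NULL` disables it.
#' @param median_radius morphometrics-branch median radius (0 disables).
#' @param lumen_median_radius lumen-branch median radius (0 disables).
#' @param extra_filters list of `list(kind=, radius=)` rank-filter stages
#'   applied to the morphometrics branch after the median.
#' @param sigma Gaussian blur SD (physical units; 0 disables).
#' @param compensate apply depth-luminosity compensation?
#' @param robust_max_prob,gain_cap passed to [compensate_depth()].
#' @param threshold `"otsu"` or a numeric intensity for [binarize()].
#' @param separate_crowded apply [gradient_separation()] to the
#'   morphometrics branch (for crowded images; off by default).
#' @return a `tier1_config` list.
#' @export
tier1_config <- function(background_radius = 25L,
                         denoise = NULL,
                         median_radius = 2L,
                         lumen_median_radius = 1L,
                         extra_filters = list(),
                         sigma = 1,
                         compensate = TRUE,
                         robust_max_prob = 0.999,
                         gain_cap = 10,
                         threshold = "otsu",
                         separate_crowded = FALSE) {
  if (!is.null(denoise) && !is.function(denoise)) {
    stop("denoise must be NULL or a function(stack) -> stack", call. = FALSE)
  }
  structure(list(
    background_radius = as.integer(background_radius),
    denoise = denoise,
    median_radius = as.integer(median_radius),
    lumen_median_radius = as.integer(lumen_median_radius),
    extra_filters = extra_filters,
    sigma = sigma,
    compensate = isTRUE(compensate),
    robust_max_prob = robust_max_prob,
    gain_cap = gain_cap,
    threshold = threshold,
    separate_crowded = isTRUE(separate_crowded)
  ), class = "tier1_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("tier-1 stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run Tier-1 preprocessing
#'
#' The mandatory, fully automated first tier: background subtraction, an
#' optional denoise hook, rank filtering, Gaussian smoothing and depth
#' compensation, producing two branches from one input.  The morphometrics
#' branch is additionally thresholded and hole-filled (so the lumen cavity
#' does not interfere with shape measurement) yielding the structure mask;
#' the lumen branch keeps its interior darkness so cavities remain
#' segmentable.  Gradient-based separation of touching structures is applied
#' to the morphometrics branch when `config$separate_crowded` is set; in
#' images where crowding is not an issue it can be left out.
#'
#' @param stack an [image_stack()].
#' @param config a [tier1_config()].
#' @return list with `morphometrics` and `lumen` (processed [image_stack()]s),
#'   `mask` (logical hole-filled structure mask) and `threshold` (the value
#'   actually applied).
#' @export
run_tier1 <- function(stack, config = tier1_config()) {
  stack <- as_image_stack(stack)
  stopifnot(inherits(config, "tier1_config"))
  base <- with_stage("subtract_background",
                     subtract_background(stack, config$background_radius))
  if (!is.null(config$denoise)) {
    base <- with_stage("denoise", as_image_stack(config$denoise(base)))
  }

  morpho <- base
  if (config$median_radius > 0) {
    morpho <- with_stage("median",
                         rank_filter_3d(morpho, "median", config$median_radius))
  }
  for (f in config$extra_filters) {
    morpho <- with_stage(paste0("rank_", f$kind),
                         rank_filter_3d(morpho, f$kind, f$radius))
  }
  if (any(config$sigma > 0)) {
    morpho <- with_stage("gaussian_blur",
                         gaussian_blur_3d(morpho, config$sigma))
  }
  if (config$compensate) {
    morpho <- with_stage("compensate_depth", suppressWarnings(
      compensate_depth(morpho, config$robust_max_prob, config$gain_cap)
    ))
  }
  if (config$separate_crowded) {
    morpho <- with_stage("gradient_separation", gradient_separation(morpho))
  }

  lum <- base
  if (config$lumen_median_radius > 0) {
    lum <- with_stage("lumen_median",
                      rank_filter_3d(lum, "median", config$lumen_median_radius))
  }
  if (any(config$sigma > 0)) {
    lum <- with_stage("lumen_blur", gaussian_blur_3d(lum, config$sigma))
  }
  if (config$compensate) {
    lum <- with_stage("lumen_compensate", suppressWarnings(
      compensate_depth(lum, config$robust_max_prob, config$gain_cap)
    ))
  }

  bin <- with_stage("binarize", binarize(morpho, config$threshold))
  mask <- with_stage("fill_holes", fill_holes_2d(bin))
  list(
    morphometrics = morpho,
    lumen = lum,
    mask = mask,
    threshold = attr(bin, "threshold")
  )
}
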