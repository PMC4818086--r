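#' 3D image stacks
#'
#' An `image_stack` is the unit every filter in the package consumes and
#' produces: a non-negative 3D intensity grid stored as an array with
#' dimensions `(z, y, x)` together with the physical voxel spacing
#' `(dz, dy, dx)` (micrometres, or unit for voxel-based work) and the bit
#' depth of the originating file.  Confocal stacks are typically anisotropic
#' (z step larger than the pixel pitch), so the spacing travels with the
#' data and every physical measurement uses it.
#'
#' @param data numeric 3D array, dimensions `(z, y, x)`, non-negative.
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)`, all > 0.
#' @param bit_depth integer, bit depth of the originating image (8 or 16);
#'   defines the intensity range `[0, 2^bit_depth - 1]` filters clip to.
#' @return an `image_stack` object.
#' @examples
#' s <- image_stack(array(0, c(4, 8, 8)))
#' dim(s)
#' @export
image_stack <- function(data, spacing = c(1, 1, 1), bit_depth = 16L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array with dimensions (z, y, x)", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("`data` must be non-empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive numbers (dz, dy, dx)",
         call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  if (anyNA(data) || min(data) < 0) {
    stop("intensities must be non-negative and finite", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' Coerce to an image stack
#'
#' @param x a 3D array or `image_stack`.
#' @param ... passed to [image_stack()] for arrays.
#' @return an `image_stack`.
#' @export
as_image_stack <- function(x, ...) {
  if (inherits(x, "image_stack")) return(x)
  image_stack(x, ...)
}

# rebuild a stack around new voxel data, keeping metadata
restack <- function(stack, data) {
  stack$data <- data
  stack
}

intensity_max <- function(stack) 2^stack$bit_depth - 1

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels (z, y, x), spacing (%g, %g, %g), %d-bit\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$bit_depth
  ))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# shared check for binary (logical or 0/1) volumes
as_mask <- function(x) {
  if (inherits(x, "image_stack")) x <- x$data
  if (is.logical(x)) {
    if (length(dim(x)) != 3L) stop("mask must be a 3D array", call. = FALSE)
    return(x)
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("mask must be a 3D array", call. = FALSE)
  }
  u <- unique(as.vector(x))
  if (!all(u %in% c(0, 1))) {
    stop("mask must be binary (logical or 0/1)", call. = FALSE)
  }
  array(x != 0, dim(x))
}
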