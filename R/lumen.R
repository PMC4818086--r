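#' Segment lumen cavities
#'
#' Lumena appear as regions darker than their surroundings that form a hole
#' inside a structure.  Candidate cavity voxels are the hole-filled
#' structure mask minus the voxels of the lumen-branch image that are above
#' the user threshold; candidates are labeled with 26-connectivity and
#' components below `min_lumen_voxels` are discarded.  The threshold is
#' user-specified (it varies from image to image) or `"otsu"` for the
#' automatic choice on the lumen-branch image.
#'
#' @param structure_mask binary structure mask (filling is applied here, and
#'   is idempotent if the mask is already filled).
#' @param lumen_stack the lumen-branch [image_stack()] from [run_tier1()]
#'   (interior darkness preserved).
#' @param lumen_threshold numeric intensity within range, or `"otsu"`.
#' @param min_lumen_voxels smallest cavity kept (default 27, a 3-voxel cube).
#' @param fill `"slice"` for per-slice (2D) hole filling (parity with the
#'   original per-slice pipeline) or `"3d"` for volumetric filling; they
#'   differ for cavities open at the top or bottom slice.
#' @return a `label_volume` of cavities.
#' @export
segment_lumena <- function(structure_mask, lumen_stack, lumen_threshold = "otsu",
                           min_lumen_voxels = 27L, fill = c("slice", "3d")) {
  fill <- match.arg(fill)
  mask <- as_mask(structure_mask)
  lumen_stack <- as_image_stack(lumen_stack)
  if (!identical(dim(mask), dim(lumen_stack$data))) {
    stop("structure mask and lumen stack must share a grid", call. = FALSE)
  }
  filled <- if (fill == "slice") fill_holes_2d(mask) else fill_holes_3d(mask)
  bright <- binarize(lumen_stack, lumen_threshold)
  candidates <- filled & !bright
  label_components(candidates, min_voxels = min_lumen_voxels,
                   spacing = lumen_stack$spacing)
}

#' Assign lumena to their parent structures
#'
#' Each lumen is assigned to the structure whose (filled) mask contains its
#' centroid; if the centroid voxel is unlabeled the structure with the
#' largest voxel overlap is used.  Lumena overlapping no structure are
#' flagged (`parent = NA`) and excluded from relative-lumen-volume
#' computations downstream.
#'
#' @param lumen_labels a [segment_lumena()] result.
#' @param structure_labels a [label_components()] result on the same grid.
#' @return a tibble with one row per lumen: `lumen`, `parent`, `n_voxels`,
#'   `volume`, centroid coordinates (0-based voxels) and `flagged`.
#' @export
assign_lumena <- function(lumen_labels, structure_labels) {
  if (!identical(dim(lumen_labels), dim(structure_labels))) {
    stop("lumen and structure label volumes must share a grid", call. = FALSE)
  }
  spacing <- attr(lumen_labels, "spacing") %||% c(1, 1, 1)
  k <- attr(lumen_labels, "n_labels") %||% max(lumen_labels)
  if (k == 0L) {
    return(tibble::tibble(
      lumen = integer(), parent = integer(), n_voxels = integer(),
      volume = numeric(), centroid_z = numeric(), centroid_y = numeric(),
      centroid_x = numeric(), flagged = logical()
    ))
  }
  idx <- which(lumen_labels > 0L)
  coords <- arrayInd(idx, dim(lumen_labels))
  ids <- lumen_labels[idx]
  parents <- structure_labels[idx]
  voxvol <- prod(spacing)
  rows <- lapply(seq_len(k), function(i) {
    sel <- ids == i
    cc <- coords[sel, , drop = FALSE]
    centroid <- colMeans(cc)
    cent_vox <- pmin(pmax(round(centroid), 1), dim(structure_labels))
    parent <- structure_labels[cent_vox[1], cent_vox[2], cent_vox[3]]
    if (parent == 0L) {
      ov <- table(parents[sel][parents[sel] > 0L])
      parent <- if (length(ov)) as.integer(names(ov)[which.max(ov)]) else NA_integer_
    }
    tibble::tibble(
      lumen = i,
      parent = ifelse(is.na(parent) || parent == 0L, NA_integer_,
                      as.integer(parent)),
      n_voxels = sum(sel),
      volume = sum(sel) * voxvol,
      centroid_z = centroid[1] - 1,
      centroid_y = centroid[2] - 1,
      centroid_x = centroid[3] - 1
    )
  })
  out <- dplyr::bind_rows(rows)
  out$flagged <- is.na(out$parent)
  if (any(out$flagged)) {
    message(sprintf("%d lumen(a) could not be assigned to a structure",
                    sum(out$flagged)))
  }
  out
}

#' Per-structure and image-level lumen metrics
#'
#' Adds to each structure row: `n_lumena`, the total assigned `lumen_volume`,
#' the relative lumen volume `rlv = lumen_volume / volume` (the cavity as a
#' fraction of the filled structure volume, in `[0, 1)`), the derived
#' inverse ratio `structure_to_lumen_ratio`, the indicator `has_lumen`, and
#' the recomputed `quality`.  The image-level lumen fraction
#' `L = (# structures with >= 1 lumen) / (# structures)` is returned
#' alongside.  Flagged (unassigned) lumena are excluded.
#'
#' @param structures a [measure_structures()] tibble.
#' @param lumena an [assign_lumena()] tibble.
#' @return list with `structures` (augmented tibble) and `lumen_fraction`
#'   (the scalar L).
#' @export
lumen_metrics <- function(structures, lumena) {
  agg <- lumena |>
    dplyr::filter(!.data$flagged) |>
    dplyr::group_by(parent = .data$parent) |>
    dplyr::summarise(
      n_lumena = dplyr::n(),
      lumen_volume = sum(.data$volume),
      .groups = "drop"
    )
  out <- structures |>
    dplyr::left_join(agg, by = c(label = "parent")) |>
    dplyr::mutate(
      n_lumena = dplyr::coalesce(.data$n_lumena, 0L),
      lumen_volume = dplyr::coalesce(.data$lumen_volume, 0),
      rlv = .data$lumen_volume / .data$volume,
      structure_to_lumen_ratio = dplyr::if_else(
        .data$lumen_volume > 0, .data$volume / .data$lumen_volume, NA_real_
      ),
      has_lumen = .data$n_lumena >= 1L,
      quality = quality(.data$elon1, .data$elon2, .data$rlv)
    )
  L <- if (nrow(out)) mean(out$has_lumen) else NA_real_
  list(structures = out, lumen_fraction = L)
}
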