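#' Read a multi-page TIFF z-stack
#'
#' Reads a single-channel 8/16-bit multi-page TIFF into an [image_stack()],
#' preserving the stored integer intensities bit-exactly (no rescaling).
#' Voxel spacing is taken from the caller (configuration); TIFF metadata is
#' not trusted for it.
#'
#' @param path file path.
#' @param spacing voxel spacing `(dz, dy, dx)`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, TRUE))) {
    stop("unsupported format: RGB/multi-channel TIFF (need single-channel grayscale)",
         call. = FALSE)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent page sizes in TIFF", call. = FALSE)
  }
  bits <- attr(pages[[1]], "bits.per.sample") %||%
    (if (max(vapply(pages, max, 0)) > 255) 16L else 8L)
  arr <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  image_stack(arr, spacing = spacing, bit_depth = as.integer(bits))
}

#' Write a stack as a 16-bit multi-page TIFF
#'
#' Integer intensities in `[0, 65535]` round-trip bit-exactly through
#' [read_stack()].
#'
#' @param stack an [image_stack()] (or 3D array).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stack <- as_image_stack(stack)
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[1]), function(i) stack$data[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a label volume as a 16-bit TIFF
#'
#' @param labels integer 3D array (labels up to 65535).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  write_stack(image_stack(array(as.numeric(labels), dim(labels))), path)
}

#' Default pipeline configuration
#'
#' One flat-ish, typed configuration drives an entire run; a resolved copy
#' is written into every output directory.  See [tier1_config()] for the
#' preprocessing block.
#'
#' @param spacing voxel spacing `(dz, dy, dx)`.
#' @param tier1 a [tier1_config()] or a named list of its arguments.
#' @param min_voxels smallest structure kept.
#' @param close_radius per-structure mask repair radius passed to
#'   [solidify_labels()] after labeling (0 disables).
#' @param exclude_border drop structures touching the stack border?
#' @param lumen list: `enabled`, `threshold` (numeric or `"otsu"`),
#'   `min_voxels`, `fill` (`"slice"`/`"3d"`).
#' @param branching list: `enabled`, `prune_length`, `method`
#'   (`"geodesic"` centreline tree or `"thinning"`; see
#'   [measure_complexity()]).
#' @param stats list: `unit` (`"stack"`/`"structure"`), `include_lumen`,
#'   `include_branching`.
#' @param seed integer seed recorded with the run.
#' @return a `sama_config` nested list.
#' @export
default_config <- function(spacing = c(1, 1, 1),
                           tier1 = tier1_config(),
                           min_voxels = 64L,
                           close_radius = 2L,
                           exclude_border = FALSE,
                           lumen = list(enabled = TRUE, threshold = "otsu",
                                        min_voxels = 27L, fill = "slice"),
                           branching = list(enabled = TRUE, prune_length = 2,
                                            method = "geodesic"),
                           stats = list(unit = "stack", include_lumen = TRUE,
                                        include_branching = TRUE),
                           seed = 1L) {
  if (!inherits(tier1, "tier1_config")) tier1 <- do.call(tier1_config, tier1)
  base <- list(
    spacing = as.numeric(spacing),
    tier1 = tier1,
    min_voxels = as.integer(min_voxels),
    close_radius = as.integer(close_radius),
    exclude_border = isTRUE(exclude_border),
    lumen = utils::modifyList(
      list(enabled = TRUE, threshold = "otsu", min_voxels = 27L,
           fill = "slice"), lumen
    ),
    branching = utils::modifyList(
      list(enabled = TRUE, prune_length = 2, method = "geodesic"),
      branching
    ),
    stats = utils::modifyList(
      list(unit = "stack", include_lumen = TRUE, include_branching = TRUE),
      stats
    ),
    seed = as.integer(seed)
  )
  validate_config(base)
}

validate_config <- function(cfg) {
  if (any(cfg$spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (cfg$min_voxels < 1L) stop("min_voxels must be >= 1", call. = FALSE)
  if (cfg$close_radius < 0L) stop("close_radius must be >= 0", call. = FALSE)
  if (!cfg$lumen$fill %in% c("slice", "3d")) {
    stop("lumen$fill must be 'slice' or '3d'", call. = FALSE)
  }
  if (cfg$branching$prune_length < 0) {
    stop("branching$prune_length must be >= 0", call. = FALSE)
  }
  if (!cfg$branching$method %in% c("geodesic", "thinning")) {
    stop("branching$method must be 'geodesic' or 'thinning'", call. = FALSE)
  }
  if (!cfg$stats$unit %in% c("stack", "structure")) {
    stop("stats$unit must be 'stack' or 'structure'", call. = FALSE)
  }
  structure(cfg, class = "sama_config")
}

#' Load a pipeline configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()].
#' Unknown keys are rejected (typo safety); every numeric field is
#' range-checked.
#'
#' @param path YAML file.
#' @return a `sama_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- unclass(default_config())
  check_keys <- function(user, ref, prefix = "") {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s): %s",
                   paste0(prefix, unknown, collapse = ", ")), call. = FALSE)
    }
    for (nm in names(user)) {
      if (is.list(user[[nm]]) && is.list(ref[[nm]]) &&
          !is.null(names(ref[[nm]]))) {
        check_keys(user[[nm]], ref[[nm]], paste0(prefix, nm, "$"))
      }
    }
  }
  ref <- base
  ref$tier1 <- unclass(tier1_config())
  check_keys(raw, ref)
  merged <- utils::modifyList(base, raw)
  merged$tier1 <- do.call(tier1_config, utils::modifyList(
    unclass(tier1_config())[setdiff(names(unclass(tier1_config())), "denoise")],
    if (is.list(raw$tier1)) raw$tier1 else list()
  ))
  validate_config(merged)
}

# serialisable view of a config (drops function hooks)
config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$tier1 <- unclass(out$tier1)
  out$tier1$denoise <- if (is.null(out$tier1$denoise)) NULL else "custom hook"
  out
}

structures_touching_border <- function(labels) {
  d <- dim(labels)
  unique(c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ],
           labels[, , c(1, d[3])]))
}

#' Process one stack through segmentation and measurement
#'
#' Runs Tier-1 preprocessing, labels the 3D structures, measures
#' morphometrics, and (when enabled) lumen and branching analyses.
#'
#' @param stack an [image_stack()].
#' @param config a [default_config()].
#' @return list: `structures`, `lumena`, `complexity` (tibbles),
#'   `labels` (the [label_components()] volume), `lumen_labels`,
#'   `threshold`, `lumen_fraction`, and `log` (per-stage notes).
#' @export
process_stack <- function(stack, config = default_config()) {
  stack <- as_image_stack(stack)
  stack$spacing <- config$spacing
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  note("input: %d x %d x %d voxels, range [%g, %g]",
       dim(stack$data)[1], dim(stack$data)[2], dim(stack$data)[3],
       min(stack$data), max(stack$data))
  t1 <- run_tier1(stack, config$tier1)
  note("tier1: threshold %.4g", t1$threshold)

  labels <- label_components(t1$mask, min_voxels = config$min_voxels,
                             spacing = config$spacing)
  if (config$close_radius > 0) {
    labels <- solidify_labels(labels, config$close_radius)
  }
  if (config$exclude_border) {
    drop <- setdiff(structures_touching_border(labels), 0L)
    if (length(drop)) {
      keep_mask <- labels > 0L & !(labels %in% drop)
      labels <- label_components(keep_mask, min_voxels = config$min_voxels,
                                 spacing = config$spacing)
      note("excluded %d border structure(s)", length(drop))
    }
  }
  note("segmentation: %d structure(s)", attr(labels, "n_labels"))
  structures <- measure_structures(labels)

  lumena <- NULL
  lumen_labels <- NULL
  lumen_fraction <- NA_real_
  if (isTRUE(config$lumen$enabled)) {
    lumen_labels <- segment_lumena(
      labels > 0L, t1$lumen, config$lumen$threshold,
      min_lumen_voxels = config$lumen$min_voxels, fill = config$lumen$fill
    )
    lumena <- suppressMessages(assign_lumena(lumen_labels, labels))
    lm <- lumen_metrics(structures, lumena)
    structures <- lm$structures
    lumen_fraction <- lm$lumen_fraction
    note("lumen: %d cavitie(s), L = %.3f", attr(lumen_labels, "n_labels"),
         lumen_fraction)
  }

  complexity <- NULL
  if (isTRUE(config$branching$enabled)) {
    complexity <- measure_complexity(labels, config$spacing,
                                     config$branching$prune_length,
                                     config$branching$method)
    note("branching: mean %.2f branch(es)/structure",
         if (nrow(complexity)) mean(complexity$n_branches) else NA)
  }

  list(
    structures = structures, lumena = lumena, complexity = complexity,
    labels = labels, lumen_labels = lumen_labels,
    threshold = t1$threshold, lumen_fraction = lumen_fraction, log = log
  )
}

#' Run the batch pipeline over a directory of stacks
#'
#' Processes every `.tif`/`.tiff` in `input_dir` through [process_stack()],
#' writes the per-structure and per-lumen CSVs and the resolved
#' configuration into `out_dir`, and — when a metadata CSV
#' (`stack_id, condition, replicate`) is supplied — consolidates everything
#' into a study table and generates the statistical report.  A stage
#' failure aborts that stack with a logged reason and the run continues; the
#' function errors only if every stack fails.
#'
#' @param input_dir directory of TIFF stacks.
#' @param out_dir output directory.
#' @param config a `sama_config`.
#' @param metadata optional path to a metadata CSV, or a data frame.
#' @return invisibly, a list with `tables` (structures/lumena/complexity),
#'   `study` (or `NULL`), and `failures`.
#' @export
run_pipeline <- function(input_dir, out_dir, config = default_config(),
                         metadata = NULL) {
  files <- list.files(input_dir, pattern = "\\.tiff?$", full.names = TRUE)
  files <- files[!grepl("_(structures|lumena)\\.tiff?$", files)]
  if (!length(files)) {
    stop(sprintf("no TIFF stacks found in '%s'", input_dir), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))
  logf <- file.path(out_dir, "run.log")
  cat(sprintf("sama3d %s run, %d stack(s)\n",
              as.character(utils::packageVersion("sama3d")), length(files)),
      file = logf)

  all_structures <- list(); all_lumena <- list(); all_complexity <- list()
  failures <- character()
  for (f in files) {
    id <- sub("\\.tiff?$", "", basename(f))
    t0 <- Sys.time()
    res <- tryCatch(
      process_stack(read_stack(f, config$spacing), config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      cat(sprintf("[%s] FAILED: %s\n", id, conditionMessage(res)),
          file = logf, append = TRUE)
      next
    }
    cat(sprintf("[%s] ok (%.1fs)\n  %s\n", id,
                as.numeric(difftime(Sys.time(), t0, units = "secs")),
                paste(res$log, collapse = "\n  ")),
        file = logf, append = TRUE)
    all_structures[[id]] <- dplyr::mutate(res$structures, stack_id = id,
                                          .before = 1)
    if (!is.null(res$lumena)) {
      all_lumena[[id]] <- dplyr::mutate(res$lumena, stack_id = id,
                                        .before = 1)
    }
    if (!is.null(res$complexity)) {
      all_complexity[[id]] <- dplyr::mutate(res$complexity, stack_id = id,
                                            .before = 1)
    }
  }
  if (!length(all_structures)) {
    stop("all stacks failed; see run.log", call. = FALSE)
  }
  structures <- dplyr::bind_rows(all_structures)
  lumena <- if (length(all_lumena)) dplyr::bind_rows(all_lumena) else NULL
  complexity <- if (length(all_complexity)) dplyr::bind_rows(all_complexity)
                else NULL
  write.csv(as.data.frame(structures),
            file.path(out_dir, "structures.csv"), row.names = FALSE)
  if (!is.null(lumena)) {
    write.csv(as.data.frame(lumena), file.path(out_dir, "lumena.csv"),
              row.names = FALSE)
  }
  if (!is.null(complexity)) {
    write.csv(as.data.frame(complexity),
              file.path(out_dir, "complexity.csv"), row.names = FALSE)
  }

  study <- NULL
  if (!is.null(metadata)) {
    meta <- if (is.data.frame(metadata)) metadata else
      tibble::as_tibble(read.csv(metadata, stringsAsFactors = FALSE))
    study <- consolidate(
      structures, lumena, complexity, meta,
      include_lumen = config$stats$include_lumen && !is.null(lumena),
      include_branching = config$stats$include_branching &&
        !is.null(complexity)
    )
    write.csv(as.data.frame(study), file.path(out_dir, "study.csv"),
              row.names = FALSE)
    generate_report(study, file.path(out_dir, "report"))
  }
  invisible(list(
    tables = list(structures = structures, lumena = lumena,
                  complexity = complexity),
    study = study, failures = failures
  ))
}

#' Run the phantom validation study end to end
#'
#' Generates `n_stacks` phantom stacks for each condition from one seed,
#' pushes each through the full pipeline (Tier-1, segmentation,
#' morphometrics, lumen, branching) as it is generated, and consolidates
#' the detected structures into a study table.  This is the
#' computer-generated validation of the method: the expected outcome is
#' more elongated structures in C2 than C1, fewer lumen-bearing structures
#' and smaller total lumen volume in C3 than C1, and higher complexity in
#' C4 than C1.
#'
#' @param seed integer seed for the whole study.
#' @param conditions condition names to include.
#' @param n_stacks stacks per condition.
#' @param config a `sama_config`.
#' @param ... [phantom_spec()] overrides applied to every condition (e.g. a
#'   smaller `grid_shape` for quick runs).
#' @return list: `study` (consolidated tibble), `truth` (generator ground
#'   truth rows per stack), `counts` (tibble: stack_id, generated,
#'   detected).
#' @export
run_validation_study <- function(seed = 1L,
                                 conditions = c("C1", "C2", "C3", "C4"),
                                 n_stacks = 6L,
                                 config = default_config(), ...) {
  set.seed(seed)
  structures <- list(); lumena <- list(); complexity <- list()
  truth <- list(); counts <- list(); meta <- list()
  for (cond in conditions) {
    spec <- phantom_condition_spec(cond, ...)
    for (s in seq_len(n_stacks)) {
      id <- sprintf("%s_%d", cond, s)
      ps <- generate_stack(spec, seed = NULL)
      res <- process_stack(ps$stack, config)
      structures[[id]] <- dplyr::mutate(res$structures, stack_id = id,
                                        .before = 1)
      if (!is.null(res$lumena)) {
        lumena[[id]] <- dplyr::mutate(res$lumena, stack_id = id, .before = 1)
      }
      if (!is.null(res$complexity)) {
        complexity[[id]] <- dplyr::mutate(res$complexity, stack_id = id,
                                          .before = 1)
      }
      truth[[id]] <- dplyr::mutate(ps$truth, stack_id = id, .before = 1)
      counts[[id]] <- tibble::tibble(
        stack_id = id, condition = cond,
        generated = nrow(ps$truth),
        detected = attr(res$labels, "n_labels")
      )
      meta[[id]] <- tibble::tibble(stack_id = id, condition = cond,
                                   replicate = sprintf("r%d", s))
      rm(ps, res)
      gc(FALSE)
    }
  }
  study <- consolidate(
    dplyr::bind_rows(structures),
    if (length(lumena)) dplyr::bind_rows(lumena) else NULL,
    if (length(complexity)) dplyr::bind_rows(complexity) else NULL,
    dplyr::bind_rows(meta),
    include_lumen = config$stats$include_lumen,
    include_branching = config$stats$include_branching
  )
  list(
    study = study,
    truth = dplyr::bind_rows(truth),
    counts = dplyr::bind_rows(counts)
  )
}

#' The four validation comparisons
#'
#' Computes the reported p-values (larger of ANOVA and exact Wilcoxon on
#' per-stack means) for the validation contrasts: elongation `Elon1` C2 vs
#' C1; lumen presence `L` and relative lumen volume `RLV` C1 vs C3; and the
#' three complexity measures (multi-branch indicator, branch count,
#' cumulated branch length) C4 vs C1, of which the largest reported p is
#' the summary.
#'
#' @param study the study tibble from [run_validation_study()].
#' @return tibble: comparison, parameter, anova_p, wilcoxon_p, reported_p.
#' @export
validation_comparisons <- function(study) {
  one <- function(conds, parameter, comparison) {
    sub <- dplyr::filter(study, .data$condition %in% conds)
    t <- compare_groups(sub, parameter, unit = "stack")
    tibble::tibble(
      comparison = comparison, parameter = parameter,
      anova_p = t$anova_p, wilcoxon_p = t$wilcoxon_p,
      reported_p = t$reported_p
    )
  }
  dplyr::bind_rows(
    one(c("C1", "C2"), "elon1", "elongation (C2 vs C1)"),
    one(c("C1", "C3"), "has_lumen", "lumen presence (C3 vs C1)"),
    one(c("C1", "C3"), "rlv", "lumen volume (C3 vs C1)"),
    one(c("C1", "C4"), "has_multiple_branches", "complexity (C4 vs C1)"),
    one(c("C1", "C4"), "n_branches", "complexity (C4 vs C1)"),
    one(c("C1", "C4"), "complexity", "complexity (C4 vs C1)")
  )
}
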