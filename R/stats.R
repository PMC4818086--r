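#' Consolidate per-structure tables into a study table
#'
#' Joins the per-structure morphometrics, the per-lumen records and the
#' per-structure complexity measures from every stack into a single table
#' with one row per structure, annotated with the experimental condition and
#' replicate from the metadata.  Lumen and branching sections can be
#' included or excluded from the basic morphometrics.  Structures without a
#' lumen row get `n_lumena = 0` and `rlv = 0`; no row is ever dropped
#' silently.
#'
#' @param structures tibble of [measure_structures()] rows carrying a
#'   `stack_id` column (rows from several stacks bound together).
#' @param lumena optional tibble of [assign_lumena()] rows with `stack_id`.
#' @param complexity optional tibble of [measure_complexity()] rows with
#'   `stack_id`.
#' @param metadata tibble mapping `stack_id` to `condition` and `replicate`.
#' @param include_lumen,include_branching include those column groups?
#' @return the study tibble: `condition`, `replicate`, `stack_id`, `label`,
#'   then the parameter columns.
#' @export
consolidate <- function(structures, lumena = NULL, complexity = NULL,
                        metadata, include_lumen = TRUE,
                        include_branching = TRUE) {
  stopifnot(is.data.frame(structures), is.data.frame(metadata))
  if (!all(c("stack_id", "condition", "replicate") %in% names(metadata))) {
    stop("metadata needs columns stack_id, condition, replicate",
         call. = FALSE)
  }
  if (anyDuplicated(structures[c("stack_id", "label")])) {
    dup <- structures[duplicated(structures[c("stack_id", "label")]), ]
    stop(sprintf("duplicate (stack_id, label) pairs in structures: %s",
                 paste(unique(dup$stack_id), collapse = ", ")),
         call. = FALSE)
  }
  missing_meta <- setdiff(unique(structures$stack_id), metadata$stack_id)
  if (length(missing_meta)) {
    stop(sprintf("stacks without metadata: %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  }
  # derived per-structure columns are recomputed here from the lumen and
  # complexity tables, so stale copies are dropped first
  derived <- c("n_lumena", "lumen_volume", "rlv", "structure_to_lumen_ratio",
               "has_lumen", "quality", "n_branches", "complexity",
               "total_length", "has_multiple_branches")
  out <- structures[setdiff(names(structures), derived)]
  if (include_lumen) {
    if (!is.null(lumena) && nrow(lumena)) {
      agg <- lumena |>
        dplyr::filter(!.data$flagged) |>
        dplyr::group_by(.data$stack_id, label = .data$parent) |>
        dplyr::summarise(
          n_lumena = dplyr::n(), lumen_volume = sum(.data$volume),
          .groups = "drop"
        )
      out <- dplyr::left_join(out, agg, by = c("stack_id", "label"))
    } else {
      out$n_lumena <- 0L
      out$lumen_volume <- 0
    }
    out <- out |>
      dplyr::mutate(
        n_lumena = dplyr::coalesce(.data$n_lumena, 0L),
        lumen_volume = dplyr::coalesce(.data$lumen_volume, 0),
        rlv = .data$lumen_volume / .data$volume,
        has_lumen = as.numeric(.data$n_lumena >= 1L),
        quality = quality(.data$elon1, .data$elon2, .data$rlv)
      )
  }
  if (include_branching) {
    if (!is.null(complexity) && nrow(complexity)) {
      cx <- complexity |>
        dplyr::select("stack_id", "label", "n_branches", "total_length",
                      "has_multiple_branches") |>
        dplyr::rename(complexity = "total_length")
      out <- dplyr::left_join(out, cx, by = c("stack_id", "label"))
    } else {
      out$n_branches <- NA_integer_
      out$complexity <- NA_real_
      out$has_multiple_branches <- NA
    }
    out$has_multiple_branches <- as.numeric(out$has_multiple_branches)
  }
  out <- dplyr::inner_join(
    dplyr::select(metadata, "stack_id", "condition", "replicate"),
    out, by = "stack_id"
  )
  tibble::as_tibble(out)
}

#' Summarise one parameter per condition and replicate
#'
#' Mean, sample standard deviation, coefficient of variation (`sd / mean`)
#' and median of a parameter over the structures of each
#' condition-by-replicate group.  Missing values are excluded with a
#' message; a group with mean 0 gets `cv = NA` with a warning.
#'
#' @param study a [consolidate()] table.
#' @param parameter name of a numeric parameter column.
#' @return tibble: condition, replicate, n, mean, sd, cv, median.
#' @export
summarize_parameter <- function(study, parameter) {
  if (!parameter %in% names(study)) {
    stop(sprintf("parameter '%s' not in the study table", parameter),
         call. = FALSE)
  }
  v <- study[[parameter]]
  n_na <- sum(is.na(v))
  if (n_na) message(sprintf("%d missing value(s) of %s excluded",
                            n_na, parameter))
  out <- study |>
    dplyr::mutate(.value = as.numeric(.data[[parameter]])) |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(
      n = sum(!is.na(.data$.value)),
      mean = mean(.data$.value, na.rm = TRUE),
      sd = sd(.data$.value, na.rm = TRUE),
      median = median(.data$.value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean = ifelse(.data$n > 0, .data$mean, NA_real_),
      median = ifelse(.data$n > 0, .data$median, NA_real_),
      sd = ifelse(.data$n > 1, .data$sd, ifelse(.data$n == 1, 0, NA_real_)),
      cv = ifelse(is.na(.data$mean) | .data$mean == 0, NA_real_,
                  .data$sd / .data$mean)
    ) |>
    dplyr::select("condition", "replicate", "n", "mean", "sd", "cv", "median")
  if (any(!is.na(out$mean) & out$mean == 0 & out$n > 0)) {
    warning("cv undefined for group(s) with mean 0; reported as NA")
  }
  out
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' For group sizes up to `exact_max` the null distribution of the rank sum
#' is obtained by exact enumeration of all `choose(n + m, n)` group
#' labelings (midranks are used, so ties are handled exactly); the two-sided
#' p-value is twice the smaller tail, capped at 1.  Larger groups fall back
#' to the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param exact_max largest group size for exact enumeration.
#' @return list with `statistic` (the Mann-Whitney U), `p_value`, `method`.
#' @export
wilcox_exact <- function(x, y, exact_max = 10L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stop("both groups need data", call. = FALSE)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  if (n <= exact_max && m <= exact_max) {
    combs <- combn(n + m, n)
    Ws <- colSums(matrix(r[combs], nrow = n))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Ws <= W + eps), mean(Ws >= W - eps)))
    method <- "exact enumeration"
  } else {
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)  # continuity correction
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W - n * (n + 1) / 2, p_value = p, method = method)
}

#' Compare a parameter between conditions
#'
#' One-way ANOVA across the conditions and, when exactly two conditions are
#' present, the exact two-sided Wilcoxon rank-sum test; the p-value reported
#' is the largest among the values obtained, a deliberately conservative
#' convention.  The default experimental unit is the per-stack mean (each
#' stack is one replicate of the condition); testing pooled per-structure
#' values is available but is flagged as pseudo-replication, since
#' structures within a stack are not independent.
#'
#' @param study a [consolidate()] table.
#' @param parameter name of a numeric parameter column.
#' @param unit `"stack"` (per-stack means, default) or `"structure"`
#'   (pooled structures).
#' @return a `sama_test` object; see [tidy.sama_test()] / [glance.sama_test()].
#' @export
compare_groups <- function(study, parameter, unit = c("stack", "structure")) {
  unit <- match.arg(unit)
  if (!parameter %in% names(study)) {
    stop(sprintf("parameter '%s' not in the study table", parameter),
         call. = FALSE)
  }
  if (unit == "structure") {
    warning("testing pooled structures treats non-independent structures ",
            "as replicates (pseudo-replication)")
    units <- study |>
      dplyr::transmute(condition = .data$condition,
                       value = as.numeric(.data[[parameter]]))
  } else {
    units <- study |>
      dplyr::group_by(.data$condition, .data$stack_id) |>
      dplyr::summarise(
        value = mean(as.numeric(.data[[parameter]]), na.rm = TRUE),
        .groups = "drop"
      )
  }
  units <- dplyr::filter(units, !is.na(.data$value))
  counts <- dplyr::count(units, .data$condition)
  if (nrow(counts) < 2L) stop("need at least two conditions", call. = FALSE)
  small <- counts$condition[counts$n < 2L]
  if (length(small)) {
    stop(sprintf("condition(s) with fewer than 2 experimental units: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  fit <- lm(value ~ factor(condition), data = units)
  anova_p <- anova(fit)[["Pr(>F)"]][1]
  if (is.nan(anova_p)) anova_p <- NA_real_
  wilcoxon_p <- NA_real_
  wilcoxon_method <- NA_character_
  if (nrow(counts) == 2L) {
    sp <- split(units$value, units$condition)
    wt <- wilcox_exact(sp[[1]], sp[[2]])
    wilcoxon_p <- wt$p_value
    wilcoxon_method <- wt$method
  }
  ps <- c(anova = anova_p, wilcoxon = wilcoxon_p)
  if (all(is.na(ps))) {
    reported_p <- 1  # no test could distinguish anything (zero variance)
  } else {
    reported_p <- max(ps, na.rm = TRUE)
  }
  summaries <- units |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), median = median(.data$value),
                     .groups = "drop")
  structure(
    list(
      parameter = parameter, unit = unit,
      groups = summaries,
      anova_p = anova_p, wilcoxon_p = wilcoxon_p,
      wilcoxon_method = wilcoxon_method,
      reported_p = reported_p
    ),
    class = "sama_test"
  )
}

#' @export
print.sama_test <- function(x, ...) {
  cat(sprintf("<sama_test> %s (unit: %s)\n", x$parameter, x$unit))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d, mean=%.4g)", x$groups$condition,
                            x$groups$n, x$groups$mean), collapse = ", ")))
  cat(sprintf("  ANOVA p = %.4g; Wilcoxon p = %.4g; reported p = %.4g\n",
              x$anova_p, x$wilcoxon_p, x$reported_p))
  invisible(x)
}

#' Tidy a group-comparison result
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return tibble with one row per test (anova, wilcoxon) plus the reported
#'   maximum.
#' @export
tidy.sama_test <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    test = c("anova", "wilcoxon", "reported"),
    p_value = c(x$anova_p, x$wilcoxon_p, x$reported_p)
  )
}

#' One-row summary of a group-comparison result
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.sama_test <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter, unit = x$unit, n_groups = nrow(x$groups),
    anova_p = x$anova_p, wilcoxon_p = x$wilcoxon_p,
    reported_p = x$reported_p
  )
}

#' Principal component overview of the study
#'
#' PCA on the correlation matrix (variables standardised to unit variance),
#' identifying the directions along which the morphometric parameters
#' co-vary most.  Rows with missing values are excluded (with a message);
#' zero-variance variables are dropped with a warning, since parameters
#' uncorrelated with the rest carry no information for this overview.
#'
#' @param study a [consolidate()] table.
#' @param variables character vector of parameter columns (default: all
#'   numeric parameter columns present).
#' @return a `sama_pca`: loadings, scores, explained-variance fractions,
#'   the variables used and the per-row condition labels.
#' @export
run_pca <- function(study, variables = NULL) {
  if (is.null(variables)) {
    candidates <- c("volume", "elon1", "elon2", "sphericity", "rve",
                    "n_lumena", "rlv", "quality", "n_branches", "complexity")
    variables <- intersect(candidates, names(study))
  }
  if (length(variables) < 2L) {
    stop("need at least two variables for a PCA", call. = FALSE)
  }
  x <- as.data.frame(study[variables])
  x[] <- lapply(x, as.numeric)
  ok <- stats::complete.cases(x)
  if (any(!ok)) {
    message(sprintf("%d row(s) with missing values excluded from the PCA",
                    sum(!ok)))
  }
  x <- x[ok, , drop = FALSE]
  sds <- vapply(x, sd, 0)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance variable(s) dropped: %s",
                    paste(variables[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
    variables <- variables[sds > 0]
  }
  if (ncol(x) < 2L) stop("fewer than two informative variables", call. = FALSE)
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      loadings = fit$rotation,
      scores = fit$x,
      sdev = fit$sdev,
      explained = explained,
      variables = variables,
      condition = if ("condition" %in% names(study)) study$condition[ok]
                  else NULL
    ),
    class = "sama_pca"
  )
}

#' @export
print.sama_pca <- function(x, ...) {
  cat(sprintf("<sama_pca> %d variable(s), %d observation(s)\n",
              length(x$variables), nrow(x$scores)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Tidy PCA loadings
#'
#' @param x a [run_pca()] result.
#' @param ... unused.
#' @return long tibble of loadings (variable, component, loading).
#' @export
tidy.sama_pca <- function(x, ...) {
  ld <- x$loadings
  tibble::tibble(
    variable = rep(rownames(ld), ncol(ld)),
    component = rep(colnames(ld), each = nrow(ld)),
    loading = as.vector(ld)
  )
}

#' Explained variance per component
#'
#' @param x a [run_pca()] result.
#' @param ... unused.
#' @return tibble: component, explained variance fraction, cumulative.
#' @export
glance.sama_pca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$loadings),
    explained = x$explained,
    cumulative = cumsum(x$explained)
  )
}

#' Replicate reproducibility curves
#'
#' Kernel density estimates of a parameter for every replicate of a
#' condition, all sharing one bandwidth (Silverman's rule on the pooled
#' condition data) so the curve shapes are comparable.  Superimposed curves
#' indicate that structures are not variable between replicates, i.e. the
#' experiment is reproducible.  As a quantitative diagnostic the pairwise
#' Kolmogorov-Smirnov distance between replicate distributions is reported
#' (0 = identical; 1 = disjoint).
#'
#' @param study a [consolidate()] table.
#' @param parameter parameter column name.
#' @param conditions conditions to include (default: all with data).
#' @return a `sama_repro`: `curves` (condition, replicate, x, density),
#'   `ks` (pairwise distances; empty when a condition has a single
#'   replicate), `bandwidths`, `parameter`.
#' @export
reproducibility_curves <- function(study, parameter, conditions = NULL) {
  if (!parameter %in% names(study)) {
    stop(sprintf("parameter '%s' not in the study table", parameter),
         call. = FALSE)
  }
  if (is.null(conditions)) conditions <- unique(study$condition)
  curves <- list(); kss <- list(); bws <- c()
  for (cond in conditions) {
    sub <- study[study$condition == cond & !is.na(study[[parameter]]), ]
    if (!nrow(sub)) next
    vals <- as.numeric(sub[[parameter]])
    bw <- tryCatch(bw.nrd0(vals), error = function(e) NA_real_)
    if (!is.finite(bw) || bw <= 0) bw <- max(1e-3, diff(range(vals)) / 10, na.rm = TRUE)
    bws[cond] <- bw
    reps <- split(vals, sub$replicate)
    lo <- min(vals) - 3 * bw; hi <- max(vals) + 3 * bw
    for (rn in names(reps)) {
      d <- density(reps[[rn]], bw = bw, from = lo, to = hi, n = 256)
      curves[[paste(cond, rn)]] <- tibble::tibble(
        condition = cond, replicate = rn, x = d$x, density = d$y
      )
    }
    if (length(reps) >= 2L) {
      prs <- combn(names(reps), 2)
      for (i in seq_len(ncol(prs))) {
        a <- prs[1, i]; b <- prs[2, i]
        stat <- suppressWarnings(
          as.numeric(ks.test(reps[[a]], reps[[b]])$statistic)
        )
        kss[[paste(cond, a, b)]] <- tibble::tibble(
          condition = cond, replicate_a = a, replicate_b = b,
          ks_distance = stat
        )
      }
    }
  }
  structure(
    list(
      curves = dplyr::bind_rows(curves),
      ks = if (length(kss)) dplyr::bind_rows(kss) else
        tibble::tibble(condition = character(), replicate_a = character(),
                       replicate_b = character(), ks_distance = numeric()),
      bandwidths = bws,
      parameter = parameter
    ),
    class = "sama_repro"
  )
}

#' @export
print.sama_repro <- function(x, ...) {
  cat(sprintf("<sama_repro> %s: %d curve(s), %d pairwise KS distance(s)\n",
              x$parameter,
              nrow(dplyr::distinct(x$curves, .data$condition,
                                   .data$replicate)),
              nrow(x$ks)))
  invisible(x)
}
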