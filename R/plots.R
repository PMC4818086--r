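#' Distribution curves of a parameter by condition
#'
#' One kernel density curve per condition-replicate, coloured by condition —
#' the per-parameter "graph of the estimated distribution of the
#' replicates" of the analysis report.
#'
#' @param study a [consolidate()] table.
#' @param parameter parameter column name.
#' @return a ggplot.
#' @export
plot_distribution <- function(study, parameter) {
  rc <- reproducibility_curves(study, parameter)
  ggplot2::ggplot(rc$curves, ggplot2::aes(
    x = .data$x, y = .data$density,
    colour = .data$condition,
    group = interaction(.data$condition, .data$replicate)
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = parameter, y = "density", colour = "condition") +
    ggplot2::theme_minimal()
}

#' Boxplot of a parameter by condition
#'
#' @param study a [consolidate()] table.
#' @param parameter parameter column name.
#' @return a ggplot.
#' @export
plot_boxplot <- function(study, parameter) {
  ggplot2::ggplot(study, ggplot2::aes(
    x = .data$condition, y = as.numeric(.data[[parameter]]),
    fill = .data$condition
  )) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = "condition", y = parameter) +
    ggplot2::theme_minimal()
}

#' Plot a PCA result
#'
#' `type = "variables"` draws the correlation circle (variable vectors on
#' the first two components, scaled by their correlation with the
#' components); `type = "individuals"` plots the per-structure scores
#' coloured by condition.
#'
#' @param object a [run_pca()] result.
#' @param type `"variables"` or `"individuals"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sama_pca <- function(object, type = c("variables", "individuals"),
                              ...) {
  type <- match.arg(type)
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$explained[1:2])
  if (type == "variables") {
    corr <- sweep(object$loadings[, 1:2, drop = FALSE], 2,
                  object$sdev[1:2], `*`)
    df <- tibble::tibble(
      variable = rownames(object$loadings),
      PC1 = corr[, 1], PC2 = corr[, 2]
    )
    circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 180))
    ggplot2::ggplot(df) +
      ggplot2::geom_path(
        data = circ,
        ggplot2::aes(x = cos(.data$t), y = sin(.data$t)),
        colour = "grey70"
      ) +
      ggplot2::geom_segment(
        ggplot2::aes(x = 0, y = 0, xend = .data$PC1, yend = .data$PC2),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
      ) +
      ggplot2::geom_text(
        ggplot2::aes(x = .data$PC1 * 1.08, y = .data$PC2 * 1.08,
                     label = .data$variable),
        size = 3
      ) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = lab[1], y = lab[2], title = "Variables factor map") +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(
      PC1 = object$scores[, 1], PC2 = object$scores[, 2],
      condition = object$condition %||% "all"
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                     colour = .data$condition)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = lab[1], y = lab[2], title = "Individuals factor map",
                    colour = "condition") +
      ggplot2::theme_minimal()
  }
}

#' Plot reproducibility curves
#'
#' @param object a [reproducibility_curves()] result.
#' @param ... unused.
#' @return a ggplot faceted by condition.
#' @export
autoplot.sama_repro <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(
    x = .data$x, y = .data$density, colour = .data$replicate
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition, scales = "free") +
    ggplot2::labs(x = object$parameter, y = "density",
                  colour = "replicate") +
    ggplot2::theme_minimal()
}

#' Generate the analysis report
#'
#' Writes, per parameter: a distribution-curve figure, a boxplot figure, a
#' condition-by-replicate summary CSV and a test-result CSV (ANOVA,
#' Wilcoxon when two conditions, and the reported maximum); plus one PCA
#' variables factor map, one individuals plot, the PCA loadings CSV, the
#' reproducibility KS diagnostics, and an `index.csv` listing every output.
#' CSV outputs are deterministic: rerunning on identical input reproduces
#' them byte for byte.
#'
#' @param study a [consolidate()] table.
#' @param out_dir output directory (created; must be writable).
#' @param parameters parameter columns to report on (default: every numeric
#'   parameter column present).
#' @param figure_format `"pdf"` or `"png"`.
#' @param p_adjust if `TRUE`, additionally write `tests_all.csv` collecting
#'   every parameter's reported p-value with a Benjamini-Hochberg adjusted
#'   column (the per-parameter reports themselves stay unadjusted).
#' @return invisibly, the index tibble (file, kind, parameter).
#' @export
generate_report <- function(study, out_dir, parameters = NULL,
                            figure_format = c("pdf", "png"),
                            p_adjust = FALSE) {
  figure_format <- match.arg(figure_format)
  ok <- tryCatch({
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    probe <- file.path(out_dir, ".write_probe")
    file.create(probe) && file.remove(probe)
  }, error = function(e) FALSE)
  if (!isTRUE(ok)) {
    stop(sprintf("output directory '%s' is not writable", out_dir),
         call. = FALSE)
  }
  if (is.null(parameters)) {
    candidates <- c("volume", "elon1", "elon2", "sphericity", "rve",
                    "n_lumena", "rlv", "has_lumen", "quality", "n_branches",
                    "complexity", "has_multiple_branches")
    parameters <- intersect(candidates, names(study))
  }
  index <- list()
  all_tests <- list()
  add <- function(file, kind, parameter = NA_character_) {
    index[[length(index) + 1]] <<- tibble::tibble(
      file = file, kind = kind, parameter = parameter
    )
  }
  for (p in parameters) {
    smry <- suppressMessages(summarize_parameter(study, p))
    f <- sprintf("summary_%s.csv", p)
    write.csv(as.data.frame(smry), file.path(out_dir, f), row.names = FALSE)
    add(f, "summary", p)

    test <- tryCatch(glance(compare_groups(study, p)),
                     error = function(e) NULL)
    if (!is.null(test)) {
      f <- sprintf("tests_%s.csv", p)
      write.csv(as.data.frame(test), file.path(out_dir, f),
                row.names = FALSE)
      add(f, "tests", p)
      all_tests[[p]] <- test
    }

    f <- sprintf("dist_%s.%s", p, figure_format)
    ggplot2::ggsave(file.path(out_dir, f), plot_distribution(study, p),
                    width = 6, height = 4)
    add(f, "distribution_figure", p)

    f <- sprintf("box_%s.%s", p, figure_format)
    ggplot2::ggsave(file.path(out_dir, f), plot_boxplot(study, p),
                    width = 6, height = 4)
    add(f, "boxplot_figure", p)

    ks <- suppressMessages(reproducibility_curves(study, p))$ks
    if (nrow(ks)) {
      f <- sprintf("reproducibility_%s.csv", p)
      write.csv(as.data.frame(ks), file.path(out_dir, f), row.names = FALSE)
      add(f, "reproducibility", p)
    }
  }
  pca <- tryCatch(suppressMessages(run_pca(study, intersect(
    parameters, c("volume", "elon1", "elon2", "sphericity", "rve",
                  "n_lumena", "rlv", "quality", "n_branches", "complexity")
  ))), error = function(e) NULL)
  if (!is.null(pca)) {
    f <- "pca_loadings.csv"
    write.csv(as.data.frame(tidy(pca)), file.path(out_dir, f),
              row.names = FALSE)
    add(f, "pca")
    f <- paste0("pca_variables.", figure_format)
    ggplot2::ggsave(file.path(out_dir, f), autoplot(pca, "variables"),
                    width = 5, height = 5)
    add(f, "pca_figure")
    f <- paste0("pca_individuals.", figure_format)
    ggplot2::ggsave(file.path(out_dir, f), autoplot(pca, "individuals"),
                    width = 6, height = 5)
    add(f, "pca_figure")
  }
  if (isTRUE(p_adjust) && length(all_tests)) {
    combined <- dplyr::bind_rows(all_tests)
    combined$reported_p_bh <- stats::p.adjust(combined$reported_p,
                                              method = "BH")
    write.csv(as.data.frame(combined), file.path(out_dir, "tests_all.csv"),
              row.names = FALSE)
    add("tests_all.csv", "tests_adjusted")
  }
  index <- dplyr::bind_rows(index)
  write.csv(as.data.frame(index), file.path(out_dir, "index.csv"),
            row.names = FALSE)
  invisible(index)
}
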