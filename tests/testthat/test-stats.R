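# small synthetic study table: 2 conditions x 3 stacks x 4 structures
toy_study <- function() {
  set.seed(14)
  grid <- expand.grid(condition = c("A", "B"), stack = 1:3, label = 1:4)
  tibble::tibble(
    condition = as.character(grid$condition),
    replicate = paste0("r", grid$stack),
    stack_id = paste0(grid$condition, "_", grid$stack),
    label = grid$label,
    volume = runif(nrow(grid), 500, 1500),
    elon1 = ifelse(grid$condition == "A", 1.2, 1.8) + rnorm(nrow(grid), 0, 0.05),
    elon2 = 1.1 + rnorm(nrow(grid), 0, 0.05),
    rlv = runif(nrow(grid), 0, 0.2)
  )
}

test_that("consolidation joins tables, fills absentees and checks keys", {
  structures <- tibble::tibble(
    stack_id = rep(c("s1", "s2"), each = 2),
    label = rep(1:2, 2),
    volume = c(100, 200, 150, 250),
    elon1 = c(1.5, 1.2, 1.4, 1.3),
    elon2 = c(1.1, 1.1, 1.2, 1.05)
  )
  lumena <- tibble::tibble(
    stack_id = "s1", lumen = 1L, parent = 1L, n_voxels = 10L, volume = 10,
    flagged = FALSE
  )
  complexity <- tibble::tibble(
    stack_id = rep(c("s1", "s2"), each = 2), label = rep(1:2, 2),
    n_branches = c(1L, 3L, 1L, 1L), total_length = c(5, 12, 4, 6),
    has_multiple_branches = c(FALSE, TRUE, FALSE, FALSE)
  )
  meta <- tibble::tibble(stack_id = c("s1", "s2"),
                         condition = c("ctrl", "trt"),
                         replicate = c("r1", "r1"))
  st <- consolidate(structures, lumena, complexity, meta)
  expect_equal(nrow(st), 4)
  expect_equal(st$n_lumena[st$stack_id == "s1" & st$label == 1], 1L)
  expect_equal(st$rlv[st$stack_id == "s1" & st$label == 1], 0.1)
  # structures without a lumen row get zeros, not NA
  expect_equal(st$n_lumena[st$stack_id == "s2"], c(0L, 0L))
  expect_equal(st$rlv[st$stack_id == "s2"], c(0, 0))
  expect_equal(st$complexity, c(5, 12, 4, 6))

  # toggles remove the column groups
  st2 <- consolidate(structures, lumena, complexity, meta,
                     include_lumen = FALSE)
  expect_false(any(c("rlv", "n_lumena", "quality") %in% names(st2)))
  st3 <- consolidate(structures, lumena, complexity, meta,
                     include_branching = FALSE)
  expect_false(any(c("n_branches", "complexity") %in% names(st3)))

  # key errors
  expect_error(consolidate(structures, lumena, complexity,
                           meta[1, ]), "without metadata")
  dup <- dplyr::bind_rows(structures, structures[1, ])
  expect_error(consolidate(dup, lumena, complexity, meta), "duplicate")
})

test_that("summaries reproduce hand-computed statistics", {
  st <- tibble::tibble(
    condition = "A", replicate = "r1", stack_id = "s1", label = 1:4,
    v = c(1, 2, 3, 4)
  )
  sm <- summarize_parameter(st, "v")
  expect_equal(sm$mean, 2.5)
  expect_equal(sm$median, 2.5)
  expect_equal(sm$sd, sd(c(1, 2, 3, 4)))          # 1.2910
  expect_equal(sm$cv, sd(1:4) / 2.5)              # 0.5164
  expect_equal(sm$n, 4L)

  # constant column
  st$v <- 7
  sm <- summarize_parameter(st, "v")
  expect_equal(sm$sd, 0)
  expect_equal(sm$cv, 0)
  expect_equal(sm$median, sm$mean)

  # zero-mean group: cv missing with warning
  st$v <- c(-1, 1, -2, 2)
  expect_warning(sm <- summarize_parameter(st, "v"), "cv undefined")
  expect_true(is.na(sm$cv))
})

test_that("exact Wilcoxon matches brute-force enumeration and wilcox.test", {
  set.seed(15)
  for (i in 1:8) {
    n <- sample(3:7, 1); m <- sample(3:7, 1)
    x <- rnorm(n); y <- rnorm(m, mean = runif(1, -1, 1))
    mine <- wilcox_exact(x, y)
    expect_equal(mine$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
  }
  # ties are handled by midrank enumeration (reference switches to
  # approximation, so compare against the oracle only)
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  expect_equal(wilcox_exact(x, y)$p_value, oracle_wilcoxon_p(x, y))
})

test_that("complete separation of 6 vs 6 gives the exact floor 2/924", {
  x <- 1:6; y <- 7:12
  expect_equal(wilcox_exact(x, y)$p_value, 2 / 924, tolerance = 1e-12)
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(16)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  mine <- wilcox_exact(x, y)
  expect_match(mine$method, "normal approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("group comparison applies the larger-p rule on per-stack means", {
  st <- toy_study()
  res <- compare_groups(st, "elon1")
  expect_s3_class(res, "sama_test")
  expect_equal(res$reported_p,
               max(res$anova_p, res$wilcoxon_p))
  expect_gte(res$reported_p, res$anova_p)
  expect_gte(res$reported_p, res$wilcoxon_p)
  # per-stack means are the experimental unit: 3 units per condition
  expect_equal(res$groups$n, c(3L, 3L))

  td <- tidy(res)
  expect_equal(td$p_value[td$test == "reported"], res$reported_p)
  gl <- glance(res)
  expect_equal(gl$reported_p, res$reported_p)

  # identical groups: Wilcoxon p = 1, reported 1
  st2 <- st
  st2$elon1 <- rep(c(1, 2, 3, 4), length.out = nrow(st2))
  st2$elon1[st2$condition == "B"] <- st2$elon1[st2$condition == "A"]
  res2 <- compare_groups(st2, "elon1")
  expect_equal(res2$wilcoxon_p, 1)
  expect_equal(res2$reported_p, 1)

  # errors: single condition; undersized group
  expect_error(compare_groups(st[st$condition == "A", ], "elon1"),
               "two conditions")
  st3 <- st[!(st$condition == "B" & st$stack_id != "B_1"), ]
  expect_error(compare_groups(st3, "elon1"), "fewer than 2")
})

test_that("two-group ANOVA equals the squared equal-variance t-test", {
  set.seed(17)
  st <- toy_study()
  res <- compare_groups(st, "elon1")
  agg <- tapply(st$elon1, list(st$condition, st$stack_id), mean)
  x <- as.numeric(na.omit(agg["A", ])); y <- as.numeric(na.omit(agg["B", ]))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$anova_p, tt$p.value, tolerance = 1e-10)
})

test_that("pooled per-structure testing is flagged as pseudo-replication", {
  expect_warning(compare_groups(toy_study(), "elon1", unit = "structure"),
                 "pseudo-replication")
})

test_that("PCA matches an independent eigen-decomposition", {
  set.seed(18)
  n <- 60
  st <- tibble::tibble(
    condition = rep(c("A", "B"), each = n / 2),
    volume = rnorm(n), elon1 = rnorm(n), elon2 = rnorm(n),
    rve = rnorm(n), rlv = runif(n)
  )
  pca <- run_pca(st, c("volume", "elon1", "elon2", "rve", "rlv"))
  # orthonormal loadings
  expect_equal(crossprod(pca$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # against eigen() of the correlation matrix, up to sign
  ev <- eigen(cor(st[, c("volume", "elon1", "elon2", "rve", "rlv")]))
  expect_equal(pca$explained, ev$values / sum(ev$values), tolerance = 1e-10)
  for (k in 1:5) {
    a <- pca$loadings[, k]; b <- ev$vectors[, k]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
  }
  # explained variance sums to 1; scores are centred
  expect_equal(sum(pca$explained), 1)
  expect_equal(colMeans(pca$scores), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # tidy/glance structure
  expect_equal(nrow(tidy(pca)), 25)
  expect_equal(glance(pca)$cumulative[5], 1, tolerance = 1e-12)
})

test_that("perfectly correlated variables load on one component", {
  st <- tibble::tibble(condition = "A",
                       a = 1:30, b = 2 * (1:30) + 5)
  pca <- run_pca(st, c("a", "b"))
  expect_equal(pca$explained[1], 1, tolerance = 1e-12)
})

test_that("zero-variance variables are dropped with a warning", {
  st <- tibble::tibble(condition = "A", a = rnorm(20), b = rnorm(20), c = 1)
  expect_warning(pca <- run_pca(st, c("a", "b", "c")), "zero-variance")
  expect_equal(pca$variables, c("a", "b"))
})

test_that("reproducibility curves integrate to 1 and rank separation", {
  set.seed(19)
  st <- tibble::tibble(
    condition = "A",
    replicate = rep(c("r1", "r2"), each = 200),
    stack_id = rep(c("s1", "s2"), each = 200),
    v = c(rnorm(200), rnorm(200))
  )
  rc <- reproducibility_curves(st, "v")
  for (rn in c("r1", "r2")) {
    cur <- rc$curves[rc$curves$replicate == rn, ]
    area <- sum(diff(cur$x) * (head(cur$density, -1) + tail(cur$density, -1)) / 2)
    expect_lt(abs(area - 1), 0.01)
  }
  # identical replicates: KS distance 0
  st2 <- st
  st2$v[st2$replicate == "r2"] <- st2$v[st2$replicate == "r1"]
  rc2 <- reproducibility_curves(st2, "v")
  expect_equal(rc2$ks$ks_distance, 0)
  c1 <- rc2$curves[rc2$curves$replicate == "r1", "density"]
  c2 <- rc2$curves[rc2$curves$replicate == "r2", "density"]
  expect_equal(c1, c2)

  # a replicate shifted by 2 sd: KS distance > 0.5 (closed form ~ 0.68)
  st3 <- st
  st3$v[st3$replicate == "r2"] <- st3$v[st3$replicate == "r1"] + 2
  rc3 <- reproducibility_curves(st3, "v")
  expect_gt(rc3$ks$ks_distance, 0.5)

  # single replicate: curves only, no diagnostic
  rc4 <- reproducibility_curves(st[st$replicate == "r1", ], "v")
  expect_equal(nrow(rc4$ks), 0)
  expect_gt(nrow(rc4$curves), 0)
})

test_that("autoplot and plot helpers return ggplot objects", {
  st <- toy_study()
  expect_s3_class(plot_distribution(st, "elon1"), "ggplot")
  expect_s3_class(plot_boxplot(st, "elon1"), "ggplot")
  pca <- run_pca(st, c("volume", "elon1", "elon2", "rlv"))
  expect_s3_class(autoplot(pca, "variables"), "ggplot")
  expect_s3_class(autoplot(pca, "individuals"), "ggplot")
  expect_s3_class(autoplot(reproducibility_curves(st, "elon1")), "ggplot")
})

test_that("the report writes every promised artifact deterministically", {
  st <- toy_study()
  out1 <- file.path(tempdir(), "report_a")
  out2 <- file.path(tempdir(), "report_b")
  idx <- generate_report(st, out1, parameters = c("elon1", "rlv"))
  expect_true(file.exists(file.path(out1, "index.csv")))
  for (p in c("elon1", "rlv")) {
    expect_true(file.exists(file.path(out1, sprintf("summary_%s.csv", p))))
    expect_true(file.exists(file.path(out1, sprintf("tests_%s.csv", p))))
    expect_true(file.exists(file.path(out1, sprintf("dist_%s.pdf", p))))
    expect_true(file.exists(file.path(out1, sprintf("box_%s.pdf", p))))
  }
  # test CSVs carry both anova and wilcoxon p for a two-condition study
  tcsv <- read.csv(file.path(out1, "tests_elon1.csv"))
  expect_true(all(c("anova_p", "wilcoxon_p", "reported_p") %in% names(tcsv)))
  expect_false(any(is.na(tcsv$wilcoxon_p)))

  generate_report(st, out2, parameters = c("elon1", "rlv"))
  for (f in c("summary_elon1.csv", "tests_elon1.csv", "index.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # opt-in multiplicity adjustment collects all parameters with a BH column
  out3 <- file.path(tempdir(), "report_c")
  generate_report(st, out3, parameters = c("elon1", "rlv"), p_adjust = TRUE)
  tall <- read.csv(file.path(out3, "tests_all.csv"))
  expect_equal(nrow(tall), 2)
  expect_true(all(tall$reported_p_bh >= tall$reported_p - 1e-12))
  expect_equal(tall$reported_p_bh,
               p.adjust(tall$reported_p, method = "BH"))
  unlink(c(out1, out2, out3), recursive = TRUE)
})
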