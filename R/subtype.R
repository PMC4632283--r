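#' Hierarchical clustering of samples on a marker-gene panel
#'
#' Clusters the samples of an expression cohort on the submatrix of panel
#' genes using complete-linkage hierarchical clustering, the standard recipe
#' for marker-driven molecular subtyping. By default genes are standardized
#' (zero mean, unit variance across samples) and samples are compared by
#' correlation distance (1 - Pearson correlation between sample profiles);
#' Euclidean distance is available via `metric`. The tree is cut into `k`
#' classes and classes are renumbered by decreasing size (class 1 = largest).
#'
#' `k` reflects the expected number of subtypes in the cohort at hand — e.g.
#' 2 major classes under the Hoshida S1/S2/S3 panel and 3 under the Chiang
#' panel in liver cohorts — and is always the caller's choice.
#'
#' @param expression Expression tibble: `gene` column plus one numeric column
#'   per sample, log2 scale (see [read_expression_matrix()]).
#' @param panel Marker panel tibble with a `gene` column (and typically
#'   `subclass`, `source`; see [read_marker_panel()]). At least 2 panel genes
#'   must be present in the matrix.
#' @param k Number of classes to cut the tree into (2 <= k <= n_samples).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param standardize Standardize each gene across samples before clustering.
#'
#' @return An object of class `subtype_clustering`: list with `assignment`
#'   (tibble `sample`, `class` — integer class, 1 = largest), `tree` (the
#'   `hclust` object), `k`, `metric`, `linkage`, `panel_genes`. Has [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods.
#' @export
cluster_subtypes <- function(expression, panel, k = 2,
                             metric = c("correlation", "euclidean"),
                             standardize = TRUE) {
  metric <- match.arg(metric)
  m <- as_expr_matrix(expression)
  check_columns(panel, "gene", "marker panel")
  k <- check_count(k, "k", min = 2)
  if (k > ncol(m)) abort_bad_arg("k = %d exceeds the %d samples", k, ncol(m))
  found <- intersect(unique(panel$gene), rownames(m))
  if (length(found) < 2) {
    abort_bad_arg("fewer than 2 panel genes found in the matrix; missing: %s",
                  paste(setdiff(unique(panel$gene), rownames(m)), collapse = ", "))
  }
  sub <- m[found, , drop = FALSE]
  if (standardize) {
    sub <- t(apply(sub, 1, function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }))
    colnames(sub) <- colnames(m)
  }
  d <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(sub))
  } else {
    stats::dist(t(sub))
  }
  tree <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(tree, k = k)
  # renumber classes by decreasing size; ties keep first-seen order
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_len(k), names(sizes))
  cls <- unname(relabel[as.character(raw)])
  structure(list(
    assignment = tibble::tibble(sample = colnames(m), class = as.integer(cls)),
    tree = tree,
    k = k,
    metric = metric,
    linkage = "complete",
    panel_genes = found
  ), class = "subtype_clustering")
}

#' Golub-style signal-to-noise-ratio scores
#'
#' For each gene, computes the signal-to-noise ratio between a designated
#' sample class and its complement:
#' `snr = (mu1 - mu0) / (sigma1 + sigma0)`,
#' with class means `mu` and population (divide-by-n) standard deviations
#' `sigma`, each floored at `max(sd_floor_rel * |mu|, sd_floor_abs)` to keep
#' the ratio stable for near-constant genes — the convention of Golub-style
#' class scoring.
#'
#' @inheritParams cluster_subtypes
#' @param labels Sample annotation tibble with columns `sample` and `class`
#'   covering every matrix sample.
#' @param class The class label designating class 1; all other samples form
#'   class 0. Both classes must contain at least 2 samples.
#' @param sd_floor_rel,sd_floor_abs Relative and absolute floors applied to
#'   each class standard deviation.
#' @return A tibble with columns `gene`, `mu1`, `mu0`, `sigma1`, `sigma0`,
#'   `snr`.
#' @export
snr_scores <- function(expression, labels, class,
                       sd_floor_rel = 0.01, sd_floor_abs = 0.01) {
  m <- as_expr_matrix(expression)
  lab <- check_sample_labels(labels, colnames(m), "class")
  in1 <- lab == class
  if (sum(in1) < 2 || sum(!in1) < 2) {
    abort_bad_arg("both classes need >= 2 samples (class '%s': %d, rest: %d)",
                  as.character(class), sum(in1), sum(!in1))
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  m1 <- rowMeans(m[, in1, drop = FALSE])
  m0 <- rowMeans(m[, !in1, drop = FALSE])
  s1 <- apply(m[, in1, drop = FALSE], 1, pop_sd)
  s0 <- apply(m[, !in1, drop = FALSE], 1, pop_sd)
  floor_sd <- function(s, mu) pmax(s, sd_floor_rel * abs(mu), sd_floor_abs)
  s1 <- floor_sd(s1, m1)
  s0 <- floor_sd(s0, m0)
  tibble::tibble(gene = rownames(m), mu1 = unname(m1), mu0 = unname(m0),
                 sigma1 = unname(s1), sigma0 = unname(s0),
                 snr = unname((m1 - m0) / (s1 + s0)))
}

#' Attribute marker-panel genes to discovered classes
#'
#' Cross-tabulates a marker panel against a clustering: each panel gene is
#' attributed to the discovered class in which its signal-to-noise ratio
#' (that class vs the rest) is maximal, and the result is summarized per
#' panel subclass as the fraction of its genes landing in each class — the
#' computation behind statements like "84% of S1 marker genes were found in
#' class 1". Ties in the maximal SNR are broken toward the larger class and
#' reported via a message.
#'
#' @param clustering A [cluster_subtypes()] result whose samples match the
#'   matrix.
#' @param panel Marker panel tibble with columns `gene` and `subclass`.
#' @inheritParams cluster_subtypes
#' @param ... Passed on to [snr_scores()] (SNR floors).
#' @return A tibble with columns `subclass`, `class`, `n_genes`, `fraction`;
#'   fractions within each subclass sum to 1. Panel genes absent from the
#'   matrix are dropped with a message.
#' @export
marker_class_composition <- function(clustering, panel, expression, ...) {
  if (!inherits(clustering, "subtype_clustering")) {
    abort_bad_arg("`clustering` must be a cluster_subtypes() result")
  }
  check_columns(panel, c("gene", "subclass"), "marker panel")
  m <- as_expr_matrix(expression)
  missing <- setdiff(unique(panel$gene), rownames(m))
  if (length(missing) > 0) {
    rlang::inform(sprintf("dropping %d panel gene(s) absent from the matrix",
                          length(missing)))
    panel <- panel[!panel$gene %in% missing, , drop = FALSE]
  }
  if (nrow(panel) == 0) abort_bad_arg("no panel genes found in the matrix")
  labels <- clustering$assignment
  classes <- sort(unique(labels$class))
  snr_by_class <- vapply(classes, function(cl) {
    snr_scores(expression, labels, class = cl, ...)$snr
  }, numeric(nrow(m)))
  rownames(snr_by_class) <- rownames(m)
  class_sizes <- table(factor(labels$class, levels = classes))

  snr_panel <- snr_by_class[panel$gene, , drop = FALSE]
  attributed <- apply(snr_panel, 1, function(s) {
    best <- which(s == max(s))
    if (length(best) > 1) {
      best <- best[order(-class_sizes[best], best)][1]
    }
    classes[best]
  })
  n_ties <- sum(apply(snr_panel, 1, function(s) sum(s == max(s)) > 1))
  if (n_ties > 0) {
    rlang::inform(sprintf(
      "%d marker gene(s) had tied maximal SNR; ties broken toward the larger class",
      n_ties))
  }
  tibble::tibble(subclass = panel$subclass, class = attributed) |>
    dplyr::count(.data$subclass, .data$class, name = "n_genes") |>
    tidyr::complete(.data$subclass, class = classes,
                    fill = list(n_genes = 0L)) |>
    dplyr::group_by(.data$subclass) |>
    dplyr::mutate(fraction = .data$n_genes / sum(.data$n_genes)) |>
    dplyr::ungroup()
}

#' Kolmogorov-Smirnov differential expression
#'
#' Per-gene two-sample, two-sided Kolmogorov-Smirnov test between two sample
#' groups (e.g. tumor vs normal). The exact small-sample null distribution is
#' used when both groups have at most `exact_max` samples, the asymptotic
#' distribution otherwise. Raw p-values are reported; a Benjamini-Hochberg
#' adjusted column is emitted alongside for convenience.
#'
#' @inheritParams cluster_subtypes
#' @param groups Sample annotation tibble with columns `sample` and `group`;
#'   exactly two groups, each of size >= 2.
#' @param exact_max Largest group size for which the exact KS null is used.
#' @return A tibble with columns `gene`, `statistic` (D in [0, 1]), `p_value`,
#'   `p_adjust_bh`.
#' @export
ks_differential_expression <- function(expression, groups, exact_max = 25) {
  m <- as_expr_matrix(expression)
  lab <- check_sample_labels(groups, colnames(m), "group", "groups")
  lv <- unique(lab)
  if (length(lv) != 2) {
    abort_bad_arg("`groups` must define exactly 2 groups (got %d)", length(lv))
  }
  i1 <- lab == lv[1]
  if (sum(i1) < 2 || sum(!i1) < 2) {
    abort_bad_arg("both groups need >= 2 samples")
  }
  exact <- sum(i1) <= exact_max && sum(!i1) <= exact_max
  res <- apply(m, 1, function(x) {
    ks <- suppressWarnings(stats::ks.test(x[i1], x[!i1], exact = exact))
    c(ks$statistic, ks$p.value)
  })
  out <- tibble::tibble(gene = rownames(m),
                        statistic = unname(res[1, ]), p_value = unname(res[2, ]))
  out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Pearson correlation between two genes across samples
#'
#' Sample Pearson correlation of two genes' expression values across all
#' samples, with `R^2 = r^2` and a p-value from the t-distribution with
#' `n - 2` degrees of freedom.
#'
#' @inheritParams cluster_subtypes
#' @param gene_x,gene_y Gene identifiers present in the matrix.
#' @return A one-row tibble with columns `gene_x`, `gene_y`, `r`, `r_squared`,
#'   `statistic`, `p_value`, `n`.
#' @export
gene_correlation <- function(expression, gene_x, gene_y) {
  m <- as_expr_matrix(expression)
  for (g in c(gene_x, gene_y)) {
    if (!g %in% rownames(m)) abort_bad_arg("gene '%s' not found in the matrix", g)
  }
  if (ncol(m) < 3) abort_bad_arg("need >= 3 samples for a correlation p-value")
  x <- m[gene_x, ]
  y <- m[gene_y, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_bad_arg("gene '%s' has zero variance across samples",
                  if (stats::sd(x) == 0) gene_x else gene_y)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(gene_x = gene_x, gene_y = gene_y,
                 r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value,
                 n = length(x))
}
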