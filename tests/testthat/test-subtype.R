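panel_of <- function(genes) tibble::tibble(gene = genes, subclass = "S", source = "t")

test_that("clustering groups identical samples and recovers planted classes", {
  expr <- tibble::tibble(
    gene = paste0("g", 1:4),
    s1 = c(1, 2, 3, 4), s2 = c(1, 2, 3, 4), s3 = c(9, -4, 2, 0)
  )
  cl <- cluster_subtypes(expr, panel_of(paste0("g", 1:4)), k = 2)
  asg <- tidy(cl)
  expect_equal(asg$class[asg$sample == "s1"], asg$class[asg$sample == "s2"])
  expect_false(asg$class[asg$sample == "s3"] == asg$class[asg$sample == "s1"])
  # class 1 is the largest
  expect_equal(sort(table(asg$class), decreasing = TRUE)[[1]],
               sum(asg$class == 1))

  coh <- simulate_expression_cohort(n_genes = 200, n_samples = 40,
                                    markers_per_class = 20, effect_size = 3,
                                    within_sd = 1, seed = 31)
  cl2 <- cluster_subtypes(coh$expression, coh$panel, k = 2)
  expect_gt(ari(tidy(cl2)$class, coh$labels$class), 0.9)
})

test_that("clustering is invariant to gene and sample order and to sample duplication", {
  coh <- simulate_expression_cohort(n_genes = 60, n_samples = 16,
                                    markers_per_class = 10, effect_size = 3,
                                    seed = 12)
  base <- cluster_subtypes(coh$expression, coh$panel, k = 2)
  # permute genes and samples
  set.seed(13)
  shuf <- coh$expression[sample(nrow(coh$expression)), ]
  shuf <- shuf[, c(1, 1 + sample(ncol(shuf) - 1))]
  perm <- cluster_subtypes(shuf, coh$panel, k = 2)
  merged <- dplyr::inner_join(tidy(base), tidy(perm), by = "sample")
  expect_equal(ari(merged$class.x, merged$class.y), 1)
  # duplicating every sample leaves the partition unchanged (up to labels)
  dup <- coh$expression
  dup_cols <- dup[-1]
  names(dup_cols) <- paste0(names(dup_cols), "_copy")
  dup <- dplyr::bind_cols(dup, dup_cols)
  cl_dup <- cluster_subtypes(dup, coh$panel, k = 2)
  asg <- tidy(cl_dup)
  orig <- asg[!grepl("_copy$", asg$sample), ]
  copies <- asg[grepl("_copy$", asg$sample), ]
  copies$sample <- sub("_copy$", "", copies$sample)
  both <- dplyr::inner_join(orig, copies, by = "sample")
  expect_equal(both$class.x, both$class.y)
  expect_equal(ari(orig$class[order(orig$sample)], tidy(base)$class), 1)
})

test_that("clustering validates panels and k", {
  expr <- tibble::tibble(gene = c("a", "b"), s1 = 1:2, s2 = 2:1, s3 = c(0, 5))
  expect_error(cluster_subtypes(expr, panel_of(c("x", "y")), k = 2),
               "missing: x, y")
  expect_error(cluster_subtypes(expr, panel_of(c("a", "b")), k = 5),
               "exceeds")
})

test_that("SNR follows the Golub convention with population sigma and floors", {
  expr <- tibble::tibble(gene = "g1", s1 = 1, s2 = 3, s3 = -1, s4 = -3)
  labels <- tibble::tibble(sample = paste0("s", 1:4),
                           class = c("T", "T", "N", "N"))
  snr <- snr_scores(expr, labels, class = "T")
  # mu1 = 2, mu0 = -2, population sd = 1 in both classes -> snr = 4/2 = 2
  expect_equal(snr$mu1, 2)
  expect_equal(snr$mu0, -2)
  expect_equal(snr$sigma1, 1)
  expect_equal(snr$snr, 2)
  # identical class distributions -> snr = 0
  flat <- tibble::tibble(gene = "g1", s1 = 1, s2 = 2, s3 = 1, s4 = 2)
  expect_equal(snr_scores(flat, labels, class = "T")$snr, 0)
  # swapping the designation negates snr exactly
  expect_equal(snr_scores(expr, labels, class = "N")$snr, -2)
  # constant genes hit the absolute floor instead of dividing by zero
  const <- tibble::tibble(gene = "g1", s1 = 5, s2 = 5, s3 = 5, s4 = 5)
  expect_equal(snr_scores(const, labels, class = "T")$snr, 0)
  expect_error(snr_scores(expr, labels[-1, ], class = "T"), "lacks an entry")
  expect_error(
    snr_scores(expr, dplyr::mutate(labels, class = c("T", "N", "N", "N")), "T"),
    ">= 2 samples")
})

test_that("SNR is shift- and scale-invariant per gene", {
  coh <- simulate_expression_cohort(n_genes = 30, n_samples = 20,
                                    markers_per_class = 5, seed = 14)
  base <- snr_scores(coh$expression, coh$labels, class = "C1")
  shifted <- coh$expression
  shifted[-1] <- shifted[-1] + 7
  scaled <- coh$expression
  scaled[-1] <- scaled[-1] * 3
  expect_equal(snr_scores(shifted, coh$labels, class = "C1")$snr, base$snr,
               tolerance = 1e-6)
  expect_equal(snr_scores(scaled, coh$labels, class = "C1")$snr, base$snr,
               tolerance = 1e-6)
})

test_that("marker composition attributes planted markers to their class", {
  coh <- simulate_expression_cohort(n_genes = 120, n_samples = 30,
                                    markers_per_class = 15, effect_size = 4,
                                    within_sd = 1, seed = 15)
  cl <- cluster_subtypes(coh$expression, coh$panel, k = 2)
  comp <- marker_class_composition(cl, coh$panel, coh$expression)
  # fractions sum to 1 within each subclass
  sums <- dplyr::summarise(dplyr::group_by(comp, subclass),
                           total = sum(fraction))
  expect_equal(sums$total, rep(1, 2))
  # each planted marker set lands in one class entirely
  top <- dplyr::slice_max(dplyr::group_by(comp, subclass), fraction, n = 1)
  expect_equal(top$fraction, rep(1, 2))
  expect_false(top$class[1] == top$class[2])
  # the class containing the C1-shifted samples is the one C1 markers map to
  cls_of_c1 <- tidy(cl)$class[match(coh$labels$sample[coh$labels$class == "C1"],
                                    tidy(cl)$sample)]
  expect_equal(top$class[top$subclass == "C1"],
               as.integer(names(sort(table(cls_of_c1), decreasing = TRUE))[1]))
})

test_that("a single-gene subclass yields a unit composition row", {
  coh <- simulate_expression_cohort(n_genes = 60, n_samples = 24,
                                    markers_per_class = 8, seed = 16)
  panel <- rbind(coh$panel,
                 tibble::tibble(gene = "g0050", subclass = "solo", source = "t"))
  cl <- cluster_subtypes(coh$expression, coh$panel, k = 2)
  comp <- marker_class_composition(cl, panel, coh$expression)
  solo <- comp[comp$subclass == "solo", ]
  expect_equal(sort(solo$fraction), c(0, 1))
})

test_that("KS differential expression reproduces exact small-sample identities", {
  expr <- tibble::tibble(
    gene = c("same", "sep"),
    a1 = c(1, 1), a2 = c(2, 2), a3 = c(3, 3), a4 = c(4, 4),
    b1 = c(1, 5), b2 = c(2, 6), b3 = c(3, 7), b4 = c(4, 8)
  )
  groups <- tibble::tibble(sample = c(paste0("a", 1:4), paste0("b", 1:4)),
                           group = rep(c("tumor", "normal"), each = 4))
  de <- ks_differential_expression(expr, groups)
  # identical groups: D = 0, p = 1
  expect_equal(de$statistic[de$gene == "same"], 0)
  expect_equal(de$p_value[de$gene == "same"], 1)
  # fully separated supports: D = 1, exact p from exhaustive enumeration
  expect_equal(de$statistic[de$gene == "sep"], 1)
  expect_equal(de$p_value[de$gene == "sep"],
               enum_ks_pvalue(c(1, 2, 3, 4), c(5, 6, 7, 8)))
  expect_error(ks_differential_expression(expr, dplyr::mutate(groups, group = "x")),
               "exactly 2 groups")
})

test_that("KS p-values match the enumeration oracle on random small groups", {
  set.seed(17)
  for (i in 1:10) {
    x <- round(stats::rnorm(4), 3)
    y <- round(stats::rnorm(4) + 0.5, 3)
    expr <- tibble::tibble(gene = "g", !!!stats::setNames(as.list(c(x, y)),
                                                          paste0("s", 1:8)))
    groups <- tibble::tibble(sample = paste0("s", 1:8),
                             group = rep(c("t", "n"), each = 4))
    de <- ks_differential_expression(expr, groups)
    expect_equal(de$p_value, enum_ks_pvalue(x, y), tolerance = 1e-8)
  }
})

test_that("KS p-values are approximately uniform on a null cohort", {
  # coprime group sizes (29 vs 31) make the support of D fine enough for the
  # exact null p-values to be near-continuous
  coh <- simulate_expression_cohort(n_genes = 600, n_samples = 60,
                                    class_proportions = c(29, 31) / 60,
                                    effect_size = 0, seed = 18)
  groups <- dplyr::rename(coh$labels, group = class)
  de <- ks_differential_expression(coh$expression, groups, exact_max = 31)
  d <- suppressWarnings(stats::ks.test(de$p_value, "punif"))$statistic
  expect_lt(d, 1.63 / sqrt(nrow(de)))
})

test_that("gene correlation reproduces hand-computed Pearson results", {
  expr <- tibble::tibble(gene = c("x", "y", "z", "c"),
                         s1 = c(1, 3, -1, 2), s2 = c(2, 5, -2, 2),
                         s3 = c(3, 7, -3, 2))
  # y = 2x + 1 -> r = 1; z = -x -> r = -1
  expect_equal(gene_correlation(expr, "x", "y")$r, 1)
  expect_equal(gene_correlation(expr, "x", "y")$r_squared, 1)
  expect_equal(gene_correlation(expr, "x", "z")$r, -1)
  # hand-computed: x = (1,2,3), w = (1,3,2) -> r = 0.5
  expr2 <- tibble::tibble(gene = c("x", "w"), s1 = c(1, 1), s2 = c(2, 3),
                          s3 = c(3, 2))
  res <- gene_correlation(expr2, "x", "w")
  expect_equal(res$r, 0.5)
  expect_equal(res$r_squared, 0.25)
  # R^2 is symmetric in its arguments
  expect_equal(gene_correlation(expr2, "w", "x")$r_squared, res$r_squared)
  expect_error(gene_correlation(expr, "x", "c"), "zero variance")
  expect_error(gene_correlation(expr, "x", "nope"), "not found")
})
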