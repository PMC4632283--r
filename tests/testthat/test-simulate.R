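test_that("planted aCGH pairs have exactly the requested structure", {
  pair <- simulate_acgh_pair(10, n_shared_gains = 3, n_shared_losses = 0,
                             noise_sd = 0, seed = 1)
  expect_identical(pair$profile_a$probe_id, pair$profile_b$probe_id)
  expect_equal(sum(pair$profile_a$log2ratio == 0.6), 3)
  expect_equal(sum(pair$profile_b$log2ratio == 0.6), 3)
  expect_identical(which(pair$profile_a$log2ratio == 0.6),
                   which(pair$profile_b$log2ratio == 0.6))
  expect_true(all(pair$profile_a$log2ratio %in% c(0, 0.6)))
  # ground truth conserves the planted counts exactly
  expect_equal(sum(pair$truth$state_a == "gain"), 3)
  expect_equal(sum(pair$truth$state_b == "gain"), 3)

  priv <- simulate_acgh_pair(10, 0, 0, n_private_a = 2, noise_sd = 0, seed = 2)
  expect_equal(sum(priv$profile_a$log2ratio != 0), 2)
  expect_true(all(priv$profile_b$log2ratio == 0))
  expect_equal(sum(priv$truth$state_a != "neutral"), 2)
  expect_true(all(priv$truth$state_b == "neutral"))
})

test_that("aCGH pair generation is deterministic under a fixed seed", {
  p1 <- simulate_acgh_pair(200, 10, 10, 5, 5, noise_sd = 0.1, seed = 99)
  p2 <- simulate_acgh_pair(200, 10, 10, 5, 5, noise_sd = 0.1, seed = 99)
  expect_identical(p1, p2)
  p3 <- simulate_acgh_pair(200, 10, 10, 5, 5, noise_sd = 0.1, seed = 100)
  expect_false(identical(p1$profile_a$log2ratio, p3$profile_a$log2ratio))
})

test_that("aCGH pair generation rejects position-count overflow", {
  expect_error(simulate_acgh_pair(10, 6, 5, noise_sd = 0),
               "exceeds n_probes")
  expect_error(simulate_acgh_pair(100, 10, 10, gain_level = -1),
               "gain_level")
  expect_error(simulate_acgh_pair(100, 10, 10, noise_sd = -0.1), "noise_sd")
})

test_that("null pairs place aberrations independently with the closed-form match rate", {
  # 10 aberrant in each of two samples on 100 probes, signs fair coins:
  # E[sign-specific matches] = 10 * (10/100) * (1/2) = 0.5
  counts <- vapply(1:2000, function(s) {
    pair <- simulate_null_pair(100, 10, 10, seed = s)
    count_matching_positions(pair$a, pair$b)
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 0.5), 3 * se)
})

test_that("null pair generation handles edge counts and is deterministic", {
  pair <- simulate_null_pair(50, 0, 5, seed = 1)
  expect_true(all(pair$a$state == "neutral"))
  expect_equal(sum(pair$b$state != "neutral"), 5)
  expect_identical(simulate_null_pair(50, 3, 4, seed = 7),
                   simulate_null_pair(50, 3, 4, seed = 7))
  expect_error(simulate_null_pair(10, 11, 2), "exceed")
})

test_that("expression cohorts plant marker shifts only in the marker's class", {
  coh <- simulate_expression_cohort(n_genes = 50, n_samples = 6, n_classes = 2,
                                    markers_per_class = 5, effect_size = 4,
                                    within_sd = 0, seed = 3)
  m <- as.matrix(coh$expression[-1])
  rownames(m) <- coh$expression$gene
  cls <- coh$labels$class
  # noiseless limit: matrix equals the mean structure exactly
  marker <- coh$panel$gene[coh$panel$subclass == "C1"][1]
  non_marker <- setdiff(coh$expression$gene, coh$panel$gene)[1]
  expect_equal(unique(round(m[marker, cls == "C1"] - m[marker, cls == "C2"], 10)), 4)
  expect_equal(unique(round(m[non_marker, cls == "C1"] - m[non_marker, cls == "C2"], 10)), 0)
  # each sample column is constant within a gene given sd -> 0
  expect_equal(length(unique(round(m[marker, cls == "C1"], 10))), 1)
})

test_that("a null expression cohort carries no class signal beyond noise", {
  coh <- simulate_expression_cohort(n_genes = 100, n_samples = 40,
                                    effect_size = 0, seed = 8)
  snr <- snr_scores(coh$expression, coh$labels, class = "C1")
  # permuted-label null for the same cohort gives the same SNR spread
  set.seed(81)
  perm <- coh$labels
  perm$class <- sample(perm$class)
  snr_perm <- snr_scores(coh$expression, perm, class = "C1")
  expect_lt(abs(max(abs(snr$snr)) - max(abs(snr_perm$snr))), 1)
  expect_gt(suppressWarnings(stats::ks.test(abs(snr$snr), abs(snr_perm$snr))$p.value),
            0.01)
})

test_that("expression cohort generation rejects empty classes", {
  expect_error(simulate_expression_cohort(n_samples = 3, n_classes = 2,
                                          class_proportions = c(0.99, 0.01)),
               "no samples")
  expect_error(simulate_expression_cohort(class_proportions = c(0.5, 0.4)),
               "summing to 1")
})

test_that("methylation cohorts respect window geometry and beta bounds", {
  coh <- simulate_methylation_cohort(n_genes = 10, probes_per_promoter = 3,
                                     promoter_window = 2000, n_tumor = 4,
                                     n_normal = 4, n_dm_genes = 2, seed = 5)
  betas <- as.matrix(coh$betas[-(1:3)])
  expect_true(all(betas >= 0 & betas <= 1))
  mapping <- map_probes_to_promoters(coh$betas[c("probe_id", "chrom", "pos")],
                                     coh$tss)
  # promoter probes map, decoys never do
  expect_equal(nrow(mapping), 10 * 3)
  expect_false(any(coh$truth$decoy_probes %in% mapping$probe_id))
  # single-probe promoters: mean equals the probe's beta
  coh1 <- simulate_methylation_cohort(n_genes = 4, probes_per_promoter = 1,
                                      n_tumor = 3, n_normal = 3, n_dm_genes = 1,
                                      seed = 6)
  map1 <- map_probes_to_promoters(coh1$betas[c("probe_id", "chrom", "pos")],
                                  coh1$tss)
  means <- promoter_methylation_means(coh1$betas, map1)
  one <- means[means$gene == "gene001", ]
  probe <- coh1$betas[coh1$betas$probe_id == map1$probe_id[map1$gene == "gene001"], ]
  expect_equal(one$tumor01, probe$tumor01)
  expect_equal(one$normal03, probe$normal03)
})

test_that("a zero-delta methylation cohort shows only noise differences", {
  coh <- simulate_methylation_cohort(n_genes = 10, delta_beta = 0,
                                     n_dm_genes = 5, n_tumor = 6, n_normal = 6,
                                     seed = 9)
  mapping <- map_probes_to_promoters(coh$betas[c("probe_id", "chrom", "pos")],
                                     coh$tss)
  means <- promoter_methylation_means(coh$betas, mapping)
  cmp <- compare_promoter_methylation(means, coh$groups)
  expect_true(all(abs(cmp$delta_beta) < 0.15))
  expect_gt(min(cmp$p_value), 0.001)
})
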