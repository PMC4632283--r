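# Synthetic cohorts with planted ground truth. Every generator is a pure
# function of its arguments including `seed`; planted aberration/marker/DM
# counts in the returned truth equal the requested counts exactly.

# Abstract probe grid on a single linear coordinate; chromosome structure is
# cosmetic and does not affect any downstream statistic.
probe_grid <- function(n_probes) {
  i <- seq_len(n_probes)
  tibble::tibble(
    chrom = "chr1",
    start = (i - 1L) * 1000L,
    end = (i - 1L) * 1000L + 60L,
    probe_id = sprintf("p%06d", i)
  )
}

#' Simulate a primary/metastasis aCGH profile pair with planted aberrations
#'
#' Generates two log2-ratio probe profiles on an identical probe grid with a
#' controllable number of shared aberrant positions (same sign in both
#' samples), private aberrant positions (aberrant in exactly one sample), and
#' i.i.d. Gaussian probe noise. All planted position sets are disjoint.
#' Private probes are assigned gain or loss with equal probability.
#'
#' Defaults emulate a clonal tumor/metastasis pair on a small array: aberrant
#' probes at log2 ratio ±0.6, comfortably beyond the 0.25 calling threshold at
#' the default noise level.
#'
#' @param n_probes Number of probes on the grid.
#' @param n_shared_gains,n_shared_losses Aberrant positions planted in BOTH
#'   samples with the same sign.
#' @param n_private_a,n_private_b Aberrant positions unique to each sample.
#' @param gain_level,loss_level True mean log2 ratio of gained / lost probes
#'   (`gain_level > 0 > loss_level`).
#' @param noise_sd Per-probe Gaussian noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#'
#' @return A list with `profile_a`, `profile_b` (probe-profile tibbles, see
#'   [call_aberrations()]) and `truth`, a tibble with per-probe planted states
#'   `state_a`, `state_b`.
#' @export
simulate_acgh_pair <- function(n_probes, n_shared_gains = 30, n_shared_losses = 30,
                               n_private_a = 0, n_private_b = 0,
                               gain_level = 0.6, loss_level = -0.6,
                               noise_sd = 0.1, seed = NULL) {
  n_probes <- check_count(n_probes, "n_probes", min = 1)
  sg <- check_count(n_shared_gains, "n_shared_gains")
  sl <- check_count(n_shared_losses, "n_shared_losses")
  pa <- check_count(n_private_a, "n_private_a")
  pb <- check_count(n_private_b, "n_private_b")
  gain_level <- check_number(gain_level, "gain_level")
  loss_level <- check_number(loss_level, "loss_level")
  noise_sd <- check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort_bad_arg("`noise_sd` must be >= 0")
  if (gain_level <= 0 || loss_level >= 0) {
    abort_bad_arg("need gain_level > 0 > loss_level (got %g, %g)",
                  gain_level, loss_level)
  }
  total <- sg + sl + pa + pb
  if (total > n_probes) {
    abort_bad_arg(paste0("planted positions must be disjoint: n_shared_gains + ",
                         "n_shared_losses + n_private_a + n_private_b = %d ",
                         "exceeds n_probes = %d"), total, n_probes)
  }
  set_seed_if_given(seed)
  pos <- sample.int(n_probes, total)
  idx_sg <- pos[seq_len(sg)]
  idx_sl <- pos[sg + seq_len(sl)]
  idx_pa <- pos[sg + sl + seq_len(pa)]
  idx_pb <- pos[sg + sl + pa + seq_len(pb)]

  state_a <- state_b <- rep("neutral", n_probes)
  state_a[idx_sg] <- state_b[idx_sg] <- "gain"
  state_a[idx_sl] <- state_b[idx_sl] <- "loss"
  state_a[idx_pa] <- sample(c("gain", "loss"), pa, replace = TRUE)
  state_b[idx_pb] <- sample(c("gain", "loss"), pb, replace = TRUE)

  level <- function(st) {
    ifelse(st == "gain", gain_level, ifelse(st == "loss", loss_level, 0))
  }
  grid <- probe_grid(n_probes)
  profile_a <- dplyr::mutate(grid,
    log2ratio = level(state_a) + stats::rnorm(n_probes, sd = noise_sd))
  profile_b <- dplyr::mutate(grid,
    log2ratio = level(state_b) + stats::rnorm(n_probes, sd = noise_sd))
  list(
    profile_a = profile_a,
    profile_b = profile_b,
    truth = dplyr::mutate(grid, state_a = state_a, state_b = state_b)
  )
}

#' Simulate an unrelated (null) pair of aberration-call profiles
#'
#' Draws the two samples' aberrant position sets independently and uniformly
#' without replacement over a shared probe grid, assigning gain or loss with
#' equal probability at each aberrant probe. Used to calibrate the null of
#' [clonality_test()].
#'
#' @param n_probes Grid size.
#' @param n_aberrant_a,n_aberrant_b Aberrant probe counts per sample
#'   (each `<= n_probes`).
#' @param seed Optional integer seed.
#' @return A list with aberration-call tibbles `a` and `b`.
#' @export
simulate_null_pair <- function(n_probes, n_aberrant_a, n_aberrant_b, seed = NULL) {
  n_probes <- check_count(n_probes, "n_probes", min = 1)
  ka <- check_count(n_aberrant_a, "n_aberrant_a")
  kb <- check_count(n_aberrant_b, "n_aberrant_b")
  if (ka > n_probes || kb > n_probes) {
    abort_bad_arg("aberrant counts (%d, %d) must not exceed n_probes = %d",
                  ka, kb, n_probes)
  }
  set_seed_if_given(seed)
  grid <- probe_grid(n_probes)
  draw <- function(k) {
    st <- rep("neutral", n_probes)
    st[sample.int(n_probes, k)] <- sample(c("gain", "loss"), k, replace = TRUE)
    dplyr::mutate(grid, state = st)
  }
  list(a = draw(ka), b = draw(kb))
}

#' Simulate an expression cohort with planted sample classes
#'
#' Builds a gene-by-sample log2 expression matrix in which a designated set of
#' marker genes is shifted upward by `effect_size` in the samples of its own
#' class, on top of gene-specific baselines and Gaussian residual noise — the
#' planted analogue of a tumor cohort carrying molecular subtypes defined by
#' published marker panels.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_classes Number of planted sample classes.
#' @param class_proportions Optional per-class sample fractions (must sum
#'   to 1); equal by default. Every class must receive at least one sample.
#' @param markers_per_class Marker genes planted per class (the first
#'   `n_classes * markers_per_class` genes, in blocks); ignored when
#'   `marker_assignment` is supplied.
#' @param marker_assignment Optional tibble (`gene`, `class`) giving an
#'   explicit marker mapping; genes must exist, classes must be in
#'   `1:n_classes`, one class per gene.
#' @param effect_size Mean log2 shift of a marker gene in its own class.
#' @param within_sd Residual per-gene standard deviation (>= 0; 0 gives the
#'   noiseless mean structure).
#' @param base_mean,base_sd Gene baseline means are drawn from
#'   `N(base_mean, base_sd)`, the scale of RMA-normalized log2 intensities.
#' @param seed Optional integer seed.
#'
#' @return A list with `expression` (tibble: `gene` column plus one column per
#'   sample), `labels` (tibble `sample`, `class` with classes `"C1"...`), and
#'   `panel` (tibble `gene`, `subclass`, `source = "simulated"` for the
#'   planted markers).
#' @export
simulate_expression_cohort <- function(n_genes = 200, n_samples = 60,
                                       n_classes = 2, class_proportions = NULL,
                                       markers_per_class = 20,
                                       marker_assignment = NULL,
                                       effect_size = 3, within_sd = 1,
                                       base_mean = 7, base_sd = 1,
                                       seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  n_samples <- check_count(n_samples, "n_samples", min = 1)
  n_classes <- check_count(n_classes, "n_classes", min = 1)
  effect_size <- check_number(effect_size, "effect_size")
  within_sd <- check_number(within_sd, "within_sd")
  if (within_sd < 0) abort_bad_arg("`within_sd` must be >= 0")
  props <- class_proportions %||% rep(1 / n_classes, n_classes)
  if (length(props) != n_classes || any(props < 0) ||
      abs(sum(props) - 1) > 1e-8) {
    abort_bad_arg("`class_proportions` must be %d non-negative fractions summing to 1",
                  n_classes)
  }
  counts <- floor(props * n_samples)
  # distribute the remainder to the largest fractional parts
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    frac <- props * n_samples - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  if (any(counts == 0)) {
    abort_bad_arg("class %d would receive no samples; increase n_samples or its proportion",
                  which(counts == 0)[1])
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(marker_assignment)) {
    mpc <- check_count(markers_per_class, "markers_per_class")
    if (mpc * n_classes > n_genes) {
      abort_bad_arg("markers_per_class * n_classes = %d exceeds n_genes = %d",
                    mpc * n_classes, n_genes)
    }
    marker_assignment <- tibble::tibble(
      gene = genes[seq_len(mpc * n_classes)],
      class = rep(seq_len(n_classes), each = mpc)
    )
  } else {
    check_columns(marker_assignment, c("gene", "class"), "marker_assignment")
    if (!all(marker_assignment$gene %in% genes)) {
      abort_bad_arg("marker_assignment names genes outside the matrix")
    }
    if (anyDuplicated(marker_assignment$gene) ||
        !all(marker_assignment$class %in% seq_len(n_classes))) {
      abort_bad_arg("marker_assignment must map each gene to one class in 1..%d",
                    n_classes)
    }
  }
  set_seed_if_given(seed)
  samples <- sprintf("s%03d", seq_len(n_samples))
  sample_class <- rep(seq_len(n_classes), counts)
  base <- stats::rnorm(n_genes, base_mean, base_sd)
  mu <- matrix(base, n_genes, n_samples)
  gene_class <- marker_assignment$class[match(genes, marker_assignment$gene)]
  for (c in seq_len(n_classes)) {
    rows <- which(!is.na(gene_class) & gene_class == c)
    cols <- which(sample_class == c)
    mu[rows, cols] <- mu[rows, cols] + effect_size
  }
  values <- mu + matrix(stats::rnorm(n_genes * n_samples, sd = within_sd),
                        n_genes, n_samples)
  expr <- tibble::as_tibble(as.data.frame(values))
  names(expr) <- samples
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes), expr)
  list(
    expression = expr,
    labels = tibble::tibble(sample = samples,
                            class = paste0("C", sample_class)),
    panel = tibble::tibble(gene = marker_assignment$gene,
                           subclass = paste0("C", marker_assignment$class),
                           source = "simulated")
  )
}

#' Simulate a promoter methylation cohort with planted tumor/normal differences
#'
#' Generates probe-level beta values for tumor and normal samples, with each
#' gene covered by `probes_per_promoter` probes placed within
#' `promoter_window` bp of its TSS plus one decoy probe placed outside the
#' window (to exercise the window filter downstream). A designated subset of
#' genes carries a planted mean beta shift `delta_beta` in tumor samples
#' across its promoter probes; decoy probes never carry the shift. Betas are
#' truncated-Gaussian: Gaussian noise around the gene baseline, clipped to
#' [0, 1].
#'
#' @param n_genes Genes, each with one strand-aware TSS (strands alternate).
#' @param probes_per_promoter Promoter probes per gene (>= 1).
#' @param promoter_window Half-width of the promoter window in bp.
#' @param n_tumor,n_normal Sample counts per group.
#' @param delta_beta Planted tumor-minus-normal mean beta difference for the
#'   first `n_dm_genes` genes (negative = hypomethylated in tumor).
#' @param n_dm_genes Number of differentially methylated genes.
#' @param noise_sd Per-probe beta noise standard deviation before clipping.
#' @param seed Optional integer seed.
#'
#' @return A list with `betas` (tibble: `probe_id`, `chrom`, `pos` (1-based),
#'   one column per sample), `tss` (BED-style tibble `chrom`, `start`, `end`,
#'   `gene`, `score`, `strand`), `groups` (tibble `sample`, `group` with
#'   levels `"tumor"`/`"normal"`), and `truth` (list: `dm_genes`,
#'   `decoy_probes`).
#' @export
simulate_methylation_cohort <- function(n_genes = 30, probes_per_promoter = 3,
                                        promoter_window = 2000,
                                        n_tumor = 10, n_normal = 10,
                                        delta_beta = -0.3, n_dm_genes = 5,
                                        noise_sd = 0.05, seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  ppp <- check_count(probes_per_promoter, "probes_per_promoter", min = 1)
  promoter_window <- check_count(promoter_window, "promoter_window", min = 1)
  n_tumor <- check_count(n_tumor, "n_tumor", min = 1)
  n_normal <- check_count(n_normal, "n_normal", min = 1)
  n_dm <- check_count(n_dm_genes, "n_dm_genes")
  delta_beta <- check_number(delta_beta, "delta_beta")
  if (n_dm > n_genes) abort_bad_arg("n_dm_genes exceeds n_genes")
  set_seed_if_given(seed)

  genes <- sprintf("gene%03d", seq_len(n_genes))
  strand <- rep(c("+", "-"), length.out = n_genes)
  tss_pos <- 100000L * seq_len(n_genes)            # 1-based TSS coordinate
  gene_len <- 2000L
  # BED intervals span the gene body; the TSS sits at the start for "+"
  # strand genes and at the end for "-" strand genes
  tss <- tibble::tibble(
    chrom = "chr1",
    start = ifelse(strand == "+", tss_pos - 1L, tss_pos - gene_len),
    end = ifelse(strand == "+", tss_pos - 1L + gene_len, tss_pos),
    gene = genes,
    score = 0L,
    strand = strand
  )

  samples <- c(sprintf("tumor%02d", seq_len(n_tumor)),
               sprintf("normal%02d", seq_len(n_normal)))
  is_tumor <- rep(c(TRUE, FALSE), c(n_tumor, n_normal))
  baseline <- stats::runif(n_genes, 0.35, 0.65)

  rows <- vector("list", n_genes)
  for (gi in seq_len(n_genes)) {
    offs <- sample.int(2L * promoter_window + 1L, ppp, replace = FALSE) -
      promoter_window - 1L                         # in [-window, window]
    decoy_off <- (promoter_window + sample.int(1500L, 1L) + 499L) *
      sample(c(-1L, 1L), 1L)                       # |off| > window
    pos <- tss_pos[gi] + c(offs, decoy_off)
    shift <- if (gi <= n_dm) delta_beta else 0
    mean_mat <- matrix(baseline[gi], ppp + 1L, length(samples))
    if (shift != 0) mean_mat[seq_len(ppp), is_tumor] <-
        mean_mat[seq_len(ppp), is_tumor] + shift
    beta <- mean_mat + matrix(stats::rnorm(length(mean_mat), sd = noise_sd),
                              nrow = nrow(mean_mat))
    beta <- pmin(pmax(beta, 0), 1)
    colnames(beta) <- samples
    rows[[gi]] <- dplyr::bind_cols(
      tibble::tibble(
        probe_id = sprintf("%s_cg%02d", genes[gi], seq_len(ppp + 1L)),
        chrom = "chr1",
        pos = pos
      ),
      tibble::as_tibble(as.data.frame(beta))
    )
  }
  betas <- dplyr::arrange(dplyr::bind_rows(rows), .data$pos)
  decoys <- sprintf("%s_cg%02d", genes, ppp + 1L)
  list(
    betas = betas,
    tss = tss,
    groups = tibble::tibble(sample = samples,
                            group = ifelse(is_tumor, "tumor", "normal")),
    truth = list(dm_genes = genes[seq_len(n_dm)], decoy_probes = decoys)
  )
}
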