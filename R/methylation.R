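#' Map methylation probes into promoter windows
#'
#' Assigns each methylation probe to every gene whose transcription start
#' site (TSS) lies within `window` bp of the probe: probe `p` maps to gene
#' `g` iff `|pos(p) - TSS(g)| <= window` (closed interval, symmetric around
#' the TSS). Strand is used only to locate the TSS — the start of the BED
#' interval for `+` genes, the end for `-` genes — not to make the window
#' asymmetric. A probe may map to multiple genes. Genes whose promoter
#' receives no probe are reported via a message.
#'
#' @param probes Probe coordinate tibble with columns `probe_id`, `chrom`,
#'   `pos` (1-based platform-manifest convention; see [read_beta_table()]).
#' @param tss TSS annotation tibble in BED layout: `chrom`, `start`, `end`
#'   (0-based half-open), `gene`, `score`, `strand`; one row per gene.
#' @param window Promoter half-width in bp (default 2000).
#' @return A tibble with columns `gene`, `probe_id`, `chrom`, `pos`, `tss`
#'   (1-based TSS coordinate) and `distance` (`pos - tss`).
#' @export
map_probes_to_promoters <- function(probes, tss, window = 2000) {
  check_columns(probes, c("probe_id", "chrom", "pos"), "probe table")
  check_columns(tss, c("chrom", "start", "end", "gene", "strand"), "TSS table")
  window <- check_count(window, "window", min = 0)
  if (!is.numeric(probes$pos) || any(!is.finite(probes$pos)) || any(probes$pos < 1)) {
    abort_bad_arg("probe `pos` must be finite 1-based coordinates")
  }
  if (any(!is.finite(tss$start)) || any(!is.finite(tss$end)) ||
      any(tss$start >= tss$end) || any(tss$start < 0)) {
    abort_bad_arg("malformed TSS intervals: need 0 <= start < end")
  }
  if (!all(tss$strand %in% c("+", "-"))) {
    abort_bad_arg("TSS strand must be '+' or '-'")
  }
  if (anyDuplicated(tss$gene)) {
    abort_bad_arg("TSS table must have one row per gene; duplicated: %s",
                  paste(unique(tss$gene[duplicated(tss$gene)]), collapse = ", "))
  }
  tss_pos <- dplyr::mutate(
    tss[c("chrom", "gene", "start", "end", "strand")],
    tss = ifelse(.data$strand == "+", .data$start + 1L, .data$end)
  )[c("chrom", "gene", "tss")]
  mapped <- dplyr::inner_join(tss_pos, probes, by = "chrom",
                              relationship = "many-to-many") |>
    dplyr::mutate(distance = .data$pos - .data$tss) |>
    dplyr::filter(abs(.data$distance) <= window) |>
    dplyr::select("gene", "probe_id", "chrom", "pos", "tss", "distance")
  unmapped <- setdiff(tss$gene, mapped$gene)
  if (length(unmapped) > 0) {
    rlang::inform(sprintf("%d gene(s) have no probe within %d bp of the TSS: %s",
                          length(unmapped), window,
                          paste(unmapped, collapse = ", ")))
  }
  mapped
}

#' Per-gene mean promoter methylation
#'
#' Averages probe-level beta values over each gene's promoter probes, per
#' sample — regions covered by multiple probes are summarized by their
#' arithmetic mean. Genes with no mapped probe are simply absent from the
#' mapping and hence from the output.
#'
#' @param betas Beta table: tibble with columns `probe_id`, `chrom`, `pos` and
#'   one numeric column in [0, 1] per sample.
#' @param mapping Promoter mapping from [map_probes_to_promoters()]; every
#'   mapped probe must be present in `betas` with a beta for every sample.
#' @return A tibble with columns `gene`, `n_probes` and one mean-beta column
#'   per sample.
#' @export
promoter_methylation_means <- function(betas, mapping) {
  check_columns(betas, c("probe_id", "chrom", "pos"), "beta table")
  check_columns(mapping, c("gene", "probe_id"), "promoter mapping")
  sample_cols <- setdiff(names(betas), c("probe_id", "chrom", "pos"))
  if (length(sample_cols) == 0) abort_bad_arg("beta table has no sample columns")
  missing <- setdiff(mapping$probe_id, betas$probe_id)
  if (length(missing) > 0) {
    abort_bad_arg("mapped probe(s) absent from the beta table: %s",
                  paste(missing, collapse = ", "))
  }
  vals <- betas[c("probe_id", sample_cols)]
  if (anyNA(vals[sample_cols])) {
    abort_bad_arg("beta table contains missing values for mapped samples")
  }
  dplyr::inner_join(mapping[c("gene", "probe_id")], vals, by = "probe_id") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_probes = dplyr::n(),
                     dplyr::across(dplyr::all_of(sample_cols), mean)) |>
    dplyr::ungroup()
}

#' Compare promoter methylation between tumor and normal samples
#'
#' Per gene, compares mean promoter betas between two sample groups with a
#' two-sample, two-sided test (Kolmogorov-Smirnov by default, consistent with
#' the expression module; Wilcoxon rank-sum via `method`), and reports the
#' direction of the shift in the designated tumor group: `"hypo"` when the
#' tumor mean is lower, `"hyper"` when higher, `"none"` when the means are
#' exactly equal.
#'
#' @param table Promoter methylation table from
#'   [promoter_methylation_means()].
#' @param groups Sample annotation tibble with columns `sample` and `group`;
#'   exactly two groups of size >= 2.
#' @param tumor_level The `group` value treated as tumor (direction
#'   reference); default `"tumor"`.
#' @param method `"ks"` or `"wilcoxon"`.
#' @return A tibble with columns `gene`, `n_probes`, `direction`,
#'   `delta_beta` (tumor mean - other mean), `statistic`, `p_value`,
#'   `p_adjust_bh`.
#' @export
compare_promoter_methylation <- function(table, groups, tumor_level = "tumor",
                                         method = c("ks", "wilcoxon")) {
  method <- match.arg(method)
  check_columns(table, c("gene", "n_probes"), "promoter methylation table")
  sample_cols <- setdiff(names(table), c("gene", "n_probes"))
  lab <- check_sample_labels(groups, sample_cols, "group", "groups")
  lv <- unique(lab)
  if (length(lv) != 2) {
    abort_bad_arg("`groups` must define exactly 2 groups (got %d)", length(lv))
  }
  if (!tumor_level %in% lv) {
    abort_bad_arg("tumor_level '%s' is not one of the groups (%s)",
                  tumor_level, paste(lv, collapse = ", "))
  }
  it <- lab == tumor_level
  if (sum(it) < 2 || sum(!it) < 2) abort_bad_arg("both groups need >= 2 samples")
  m <- as.matrix(table[sample_cols])
  res <- apply(m, 1, function(x) {
    ht <- if (method == "ks") {
      suppressWarnings(stats::ks.test(x[it], x[!it]))
    } else {
      suppressWarnings(stats::wilcox.test(x[it], x[!it]))
    }
    c(mean(x[it]) - mean(x[!it]), unname(ht$statistic), ht$p.value)
  })
  out <- tibble::tibble(
    gene = table$gene,
    n_probes = table$n_probes,
    delta_beta = unname(res[1, ]),
    direction = dplyr::case_when(res[1, ] < 0 ~ "hypo",
                                 res[1, ] > 0 ~ "hyper",
                                 TRUE ~ "none"),
    statistic = unname(res[2, ]),
    p_value = unname(res[3, ])
  )
  out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  out[c("gene", "n_probes", "direction", "delta_beta",
        "statistic", "p_value", "p_adjust_bh")]
}
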