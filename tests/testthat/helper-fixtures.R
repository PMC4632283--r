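# Small in-code fixture builders and independent oracles.

# probe profile on an abstract grid from a vector of log2 ratios
make_profile <- function(log2ratios) {
  n <- length(log2ratios)
  tibble::tibble(
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 60L,
    probe_id = sprintf("p%06d", seq_len(n)),
    log2ratio = log2ratios
  )
}

# aberration calls from a vector of states ("gain"/"loss"/"neutral")
make_calls <- function(states) {
  prof <- make_profile(rep(0, length(states)))
  prof$log2ratio <- NULL
  prof$state <- states
  prof
}

# brute-force match count between two state vectors, by direct per-probe
# comparison (oracle for count_matching_positions)
brute_matches <- function(sa, sb, mode = "sign_specific") {
  n <- 0L
  for (i in seq_along(sa)) {
    ab_a <- sa[i] != "neutral"
    ab_b <- sb[i] != "neutral"
    hit <- if (mode == "sign_specific") ab_a && ab_b && sa[i] == sb[i] else ab_a && ab_b
    n <- n + as.integer(hit)
  }
  n
}

# exact two-sided two-sample KS p-value by exhaustive enumeration of all
# choose(n1 + n2, n1) group assignments of the pooled values (oracle;
# assumes no ties between pooled values)
enum_ks_pvalue <- function(x, y) {
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
  }
  pool <- c(x, y)
  d_obs <- ks_stat(x, y)
  splits <- utils::combn(length(pool), length(x))
  d_all <- apply(splits, 2, function(idx) ks_stat(pool[idx], pool[-idx]))
  mean(d_all >= d_obs - 1e-12)
}

# adjusted Rand index between two labelings (independent oracle via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
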