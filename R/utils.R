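# Internal helpers shared across modules.

STATE_LEVELS <- c("loss", "neutral", "gain")

PROBE_COLS <- c("chrom", "start", "end", "probe_id", "log2ratio")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "hccstats_error")
}

check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort_bad_arg("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", "))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort_bad_arg("`%s` must be a single integer >= %d (got %s)",
                  name, min, paste(x, collapse = ","))
  }
  as.integer(x)
}

check_number <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    abort_bad_arg("`%s` must be a single finite number", name)
  }
  as.numeric(x)
}

# Probe grids must be positionally comparable across samples: identity is
# checked on the probe_id sequence, not on coordinates alone.
check_same_grid <- function(a, b, what_a = "a", what_b = "b") {
  if (nrow(a) != nrow(b)) {
    abort_bad_arg("probe grids differ: %s has %d probes, %s has %d",
                  what_a, nrow(a), what_b, nrow(b))
  }
  diff <- which(a$probe_id != b$probe_id)
  if (length(diff) > 0) {
    abort_bad_arg("probe grids differ at position %d: '%s' vs '%s'",
                  diff[1], a$probe_id[diff[1]], b$probe_id[diff[1]])
  }
  invisible(TRUE)
}

# state character vector -> integer code: loss = -1, neutral = 0, gain = +1
state_code <- function(state) {
  unname(c(loss = -1L, neutral = 0L, gain = 1L)[state])
}

# Convert a tibble with a `gene` identifier column and one numeric column per
# sample into a genes-x-samples matrix.
as_expr_matrix <- function(x, what = "expression matrix") {
  check_columns(x, "gene", what)
  if (anyDuplicated(x$gene)) {
    abort_bad_arg("%s has duplicated gene identifier(s): %s", what,
                  paste(unique(x$gene[duplicated(x$gene)]), collapse = ", "))
  }
  m <- as.matrix(x[setdiff(names(x), "gene")])
  if (!is.numeric(m)) abort_bad_arg("%s has non-numeric sample columns", what)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort_bad_arg("%s has a non-finite value at gene '%s', sample '%s'",
                  what, x$gene[bad[1]], colnames(m)[bad[2]])
  }
  rownames(m) <- x$gene
  m
}

# Resolve a (sample, <label>) annotation data frame against matrix columns.
check_sample_labels <- function(labels, samples, label_col, what = "labels") {
  check_columns(labels, c("sample", label_col), what)
  missing <- setdiff(samples, labels$sample)
  if (length(missing) > 0) {
    abort_bad_arg("%s lacks an entry for sample(s): %s", what,
                  paste(missing, collapse = ", "))
  }
  lab <- labels[[label_col]][match(samples, labels$sample)]
  if (anyNA(lab)) abort_bad_arg("%s contains missing values", what)
  lab
}

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    set.seed(check_count(seed, "seed"))
  }
  invisible(NULL)
}
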