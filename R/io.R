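# Readers and writers for the tabular formats used across the pipeline.
# Parsers reject malformed input rather than coercing it; every writer
# produces files its own reader round-trips. '#'-prefixed lines are header
# comments (provenance: tool version, seed, parameters) and are skipped on
# read.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) abort_bad_arg("cannot read %s: no such file '%s'", what, path)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

write_table_with_comments <- function(x, path, comments = NULL, delim = "\t",
                                      col_names = TRUE) {
  lines <- character(0)
  if (!is.null(comments) && length(comments) > 0) {
    lines <- paste0("# ", comments)
  }
  body <- readr::format_delim(x, delim = delim, col_names = col_names)
  # atomic write: temp file in the target directory, then rename
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(c(lines, sub("\n$", "", body)), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read / write an aCGH probe profile
#'
#' A probe profile is a TSV with header columns `chrom`, `start`, `end`,
#' `probe_id`, `log2ratio` (BED-style 0-based half-open coordinates), one file
#' per sample. Rows are validated (numeric finite log2 ratios, `start < end`,
#' unique probe ids) and sorted by `(chrom, start)`.
#'
#' @param path File path.
#' @return `read_probe_table()`: a probe-profile tibble.
#' @export
read_probe_table <- function(path) {
  x <- read_tsv_checked(path, "probe table")
  check_columns(x, PROBE_COLS, sprintf("probe table '%s'", path))
  validate_probe_table(x, path)
}

validate_probe_table <- function(x, path = "<probe table>") {
  for (col in c("start", "end")) {
    if (!is.numeric(x[[col]])) {
      abort_bad_arg("'%s': column %s is not numeric", path, col)
    }
  }
  bad <- which(!(x$start < x$end))
  if (length(bad) > 0) {
    abort_bad_arg("'%s': start >= end on data line %d (probe '%s')",
                  path, bad[1], x$probe_id[bad[1]])
  }
  if (!is.numeric(x$log2ratio) || any(!is.finite(x$log2ratio))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x$log2ratio))))
    abort_bad_arg("'%s': non-finite or non-numeric log2ratio on data line %d",
                  path, if (length(bad)) bad[1] else NA_integer_)
  }
  if (anyDuplicated(x$probe_id)) {
    dup <- x$probe_id[duplicated(x$probe_id)][1]
    abort_bad_arg("'%s': duplicate probe_id '%s' (data line %d)",
                  path, dup, which(x$probe_id == dup)[2])
  }
  dplyr::arrange(tibble::as_tibble(x), .data$chrom, .data$start)
}

#' @rdname read_probe_table
#' @param x Table to write.
#' @param comments Optional character vector written as `#`-prefixed header
#'   lines (provenance: seed, parameters).
#' @return Writers return `path` invisibly.
#' @export
write_probe_table <- function(x, path, comments = NULL) {
  check_columns(x, PROBE_COLS, "probe table")
  write_table_with_comments(x, path, comments)
}

#' Read / write aberration calls
#'
#' Same layout as a probe table plus a `state` column in
#' `{loss, neutral, gain}`, as written by the `call` pipeline step.
#'
#' @inheritParams read_probe_table
#' @return `read_aberration_calls()`: a calls tibble.
#' @export
read_aberration_calls <- function(path) {
  x <- read_tsv_checked(path, "aberration calls")
  check_columns(x, c(PROBE_COLS[1:4], "state"), sprintf("calls '%s'", path))
  bad <- which(!x$state %in% STATE_LEVELS)
  if (length(bad) > 0) {
    abort_bad_arg("'%s': invalid state '%s' on data line %d",
                  path, x$state[bad[1]], bad[1])
  }
  if (anyDuplicated(x$probe_id)) {
    abort_bad_arg("'%s': duplicate probe_id '%s'", path,
                  x$probe_id[duplicated(x$probe_id)][1])
  }
  dplyr::arrange(tibble::as_tibble(x), .data$chrom, .data$start)
}

#' @rdname read_aberration_calls
#' @param x Table to write.
#' @param comments Optional `#` header lines.
#' @export
write_aberration_calls <- function(x, path, comments = NULL) {
  check_columns(x, c(PROBE_COLS[1:4], "state"), "aberration calls")
  write_table_with_comments(x, path, comments)
}

#' Write a gain/loss frequency track
#'
#' TSV with columns `chrom`, `start`, `end`, `probe_id`, `frac_gain`,
#' `frac_loss` (see [aberration_frequencies()]).
#'
#' @param x A `frequency_track` tibble.
#' @inheritParams write_probe_table
#' @export
write_frequency_track <- function(x, path, comments = NULL) {
  check_columns(x, c(PROBE_COLS[1:4], "frac_gain", "frac_loss"), "frequency track")
  n <- attr(x, "n_samples")
  if (!is.null(n)) comments <- c(comments, sprintf("n_samples=%d", n))
  write_table_with_comments(tibble::as_tibble(x), path, comments)
}

#' Read / write a gene-by-sample expression matrix
#'
#' TSV whose first column (`gene`) holds gene identifiers and whose remaining
#' columns are samples, log2 scale. All cells must be numeric; gene and
#' sample identifiers must be unique. Offending cells are reported by gene
#' row and sample column.
#'
#' @inheritParams read_probe_table
#' @return `read_expression_matrix()`: an expression tibble.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort_bad_arg("cannot read expression matrix: no such file '%s'", path)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (ncol(x) < 2) abort_bad_arg("'%s': expected a gene column plus sample columns", path)
  names(x)[1] <- "gene"
  if (anyDuplicated(names(x))) {
    abort_bad_arg("'%s': duplicated sample column '%s'", path,
                  names(x)[duplicated(names(x))][1])
  }
  if (anyDuplicated(x$gene)) {
    abort_bad_arg("'%s': duplicated gene identifier '%s'", path,
                  x$gene[duplicated(x$gene)][1])
  }
  for (j in seq(2, ncol(x))) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    bad <- which(is.na(v) | is.na(x[[j]]))
    if (length(bad) > 0) {
      abort_bad_arg("'%s': non-numeric cell at gene '%s', column '%s'",
                    path, x$gene[bad[1]], names(x)[j])
    }
    x[[j]] <- v
  }
  tibble::as_tibble(x)
}

#' @rdname read_expression_matrix
#' @param x Expression tibble (`gene` column plus sample columns).
#' @param comments Optional `#` header lines.
#' @export
write_expression_matrix <- function(x, path, comments = NULL) {
  check_columns(x, "gene", "expression matrix")
  write_table_with_comments(x, path, comments)
}

#' Read / write a marker panel
#'
#' CSV with columns `gene`, `subclass` and optionally `source` (defaulted to
#' `"panel"`). A gene may appear once per source; duplicated
#' `(gene, source)` pairs are rejected.
#'
#' @inheritParams read_probe_table
#' @return `read_marker_panel()`: a panel tibble (`gene`, `subclass`,
#'   `source`).
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) abort_bad_arg("cannot read marker panel: no such file '%s'", path)
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  check_columns(x, c("gene", "subclass"), sprintf("marker panel '%s'", path))
  if (!"source" %in% names(x)) x$source <- "panel"
  dup <- duplicated(x[c("gene", "source")])
  if (any(dup)) {
    abort_bad_arg("'%s': duplicated (gene, source) pair: (%s, %s)",
                  path, x$gene[dup][1], x$source[dup][1])
  }
  tibble::as_tibble(x[c("gene", "subclass", "source")])
}

#' @rdname read_marker_panel
#' @param x Panel tibble.
#' @export
write_marker_panel <- function(x, path) {
  check_columns(x, c("gene", "subclass"), "marker panel")
  if (!"source" %in% names(x)) x$source <- "panel"
  write_table_with_comments(x[c("gene", "subclass", "source")], path,
                            comments = NULL, delim = ",")
}

#' Read / write a TSS annotation in BED format
#'
#' Six-column headerless BED: `chrom`, `start`, `end`, `gene` (name), `score`,
#' `strand`; 0-based half-open coordinates; strand in `{+, -}`. One row per
#' gene.
#'
#' @inheritParams read_probe_table
#' @return `read_tss_bed()`: a TSS tibble.
#' @export
read_tss_bed <- function(path) {
  if (!file.exists(path)) abort_bad_arg("cannot read TSS BED: no such file '%s'", path)
  x <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                       show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 6) abort_bad_arg("'%s': BED file needs 6 columns (got %d)", path, ncol(x))
  x <- x[1:6]
  names(x) <- c("chrom", "start", "end", "gene", "score", "strand")
  if (!is.numeric(x$start) || !is.numeric(x$end) || any(x$start >= x$end) ||
      any(x$start < 0)) {
    abort_bad_arg("'%s': malformed BED intervals (need 0 <= start < end)", path)
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort_bad_arg("'%s': BED strand must be '+' or '-'", path)
  }
  if (anyDuplicated(x$gene)) {
    abort_bad_arg("'%s': duplicated gene '%s'", path,
                  x$gene[duplicated(x$gene)][1])
  }
  tibble::as_tibble(x)
}

#' @rdname read_tss_bed
#' @param x TSS tibble.
#' @export
write_tss_bed <- function(x, path) {
  check_columns(x, c("chrom", "start", "end", "gene", "score", "strand"), "TSS table")
  write_table_with_comments(x[c("chrom", "start", "end", "gene", "score", "strand")],
                            path, comments = NULL, col_names = FALSE)
}

#' Read / write a methylation beta table
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (1-based probe coordinate,
#' platform-manifest convention) and one numeric column per sample; betas
#' must lie in [0, 1].
#'
#' @inheritParams read_probe_table
#' @return `read_beta_table()`: a beta tibble.
#' @export
read_beta_table <- function(path) {
  x <- read_tsv_checked(path, "beta table")
  check_columns(x, c("probe_id", "chrom", "pos"), sprintf("beta table '%s'", path))
  if (anyDuplicated(x$probe_id)) {
    abort_bad_arg("'%s': duplicate probe_id '%s'", path,
                  x$probe_id[duplicated(x$probe_id)][1])
  }
  sample_cols <- setdiff(names(x), c("probe_id", "chrom", "pos"))
  if (length(sample_cols) == 0) abort_bad_arg("'%s': no sample columns", path)
  for (col in sample_cols) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                     suppressWarnings(as.numeric(v)) < 0 |
                     suppressWarnings(as.numeric(v)) > 1)
      abort_bad_arg("'%s': beta outside [0,1] or non-numeric in column '%s', data line %d",
                    path, col, if (length(bad)) bad[1] else NA_integer_)
    }
  }
  tibble::as_tibble(x)
}

#' @rdname read_beta_table
#' @param x Beta tibble.
#' @param comments Optional `#` header lines.
#' @export
write_beta_table <- function(x, path, comments = NULL) {
  check_columns(x, c("probe_id", "chrom", "pos"), "beta table")
  write_table_with_comments(x, path, comments)
}

#' Read / write a sample annotation table
#'
#' TSV with a `sample` column plus one or more label columns (`group`,
#' `class`, ...).
#'
#' @inheritParams read_probe_table
#' @return `read_sample_annotation()`: an annotation tibble.
#' @export
read_sample_annotation <- function(path) {
  x <- read_tsv_checked(path, "sample annotation")
  check_columns(x, "sample", sprintf("sample annotation '%s'", path))
  if (anyDuplicated(x$sample)) {
    abort_bad_arg("'%s': duplicated sample '%s'", path,
                  x$sample[duplicated(x$sample)][1])
  }
  tibble::as_tibble(x)
}

#' @rdname read_sample_annotation
#' @param x Annotation tibble.
#' @export
write_sample_annotation <- function(x, path) {
  check_columns(x, "sample", "sample annotation")
  write_table_with_comments(x, path, comments = NULL)
}
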