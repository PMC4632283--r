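#' Call copy-number aberrations from a log2-ratio probe profile
#'
#' Labels every probe of an aCGH profile as `gain`, `loss` or `neutral` by a
#' fixed log2-ratio threshold: `gain` if `log2ratio > threshold`, `loss` if
#' `log2ratio < -threshold`, `neutral` otherwise. A probe whose magnitude
#' equals the threshold exactly is neutral (strict inequalities). The default
#' threshold of 0.25 is the standard calling cutoff for log-ratio aCGH data.
#'
#' @param profile A probe profile: data frame with columns `chrom`, `start`,
#'   `end`, `probe_id`, `log2ratio`, sorted by position. See
#'   [read_probe_table()] and [simulate_acgh_pair()].
#' @param threshold Positive calling threshold on the absolute log2 ratio.
#'
#' @return A tibble with the input probe grid plus a `state` column
#'   (`"loss"`, `"neutral"` or `"gain"`). The threshold used is stored in the
#'   `"threshold"` attribute.
#'
#' @examples
#' prof <- tibble::tibble(
#'   chrom = "chr1", start = c(0, 100, 200, 300),
#'   end = c(60, 160, 260, 360),
#'   probe_id = paste0("p", 1:4),
#'   log2ratio = c(0.30, -0.30, 0.10, 0.25)
#' )
#' call_aberrations(prof)$state
#' @export
call_aberrations <- function(profile, threshold = 0.25) {
  check_columns(profile, PROBE_COLS, "probe profile")
  threshold <- check_number(threshold, "threshold")
  if (threshold <= 0) abort_bad_arg("`threshold` must be > 0 (got %g)", threshold)
  bad <- which(!is.finite(profile$log2ratio))
  if (length(bad) > 0) {
    abort_bad_arg("non-finite log2ratio at probe '%s'", profile$probe_id[bad[1]])
  }
  out <- tibble::as_tibble(profile)
  out$state <- dplyr::case_when(
    out$log2ratio > threshold ~ "gain",
    out$log2ratio < -threshold ~ "loss",
    TRUE ~ "neutral"
  )
  attr(out, "threshold") <- threshold
  out
}

#' Gain/loss frequency track across a cohort of called samples
#'
#' For a list of aberration-call tables on an identical probe grid, computes
#' per probe the fraction of samples called gained and the fraction called
#' lost — the data behind the classic genome-wide frequency plot of a tumor
#' cohort.
#'
#' @param calls A non-empty list of aberration-call tables as produced by
#'   [call_aberrations()]; all must share the same probe grid (checked by
#'   probe_id sequence).
#'
#' @return A tibble of class `frequency_track` with columns `chrom`, `start`,
#'   `end`, `probe_id`, `frac_gain`, `frac_loss` and attribute `n_samples`.
#'   `frac_gain + frac_loss <= 1` for every probe.
#' @seealso [autoplot.frequency_track()]
#' @export
aberration_frequencies <- function(calls) {
  if (!is.list(calls) || length(calls) == 0 || is.data.frame(calls)) {
    abort_bad_arg("`calls` must be a non-empty list of aberration-call tables")
  }
  ref <- calls[[1]]
  check_columns(ref, c(PROBE_COLS[1:4], "state"), "aberration calls")
  for (i in seq_along(calls)[-1]) {
    check_columns(calls[[i]], c(PROBE_COLS[1:4], "state"), "aberration calls")
    check_same_grid(ref, calls[[i]], "sample 1", paste("sample", i))
  }
  states <- vapply(calls, function(x) state_code(x$state), integer(nrow(ref)))
  states <- matrix(states, nrow = nrow(ref))
  out <- tibble::tibble(
    chrom = ref$chrom, start = ref$start, end = ref$end,
    probe_id = ref$probe_id,
    frac_gain = rowMeans(states == 1L),
    frac_loss = rowMeans(states == -1L)
  )
  attr(out, "n_samples") <- length(calls)
  class(out) <- c("frequency_track", class(out))
  out
}
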