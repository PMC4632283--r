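#' Count positionally matching aberrations between two samples
#'
#' The clonality statistic: the number of probes at which two aberration
#' profiles agree. In `sign_specific` mode (default) a probe matches when both
#' samples carry a gain there, or both a loss; in `any_aberration` mode it
#' matches whenever both are non-neutral, regardless of sign.
#'
#' @param a,b Aberration-call tables on an identical probe grid
#'   (see [call_aberrations()]).
#' @param mode `"sign_specific"` or `"any_aberration"`.
#' @return Integer match count.
#' @export
count_matching_positions <- function(a, b, mode = c("sign_specific", "any_aberration")) {
  mode <- match.arg(mode)
  check_columns(a, c("probe_id", "state"), "sample a")
  check_columns(b, c("probe_id", "state"), "sample b")
  check_same_grid(a, b, "sample a", "sample b")
  sa <- state_code(a$state)
  sb <- state_code(b$state)
  if (mode == "sign_specific") {
    sum(sa != 0L & sa == sb)
  } else {
    sum(sa != 0L & sb != 0L)
  }
}

# Internal: draw `n_perm` replicate match counts by redrawing the positions of
# a sample with `g` gains and `l` losses uniformly without replacement from
# `pool`, against a fixed state vector `other` (integer codes).
perm_replicates <- function(other, pool, g, l, n_perm, mode) {
  m <- g + l
  is_gain <- other == 1L
  is_loss <- other == -1L
  nonneutral <- other != 0L
  np <- length(pool)
  ri <- integer(n_perm)
  gi <- seq_len(g)
  li <- g + seq_len(l)
  if (mode == "sign_specific") {
    for (i in seq_len(n_perm)) {
      idx <- pool[sample.int(np, m)]
      ri[i] <- sum(is_gain[idx[gi]]) + sum(is_loss[idx[li]])
    }
  } else {
    for (i in seq_len(n_perm)) {
      idx <- pool[sample.int(np, m)]
      ri[i] <- sum(nonneutral[idx])
    }
  }
  ri
}

#' Permutation test for clonality of two aberration profiles
#'
#' Tests whether two samples (typically a primary tumor and a metastasis)
#' share more positionally matching aberrations than expected by chance. The
#' observed match count `o` is computed on the original profiles; then, in
#' each of `n_permutations` replicates, the aberration positions of the sample
#' containing fewer aberrant probes are redrawn uniformly without replacement
#' over the probe grid (its gain and loss counts preserved, the other sample
#' held fixed) and the replicate match count `ri` is recorded. The number of
#' replicates exceeding the observed count, `r = #\{ri > o\}` (strict), gives
#' the estimate `P = r/n`. When `r = 0` the result is flagged as an upper
#' bound and reported as `P < 1/n`.
#'
#' The tie count `#\{ri = o\}` is returned alongside `r`, so alternative
#' estimators — the inclusive `#\{ri >= o\}/n`, the add-one `(r+1)/(n+1)`, or
#' the randomized estimator used for calibration checks — can be formed from
#' the result without re-running the permutations.
#'
#' @inheritParams count_matching_positions
#' @param n_permutations Number of Monte-Carlo replicates (paper-scale default
#'   100 000).
#' @param seed Optional integer seed for reproducibility.
#' @param redraw_pool `"genome"` (default): redraw positions over the whole
#'   probe grid. `"other_aberrant"`: restrict redraws to the other sample's
#'   aberrant positions (the alternative reading of "matched to a random set
#'   of aberration positions of the other sample"), for sensitivity analysis.
#'
#' @return An object of class `clonality_test`: a list with elements
#'   `observed` (o), `r` (strict exceedances), `r_eq` (ties), `n_permutations`,
#'   `p_estimate` (= r/n), `p_is_upper_bound` (TRUE iff r = 0), `mode`,
#'   `redraw_pool`, `seed`, `n_probes`, `n_aberrant_a`, `n_aberrant_b`, and
#'   `replicates`, a tibble tabulating the replicate match counts. Has
#'   [tidy()], [glance()], [print()] and [ggplot2::autoplot()] methods.
#'
#' @examples
#' pair <- simulate_null_pair(100, 10, 10, seed = 1)
#' res <- clonality_test(pair$a, pair$b, n_permutations = 1000, seed = 1)
#' res
#' tidy(res)
#' @export
clonality_test <- function(a, b, n_permutations = 100000,
                           mode = c("sign_specific", "any_aberration"),
                           seed = NULL,
                           redraw_pool = c("genome", "other_aberrant")) {
  mode <- match.arg(mode)
  redraw_pool <- match.arg(redraw_pool)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1)
  o <- count_matching_positions(a, b, mode)   # also validates the grids
  sa <- state_code(a$state)
  sb <- state_code(b$state)
  na <- sum(sa != 0L)
  nb <- sum(sb != 0L)
  if (na == 0 || nb == 0) {
    abort_bad_arg("clonality test undefined: sample %s has no aberrant probe",
                  if (na == 0) "a" else "b")
  }
  set_seed_if_given(seed)
  # redraw the sample with fewer aberrations; the other stays fixed
  if (na <= nb) {
    moved <- sa; fixed <- sb
  } else {
    moved <- sb; fixed <- sa
  }
  g <- sum(moved == 1L)
  l <- sum(moved == -1L)
  pool <- if (redraw_pool == "genome") seq_along(fixed) else which(fixed != 0L)
  if (length(pool) < g + l) {
    abort_bad_arg("redraw pool (%d positions) smaller than the %d aberrations to place",
                  length(pool), g + l)
  }
  ri <- perm_replicates(fixed, pool, g, l, n_permutations, mode)
  r <- sum(ri > o)
  structure(list(
    observed = o,
    r = r,
    r_eq = sum(ri == o),
    n_permutations = n_permutations,
    p_estimate = r / n_permutations,
    p_is_upper_bound = r == 0L,
    mode = mode,
    redraw_pool = redraw_pool,
    seed = seed,
    n_probes = length(sa),
    n_aberrant_a = na,
    n_aberrant_b = nb,
    replicates = dplyr::count(tibble::tibble(match_count = ri),
                              .data$match_count, name = "n_replicates")
  ), class = "clonality_test")
}

#' Exact clonality test by exhaustive enumeration
#'
#' Brute-force companion to [clonality_test()]: enumerates every redraw
#' configuration of the smaller sample's aberrant positions over the probe
#' grid (gain/loss counts preserved, states assigned to positions exactly as
#' the Monte-Carlo scheme would) and reports the exact exceedance probability
#' `P = #\{configurations with ri > o\} / #\{configurations\}`. Intended as a
#' testing oracle on small grids; rejects when the configuration count
#' exceeds `max_configurations`.
#'
#' @inheritParams count_matching_positions
#' @param max_configurations Enumeration cap (default 1e6).
#' @return A one-row tibble with columns `observed`, `n_configurations`,
#'   `n_exceeding` and `p_exact`.
#' @export
exact_clonality_test <- function(a, b, mode = c("sign_specific", "any_aberration"),
                                 max_configurations = 1e6) {
  mode <- match.arg(mode)
  o <- count_matching_positions(a, b, mode)
  sa <- state_code(a$state)
  sb <- state_code(b$state)
  na <- sum(sa != 0L)
  nb <- sum(sb != 0L)
  if (na == 0 || nb == 0) {
    abort_bad_arg("exact test undefined: sample %s has no aberrant probe",
                  if (na == 0) "a" else "b")
  }
  if (na <= nb) {
    moved <- sa; fixed <- sb
  } else {
    moved <- sb; fixed <- sa
  }
  g <- sum(moved == 1L)
  l <- sum(moved == -1L)
  np <- length(fixed)

  if (mode == "any_aberration") {
    # states do not matter for matching: enumerate position sets only
    m <- g + l
    n_config <- choose(np, m)
    if (n_config > max_configurations) {
      abort_bad_arg("enumeration cap exceeded: %g configurations > %g",
                    n_config, max_configurations)
    }
    nonneutral <- fixed != 0L
    exceed <- utils::combn(np, m, FUN = function(idx) sum(nonneutral[idx]) > o)
    n_exceed <- sum(exceed)
  } else {
    is_gain <- fixed == 1L
    is_loss <- fixed == -1L
    n_config <- choose(np, g) * choose(np - g, l)
    if (n_config > max_configurations) {
      abort_bad_arg("enumeration cap exceeded: %g configurations > %g",
                    n_config, max_configurations)
    }
    if (l == 0L) {
      n_exceed <- sum(utils::combn(np, g, FUN = function(idx) sum(is_gain[idx]) > o))
    } else if (g == 0L) {
      n_exceed <- sum(utils::combn(np, l, FUN = function(idx) sum(is_loss[idx]) > o))
    } else {
      gain_sets <- utils::combn(np, g)
      n_exceed <- 0L
      for (j in seq_len(ncol(gain_sets))) {
        gset <- gain_sets[, j]
        x <- sum(is_gain[gset])
        rest <- setdiff(seq_len(np), gset)
        # index into `rest` by position: combn(v, l) would expand a length-1
        # numeric v into 1:v
        n_exceed <- n_exceed +
          sum(utils::combn(length(rest), l,
                           FUN = function(k) x + sum(is_loss[rest[k]]) > o))
      }
    }
  }
  tibble::tibble(
    observed = o,
    n_configurations = n_config,
    n_exceeding = as.numeric(n_exceed),
    p_exact = n_exceed / n_config
  )
}
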