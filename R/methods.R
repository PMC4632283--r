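#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.clonality_test <- function(x, ...) {
  cat(sprintf("Permutation clonality test (%s, redraw over %s)\n",
              x$mode, x$redraw_pool))
  cat(sprintf("  probes: %d; aberrant: a = %d, b = %d\n",
              x$n_probes, x$n_aberrant_a, x$n_aberrant_b))
  cat(sprintf("  observed matching positions o = %d\n", x$observed))
  cat(sprintf("  replicates n = %d, exceedances r = %d, ties = %d\n",
              x$n_permutations, x$r, x$r_eq))
  if (x$p_is_upper_bound) {
    cat(sprintf("  P < %g (upper bound: no replicate exceeded o)\n",
                1 / x$n_permutations))
  } else {
    cat(sprintf("  P = r/n = %g\n", x$p_estimate))
  }
  invisible(x)
}

#' Tidiers for clonality test results
#'
#' `tidy()` returns the test as a one-row tibble; `glance()` is an alias with
#' the same columns, in broom convention.
#'
#' @param x A [clonality_test()] result.
#' @param ... Unused.
#' @return A one-row tibble with columns `observed`, `r`, `r_eq`,
#'   `n_permutations`, `p_estimate`, `p_is_upper_bound`, `mode`,
#'   `redraw_pool`, `n_probes`, `n_aberrant_a`, `n_aberrant_b`.
#' @method tidy clonality_test
#' @export
tidy.clonality_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, r = x$r, r_eq = x$r_eq,
    n_permutations = x$n_permutations,
    p_estimate = x$p_estimate,
    p_is_upper_bound = x$p_is_upper_bound,
    mode = x$mode, redraw_pool = x$redraw_pool,
    n_probes = x$n_probes,
    n_aberrant_a = x$n_aberrant_a, n_aberrant_b = x$n_aberrant_b
  )
}

#' @rdname tidy.clonality_test
#' @method glance clonality_test
#' @export
glance.clonality_test <- function(x, ...) tidy.clonality_test(x, ...)

#' @export
print.subtype_clustering <- function(x, ...) {
  sizes <- table(x$assignment$class)
  cat(sprintf("Subtype clustering: %s linkage, %s distance, k = %d\n",
              x$linkage, x$metric, x$k))
  cat(sprintf("  %d samples on %d panel genes\n",
              nrow(x$assignment), length(x$panel_genes)))
  cat("  class sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Tidiers for subtype clusterings
#'
#' `tidy()` returns the per-sample class assignment; `glance()` a one-row
#' summary.
#'
#' @param x A [cluster_subtypes()] result.
#' @param ... Unused.
#' @return `tidy()`: tibble (`sample`, `class`). `glance()`: one-row tibble
#'   (`k`, `n_samples`, `n_panel_genes`, `metric`, `linkage`).
#' @method tidy subtype_clustering
#' @export
tidy.subtype_clustering <- function(x, ...) x$assignment

#' @rdname tidy.subtype_clustering
#' @method glance subtype_clustering
#' @export
glance.subtype_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, n_samples = nrow(x$assignment),
                 n_panel_genes = length(x$panel_genes),
                 metric = x$metric, linkage = x$linkage)
}
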