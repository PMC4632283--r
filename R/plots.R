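# ggplot2 displays for the main result types.

#' Plot a gain/loss frequency track
#'
#' Genome-wide frequency plot: per-probe fraction of samples gained (up, in
#' red) and lost (down, in blue), faceted by chromosome.
#'
#' @param object A `frequency_track` from [aberration_frequencies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frequency_track
#' @export
autoplot.frequency_track <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$frac_gain), color = "#b2182b") +
    ggplot2::geom_step(ggplot2::aes(y = -.data$frac_loss), color = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(limits = c(-1, 1),
                                labels = function(v) abs(v)) +
    ggplot2::labs(x = "position (bp)",
                  y = "fraction lost | gained",
                  title = sprintf("Aberration frequencies (n = %s samples)",
                                  attr(object, "n_samples") %||% "?")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.frequency_track
#' @export
plot_frequency_track <- function(object, ...) autoplot.frequency_track(object, ...)

#' Plot the permutation null of a clonality test
#'
#' Histogram of replicate match counts with the observed count marked; the
#' estimated P is the mass strictly to the right of the observed line.
#'
#' @param object A [clonality_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clonality_test
#' @export
autoplot.clonality_test <- function(object, ...) {
  lab <- if (object$p_is_upper_bound) {
    sprintf("o = %d, P < %g", object$observed, 1 / object$n_permutations)
  } else {
    sprintf("o = %d, P = %g", object$observed, object$p_estimate)
  }
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = .data$match_count, y = .data$n_replicates)) +
    ggplot2::geom_col(fill = "grey55", width = 0.9) +
    ggplot2::geom_vline(xintercept = object$observed, color = "#b2182b",
                        linewidth = 0.8) +
    ggplot2::labs(x = "replicate match count", y = "replicates",
                  title = "Permutation null of matching aberrations",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot class sizes of a subtype clustering
#'
#' @param object A [cluster_subtypes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subtype_clustering
#' @export
autoplot.subtype_clustering <- function(object, ...) {
  df <- dplyr::count(object$assignment, .data$class, name = "n_samples")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class), y = .data$n_samples)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "class (1 = largest)", y = "samples",
                  title = sprintf("Subtype clustering (%s, %s, k = %d)",
                                  object$linkage, object$metric, object$k)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot for promoter methylation comparisons
#'
#' Tumor-vs-normal mean beta difference against -log10 p per gene.
#'
#' @param comparison Output of [compare_promoter_methylation()].
#' @param alpha Significance line (raw p).
#' @return A ggplot object.
#' @export
plot_methylation_comparison <- function(comparison, alpha = 0.05) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$delta_beta,
                               y = -log10(.data$p_value),
                               color = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_color_manual(values = c(hypo = "#2166ac", hyper = "#b2182b",
                                           none = "grey60")) +
    ggplot2::labs(x = "tumor - normal mean beta",
                  y = expression(-log[10](p)),
                  title = "Promoter methylation: tumor vs normal") +
    ggplot2::theme_minimal()
}
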