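#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the per-bin across-trial Fano factors
#'
#' @param object A [across_trial_fano()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fano_result <- function(object, ...) {
  ggplot2::ggplot(object$per_bin,
                  ggplot2::aes(x = .data$t_start, y = .data$fano)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_hline(yintercept = object$ff, colour = "firebrick") +
    ggplot2::labs(x = "time (ms)", y = "Fano factor across trials",
                  title = sprintf("FF = %.3g (%d ms bins, %d trials)",
                                  object$ff, object$bin, object$n_trials)) +
    ggplot2::theme_minimal()
}

#' Plot per-trial output correlations
#'
#' Scatter of within-group against between-group mean pairwise correlation
#' per trial, with the trial average marked.
#'
#' @param object A [correlation_transfer()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.corr_transfer <- function(object, ...) {
  ggplot2::ggplot(object$per_trial,
                  ggplot2::aes(x = .data$w_out, y = .data$b_out)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::annotate("point", x = object$w_out, y = object$b_out,
                      colour = "firebrick", size = 3) +
    ggplot2::labs(x = "within-group correlation (w_out)",
                  y = "between-group correlation (b_out)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a sweep statistic over the input grid
#'
#' Renders one statistic of a [run_experiment()] table as a
#' `w_in` by `n_fsi` heatmap (faceted over `b_in` when several values are
#' present), the layout used for the variability sweeps.
#'
#' @param results A [run_experiment()] tibble.
#' @param stat Column to plot (default `"ff_msn"`).
#' @return A ggplot.
#' @export
plot_sweep_grid <- function(results, stat = "ff_msn") {
  stopifnot(stat %in% names(results))
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = factor(.data$w_in),
                                    y = factor(.data$n_fsi),
                                    fill = .data[[stat]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = stat) +
    ggplot2::labs(x = "within-group input sharing (w_in)",
                  y = "number of FSIs") +
    ggplot2::theme_minimal()
  if (length(unique(results$b_in)) > 1) {
    p <- p + ggplot2::facet_wrap(~b_in, labeller = ggplot2::label_both)
  }
  p
}
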