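# ggplot2 views of the result tables. Each returns a ggplot object the
# caller can theme further.

#' Plot per-residue hotspot hit rates
#'
#' @param rates Hit-rate tibble from [hit_rates()].
#' @param mode Plot `"rate"` (default) or `"count"`.
#' @return A ggplot.
#' @export
plot_hit_rates <- function(rates, mode = c("rate", "count")) {
  mode <- match.arg(mode)
  yvar <- if (mode == "rate") "hit_rate" else "hit_count"
  rates$label <- paste0(rates$chain, rates$resnum, rates$icode)
  ggplot2::ggplot(rates, ggplot2::aes(
    x = stats::reorder(.data$label, .data$resnum), y = .data[[yvar]]
  )) +
    ggplot2::geom_col(ggplot2::aes(fill = .data[[yvar]])) +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "residue",
                  y = if (mode == "rate") "hotspot hit rate"
                      else "hotspot hit count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   legend.position = "none")
}

#' Plot a hotspot recovery histogram
#'
#' Bars give the number of models recovering each count of reference
#' hotspots; the baseline (crystal) count, when present, is marked with
#' a star.
#'
#' @param hist Tibble from [recovery_histogram()].
#' @return A ggplot.
#' @export
plot_recovery_histogram <- function(hist) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$n_recovered,
                                          y = .data$n_models)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = hist$n_recovered) +
    ggplot2::labs(x = "reference hotspots recovered", y = "models") +
    ggplot2::theme_minimal()
  base <- attr(hist, "baseline_recovered")
  if (!is.null(base)) {
    p <- p + ggplot2::annotate("point", x = base,
                               y = max(hist$n_models) * 1.05,
                               shape = 8, size = 3, colour = "firebrick")
  }
  p
}

#' Tile plot of metric correlations
#'
#' @param object A `pepqa_cor` from [metric_correlations()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pepqa_cor <- function(object, ...) {
  td <- tidy(object)
  td2 <- dplyr::bind_rows(
    td,
    dplyr::rename(td, metric_x = "metric_y", metric_y = "metric_x")
  )
  ggplot2::ggplot(td2, ggplot2::aes(x = .data$metric_x, y = .data$metric_y,
                                    fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho))) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Scatter of side-chain vs backbone interface accuracy
#'
#' The S-RMSD vs I-RMSD view, coloured by CAPRI class, that motivates
#' capping S-RMSD when loosening backbone thresholds.
#'
#' @param assessment Assessment tibble from [assess_models()] (or any
#'   table with `i_rmsd`, `s_rmsd` and `class` columns).
#' @return A ggplot.
#' @export
plot_srmsd_vs_irmsd <- function(assessment) {
  ok <- dplyr::filter(assessment, !is.na(.data$s_rmsd))
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$i_rmsd, y = .data$s_rmsd,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = "interface backbone RMSD (A)",
                  y = "interface side-chain RMSD (A)",
                  colour = "CAPRI class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
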