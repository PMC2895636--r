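#' Plot a voltage trace
#'
#' @param object A `voltage_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.voltage_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time / 1000, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D conductance histogram
#'
#' Heat map of model counts per grid cell, the standard view of one
#' conductance pair within one activity type.
#'
#' @param object A `cond_hist2d`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cond_hist2d <- function(object, ...) {
  pair <- attr(object, "pair")
  df <- as_tibble(as.data.frame(as.table(unclass(object)),
                                stringsAsFactors = FALSE))
  names(df) <- c("a", "b", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = paste0("g_", pair[1], " (mS/cm²)"),
                  y = paste0("g_", pair[2], " (mS/cm²)"),
                  fill = "models") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a difference matrix
#'
#' Observed minus independence-expected model density, percent of the
#' population per cell: a linear dependence shows as a diagonal band of
#' positive cells flanked by negative ones; a relationship explained by
#' independent variation shows no structure.
#'
#' @param hist A `cond_hist2d`.
#' @return A ggplot.
#' @export
plot_difference_matrix <- function(hist) {
  pair <- attr(hist, "pair")
  d <- independence_difference(hist)$difference
  df <- as_tibble(as.data.frame(as.table(d), stringsAsFactors = FALSE))
  names(df) <- c("a", "b", "pct_diff")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$pct_diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = paste0("g_", pair[1], " (mS/cm²)"),
                  y = paste0("g_", pair[2], " (mS/cm²)"),
                  fill = "% diff") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a correlation scan
#'
#' chi-squared statistic against Spearman rho for every pair tested, with
#' the correlation-criteria cutoffs drawn in; correlations sit outside
#' both dashed lines.
#'
#' @param object A `correlation_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_scan <- function(object, ...) {
  cut <- attr(object, "cutoffs") %||% c(chi2 = 500, rho = 0.2)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$chi2,
                                   colour = .data$is_correlation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = cut[["chi2"]], linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * cut[["rho"]], linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Spearman ρ", y = "χ² (raw)",
                  colour = "correlation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
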