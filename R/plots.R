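#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot an axial slice of a T-map
#'
#' @param object A `t_map`.
#' @param z 1-based axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot2 object.
#' @export
autoplot.t_map <- function(object, z = NULL, ...) {
  d <- object$grid$dims
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- object$t[, , z]
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))  # x fastest,
  df$t <- as.vector(sl)                                    # matching R arrays
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("T-map slice z = %d (df = %d)", z,
                                  object$df),
                  fill = "t") +
    ggplot2::theme_minimal()
}

#' Group comparison of the resected-Rolandic mean T
#'
#' Jittered points and boxplots of the predictor by outcome group.
#'
#' @param metrics Tibble from [extract_patient_metrics()].
#' @return A ggplot2 object.
#' @export
plot_group_comparison <- function(metrics) {
  df <- metrics
  df$group <- ifelse(df$deficit == 1, "deficit", "non-deficit")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_t)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5,
                          fill = "grey92") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "Resected-Rolandic mean T") +
    ggplot2::theme_minimal()
}
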