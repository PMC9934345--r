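# Figures for the evaluation reports (ggplot2, optional dependency).

#' Plot per-age MAE curves for several methods
#'
#' One panel per sex, MAE (mm) against the last observed age — the standard
#' method-comparison figure.
#'
#' @param cmp Output of [compare_methods()].
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(cmp) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$upto_age, y = .data$mae_mm,
                                    colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::scale_x_continuous(breaks = 8:17) +
    ggplot2::labs(x = "last observed age (yr)",
                  y = "mean absolute error at 18 (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a year-by-year forecast with its confidence band
#'
#' Observed heights, the forecast at each future age, and the 95% band
#' (2-SD half-widths) when calibrated.
#'
#' @param query The `aligned_series` that was forecast.
#' @param fc A `gcc_forecast`.
#' @return A ggplot object.
#' @export
plot_forecast <- function(query, fc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  obs <- data.frame(age = query$ages, height = query$heights,
                    what = "observed")
  prd <- data.frame(age = as.integer(names(fc$predictions)),
                    height = unname(fc$predictions), what = "forecast")
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$age,
                                              y = .data$height))
  if (!is.null(fc$ci_half_width) && !anyNA(fc$ci_half_width)) {
    band <- data.frame(age = prd$age,
                       lo = prd$height - unname(fc$ci_half_width),
                       hi = prd$height + unname(fc$ci_half_width))
    p <- p + ggplot2::geom_ribbon(
      data = band, ggplot2::aes(x = .data$age, ymin = .data$lo,
                                ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.2)
  }
  p + ggplot2::geom_line(data = rbind(obs, prd),
                         ggplot2::aes(linetype = .data$what)) +
    ggplot2::geom_point(data = rbind(obs, prd),
                        ggplot2::aes(shape = .data$what)) +
    ggplot2::labs(x = "age (yr)", y = "height (cm)", linetype = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal()
}
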