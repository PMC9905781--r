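# Optional figures; ggplot2 is a suggested dependency only and never feeds
# back into any statistic.

stage_colors <- function() {
  c(W = "grey60", N1 = "cyan3", N2 = "blue3", N3 = "green4", R = "red3")
}

#' Stacked-area hypnodensity chart
#'
#' @param h A [hypnodensity()].
#' @return A ggplot object.
#' @export
plot_hypnodensity <- function(h) {
  stopifnot(inherits(h, "hypnodensity"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- h$probabilities
  df <- data.frame(
    hours = rep((seq_len(nrow(p)) - 1L) * h$epoch_duration / 3600, 5L),
    stage = factor(rep(sleep_stages(), each = nrow(p)),
                   levels = rev(sleep_stages())),
    probability = as.vector(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$probability,
                                   fill = .data$stage)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = stage_colors()) +
    ggplot2::labs(x = "Time (h)", y = "Stage probability",
                  title = sprintf("Hypnodensity (%s, %s)", h$psg_id, h$source)) +
    ggplot2::theme_minimal()
}

#' Agreement-decay curve with its fitted power model
#'
#' @param curve An `agreement_curve`.
#' @param fit Optional `power_fit` overlay.
#' @return A ggplot object.
#' @export
plot_agreement_curve <- function(curve, fit = NULL) {
  stopifnot(inherits(curve, "agreement_curve"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- curve$summary
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k,
                                        y = .data$mean_agreement)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Number of scorers",
                  y = "Epochs with complete agreement (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(df$k), max(df$k), length.out = 200)
    g <- g + ggplot2::geom_line(
      data = data.frame(k = xs, mean_agreement = predict_agreement(fit, xs)),
      linetype = "dashed")
  }
  g
}
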