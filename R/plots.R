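# ggplot2 views of the main result types. These are monitoring aids, not the
# analysis itself; everything they show is available in the returned tables.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline geom_abline labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a beam profile
#'
#' Signal versus position, optionally with detected edges overlaid.
#'
#' @param object a [beam_profile()].
#' @param edges optional `c(edge_low, edge_high)` from
#'   [detect_field_edges()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.beam_profile <- function(object, edges = NULL, ...) {
  df <- as.data.frame(object)
  p <- ggplot(df, aes(x = .data$position_mm, y = .data$value)) +
    geom_line(colour = "steelblue") +
    labs(
      x = sprintf("%s position (mm at isocenter)", object$axis),
      y = "signal",
      title = sprintf("%s beam profile", object$axis)
    ) +
    theme_minimal()
  if (!is.null(edges)) {
    p <- p + geom_vline(xintercept = unname(edges), linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot an ROI shift-sensitivity scan
#'
#' Output (and beam-quality, when present) deviation versus introduced offset,
#' one panel per statistic, one line per direction.
#'
#' @param scan tibble from [shift_sensitivity()].
#' @return a ggplot.
#' @export
plot_sensitivity <- function(scan) {
  long <- dplyr::bind_rows(
    dplyr::transmute(scan, .data$direction, .data$offset_mm,
      statistic = "output", deviation_pct = .data$output_dev_pct
    ),
    dplyr::transmute(scan, .data$direction, .data$offset_mm,
      statistic = "beam quality (W)", deviation_pct = .data$bq_dev_pct
    )
  )
  long <- dplyr::filter(long, !is.na(.data$deviation_pct))
  ggplot(long, aes(.data$offset_mm, .data$deviation_pct, colour = .data$direction)) +
    geom_line() +
    geom_point(size = 1) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    facet_wrap(~statistic, scales = "free_y") +
    labs(x = "introduced offset (mm)", y = "deviation (%)") +
    theme_minimal()
}

#' Plot a dose-response linearity fit
#'
#' @param object a `linearity_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.linearity_fit <- function(object, ...) {
  ggplot(object$series, aes(.data$mu_set, .data$mu_measured)) +
    geom_point() +
    geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "firebrick"
    ) +
    labs(
      x = "delivered MU", y = expression(mu ~ "(central-ROI mean signal)"),
      title = sprintf("R^2 = %.6f", object$r_squared)
    ) +
    theme_minimal()
}

#' Plot a daily QA result against its tolerances
#'
#' Deviation per parameter with the tolerance band; failed parameters in red.
#'
#' @param result a `qa_result` from [evaluate_daily()].
#' @return a ggplot.
#' @export
plot_qa_result <- function(result) {
  df <- as.data.frame(result)
  df <- df[!is.na(df$deviation), ]
  ggplot(df, aes(x = .data$parameter, y = .data$deviation, colour = .data$status)) +
    geom_point(size = 2) +
    ggplot2::geom_errorbar(
      aes(ymin = -.data$tolerance, ymax = .data$tolerance),
      width = 0.3, colour = "grey60", linetype = "dashed"
    ) +
    geom_hline(yintercept = 0, colour = "grey40") +
    labs(x = NULL, y = "deviation (native unit)", colour = "status") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
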