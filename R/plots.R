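#' Plot methods for panelcov results
#'
#' Each result type has an `autoplot()` method returning a ggplot object:
#' capture assessments a captured/non-captured bar, coverage summaries the
#' per-sample category proportions with their cross-sample mean,
#' detectability results the depth-bin distribution, and triage yields the
#' verdict shares.
#'
#' @param object a panelcov result object.
#' @param ... unused.
#' @return a `ggplot`.
#' @name panelcov-autoplot
NULL

#' @rdname panelcov-autoplot
#' @method autoplot panelcov_capture
#' @export
autoplot.panelcov_capture <- function(object, ...) {
  s <- object$summary
  df <- tibble(
    status = factor(c("captured", "not captured"),
      levels = c("captured", "not captured")
    ),
    n = c(s$n_captured, s$n_not_captured),
    pct = c(s$pct_captured, s$pct_not_captured)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = c("#2c7fb8", "#d95f0e")) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n, .data$pct)),
      vjust = -0.4
    ) +
    ggplot2::labs(
      x = NULL, y = "exons",
      title = "Panel exons by capture status"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname panelcov-autoplot
#' @method autoplot panelcov_coverage
#' @export
autoplot.panelcov_coverage <- function(object, ...) {
  props <- mutate(object$proportions, pct = 100 * .data$proportion)
  means <- mutate(object$mean_proportions, pct = 100 * .data$mean_proportion)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.8) +
    ggplot2::geom_crossbar(
      data = means,
      ggplot2::aes(ymin = .data$pct, ymax = .data$pct),
      width = 0.5, colour = "#d95f0e"
    ) +
    ggplot2::labs(
      x = "coverage category",
      y = "% of exons",
      title = sprintf(
        "Exon coverage categories at %dx (points: samples; bars: mean)",
        object$scheme$depth_threshold
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname panelcov-autoplot
#' @method autoplot panelcov_detectability
#' @export
autoplot.panelcov_detectability <- function(object, ...) {
  df <- object$bin_counts
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n_positions)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_positions), vjust = -0.4) +
    ggplot2::labs(
      x = sprintf(
        "summary depth bin (threshold %dx)", object$summary$depth_threshold
      ),
      y = "variant positions",
      title = "Variant positions by sequencing-depth bin"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname panelcov-autoplot
#' @method autoplot panelcov_yield
#' @export
autoplot.panelcov_yield <- function(object, ...) {
  df <- object$yield
  ggplot2::ggplot(df, ggplot2::aes(x = .data$verdict, y = .data$n)) +
    ggplot2::geom_col(fill = "#31a354") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%d (%d%%)", .data$n, .data$pct)),
      vjust = -0.4
    ) +
    ggplot2::labs(
      x = NULL, y = "cases",
      title = sprintf("Diagnostic yield (%d cases)", object$n_cases)
    ) +
    ggplot2::theme_minimal()
}
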