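#' Layout data for a forest plot with a prediction-interval row
#'
#' Builds the row-by-row geometry: one row per study (marker and CI
#' whiskers), a summary diamond for the pooled estimate, and — on its own
#' row — the 95% prediction interval drawn as a rectangle, so that it
#' cannot be mistaken for another confidence diamond.
#'
#' @param studies A tibble with columns `effect` and `variance` (analysis
#'   scale), optionally `label`.
#' @param fit A [dl_fit()] for the same studies; computed if omitted.
#' @param df_offset Degrees-of-freedom rule for the PI.
#' @return A list with tibbles `rows` (study rows with CI bounds),
#'   `diamond` (polygon vertices), `pi_rect` (rectangle bounds), and the
#'   `fit`.
#' @export
forest_data <- function(studies, fit = NULL, df_offset = 2) {
  if (is.null(fit)) fit <- dl_fit(studies$effect, studies$variance)
  k <- nrow(studies)
  label <- if ("label" %in% names(studies)) {
    studies$label
  } else {
    sprintf("Study %d", seq_len(k))
  }
  rows <- tibble::tibble(
    label = label,
    effect = studies$effect,
    lower = studies$effect - Z975 * sqrt(studies$variance),
    upper = studies$effect + Z975 * sqrt(studies$variance),
    y = rev(seq_len(k)) + 2
  )
  ci <- confidence_interval(fit$m, fit$se_m, "MD")
  pi <- prediction_interval(fit$m, fit$se_m, fit$tau2, k, "MD",
    df_offset = df_offset
  )
  diamond <- tibble::tibble(
    x = c(ci$lower, fit$m, ci$upper, fit$m),
    y = c(2, 2.25, 2, 1.75)
  )
  pi_rect <- tibble::tibble(
    xmin = pi$lower, xmax = pi$upper, ymin = 0.8, ymax = 1.2
  )
  list(rows = rows, diamond = diamond, pi_rect = pi_rect, fit = fit)
}

#' Forest plot with the prediction interval as a separate-row rectangle
#'
#' @inheritParams forest_data
#' @param null_line Vertical reference line (0 on the analysis scale).
#' @return A ggplot object.
#' @examples
#' studies <- tibble::tibble(
#'   effect = c(0.2, 0.5, 0.8), variance = c(0.02, 0.03, 0.02)
#' )
#' plot_forest(studies)
#' @export
plot_forest <- function(studies, fit = NULL, df_offset = 2, null_line = 0) {
  fd <- forest_data(studies, fit, df_offset)
  labels <- c(
    stats::setNames(fd$rows$y, fd$rows$label),
    "Pooled (95% CI)" = 2, "95% prediction interval" = 1
  )
  ggplot2::ggplot() +
    ggplot2::geom_vline(
      xintercept = null_line, linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_errorbarh(
      data = fd$rows,
      ggplot2::aes(
        xmin = .data$lower, xmax = .data$upper, y = .data$y
      ),
      height = 0.15
    ) +
    ggplot2::geom_point(
      data = fd$rows,
      ggplot2::aes(x = .data$effect, y = .data$y),
      shape = 15, size = 2
    ) +
    ggplot2::geom_polygon(
      data = fd$diamond,
      ggplot2::aes(x = .data$x, y = .data$y),
      fill = "grey30"
    ) +
    ggplot2::geom_rect(
      data = fd$pi_rect,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$ymin, ymax = .data$ymax
      ),
      fill = "steelblue", alpha = 0.7
    ) +
    ggplot2::scale_y_continuous(
      breaks = unname(labels), labels = names(labels)
    ) +
    ggplot2::labs(x = "Effect (analysis scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a forest plot to a file
#'
#' @inheritParams plot_forest
#' @param out Output path; the extension selects the graphics device (pdf
#'   or png).
#' @param width,height Device size in inches.
#' @return `out`, invisibly.
#' @export
render_forest <- function(studies, out, fit = NULL, df_offset = 2,
                          width = 7, height = 4) {
  p <- plot_forest(studies, fit, df_offset)
  ggplot2::ggsave(out, p, width = width, height = height)
  invisible(out)
}

#' Bar chart of CI/PI agreement categories
#'
#' @param agreement Output of [summarize_agreement()] (or the `agreement`
#'   element of a pipeline report).
#' @return A ggplot object.
#' @export
plot_agreement <- function(agreement) {
  df <- tibble::tibble(
    category = factor(
      c(
        "CI and PI\nsignificant", "Both\nnon-significant",
        "CI significant,\nPI spans null"
      ),
      levels = c(
        "CI and PI\nsignificant", "Both\nnon-significant",
        "CI significant,\nPI spans null"
      )
    ),
    n = c(
      agreement$n_corroborated, agreement$n_both_nonsig,
      agreement$n_ci_sig_pi_not
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(
      x = NULL, y = "Meta-analyses",
      title = sprintf(
        "Agreement between 95%% CIs and prediction intervals (N = %d)",
        agreement$n_total
      )
    ) +
    ggplot2::theme_minimal()
}
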