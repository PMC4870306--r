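# ggplot2 displays of Stage-1 scales and the change decomposition.

#' Plot Stage-1 item scales
#'
#' Dot-and-segment display of the per-item underlying-variable change: means at
#' both occasions with the effect size d as label.
#'
#' @param object A `stage1_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stage1_result <- function(object, ...) {
  rep <- object$report %>% filter(!.data$excluded)
  df <- rep %>%
    select("item", "mean_pre", "mean_post", "d") %>%
    tidyr::pivot_longer(c("mean_pre", "mean_post"),
                        names_to = "occasion", values_to = "mean") %>%
    mutate(occasion = ifelse(.data$occasion == "mean_pre", "1", "2"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$item)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$item), colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$occasion), size = 2) +
    ggplot2::geom_text(
      data = rep, ggplot2::aes(x = pmax(.data$mean_pre, .data$mean_post),
                               label = sprintf(" d = %.2f", .data$d)),
      hjust = 0, size = 3
    ) +
    ggplot2::labs(x = "underlying-variable mean", y = NULL, colour = "occasion",
                  title = "Change in the underlying variables") +
    ggplot2::theme_minimal()
}

#' Plot the decomposition of change
#'
#' Stacked bars of the per-item effect-size components (recalibration,
#' reprioritization/reconceptualization, true change) with the modeled change
#' marked.
#'
#' @param object An `rs_detect` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rs_detect <- function(object, ...) {
  plot_decomposition(object$decomposition)
}

#' @rdname autoplot.rs_detect
#' @param decomposition A tibble from [decompose_change()].
#' @export
plot_decomposition <- function(decomposition, ...) {
  df <- decomposition %>%
    filter(.data$interpretable) %>%
    select("item", recalibration = "d_recalibration",
           reprioritization = "d_reprioritization", `true change` = "d_true") %>%
    tidyr::pivot_longer(-"item", names_to = "component", values_to = "d")
  pts <- decomposition %>% filter(.data$interpretable)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$item)) +
    ggplot2::geom_col(ggplot2::aes(x = .data$d, fill = .data$component)) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$d_modeled), shape = 4, size = 2) +
    ggplot2::labs(x = "effect size d (x = modeled change)", y = NULL,
                  title = "Decomposition of change") +
    ggplot2::theme_minimal()
}
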