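#' Dispersion-from-reference summary plot
#'
#' Bar chart of the Bland-Altman sigma of each quantifier (and fused score)
#' from the reference, by region, with bootstrap CIs when present.
#'
#' @param agreements Tibble from [agreement_table()].
#' @return A ggplot object.
#' @export
plot_dispersion <- function(agreements) {
  p <- ggplot2::ggplot(agreements,
                       ggplot2::aes(x = .data$region, y = .data$sigma,
                                    fill = .data$quantifier)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = NULL, y = "Bland-Altman sigma (z-units)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (all(c("sigma_ci_low", "sigma_ci_high") %in% names(agreements))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$sigma_ci_low, ymax = .data$sigma_ci_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3)
  }
  p
}

#' Age versus score scatter in the amyloid-negative subset
#'
#' @param scores Long ScoreTable tibble.
#' @param metadata Cohort metadata tibble.
#' @param quantifiers Quantifiers to facet over.
#' @param region Target region.
#' @return A ggplot object with per-quantifier OLS trend lines.
#' @export
plot_age_association <- function(scores, metadata,
                                 quantifiers = c("SI", "TDr"),
                                 region = "global") {
  df <- scores |>
    dplyr::filter(.data$quantifier %in% quantifiers,
                  .data$region == !!region) |>
    dplyr::inner_join(metadata[metadata$class_label == "negative",
                               c("subject_id", "age")],
                      by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~quantifier, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "score (z-units)",
                  title = paste("Amyloid-negative subset,", region, "region")) +
    ggplot2::theme_minimal()
}
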