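#' Z-score each (quantifier, region) column of a score table
#'
#' Standardises every quantifier/region column to mean 0 and sample
#' (ddof = 1) standard deviation 1 over the whole cohort, so quantifiers
#' with different native scales become comparable. Flagged (missing) scores
#' are ignored by the column statistics and propagate unchanged.
#'
#' @param scores Long ScoreTable tibble from [quantify_cohort()].
#' @return The table with `value` replaced by its per-column z-score.
#' @export
zscore_scores <- function(scores) {
  chk <- scores |>
    dplyr::group_by(.data$quantifier, .data$region) |>
    dplyr::summarise(
      n_distinct_finite = dplyr::n_distinct(.data$value[is.finite(.data$value)]),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  bad <- chk[chk$n_distinct_finite < 2 | !is.finite(chk$sd) | chk$sd == 0, ]
  if (nrow(bad) > 0) {
    stop("cannot z-score zero-variance column(s): ",
         paste(bad$quantifier, bad$region, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  scores |>
    dplyr::group_by(.data$quantifier, .data$region) |>
    dplyr::mutate(value = (.data$value - mean(.data$value, na.rm = TRUE)) /
                    stats::sd(.data$value, na.rm = TRUE)) |>
    dplyr::ungroup()
}
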