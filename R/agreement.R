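#' Bland-Altman agreement between two paired score vectors
#'
#' Computes the bias (mean of differences), the dispersion sigma (sample SD
#' of differences), and the proportional-bias trend: the OLS slope of the
#' differences on the pair means with its 95% confidence interval. The
#' object also records whether the zero-bias line lies inside the bias CI
#' and whether the trend CI contains a flat line — the checks used to
#' exclude bias changes over the measuring interval.
#'
#' @param x Numeric scores under evaluation.
#' @param y Reference scores, same length; incomplete pairs are dropped.
#' @return An `amyq_agreement` object (supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()]).
#' @examples
#' set.seed(1)
#' y <- rnorm(40); x <- y + rnorm(40, sd = 0.3)
#' glance(bland_altman(x, y))
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Bland-Altman needs at least 3 complete pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  sigma <- stats::sd(d)
  bias_se <- sigma / sqrt(n)
  tcrit <- stats::qt(0.975, n - 1)
  if (stats::var(m) > 0 && sigma > 0) {
    fit <- stats::lm(d ~ m)
    ci <- stats::confint(fit)["m", ]
    trend <- unname(stats::coef(fit)[["m"]])
  } else {
    trend <- 0; ci <- c(0, 0)
  }
  structure(
    list(bias = bias, sigma = sigma, n_pairs = n,
         trend_slope = trend, trend_ci = unname(ci),
         bias_ci = bias + c(-1, 1) * tcrit * bias_se,
         zero_bias_within = (bias - tcrit * bias_se) <= 0 &
           0 <= (bias + tcrit * bias_se),
         trend_flat = ci[1] <= 0 & 0 <= ci[2],
         differences = d, means = m),
    class = "amyq_agreement"
  )
}

#' @export
print.amyq_agreement <- function(x, ...) {
  cat(sprintf("<amyq_agreement> n = %d, bias = %.4f, sigma = %.4f, trend = %.4f [%.4f, %.4f]\n",
              x$n_pairs, x$bias, x$sigma, x$trend_slope,
              x$trend_ci[1], x$trend_ci[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.amyq_agreement <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "sigma", "trend_slope"),
    estimate = c(x$bias, x$sigma, x$trend_slope),
    conf.low = c(x$bias_ci[1], NA_real_, x$trend_ci[1]),
    conf.high = c(x$bias_ci[2], NA_real_, x$trend_ci[2])
  )
}

#' @export
glance.amyq_agreement <- function(x, ...) {
  tibble::tibble(bias = x$bias, sigma = x$sigma,
                 trend_slope = x$trend_slope,
                 zero_bias_within = x$zero_bias_within,
                 trend_flat = x$trend_flat, n_pairs = x$n_pairs)
}

#' @export
autoplot.amyq_agreement <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, difference = object$differences)
  loa <- object$bias + c(-1.96, 1.96) * object$sigma
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = loa, colour = "firebrick", linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "pair mean (z-units)", y = "difference (z-units)",
                  title = sprintf("Bland-Altman: bias %.3f, sigma %.3f",
                                  object$bias, object$sigma)) +
    ggplot2::theme_minimal()
}

#' Percentile bootstrap interval for the Bland-Altman sigma
#'
#' Resamples subjects with replacement and returns the 2.5-97.5 percentile
#' interval of the dispersion sigma. Deterministic under `seed`.
#'
#' @inheritParams bland_altman
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Numeric length-2 interval (lower, upper).
#' @export
bootstrap_sigma_ci <- function(x, y, n_boot = 1000, seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  sig <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot),
           function(i) stats::sd(d[sample.int(n, n, replace = TRUE)]), 0)
  })
  unname(stats::quantile(sig, c(0.025, 0.975)))
}

#' Agreement of every quantifier with the reference, per region
#'
#' Maps [bland_altman()] (and optionally [bootstrap_sigma_ci()]) over all
#' quantifier/region columns of a z-scored score table against the
#' reference quantifier, with pairwise deletion of flagged scores.
#'
#' @param scores Long (typically z-scored) ScoreTable tibble.
#' @param reference Reference quantifier name (default `"SI"`).
#' @param n_boot Bootstrap resamples for the sigma CI; 0 skips the bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @return Tibble: quantifier, region, bias, sigma, trend_slope, trend CI,
#'   zero-bias / flat-trend indicators, sigma CI (if bootstrapped), n_pairs.
#' @export
agreement_table <- function(scores, reference = "SI", n_boot = 1000, seed = 1L) {
  wide <- scores_wide(scores)
  quants <- setdiff(unique(scores$quantifier), reference)
  grid <- tidyr::expand_grid(quantifier = quants,
                             region = unique(scores$region))
  purrr::pmap_dfr(grid, function(quantifier, region) {
    sub <- wide[wide$region == region, ]
    x <- sub[[quantifier]]; y <- sub[[reference]]
    ba <- bland_altman(x, y)
    row <- glance(ba)
    row$trend_ci_low <- ba$trend_ci[1]; row$trend_ci_high <- ba$trend_ci[2]
    if (n_boot > 0) {
      ci <- bootstrap_sigma_ci(x, y, n_boot = n_boot, seed = seed)
      row$sigma_ci_low <- ci[1]; row$sigma_ci_high <- ci[2]
    }
    dplyr::bind_cols(tibble::tibble(quantifier = quantifier, region = region), row)
  })
}

# long ScoreTable -> wide tibble (subject_id, region, one column per quantifier)
scores_wide <- function(scores) {
  scores |>
    dplyr::select("subject_id", "quantifier", "region", "value") |>
    tidyr::pivot_wider(names_from = "quantifier", values_from = "value")
}
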