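#' Pearson correlation of every quantifier with the reference, per region
#'
#' Product-moment correlation with a two-sided test, pairwise deletion of
#' flagged scores. A cell whose scores are constant is reported with a
#' missing correlation and a reason rather than an error.
#'
#' @param scores Long ScoreTable tibble (raw or z-scored; Pearson's rho is
#'   invariant to the affine z-transform).
#' @param reference Reference quantifier name.
#' @return Tibble: quantifier, region, rho, p_value, n, note.
#' @export
pearson_matrix <- function(scores, reference = "SI") {
  wide <- scores_wide(scores)
  quants <- setdiff(unique(scores$quantifier), reference)
  grid <- tidyr::expand_grid(quantifier = quants,
                             region = unique(scores$region))
  purrr::pmap_dfr(grid, function(quantifier, region) {
    sub <- wide[wide$region == region, ]
    x <- sub[[quantifier]]; y <- sub[[reference]]
    ok <- is.finite(x) & is.finite(y)
    base <- tibble::tibble(quantifier = quantifier, region = region,
                           rho = NA_real_, p_value = NA_real_,
                           n = sum(ok), note = NA_character_)
    if (sum(ok) < 3) {
      base$note <- "fewer than 3 complete pairs"
      return(base)
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      base$note <- "constant column; correlation undefined"
      return(base)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    base$rho <- unname(ct$estimate)
    base$p_value <- ct$p.value
    base
  })
}

#' Residual-independence check between quantifier pairs
#'
#' For each ordered pair among SUVr, ELBA, TDr and WMR, fits y ~ x by OLS
#' and reports (i) the correlation between the residuals and the predictor
#' (identically zero under OLS, reported as the sanity check it is), (ii)
#' the F-test of refitting residuals ~ x against the null model, and (iii)
#' as a supplementary diagnostic, the correlation of each model's residuals
#' with every third quantifier — the non-trivial independence check.
#'
#' @param scores Long ScoreTable tibble.
#' @param region Target region to analyse (default `"global"`).
#' @param quantifiers The four quantifiers to pair up.
#' @return List with `pairs` (per-model tibble) and `cross` (residual vs
#'   third-quantifier tibble).
#' @export
residual_independence <- function(scores, region = "global",
                                  quantifiers = c("SUVr", "ELBA", "TDr", "WMR")) {
  wide <- scores_wide(scores)
  sub <- wide[wide$region == region, ]
  combos <- utils::combn(quantifiers, 2, simplify = FALSE)
  pair_rows <- list(); cross_rows <- list()
  for (cb in combos) {
    yq <- cb[1]; xq <- cb[2]
    x <- sub[[xq]]; y <- sub[[yq]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4) stop("fewer than 4 complete pairs for ", yq, " ~ ", xq,
                          call. = FALSE)
    if (stats::sd(x[ok]) == 0) stop("degenerate predictor variance in ", xq,
                                    call. = FALSE)
    fit <- stats::lm(y[ok] ~ x[ok])
    res <- stats::residuals(fit)
    refit <- stats::lm(res ~ x[ok])
    an <- stats::anova(refit)
    pair_rows[[paste(yq, xq)]] <- tibble::tibble(
      response = yq, predictor = xq,
      n = sum(ok),
      resid_predictor_cor = if (stats::sd(res) == 0) 0 else stats::cor(res, x[ok]),
      refit_slope = unname(stats::coef(refit)[2]),
      refit_r_squared = summary(refit)$r.squared,
      null_model_f = an$`F value`[1],
      null_model_p = an$`Pr(>F)`[1]
    )
    for (zq in setdiff(quantifiers, cb)) {
      z <- sub[[zq]][ok]
      ok2 <- is.finite(z) & is.finite(res)
      cross_rows[[paste(yq, xq, zq)]] <- tibble::tibble(
        response = yq, predictor = xq, third = zq,
        n = sum(ok2),
        resid_third_cor = if (sum(ok2) >= 3 && stats::sd(z[ok2]) > 0)
          stats::cor(res[ok2], z[ok2]) else NA_real_
      )
    }
  }
  list(pairs = dplyr::bind_rows(pair_rows),
       cross = dplyr::bind_rows(cross_rows))
}
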