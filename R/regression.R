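#' Variance inflation factors of a covariate matrix
#'
#' VIF of covariate j is 1 / (1 - R^2) from regressing it on the other
#' covariates. Perfect collinearity yields an infinite VIF with a warning,
#' not an error.
#'
#' @param covariates Numeric matrix or data frame with >= 2 columns and
#'   more rows than columns.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(covariates) {
  x <- as.matrix(covariates)
  p <- ncol(x)
  if (p < 2) stop("need at least 2 covariates", call. = FALSE)
  if (nrow(x) <= p) stop("need more observations than covariates", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm(x[, j] ~ x[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # silence perfect-fit note
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity: infinite VIF for ", colnames(x)[j],
              call. = FALSE)
      return(Inf)
    }
    1 / (1 - r2)
  }, 0)
  stats::setNames(out, colnames(x))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (monotone, capped at 1). The
#' family over which the correction runs is whatever vector is passed in;
#' [negative_subset_regressions()] exposes the family choice.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA`s pass through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Age and thickness associations in the amyloid-negative subset
#'
#' For every quantifier and region, fits an OLS model of the score on age
#' and the matching region's cortical thickness over amyloid-negative
#' subjects only, screens the covariates for collinearity with [vif()], and
#' adjusts the p-values with [bh_adjust()].
#'
#' @param scores Long ScoreTable tibble (z-scored or raw).
#' @param metadata Cohort metadata with `subject_id`, `age`, `class_label`
#'   and `thickness_<region>` columns.
#' @param bh_family `"all"` (default): one BH family across every
#'   quantifier x region x covariate test in the run; `"covariate"`:
#'   separate families for age and thickness; `"region"`: one family per
#'   region.
#' @param min_negatives Minimum number of negatives required.
#' @return Tibble with one row per quantifier x region: `beta_age`,
#'   `p_age`, `beta_thickness`, `p_thickness`, `vif_age`,
#'   `vif_thickness`, `p_age_adj`, `p_thickness_adj`, `n`; the BH family
#'   used is recorded in the `"bh_family"` attribute.
#' @export
negative_subset_regressions <- function(scores, metadata,
                                        bh_family = c("all", "covariate", "region"),
                                        min_negatives = 10L) {
  bh_family <- match.arg(bh_family)
  neg <- metadata[metadata$class_label == "negative", ]
  if (nrow(neg) < min_negatives) {
    stop("need at least ", min_negatives, " amyloid-negative subjects (got ",
         nrow(neg), ")", call. = FALSE)
  }
  wide <- scores_wide(scores)
  quants <- unique(scores$quantifier)
  regions <- unique(scores$region)
  rows <- list()
  for (rg in regions) {
    th_col <- paste0("thickness_", rg)
    if (!th_col %in% names(neg)) {
      stop("metadata lacks column ", th_col, call. = FALSE)
    }
    sub <- dplyr::inner_join(wide[wide$region == rg, ],
                             neg[, c("subject_id", "age", th_col)],
                             by = "subject_id")
    for (q in quants) {
      y <- sub[[q]]; age <- sub$age; th <- sub[[th_col]]
      ok <- is.finite(y) & is.finite(age) & is.finite(th)
      n_ok <- sum(ok)
      if (n_ok < 4) next
      v <- vif(cbind(age = age[ok], thickness = th[ok]))
      fit <- stats::lm(y[ok] ~ age[ok] + th[ok])
      cf <- summary(fit)$coefficients
      rows[[paste(q, rg)]] <- tibble::tibble(
        quantifier = q, region = rg,
        beta_age = cf[2, 1], p_age = cf[2, 4],
        beta_thickness = cf[3, 1], p_thickness = cf[3, 4],
        vif_age = v[["age"]], vif_thickness = v[["thickness"]],
        n = n_ok
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (bh_family == "all") {
    adj <- bh_adjust(c(out$p_age, out$p_thickness))
    out$p_age_adj <- adj[seq_len(nrow(out))]
    out$p_thickness_adj <- adj[nrow(out) + seq_len(nrow(out))]
  } else if (bh_family == "covariate") {
    out$p_age_adj <- bh_adjust(out$p_age)
    out$p_thickness_adj <- bh_adjust(out$p_thickness)
  } else {
    out <- out |>
      dplyr::group_by(.data$region) |>
      dplyr::group_modify(function(df, key) {
        adj <- bh_adjust(c(df$p_age, df$p_thickness))
        df$p_age_adj <- adj[seq_len(nrow(df))]
        df$p_thickness_adj <- adj[nrow(df) + seq_len(nrow(df))]
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::relocate("quantifier", "region")
  }
  attr(out, "bh_family") <- bh_family
  out
}

#' Render regression results as a significance-star summary table
#'
#' One row per region/quantifier with the age and thickness coefficients
#' annotated `**` (p < 0.001), `*` (p < 0.05) or `n.s.`; a trailing `(a)`
#' marks associations still significant after BH adjustment.
#'
#' @param records Output of [negative_subset_regressions()].
#' @return Tibble with formatted `age` and `thickness` columns.
#' @export
format_regression_table <- function(records) {
  star <- function(beta, p, p_adj) {
    ifelse(p > 0.05, "n.s.",
           paste0(formatC(beta, digits = 3, format = "f"),
                  ifelse(p < 0.001, "**", "*"),
                  ifelse(p_adj < 0.05, " (a)", "")))
  }
  tibble::tibble(
    region = records$region,
    quantifier = records$quantifier,
    age = star(records$beta_age, records$p_age, records$p_age_adj),
    thickness = star(records$beta_thickness, records$p_thickness,
                     records$p_thickness_adj)
  )
}
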