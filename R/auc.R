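#' Mann-Whitney AUC point estimate
#'
#' P(score_positive > score_negative) with ties counting one half,
#' computed from midranks (equivalent to brute-force pair counting).
#'
#' @param scores Numeric vector.
#' @param labels Vector with exactly two classes; `positive` names the
#'   positive class.
#' @param positive Positive-class label.
#' @return Scalar AUC in \[0, 1\].
#' @export
mann_whitney_auc <- function(scores, labels, positive = "positive") {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap ROC analysis of a score against binary class labels
#'
#' The point statistic is the Mann-Whitney AUC; generalised performance is
#' summarised as the mean and 2.5-97.5 percentile interval of the AUC over
#' stratified bootstrap resamples (each class resampled with replacement
#' within itself, so both classes are always present). Deterministic under
#' `seed`.
#'
#' @inheritParams mann_whitney_auc
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return An `amyq_auc` object with `auc` (point estimate), `auc_mean`,
#'   `auc_ci`, `n_boot`, and class counts; supports `tidy()`/`glance()`.
#' @export
auc_bootstrap <- function(scores, labels, n_boot = 1000, seed = 1L,
                          positive = "positive") {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos_idx <- which(labels == positive)
  neg_idx <- which(labels != positive)
  if (length(pos_idx) < 2 || length(neg_idx) < 2) {
    stop("need at least 2 subjects per class (got ", length(neg_idx),
         " negative, ", length(pos_idx), " positive)", call. = FALSE)
  }
  point <- mann_whitney_auc(scores, labels, positive)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos_idx, length(pos_idx), replace = TRUE),
               sample(neg_idx, length(neg_idx), replace = TRUE))
      mann_whitney_auc(scores[idx], labels[idx], positive)
    }, 0)
  })
  structure(
    list(auc = point, auc_mean = mean(boot),
         auc_ci = unname(stats::quantile(boot, c(0.025, 0.975))),
         n_boot = n_boot, n_positive = length(pos_idx),
         n_negative = length(neg_idx)),
    class = "amyq_auc"
  )
}

#' @export
print.amyq_auc <- function(x, ...) {
  cat(sprintf("<amyq_auc> AUC = %.3f (bootstrap mean %.3f, 95%% CI [%.3f, %.3f], %d resamples)\n",
              x$auc, x$auc_mean, x$auc_ci[1], x$auc_ci[2], x$n_boot))
  invisible(x)
}

#' @export
tidy.amyq_auc <- function(x, ...) {
  tibble::tibble(term = "auc", estimate = x$auc,
                 boot_mean = x$auc_mean,
                 conf.low = x$auc_ci[1], conf.high = x$auc_ci[2])
}

#' @export
glance.amyq_auc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_mean = x$auc_mean,
                 auc_ci_low = x$auc_ci[1], auc_ci_high = x$auc_ci[2],
                 n_boot = x$n_boot,
                 n_positive = x$n_positive, n_negative = x$n_negative)
}

#' Bootstrap AUC of every quantifier (and fused score), per region
#'
#' @param scores Long ScoreTable tibble (raw or z-scored; AUC is invariant
#'   to strictly monotone transforms).
#' @param metadata Cohort metadata tibble with `subject_id`, `class_label`.
#' @inheritParams auc_bootstrap
#' @return Tibble: quantifier, region, auc, auc_mean, CI bounds, n per class.
#' @export
auc_table <- function(scores, metadata, n_boot = 1000, seed = 1L) {
  joined <- dplyr::inner_join(
    scores, metadata[, c("subject_id", "class_label")], by = "subject_id")
  joined |>
    dplyr::group_by(.data$quantifier, .data$region) |>
    dplyr::group_modify(function(df, key) {
      glance(auc_bootstrap(df$value, df$class_label,
                           n_boot = n_boot, seed = seed))
    }) |>
    dplyr::ungroup()
}
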