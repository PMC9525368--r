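#' Preset quantifier combinations
#'
#' AVG1 = SUVr + ELBA (late frame only), AVG2 adds TDr (dual time point),
#' AVG3 adds WMR.
#' @return Named list of member vectors.
#' @export
avg_presets <- function() {
  list(AVG1 = c("SUVr", "ELBA"),
       AVG2 = c("SUVr", "ELBA", "TDr"),
       AVG3 = c("SUVr", "ELBA", "TDr", "WMR"))
}

#' Inverse-dispersion fusion weights
#'
#' Weight of member i is (1/sigma_i) / sum_j (1/sigma_j), where sigma_i is
#' the member's global (whole-brain) Bland-Altman dispersion from the
#' reference. Quantifiers agreeing better with the reference contribute
#' more.
#'
#' @param agreements Agreement tibble from [agreement_table()]; only its
#'   `region == "global"` rows are used.
#' @param members Character vector of at least two quantifier names.
#' @return Tibble with `quantifier`, `sigma`, `weight` (weights sum to 1,
#'   ordered as `members`).
#' @export
fusion_weights <- function(agreements, members) {
  if (length(members) < 2) stop("need at least two members to fuse", call. = FALSE)
  glob <- agreements[agreements$region == "global", ]
  sig <- glob$sigma[match(members, glob$quantifier)]
  if (anyNA(sig)) {
    stop("missing global sigma for member(s): ",
         paste(members[is.na(sig)], collapse = ", "), call. = FALSE)
  }
  if (any(sig <= 0)) {
    stop("zero global sigma for member(s): ",
         paste(members[sig <= 0], collapse = ", "),
         " (infinite weight)", call. = FALSE)
  }
  w <- (1 / sig) / sum(1 / sig)
  tibble::tibble(quantifier = members, sigma = sig, weight = w)
}

#' Fuse z-scored quantifiers into a combined score
#'
#' Per subject and region, the fused score is the weighted mean of the
#' members' z-scores, with weights either inverse to each member's global
#' dispersion from the reference (`"inverse_sigma"`, the default) or equal
#' (`"unweighted"`). Regional fusion reuses the global weights. A subject /
#' region cell is missing when any member score is missing there.
#'
#' @param scores Z-scored long ScoreTable.
#' @param members Quantifier names to combine (>= 2).
#' @param agreements [agreement_table()] output (required for
#'   `"inverse_sigma"` mode).
#' @param name Quantifier name given to the fused score rows.
#' @param mode `"inverse_sigma"` or `"unweighted"`.
#' @return List with `scores` (long tibble of fused rows, same columns as
#'   the input minus diagnostics) and `weights` (the weight tibble).
#' @export
fuse <- function(scores, members, agreements = NULL, name = "AVG",
                 mode = c("inverse_sigma", "unweighted")) {
  mode <- match.arg(mode)
  if (mode == "inverse_sigma") {
    if (is.null(agreements)) {
      stop("`agreements` is required for inverse-sigma weighting", call. = FALSE)
    }
    wt <- fusion_weights(agreements, members)
  } else {
    if (length(members) < 2) stop("need at least two members to fuse", call. = FALSE)
    wt <- tibble::tibble(quantifier = members, sigma = NA_real_,
                         weight = rep(1 / length(members), length(members)))
  }
  fused <- scores |>
    dplyr::filter(.data$quantifier %in% members) |>
    dplyr::inner_join(wt[, c("quantifier", "weight")], by = "quantifier") |>
    dplyr::group_by(.data$subject_id, .data$region) |>
    dplyr::summarise(value = sum(.data$value * .data$weight), .groups = "drop") |>
    dplyr::mutate(quantifier = name, flag = NA_character_, .after = "subject_id")
  list(scores = fused, weights = wt)
}

#' Append the three preset combinations to a z-scored score table
#'
#' @inheritParams fuse
#' @param agreements [agreement_table()] output against the reference.
#' @return List with `scores` (input table plus AVG1/AVG2/AVG3 rows) and
#'   `weights` (tibble of per-preset weights).
#' @export
fuse_presets <- function(scores, agreements,
                         mode = c("inverse_sigma", "unweighted")) {
  mode <- match.arg(mode)
  presets <- avg_presets()
  out <- purrr::imap(presets, function(members, nm) {
    fuse(scores, members, agreements, name = nm, mode = mode)
  })
  fused_rows <- purrr::map_dfr(out, "scores")
  weights <- purrr::imap_dfr(out, function(x, nm) {
    dplyr::mutate(x$weights, preset = nm, .before = 1)
  })
  list(scores = dplyr::bind_rows(
         dplyr::select(scores, -dplyr::any_of("diagnostics")), fused_rows),
       weights = weights)
}
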