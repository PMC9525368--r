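# Disk-level orchestration: simulate -> quantify -> compare with a single
# YAML config and a content-hash manifest per stage.

#' Load and validate a pipeline run configuration
#'
#' The configuration is a flat YAML file with optional sections `atlas`,
#' `cohort`, `quantifier` and `comparison`, plus a mandatory top-level
#' `seed`. Any field omitted falls back to the package defaults
#' ([cohort_spec()], [quantifier_config()]); unknown fields are rejected.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated `run_config` list with fully-populated sections.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$seed)) {
    stop("config schema: mandatory field `seed` is missing", call. = FALSE)
  }
  known <- c("seed", "atlas", "cohort", "quantifier", "comparison", "output_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("config schema: unknown field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  atlas_args <- cfg$atlas %||% list()
  atlas_args$shape <- unlist(atlas_args$shape %||% c(48L, 48L, 48L))
  atlas_args$voxel_size_mm <- unlist(atlas_args$voxel_size_mm %||% c(3, 3, 3))
  atlas_args$seed <- atlas_args$seed %||% cfg$seed

  cohort_args <- cfg$cohort %||% list()
  if (!is.null(cohort_args$age_range)) {
    cohort_args$age_range <- unlist(cohort_args$age_range)
  }
  cohort_args$seed <- cohort_args$seed %||% cfg$seed
  spec <- do.call(cohort_spec, cohort_args)

  qcfg <- do.call(quantifier_config, cfg$quantifier %||% list())

  comparison <- cfg$comparison %||% list()
  comparison$n_boot <- comparison$n_boot %||% 1000L
  comparison$bh_family <- comparison$bh_family %||% "all"
  comparison$reference <- comparison$reference %||% "SI"
  comparison$fusion_mode <- comparison$fusion_mode %||% "inverse_sigma"

  structure(list(seed = as.integer(cfg$seed), atlas = atlas_args,
                 cohort = spec, quantifier = qcfg, comparison = comparison),
            class = "run_config")
}

config_as_list <- function(config) {
  list(seed = config$seed,
       atlas = config$atlas,
       cohort = unclass(config$cohort),
       quantifier = unclass(config$quantifier),
       comparison = config$comparison)
}

write_manifest <- function(dir, config, files) {
  hashes <- tools::md5sum(file.path(dir, files))
  names(hashes) <- files
  manifest <- list(
    tool = "amyquant",
    version = as.character(utils::packageVersion("amyquant")),
    seed = config$seed,
    config = config_as_list(config),
    files = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort to disk
#'
#' Writes, under `out_dir`: one early and one late NIfTI volume per subject
#' (`sub-XXX_early.nii.gz`, `sub-XXX_late.nii.gz`), the shared integer label
#' map (`labels.nii.gz`), the cortical shell-depth map used for
#' atrophy-aware segmentation (`shellfrac.nii.gz`), the cohort metadata
#' table (`cohort.csv`, including the per-subject registration shifts so a
#' re-read cohort scores identically), and a `manifest.json` with the
#' effective config and an md5 hash of every file. NIfTI affines are
#' diagonal RAS at the configured voxel size.
#'
#' @param config A `run_config` from [load_run_config()] (or a path to one).
#' @param out_dir Output directory, created if needed.
#' @return (Invisibly) the in-memory `phantom_cohort`.
#' @export
pipeline_simulate <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- do.call(make_atlas, config$atlas)
  cohort <- simulate_cohort(atlas, config$cohort)

  vox <- atlas$voxel_size_mm
  write_vol <- function(arr, path) {
    img <- RNifti::asNifti(arr, reference = NULL)
    RNifti::pixdim(img) <- vox
    RNifti::writeNifti(img, path)
  }
  files <- character(0)
  write_vol(atlas$label_map, file.path(out_dir, "labels.nii.gz"))
  sf <- atlas$shell_frac
  sf[is.na(sf)] <- -1
  write_vol(sf, file.path(out_dir, "shellfrac.nii.gz"))
  jsonlite::write_json(as.list(atlas$label_codes),
                       file.path(out_dir, "labels.json"), auto_unbox = TRUE)
  files <- c(files, "labels.nii.gz", "shellfrac.nii.gz", "labels.json")
  for (s in cohort$subjects) {
    fe <- paste0(s$meta$subject_id, "_early.nii.gz")
    fl <- paste0(s$meta$subject_id, "_late.nii.gz")
    write_vol(s$early, file.path(out_dir, fe))
    write_vol(s$late, file.path(out_dir, fl))
    files <- c(files, fe, fl)
  }
  md <- cohort$metadata
  sh <- t(vapply(cohort$subjects,
                 function(s) unlist(s$meta$misreg_shift), integer(12)))
  colnames(sh) <- paste0("misreg_", rep(c("suvr", "elba", "tdr", "wmr"), each = 3),
                         "_", rep(c("x", "y", "z"), 4))
  md <- dplyr::bind_cols(md, tibble::as_tibble(sh))
  utils::write.csv(md, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  files <- c(files, "cohort.csv")
  write_manifest(out_dir, config, files)
  invisible(cohort)
}

#' Read a simulated (or user-supplied) cohort directory
#'
#' Expects the layout written by [pipeline_simulate()]. When the metadata
#' carries registration-shift and atrophy columns the reconstructed scans
#' score identically to the in-memory originals; a minimal directory
#' (volumes + labels + ids) is also accepted, in which case registration is
#' taken as exact and segmentation as atlas-complete.
#'
#' @param dir Cohort directory.
#' @return A `phantom_cohort`-shaped list (`subjects`, `metadata`, `atlas`).
#' @export
read_cohort <- function(dir) {
  lab_path <- file.path(dir, "labels.nii.gz")
  if (!file.exists(lab_path)) stop("no labels.nii.gz in ", dir, call. = FALSE)
  lab_img <- RNifti::readNifti(lab_path)
  vox <- RNifti::pixdim(lab_img)[1:3]
  lab <- array(as.integer(round(as.array(lab_img))), dim(lab_img))
  # label dictionary: a labels.json next to the volume overrides the
  # package's built-in codes (user-supplied cohorts may label differently)
  codes <- atlas_label_codes
  dict_path <- file.path(dir, "labels.json")
  if (file.exists(dict_path)) {
    dict <- jsonlite::read_json(dict_path)
    missing_labels <- setdiff(names(atlas_label_codes), names(dict))
    if (length(missing_labels) > 0) {
      stop("label dictionary ", dict_path, " lacks: ",
           paste(missing_labels, collapse = ", "), call. = FALSE)
    }
    codes <- vapply(dict[names(atlas_label_codes)], as.integer, 0L)
  }
  atlas <- structure(
    list(label_map = lab, voxel_size_mm = as.numeric(vox),
         label_codes = codes,
         shell_frac = NULL, seed = NA_integer_,
         cache = new.env(parent = emptyenv())),
    class = "phantom_atlas"
  )
  sf_path <- file.path(dir, "shellfrac.nii.gz")
  if (file.exists(sf_path)) {
    sf <- as.array(RNifti::readNifti(sf_path))
    sf[sf < 0] <- NA_real_
    atlas$shell_frac <- sf
  }
  md <- tibble::as_tibble(utils::read.csv(file.path(dir, "cohort.csv"),
                                          stringsAsFactors = FALSE))
  subjects <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    id <- md$subject_id[i]
    early <- as.array(RNifti::readNifti(file.path(dir, paste0(id, "_early.nii.gz"))))
    late <- as.array(RNifti::readNifti(file.path(dir, paste0(id, "_late.nii.gz"))))
    shift <- NULL
    if ("misreg_suvr_x" %in% names(md)) {
      g <- function(q) as.integer(md[i, paste0("misreg_", q, "_", c("x", "y", "z"))])
      shift <- list(SUVr = g("suvr"), ELBA = g("elba"), TDr = g("tdr"),
                    WMR = if ("misreg_wmr_x" %in% names(md)) g("wmr")
                          else c(0L, 0L, 0L))
    }
    atrophied <- NULL
    if (!is.null(atlas$shell_frac) && "atrophy" %in% names(md)) {
      atrophied <- !is.na(atlas$shell_frac) & atlas$shell_frac > md$atrophy[i]
    }
    subjects[[i]] <- structure(
      list(early = early, late = late, atlas = atlas, atrophied = atrophied,
           meta = list(subject_id = id,
                       age = md$age[i] %||% NA_real_,
                       class_label = md$class_label[i] %||% NA_character_,
                       misreg_shift = shift)),
      class = "subject_scan"
    )
  }
  names(subjects) <- md$subject_id
  structure(list(subjects = subjects, metadata = md, atlas = atlas),
            class = "phantom_cohort")
}

#' Quantify a cohort directory to a long-format score CSV
#'
#' @param cohort_dir Directory from [pipeline_simulate()] (or equivalent).
#' @param config A `run_config` or path; only the quantifier section is used.
#' @param out_csv Output CSV path (long format; diagnostics serialised as
#'   JSON strings).
#' @return (Invisibly) the ScoreTable tibble.
#' @export
pipeline_quantify <- function(cohort_dir, config, out_csv) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  cohort <- read_cohort(cohort_dir)
  excluded <- character(0)
  scans <- list()
  for (s in cohort$subjects) {
    ok <- tryCatch({
      stopifnot(all(is.finite(s$late)), all(is.finite(s$early)))
      TRUE
    }, error = function(e) FALSE)
    if (ok) scans[[s$meta$subject_id]] <- s
    else excluded[[s$meta$subject_id]] <- "unreadable or non-finite volume"
  }
  scores <- quantify_cohort(scans, config$quantifier)
  excluded <- c(excluded, attr(scores, "excluded"))
  out <- scores
  out$diagnostics <- vapply(out$diagnostics, function(d) {
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA))
  }, "")
  dir.create(dirname(out_csv), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, out_csv, row.names = FALSE)
  if (length(excluded) > 0) {
    message(length(excluded), " subject(s) excluded: ",
            paste(names(excluded), collapse = ", "))
  }
  attr(scores, "excluded") <- excluded
  invisible(scores)
}

#' Run the full statistical comparison on score and metadata files
#'
#' Z-scores the table, computes the Bland-Altman agreement of every
#' quantifier with the reference (with bootstrap sigma CIs), the three
#' preset fused scores and their weights, Pearson correlations, the
#' residual-independence diagnostics, bootstrap AUCs against the visual
#' labels, and the amyloid-negative age/thickness regressions. Writes each
#' result as CSV plus a `manifest.json` and a significance-star summary
#' (`regressions_formatted.txt`).
#'
#' @param scores_csv Long ScoreTable CSV from [pipeline_quantify()].
#' @param metadata_csv Cohort metadata CSV.
#' @param config A `run_config` or path (comparison section: `n_boot`,
#'   `bh_family`, `reference`, `fusion_mode`).
#' @param out_dir Output directory.
#' @return (Invisibly) a named list of all result tibbles.
#' @export
pipeline_compare <- function(scores_csv, metadata_csv, config, out_dir) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  cmp <- config$comparison
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- tibble::as_tibble(utils::read.csv(scores_csv, stringsAsFactors = FALSE))
  metadata <- tibble::as_tibble(utils::read.csv(metadata_csv, stringsAsFactors = FALSE))
  if (!all(unique(scores$subject_id) %in% metadata$subject_id)) {
    stop("subject ids in scores are missing from metadata", call. = FALSE)
  }
  scores$value <- as.numeric(scores$value)

  z <- zscore_scores(scores)
  agreements <- agreement_table(z, reference = cmp$reference,
                                n_boot = cmp$n_boot, seed = config$seed)
  fused <- fuse_presets(z, agreements, mode = cmp$fusion_mode)
  agreements_fused <- agreement_table(fused$scores, reference = cmp$reference,
                                      n_boot = cmp$n_boot, seed = config$seed)
  correlations <- pearson_matrix(fused$scores, reference = cmp$reference)
  resid <- residual_independence(z)

  results <- list(agreement = agreements_fused,
                  fusion_weights = fused$weights,
                  correlation = correlations,
                  residual_pairs = resid$pairs,
                  residual_cross = resid$cross)

  if ("class_label" %in% names(metadata) &&
      all(c("negative", "positive") %in% metadata$class_label)) {
    results$auc <- auc_table(fused$scores, metadata,
                             n_boot = cmp$n_boot, seed = config$seed)
  } else if (isTRUE(cmp$require_auc)) {
    stop("AUC requested but both class labels are not present", call. = FALSE)
  }
  n_neg <- sum(metadata$class_label == "negative")
  if (n_neg >= 10) {
    results$regressions <- negative_subset_regressions(
      z, metadata, bh_family = cmp$bh_family)
  }

  files <- character(0)
  for (nm in names(results)) {
    f <- paste0(nm, ".csv")
    utils::write.csv(results[[nm]], file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(results$regressions)) {
    fmt <- format_regression_table(results$regressions)
    writeLines(
      c(sprintf("%-12s %-10s %-16s %-16s", "region", "quantifier", "age", "thickness"),
        sprintf("%-12s %-10s %-16s %-16s", fmt$region, fmt$quantifier,
                fmt$age, fmt$thickness)),
      file.path(out_dir, "regressions_formatted.txt"))
    files <- c(files, "regressions_formatted.txt")
  }
  write_manifest(out_dir, config, files)
  invisible(results)
}

#' Run simulate, quantify and compare end to end
#'
#' One seed (from the config) governs the whole chain; two runs with the
#' same config produce byte-identical data files.
#'
#' @param config A `run_config` or path to a YAML config.
#' @param out_dir Root output directory (`cohort/`, `scores.csv`,
#'   `comparison/` are created inside).
#' @return (Invisibly) the comparison results list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  cohort_dir <- file.path(out_dir, "cohort")
  pipeline_simulate(config, cohort_dir)
  scores_csv <- file.path(out_dir, "scores.csv")
  pipeline_quantify(cohort_dir, config, scores_csv)
  pipeline_compare(scores_csv, file.path(cohort_dir, "cohort.csv"),
                   config, file.path(out_dir, "comparison"))
}
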