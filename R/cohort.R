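#' Specification of a synthetic dual time-point cohort
#'
#' The defaults emulate the study conditions the package is designed around:
#' 54 amyloid-negative and 31 amyloid-positive subjects aged 44–87, a mild
#' physiological age-related amyloid accumulation inside the negative
#' cluster, a positive cluster centred at 0.65 with SD 0.19 on the
#' ground-truth load scale (mirroring the reported reference-index cluster
#' statistics 0.01 ± 0.12 vs 0.65 ± 0.19, i.e. a standardised separation of
#' roughly 3.4), and a moderate negative age–thickness correlation.
#'
#' @param n_negative,n_positive Class sizes; their sum must be >= 2 and both
#'   must be >= 1 when an AUC analysis is intended.
#' @param age_range Two ages in years.
#' @param age_slope Ground-truth amyloid accumulation inside the negative
#'   cluster, load units per year.
#' @param neg_load_base Negative-cluster load at the lower age bound.
#' @param pos_load_mean,pos_load_sd Positive-cluster load distribution
#'   (normal truncated at 0).
#' @param load_jitter_sd SD of the independent per-lobe load jitter.
#' @param thickness_age_corr Target age–thickness correlation in (-1, 0].
#' @param thickness_base,thickness_noise_sd,thickness_region_sd Cortical
#'   thickness model (mm): subject mean = base + slope * centred age +
#'   subject noise; per-lobe values add independent regional jitter.
#' @param flow_factor_sd SD of the subject-level global flow/dose factor
#'   that scales both tissues' early-frame intensity together (global
#'   cerebral blood flow and injected-dose kinetics vary per subject but
#'   affect grey and white matter jointly).
#' @param perfusion_gm_mean,perfusion_gm_sd,perfusion_wm_mean,perfusion_wm_sd
#'   Tissue-specific early-frame perfusion: per-subject values are the
#'   global flow factor times independent tissue draws, so the GM/WM
#'   contrast varies much less than absolute flow.
#' @param misreg_vox Template-registration error (voxels per axis) applied
#'   to the MRI-free quantifiers' masks; see [subject_params()].
#' @param wm_seg_vox PET-space WM segmentation error of the WMR pipeline
#'   (voxels per axis); see [subject_params()].
#' @param s_wm_nonspec_sd,s_gm_nonspec_sd Relative SDs of the per-subject
#'   nonspecific white- and grey-matter late-frame binding (multiplicative
#'   around the [subject_params()] tissue constants); between-subject
#'   variation of nonspecific binding is a dominant error source for
#'   white-matter-referenced indices.
#' @param cereb_binding_sd Relative SD of the per-subject cerebellar
#'   binding scale (reference-region variability, hits SUVr).
#' @param noise_sd,psf_fwhm_mm Acquisition noise and resolution passed to
#'   [simulate_subject()].
#' @param texture_fwhm_mm,binding_texture_sd,perfusion_texture_sd Smooth
#'   within-subject biological heterogeneity of late-frame binding and
#'   early-frame perfusion; see [subject_params()].
#' @param atrophy_ref_thickness Thickness (mm) at and above which the
#'   cortical shell is fully preserved; thinner cortices are proportionally
#'   eroded.
#' @param seed Integer master seed; one seed governs ages, loads, thickness,
#'   perfusion and all per-subject acquisition noise.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_negative = 54L,
                        n_positive = 31L,
                        age_range = c(44, 87),
                        age_slope = 0.004,
                        neg_load_base = 0,
                        pos_load_mean = 0.65,
                        pos_load_sd = 0.19,
                        load_jitter_sd = 0.03,
                        thickness_age_corr = -0.4,
                        thickness_base = 2.8,
                        thickness_noise_sd = 0.15,
                        thickness_region_sd = 0.08,
                        flow_factor_sd = 0.03,
                        perfusion_gm_mean = 1.0,
                        perfusion_gm_sd = 0.03,
                        perfusion_wm_mean = 0.6,
                        perfusion_wm_sd = 0.015,
                        noise_sd = 0.05,
                        psf_fwhm_mm = 6,
                        texture_fwhm_mm = 12,
                        binding_texture_sd = 0.04,
                        perfusion_texture_sd = 0.04,
                        misreg_vox = 1L,
                        wm_seg_vox = 0L,
                        s_wm_nonspec_sd = 0.06,
                        s_gm_nonspec_sd = 0.03,
                        cereb_binding_sd = 0.02,
                        atrophy_ref_thickness = 3.0,
                        seed = 1L) {
  n_negative <- as.integer(n_negative); n_positive <- as.integer(n_positive)
  if (n_negative < 0 || n_positive < 0 || n_negative + n_positive < 2L) {
    stop("need at least two subjects in total", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("`age_range` must be increasing [lo, hi]", call. = FALSE)
  }
  if (abs(thickness_age_corr) >= 1) {
    stop("`thickness_age_corr` magnitude must be < 1", call. = FALSE)
  }
  if (thickness_age_corr > 0) {
    stop("`thickness_age_corr` must be in (-1, 0]", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a full phantom cohort
#'
#' Draws per-subject ground truth (age, class, per-lobe amyloid load,
#' thickness, perfusion, atrophy) from a [cohort_spec()] and renders every
#' subject's dual time-point scan with [simulate_subject()]. The master seed
#' makes the whole cohort — metadata and voxel data — bit-reproducible.
#'
#' Ground-truth model: ages are uniform on `age_range`; negative subjects
#' accumulate load linearly with age (`neg_load_base + age_slope * (age -
#' lo)`) plus per-lobe jitter, truncated at 0; positive subjects draw a
#' subject-level load from a truncated normal plus the same per-lobe jitter.
#' Thickness declines with age at a rate calibrated analytically so the
#' population age–thickness correlation equals `thickness_age_corr`; the
#' subject's mean thickness drives cortical atrophy (thickness /
#' `atrophy_ref_thickness`, capped at 1), which in turn dilutes uncorrected
#' region means — the partial-volume error channel of the phantom.
#'
#' @param atlas A [make_atlas()] phantom shared by all subjects.
#' @param spec A [cohort_spec()].
#' @param metadata_only If `TRUE`, draw the ground truth but skip rendering
#'   the volumes (`subjects` is `NULL`); the metadata is identical to a full
#'   run with the same spec. Useful for statistical studies of the
#'   generator itself.
#' @return A `phantom_cohort`: list with `subjects` (list of `subject_scan`),
#'   `metadata` (tibble: subject_id, age, class_label, atrophy, perfusion,
#'   `thickness_<region>`, `true_load_<region>`, and global summaries),
#'   `atlas`, and `spec`.
#' @examples
#' atl <- make_atlas(seed = 1)
#' coh <- simulate_cohort(atl, cohort_spec(n_negative = 3, n_positive = 2, seed = 7))
#' coh$metadata[, c("subject_id", "age", "class_label", "true_load_global")]
#' @export
simulate_cohort <- function(atlas, spec = cohort_spec(), metadata_only = FALSE) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(spec, "cohort_spec"))
  n <- spec$n_negative + spec$n_positive
  lobes <- lobar_regions()

  draws <- withr::with_seed(as.integer(spec$seed), {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    cls <- rep(c("negative", "positive"), c(spec$n_negative, spec$n_positive))

    # thickness slope calibrated so cor(age, thickness) == thickness_age_corr
    # in population: b = rho * sd_eps / (sd_age * sqrt(1 - rho^2))
    sd_age <- diff(spec$age_range) / sqrt(12)
    rho <- spec$thickness_age_corr
    b <- if (rho == 0) 0 else rho * spec$thickness_noise_sd / (sd_age * sqrt(1 - rho^2))
    th_subj <- spec$thickness_base + b * (age - mean(spec$age_range)) +
      stats::rnorm(n, 0, spec$thickness_noise_sd)
    th_reg <- matrix(stats::rnorm(n * length(lobes), 0, spec$thickness_region_sd),
                     n, length(lobes), dimnames = list(NULL, lobes))
    thickness <- th_subj + th_reg
    thickness[] <- pmax(1.0, thickness)

    subj_load <- ifelse(
      cls == "negative",
      spec$neg_load_base + spec$age_slope * (age - spec$age_range[1]),
      pmax(0, stats::rnorm(n, spec$pos_load_mean, spec$pos_load_sd))
    )
    load_reg <- matrix(stats::rnorm(n * length(lobes), 0, spec$load_jitter_sd),
                       n, length(lobes), dimnames = list(NULL, lobes))
    load <- subj_load + load_reg
    load[] <- pmax(0, load)

    flow <- pmax(0.5, stats::rnorm(n, 1, spec$flow_factor_sd))
    pg <- flow * pmax(0.2, stats::rnorm(n, spec$perfusion_gm_mean, spec$perfusion_gm_sd))
    pw <- flow * pmax(0.1, stats::rnorm(n, spec$perfusion_wm_mean, spec$perfusion_wm_sd))
    pw <- pmin(pw, pg - 1e-3)  # GM stays better perfused than WM

    s_wm <- 1.0 * pmax(0.5, stats::rnorm(n, 1, spec$s_wm_nonspec_sd))
    s_gm <- 0.55 * pmax(0.5, stats::rnorm(n, 1, spec$s_gm_nonspec_sd))
    cereb <- pmax(0.5, stats::rnorm(n, 1, spec$cereb_binding_sd))

    noise_seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(age = age, cls = cls, thickness = thickness, load = load,
         flow = flow, pg = pg, pw = pw,
         s_wm = s_wm, s_gm = s_gm, cereb = cereb,
         noise_seeds = noise_seeds)
  })

  ids <- sprintf("sub-%03d", seq_len(n))
  atrophy_vec <- pmin(1, rowMeans(draws$thickness) / spec$atrophy_ref_thickness)
  subjects <- NULL
  if (!metadata_only) {
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    atrophy <- atrophy_vec[i]
    params <- subject_params(
      age = min(max(draws$age[i], 44), 87),
      amyloid_load = draws$load[i, ],
      perfusion_gm = draws$pg[i],
      perfusion_wm = draws$pw[i],
      atrophy = atrophy,
      thickness = draws$thickness[i, ],
      noise_sd = spec$noise_sd,
      psf_fwhm_mm = spec$psf_fwhm_mm,
      texture_fwhm_mm = spec$texture_fwhm_mm,
      binding_texture_sd = spec$binding_texture_sd,
      perfusion_texture_sd = spec$perfusion_texture_sd,
      misreg_vox = spec$misreg_vox,
      wm_seg_vox = spec$wm_seg_vox,
      s_wm_nonspec = draws$s_wm[i],
      s_gm_nonspec = draws$s_gm[i],
      cereb_binding_scale = draws$cereb[i]
    )
    subjects[[i]] <- simulate_subject(atlas, params,
                                      seed = draws$noise_seeds[i],
                                      subject_id = ids[i],
                                      class_label = draws$cls[i])
  }
  names(subjects) <- ids
  }

  md <- tibble::tibble(
    subject_id = ids,
    age = draws$age,
    class_label = draws$cls,
    atrophy = atrophy_vec,
    flow_factor = draws$flow,
    perfusion_gm = draws$pg,
    perfusion_wm = draws$pw
  )
  for (r in lobes) md[[paste0("thickness_", r)]] <- draws$thickness[, r]
  for (r in lobes) md[[paste0("true_load_", r)]] <- draws$load[, r]
  md$thickness_global <- rowMeans(draws$thickness)
  md$true_load_global <- rowMeans(draws$load)

  structure(list(subjects = subjects, metadata = md,
                 atlas = atlas, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$subjects), " subjects (",
      sum(x$metadata$class_label == "negative"), " negative / ",
      sum(x$metadata$class_label == "positive"), " positive), atlas ",
      paste(dim(x$atlas$label_map), collapse = "x"), "\n", sep = "")
  invisible(x)
}
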