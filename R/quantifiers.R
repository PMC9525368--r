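# The five semi-quantitative amyloid indices. Each user-facing function
# returns a one-row RegionScore tibble so that results bind naturally into
# the long ScoreTable format; quantify_subject() drives the shared numeric
# cores directly and assembles one tibble per subject.

QUANTIFIERS <- c("SUVr", "ELBA", "TDr", "WMR", "SI")

region_score <- function(scan, quantifier, region, value,
                         flag = NA_character_, diagnostics = list()) {
  tibble::tibble(
    subject_id = scan$meta$subject_id,
    quantifier = quantifier,
    region = region,
    value = value,
    flag = flag,
    diagnostics = list(diagnostics)
  )
}

#' Mean intensity over a voxel mask
#'
#' @param volume 3D numeric array.
#' @param mask Logical array of the same shape.
#' @param region_name Used in the error message when the mask is empty.
#' @return Scalar mean.
#' @export
roi_mean <- function(volume, mask, region_name = "region") {
  if (!any(mask)) {
    stop("empty mask for region '", region_name, "'", call. = FALSE)
  }
  mean(volume[mask])
}

# ---- mask plumbing ---------------------------------------------------------

# All masks derived from an atlas, cached in the atlas environment so that
# scoring a whole cohort against one atlas computes them once.
atlas_masks <- function(atlas, erosion_mm) {
  key <- paste0("masks_", format(erosion_mm))
  if (!is.null(atlas$cache) && !is.null(atlas$cache[[key]])) {
    return(atlas$cache[[key]])
  }
  gm <- lapply(stats::setNames(nm = target_regions()),
               function(r) region_mask(atlas, r))
  m <- list(
    gm = gm,
    wm = region_mask(atlas, "wm"),
    cerebellum = region_mask(atlas, "cerebellum"),
    cerebellum_gm = region_mask(atlas, "cerebellum_gm"),
    all_gm = array(atlas$label_map %in%
                     atlas$label_codes[c(lobar_regions(), "cerebellum_gm")],
                   dim(atlas$label_map))
  )
  m$wm_core <- erode_mask(m$wm, erosion_mm, atlas$voxel_size_mm)
  if (!is.null(atlas$cache)) atlas$cache[[key]] <- m
  m
}

# integer-voxel translation of a logical mask, FALSE outside the grid
translate_mask <- function(mask, shift) {
  if (all(shift == 0L)) return(mask)
  d <- dim(mask)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(array(FALSE, d))
    if (s >= 0) {
      src[[ax]] <- seq_len(d[ax] - s); dst[[ax]] <- seq_len(d[ax] - s) + s
    } else {
      src[[ax]] <- seq_len(d[ax] + s) - s; dst[[ax]] <- seq_len(d[ax] + s)
    }
  }
  out <- array(FALSE, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# Registration context. WMR and SI are MRI-guided: they see the subject's
# own segmentation, i.e. atlas masks with the atrophy-eroded cortical
# voxels removed (what a structural scan segments as grey matter). Each
# MRI-free quantifier (SUVr, ELBA, TDr) instead sees the static atlas
# displaced by its own pipeline's template-registration error.
scan_masks <- function(scan, cfg, regions = target_regions()) {
  exact <- atlas_masks(scan$atlas, cfg$wm_core_erosion_mm)
  atro <- scan$atrophied
  if (!is.null(atro) && any(atro)) {
    keep <- !atro
    mri <- exact
    mri$gm <- lapply(exact$gm, function(m) m & keep)
    mri$all_gm <- exact$all_gm & keep
  } else {
    mri <- exact
  }
  shifts <- scan$meta$misreg_shift
  if (is.null(shifts)) {
    z <- c(0L, 0L, 0L)
    shifts <- list(SUVr = z, ELBA = z, TDr = z, WMR = z)
  }
  if (is.null(shifts$WMR)) shifts$WMR <- c(0L, 0L, 0L)
  coarse_for <- function(sh) {
    if (all(sh == 0L)) return(exact)
    list(
      gm = lapply(exact$gm[regions], translate_mask, shift = sh),
      wm = translate_mask(exact$wm, sh),
      cerebellum = translate_mask(exact$cerebellum, sh),
      wm_core = translate_mask(exact$wm_core, sh)
    )
  }
  # WMR: MRI-guided GM target, but its WM sample is segmented in PET space
  # (the documented source of extra WMR variability), modelled as an
  # independently displaced WM mask
  wmr_masks <- mri
  if (!all(shifts$WMR == 0L)) {
    wmr_masks$wm <- translate_mask(exact$wm, shifts$WMR)
  }
  list(exact = mri,
       WMRseg = wmr_masks,
       SUVr = coarse_for(shifts$SUVr),
       ELBA = coarse_for(shifts$ELBA),
       TDr = coarse_for(shifts$TDr))
}

# ---- numeric cores ---------------------------------------------------------

suvr_core <- function(scan, region, masks) {
  ref <- roi_mean(scan$late, masks$cerebellum, "cerebellum")
  if (ref <= 0) stop("cerebellar reference mean is not positive", call. = FALSE)
  tgt <- roi_mean(scan$late, masks$gm[[region]], region)
  list(value = tgt / ref, flag = NA_character_,
       diagnostics = list(ref_mean = ref))
}

elba_core <- function(scan, region, masks) {
  g <- scan$late[masks$gm[[region]]]
  w <- scan$late[masks$wm]
  if (length(g) == 0 || length(w) == 0) {
    stop("empty GM or WM sample for ELBA in region '", region, "'", call. = FALSE)
  }
  r <- rank(c(g, w))  # midranks handle ties at one half
  u <- sum(r[seq_along(g)]) - length(g) * (length(g) + 1) / 2
  list(value = 2 * u / (length(g) * length(w)) - 1, flag = NA_character_,
       diagnostics = list(n_gm = length(g), n_wm = length(w)))
}

tdr_core <- function(scan, region, cfg, masks) {
  gm <- masks$gm[[region]]
  e_gm <- scan$early[gm]
  if (length(e_gm) == 0) stop("empty GM mask for TDr in region '", region, "'",
                              call. = FALSE)
  thr <- stats::quantile(e_gm, cfg$hotspot_percentile / 100, names = FALSE)
  hot <- gm & scan$early > thr
  if (!any(hot)) {
    stop("TDr hotspot empty in region '", region, "' at percentile ",
         cfg$hotspot_percentile, call. = FALSE)
  }
  core <- masks$wm_core
  if (!any(core)) stop("TDr WM core empty after ", cfg$wm_core_erosion_mm,
                       " mm erosion", call. = FALSE)
  ref <- core & scan$early >= stats::median(scan$early[core])
  if (!any(ref)) {
    stop("TDr adapted WM reference empty after ", cfg$wm_core_erosion_mm,
         " mm erosion", call. = FALSE)
  }
  list(value = roi_mean(scan$late, hot, "hotspot") /
         roi_mean(scan$late, ref, "adapted WM"),
       flag = NA_character_,
       diagnostics = list(n_hotspot = sum(hot), n_ref = sum(ref)))
}

wmr_core <- function(scan, region, cfg, masks) {
  gm <- masks$gm[[region]]
  num <- roi_mean(scan$late, gm, region) - roi_mean(scan$late, masks$wm, "wm")
  e_wm <- roi_mean(scan$early, masks$wm, "wm")
  den <- roi_mean(scan$early, gm, region) - e_wm
  floor_abs <- cfg$wmr_denominator_floor * abs(e_wm)
  diag <- list(numerator = num, denominator = den, floor = floor_abs)
  if (abs(den) < floor_abs) {
    return(list(value = NA_real_, flag = "unstable_denominator",
                diagnostics = diag))
  }
  list(value = num / den, flag = NA_character_, diagnostics = diag)
}

# Shared slope-index machinery: white-matter-core normalisation of both
# frames and (optionally) PVE correction of the normalised late frame.
si_context <- function(scan, cfg, masks = NULL) {
  if (is.null(masks)) masks <- atlas_masks(scan$atlas, cfg$wm_core_erosion_mm)
  e_wm <- roi_mean(scan$early, masks$wm_core, "wm core")
  l_wm <- roi_mean(scan$late, masks$wm_core, "wm core")
  if (e_wm <= 0 || l_wm <= 0) {
    stop("white-matter core mean not positive; cannot normalise", call. = FALSE)
  }
  en <- scan$early / e_wm
  ln <- scan$late / l_wm
  if (cfg$pvec_enabled) {
    ln <- pve_correct(ln, masks$all_gm, cfg$pvec_psf_fwhm_mm,
                      scan$atlas$voxel_size_mm, cfg$gm_inclusion_threshold)
  }
  list(en = en, ln = ln, masks = masks)
}

si_slope <- function(en, ln, mask) {
  x <- en[mask]; y <- ln[mask]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::var(x) < 1e-12) {
    return(list(slope = NA_real_, r2 = NA_real_, n = n, unstable = TRUE))
  }
  sl <- stats::cov(x, y) / stats::var(x)
  r2 <- stats::cor(x, y)^2
  list(slope = sl, r2 = r2, n = n, unstable = FALSE)
}

si_core <- function(scan, region, ctx) {
  fit <- si_slope(ctx$en, ctx$ln, ctx$masks$gm[[region]])
  cal <- si_slope(ctx$en, ctx$ln, ctx$masks$cerebellum_gm)
  diag <- list(r2 = fit$r2, n_voxels = fit$n, cal_slope = cal$slope)
  if (fit$unstable || cal$unstable) {
    return(list(value = NA_real_, flag = "degenerate_early_frame",
                diagnostics = diag))
  }
  list(value = fit$slope - cal$slope, flag = NA_character_, diagnostics = diag)
}

# ---- user-facing quantifiers ----------------------------------------------

#' SUVr: standardized uptake value ratio
#'
#' Late-frame mean of the target grey matter divided by the late-frame mean
#' of the whole cerebellum (grey + white), the amyloid-free reference.
#' Uses only the late frame and the (template-registered) atlas.
#'
#' @param scan A [simulate_subject()] scan (or any `subject_scan`).
#' @param region `"global"` or a lobar region name.
#' @param cfg A [quantifier_config()].
#' @return One-row RegionScore tibble.
#' @export
suvr <- function(scan, region = "global", cfg = quantifier_config()) {
  res <- suvr_core(scan, region, scan_masks(scan, cfg, region)$SUVr)
  region_score(scan, "SUVr", region, res$value, res$flag, res$diagnostics)
}

#' ELBA-style rank contrast
#'
#' A reference-region-free index of the late-frame grey/white intensity
#' distribution contrast: the Mann-Whitney rank statistic between the target
#' region's GM voxels and the whole-brain WM voxels, rescaled to \[-1, 1\]
#' (ties count one half). Negative scans show GM below WM (score near -1);
#' amyloid drives GM intensities up through and past WM. This is an
#' operational surrogate for the radiomic ELBA score, preserving its
#' documented character (late frame only, no reference ROI, GM-vs-WM
#' contrast); it is not the original algorithm.
#'
#' @inheritParams suvr
#' @return One-row RegionScore tibble.
#' @export
elba_score <- function(scan, region = "global", cfg = quantifier_config()) {
  res <- elba_core(scan, region, scan_masks(scan, cfg, region)$ELBA)
  region_score(scan, "ELBA", region, res$value, res$flag, res$diagnostics)
}

#' TDr: time-delayed ratio on the individually adapted hotspot
#'
#' Uses the early frame to adapt both ROIs: the target is the subset of the
#' region's GM whose early-frame intensity exceeds the configured percentile
#' of early intensities within that GM mask (the area of maximal perfusion),
#' and the reference is the eroded white-matter core restricted to its
#' upper-median early intensities. The score is the late-frame mean ratio of
#' hotspot to adapted reference.
#'
#' @inheritParams suvr
#' @return One-row RegionScore tibble.
#' @export
tdr <- function(scan, region = "global", cfg = quantifier_config()) {
  res <- tdr_core(scan, region, cfg, scan_masks(scan, cfg, region)$TDr)
  region_score(scan, "TDr", region, res$value, res$flag, res$diagnostics)
}

#' WMR: white-matter-referenced early/late difference ratio
#'
#' Ratio of the (target GM - WM) mean-activity difference on the late frame
#' to the same difference on the early frame, computed on the MRI-guided
#' (exact) masks. When the early-frame difference falls below the configured
#' floor in magnitude — the documented low-perfusion degeneracy — the score
#' is returned flagged-unstable with a missing value rather than as an
#' exploding ratio.
#'
#' @inheritParams suvr
#' @return One-row RegionScore tibble; `flag` is `"unstable_denominator"`
#'   and `value` is `NA` in the degenerate case.
#' @export
wmr <- function(scan, region = "global", cfg = quantifier_config()) {
  res <- wmr_core(scan, region, cfg, scan_masks(scan, cfg)$WMRseg)
  region_score(scan, "WMR", region, res$value, res$flag, res$diagnostics)
}

#' Meltzer-style partial volume effect correction
#'
#' Divides the image by the PSF-smoothed binary GM mask, recovering the true
#' GM plateau where the mask retention is reliable; voxels where the
#' smoothed mask falls at or below `gm_inclusion_threshold` are set to `NA`
#' (excluded rather than amplified).
#'
#' @param late 3D numeric array (typically the late frame).
#' @param gm_mask Logical 3D array of grey-matter voxels.
#' @param psf_fwhm_mm Assumed PSF FWHM in mm (> 0).
#' @param voxel_size_mm Voxel size triple in mm.
#' @param gm_inclusion_threshold Retention cut-off in (0, 1].
#' @return 3D array of corrected values, `NA` where excluded.
#' @export
pve_correct <- function(late, gm_mask, psf_fwhm_mm,
                        voxel_size_mm = c(3, 3, 3),
                        gm_inclusion_threshold = 0.5) {
  if (psf_fwhm_mm <= 0) stop("`psf_fwhm_mm` must be > 0", call. = FALSE)
  sm <- smooth_gaussian_3d(array(as.numeric(gm_mask), dim(gm_mask)),
                           psf_fwhm_mm, voxel_size_mm)
  keep <- sm > gm_inclusion_threshold
  if (!any(keep)) {
    stop("smoothed GM mask nowhere exceeds the inclusion threshold ",
         gm_inclusion_threshold, call. = FALSE)
  }
  out <- array(NA_real_, dim(late))
  out[keep] <- late[keep] / sm[keep]
  out
}

#' Slope index: kinetic late-vs-early GM regression slope
#'
#' The reference quantifier of the comparison. Both frames are normalised by
#' the eroded white-matter core mean (a dose/flow normalisation); the
#' normalised late frame is optionally PVE-corrected on grey matter; the
#' index is the least-squares slope of normalised-late on normalised-early
#' over the region's GM voxels, minus the same slope over the amyloid-free
#' cerebellar grey matter. A fully amyloid-negative subject therefore sits
#' near zero. This is an operational surrogate for the full kinetic slope
#' model: it keeps every asserted property (kinetic, GM-only, flow
#' normalised, robust to atrophy and spillover, which attenuate both frames
#' together) without the original's patient-specific atlas machinery. Uses
#' the MRI-guided (exact) masks.
#'
#' @inheritParams suvr
#' @return One-row RegionScore tibble; flagged `"degenerate_early_frame"`
#'   when the early-frame variance over the region's GM vanishes.
#' @export
slope_index <- function(scan, region = "global", cfg = quantifier_config()) {
  ctx <- si_context(scan, cfg)
  res <- si_core(scan, region, ctx)
  region_score(scan, "SI", region, res$value, res$flag, res$diagnostics)
}

#' Score one subject with all five quantifiers over all target regions
#'
#' @inheritParams suvr
#' @param regions Character vector of target regions (default: global plus
#'   the ten lobes).
#' @return RegionScore tibble with 5 x `length(regions)` rows.
#' @export
quantify_subject <- function(scan, cfg = quantifier_config(),
                             regions = target_regions()) {
  mk <- scan_masks(scan, cfg, regions)
  ctx <- si_context(scan, cfg, mk$exact)
  res <- lapply(regions, function(r) {
    list(
      SUVr = suvr_core(scan, r, mk$SUVr),
      ELBA = elba_core(scan, r, mk$ELBA),
      TDr = tdr_core(scan, r, cfg, mk$TDr),
      WMR = wmr_core(scan, r, cfg, mk$WMRseg),
      SI = si_core(scan, r, ctx)
    )
  })
  flat <- unlist(res, recursive = FALSE)
  tibble::tibble(
    subject_id = scan$meta$subject_id,
    quantifier = rep(QUANTIFIERS, times = length(regions)),
    region = rep(regions, each = length(QUANTIFIERS)),
    value = vapply(flat, function(x) x$value, 0),
    flag = vapply(flat, function(x) x$flag, ""),
    diagnostics = lapply(flat, function(x) x$diagnostics)
  )
}

#' Score a whole cohort
#'
#' Applies [quantify_subject()] to every subject. A failing subject does not
#' abort the run: it is excluded, the failure is logged with the subject id,
#' and the exclusions are reported in the `"excluded"` attribute of the
#' returned table.
#'
#' @param cohort A [simulate_cohort()] result (or a list with a `subjects`
#'   element of `subject_scan`s).
#' @param cfg A [quantifier_config()].
#' @param regions Target regions to score.
#' @return Long ScoreTable tibble: `subject_id`, `quantifier`, `region`,
#'   `value`, `flag`, `diagnostics` (list-column). Attribute `"excluded"` is
#'   a named character vector of per-subject error messages (empty when all
#'   subjects scored).
#' @export
quantify_cohort <- function(cohort, cfg = quantifier_config(),
                            regions = target_regions()) {
  subjects <- if (inherits(cohort, "phantom_cohort")) cohort$subjects else cohort
  if (length(subjects) == 0) stop("empty cohort", call. = FALSE)
  excluded <- character(0)
  res <- lapply(subjects, function(s) {
    tryCatch(quantify_subject(s, cfg, regions), error = function(e) {
      excluded[[s$meta$subject_id]] <<- conditionMessage(e)
      warning("subject ", s$meta$subject_id, " excluded: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  out <- dplyr::bind_rows(res)
  attr(out, "excluded") <- excluded
  out
}
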