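#' Tuning parameters for the five quantifiers
#'
#' @param hotspot_percentile Percentile (in (50, 100)) of the early-frame
#'   intensity distribution within a region's grey matter above which voxels
#'   enter the TDr hotspot target.
#' @param wm_core_erosion_mm Morphological erosion, in mm, applied to the
#'   cerebral white-matter mask before it is used as the TDr reference and
#'   the slope-index normalisation region; erosion keeps the core clear of
#'   grey-matter spill-in.
#' @param wmr_denominator_floor Stability floor for the WMR denominator,
#'   expressed as a fraction of the white-matter early-frame mean. When the
#'   early-frame GM-minus-WM difference falls below this floor in magnitude
#'   (the documented low-perfusion failure mode) the score is returned
#'   flagged-unstable rather than as an exploding ratio.
#' @param pvec_enabled Apply a Meltzer-style partial volume effect
#'   correction to the late frame before the slope-index regression.
#'   Off by default: on a homogeneous-plateau phantom the correction
#'   flattens the late frame over grey matter and with it the cross-voxel
#'   late-vs-early contrast that the slope surrogate measures (the
#'   voxelwise slope is already largely insensitive to partial-volume
#'   dilution, which attenuates both frames together).
#' @param pvec_psf_fwhm_mm Assumed scanner PSF FWHM (mm) for the correction.
#' @param gm_inclusion_threshold Voxels where the PSF-smoothed binary GM
#'   mask falls at or below this fraction are excluded from corrected maps.
#' @return A `quantifier_config` list.
#' @export
quantifier_config <- function(hotspot_percentile = 90,
                              wm_core_erosion_mm = 6,
                              wmr_denominator_floor = 0.05,
                              pvec_enabled = FALSE,
                              pvec_psf_fwhm_mm = 6,
                              gm_inclusion_threshold = 0.5) {
  assert_scalar_num(hotspot_percentile, "hotspot_percentile", 50 + 1e-9, 100 - 1e-9)
  assert_scalar_num(wm_core_erosion_mm, "wm_core_erosion_mm", 0)
  assert_scalar_num(wmr_denominator_floor, "wmr_denominator_floor", 1e-12)
  assert_scalar_num(pvec_psf_fwhm_mm, "pvec_psf_fwhm_mm", 1e-12)
  assert_scalar_num(gm_inclusion_threshold, "gm_inclusion_threshold", 1e-12, 1)
  structure(list(hotspot_percentile = hotspot_percentile,
                 wm_core_erosion_mm = wm_core_erosion_mm,
                 wmr_denominator_floor = wmr_denominator_floor,
                 pvec_enabled = isTRUE(pvec_enabled),
                 pvec_psf_fwhm_mm = pvec_psf_fwhm_mm,
                 gm_inclusion_threshold = gm_inclusion_threshold),
            class = "quantifier_config")
}
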