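#' Ground-truth parameters for one simulated subject
#'
#' Bundles everything the dual time-point simulator needs: per-lobe amyloid
#' burden, grey/white-matter perfusion driving the early frame, tissue
#' intensity constants for the late frame, cortical atrophy, per-region
#' cortical thickness, acquisition noise and scanner resolution.
#'
#' The late-frame model is: white matter binds the tracer non-specifically at
#' `s_wm_nonspec`; lobar grey matter takes `s_gm_nonspec + a_r * s_spec`
#' where `a_r` is that lobe's amyloid load; cerebellar grey matter is
#' amyloid-free by construction (`s_gm_nonspec` only), which is what makes
#' the whole cerebellum a valid SUVr reference. The defaults give negative
#' subjects the florbetaben-like appearance of grey matter darker than white
#' matter on the late frame.
#'
#' @param age Age in years, in \[44, 87\].
#' @param amyloid_load Named numeric vector of per-lobe burden in \[0, 1.2\]
#'   (names = [lobar_regions()]), or a single scalar recycled to all lobes.
#' @param perfusion_gm,perfusion_wm Early-frame tissue intensities; grey
#'   matter must be better perfused than white matter (`perfusion_gm >
#'   perfusion_wm > 0`) at defaults.
#' @param atrophy Grey-shell thinning factor in (0, 1]; values below 1 erode
#'   the outer part of the cortical shell to CSF before intensities are
#'   assigned (the atlas labels are left untouched, so region means are
#'   diluted exactly as partial-volume-naive scoring of an atrophic brain
#'   would be).
#' @param thickness Named numeric vector, cortical thickness in mm per lobe;
#'   scalar recycled.
#' @param noise_sd Standard deviation of additive Gaussian noise applied
#'   after the point-spread function; nonnegative.
#' @param texture_fwhm_mm,binding_texture_sd,perfusion_texture_sd Smooth
#'   within-subject heterogeneity of tracer binding (late frame) and
#'   perfusion (early frame): each frame's tissue intensities are modulated
#'   by an independent multiplicative random field `1 + f(x)`, where `f` is
#'   white noise smoothed to `texture_fwhm_mm` and rescaled to the given
#'   relative SD. This emulates the spatially structured biological
#'   variability (periventricular binding gradients, regional perfusion
#'   patterns) that penalises small adaptive ROIs more than whole-region
#'   means. Set the SDs to 0 for perfectly homogeneous tissue.
#' @param misreg_vox Maximum template-registration error, in voxels per
#'   axis. The MRI-free quantifiers (SUVr, ELBA, TDr) align the atlas to
#'   the PET through a generic template, which is coarser than MRI-guided
#'   registration; this is modelled as a uniform integer-voxel shift of
#'   their label masks, drawn per subject from the scan seed. Set to 0 for
#'   perfect registration everywhere.
#' @param wm_seg_vox Maximum error, in voxels per axis, of the PET-space
#'   white-matter segmentation used by the WMR pipeline (a documented
#'   extra source of WMR variability). Off (0) by default: at 3 mm voxels
#'   a one-voxel displacement already overstates the effect.
#' @param psf_fwhm_mm Full width at half maximum of the isotropic Gaussian
#'   point-spread function in mm; nonnegative.
#' @param s_wm_nonspec,s_gm_nonspec,s_spec Late-frame tissue constants
#'   (nonspecific white-matter binding, nonspecific grey-matter binding,
#'   and the specific signal per unit amyloid load).
#' @param cereb_binding_scale Multiplier on both cerebellar tissues'
#'   late-frame intensity, modelling subject-level variation of reference
#'   region binding (affects SUVr's denominator and the slope-index
#'   calibration, not the cerebral target regions).
#' @return A `subject_params` list.
#' @export
subject_params <- function(age = 70,
                           amyloid_load = 0,
                           perfusion_gm = 1.0,
                           perfusion_wm = 0.6,
                           atrophy = 1.0,
                           thickness = 2.5,
                           noise_sd = 0.05,
                           psf_fwhm_mm = 6,
                           misreg_vox = 1L,
                           wm_seg_vox = 0L,
                           texture_fwhm_mm = 12,
                           binding_texture_sd = 0.04,
                           perfusion_texture_sd = 0.04,
                           s_wm_nonspec = 1.0,
                           s_gm_nonspec = 0.55,
                           s_spec = 0.9,
                           cereb_binding_scale = 1.0) {
  assert_scalar_num(age, "age", 44, 87)
  lobes <- lobar_regions()
  if (length(amyloid_load) == 1L) {
    amyloid_load <- stats::setNames(rep(amyloid_load, length(lobes)), lobes)
  }
  if (!all(lobes %in% names(amyloid_load))) {
    stop("`amyloid_load` must be named by the ten lobar regions", call. = FALSE)
  }
  amyloid_load <- amyloid_load[lobes]
  if (any(!is.finite(amyloid_load)) || any(amyloid_load < 0)) {
    stop("`amyloid_load` entries must be finite and nonnegative", call. = FALSE)
  }
  if (perfusion_wm <= 0 || perfusion_gm <= 0) {
    stop("perfusion values must be positive", call. = FALSE)
  }
  assert_scalar_num(atrophy, "atrophy", lo = 1e-6, hi = 1)
  if (length(thickness) == 1L) {
    thickness <- stats::setNames(rep(thickness, length(lobes)), lobes)
  }
  thickness <- thickness[lobes]
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("`psf_fwhm_mm` must be nonnegative", call. = FALSE)
  misreg_vox <- as.integer(misreg_vox)
  if (misreg_vox < 0) stop("`misreg_vox` must be nonnegative", call. = FALSE)
  wm_seg_vox <- as.integer(wm_seg_vox)
  if (wm_seg_vox < 0) stop("`wm_seg_vox` must be nonnegative", call. = FALSE)
  if (texture_fwhm_mm <= 0 || binding_texture_sd < 0 || perfusion_texture_sd < 0) {
    stop("texture FWHM must be positive and texture SDs nonnegative",
         call. = FALSE)
  }
  structure(
    list(age = age, amyloid_load = amyloid_load,
         perfusion_gm = perfusion_gm, perfusion_wm = perfusion_wm,
         atrophy = atrophy, thickness = thickness,
         noise_sd = noise_sd, psf_fwhm_mm = psf_fwhm_mm,
         misreg_vox = misreg_vox, wm_seg_vox = wm_seg_vox,
         texture_fwhm_mm = texture_fwhm_mm,
         binding_texture_sd = binding_texture_sd,
         perfusion_texture_sd = perfusion_texture_sd,
         s_wm_nonspec = s_wm_nonspec, s_gm_nonspec = s_gm_nonspec,
         s_spec = s_spec, cereb_binding_scale = cereb_binding_scale),
    class = "subject_params"
  )
}

#' Simulate one dual time-point PET acquisition
#'
#' Renders an early (perfusion-weighted) and a late (amyloid-weighted) frame
#' on the phantom atlas. The early frame only sees tissue perfusion — it is
#' identical across subjects that differ solely in amyloid load. Both frames
#' are blurred by the same Gaussian point-spread function and then receive
#' independent additive Gaussian noise.
#'
#' @param atlas A [make_atlas()] phantom.
#' @param params A [subject_params()] object.
#' @param seed Integer seed for the noise; the same `(atlas, params, seed)`
#'   gives bit-identical output.
#' @param subject_id Optional identifier carried into the metadata.
#' @param class_label `"negative"` or `"positive"` visual-read label.
#' @return A `subject_scan`: list with `early`, `late` (3D arrays), `atlas`,
#'   and `meta` (age, thickness, class label, ground-truth load).
#' @export
simulate_subject <- function(atlas, params, seed = 1L,
                             subject_id = "sub-001",
                             class_label = c("negative", "positive")) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(params, "subject_params"))
  class_label <- match.arg(class_label)
  lab <- atlas$label_map
  codes <- atlas$label_codes
  shape <- dim(lab)

  gm_cortical <- lab %in% codes[setdiff(lobar_regions(),
                                        c("central_L", "central_R"))]
  dim(gm_cortical) <- shape
  # atrophy: the outer (1 - atrophy) fraction of the cortical shell becomes
  # CSF-like before intensity assignment
  atrophied <- gm_cortical & !is.na(atlas$shell_frac) &
    atlas$shell_frac > params$atrophy

  is_gm <- lab %in% codes[c(lobar_regions(), "cerebellum_gm")]
  dim(is_gm) <- shape
  is_wm <- lab %in% codes[c("wm", "cerebellum_wm")]
  dim(is_wm) <- shape

  early <- array(0, shape)
  early[is_gm] <- params$perfusion_gm
  early[is_wm] <- params$perfusion_wm
  early[atrophied] <- 0

  late <- array(0, shape)
  late[lab == codes[["wm"]]] <- params$s_wm_nonspec
  late[lab == codes[["cerebellum_wm"]]] <-
    params$s_wm_nonspec * params$cereb_binding_scale
  late[lab == codes[["cerebellum_gm"]]] <-
    params$s_gm_nonspec * params$cereb_binding_scale
  for (r in lobar_regions()) {
    late[lab == codes[[r]]] <- params$s_gm_nonspec +
      params$amyloid_load[[r]] * params$s_spec
  }
  late[atrophied] <- 0

  texture_field <- function(sd_target) {
    if (sd_target <= 0) return(NULL)
    f <- smooth_gaussian_3d(array(stats::rnorm(prod(shape)), shape),
                            params$texture_fwhm_mm, atlas$voxel_size_mm)
    f * (sd_target / stats::sd(f))
  }
  draws <- withr::with_seed(as.integer(seed), {
    # one independent template-registration error per MRI-free pipeline,
    # plus the optional PET-space WM segmentation error of the WMR pipeline
    z <- c(0L, 0L, 0L)
    shift <- if (params$misreg_vox > 0) {
      s <- sample(seq(-params$misreg_vox, params$misreg_vox), 9L, replace = TRUE)
      list(SUVr = s[1:3], ELBA = s[4:6], TDr = s[7:9])
    } else {
      list(SUVr = z, ELBA = z, TDr = z)
    }
    shift$WMR <- if (params$wm_seg_vox > 0) {
      sample(seq(-params$wm_seg_vox, params$wm_seg_vox), 3L, replace = TRUE)
    } else z
    list(shift = lapply(shift, as.integer),
         tex_e = texture_field(params$perfusion_texture_sd),
         tex_l = texture_field(params$binding_texture_sd),
         noise = if (params$noise_sd > 0) {
           list(e = stats::rnorm(length(early), 0, params$noise_sd),
                l = stats::rnorm(length(late), 0, params$noise_sd))
         })
  })
  # smooth multiplicative biological heterogeneity, applied before the PSF
  if (!is.null(draws$tex_e)) early <- early * pmax(0.2, 1 + draws$tex_e)
  if (!is.null(draws$tex_l)) late <- late * pmax(0.2, 1 + draws$tex_l)

  early <- smooth_gaussian_3d(early, params$psf_fwhm_mm, atlas$voxel_size_mm)
  late  <- smooth_gaussian_3d(late,  params$psf_fwhm_mm, atlas$voxel_size_mm)

  if (!is.null(draws$noise)) {
    early <- early + draws$noise$e
    late <- late + draws$noise$l
  }
  # PET activity is nonnegative
  early[early < 0] <- 0
  late[late < 0] <- 0

  structure(
    list(early = early, late = late, atlas = atlas,
         atrophied = atrophied,
         meta = list(subject_id = subject_id,
                     age = params$age,
                     thickness = params$thickness,
                     class_label = class_label,
                     amyloid_load = params$amyloid_load,
                     misreg_shift = draws$shift,
                     params = params,
                     seed = as.integer(seed))),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  cat("<subject_scan> ", x$meta$subject_id, ": ",
      paste(dim(x$early), collapse = " x "),
      " voxels, age ", x$meta$age, ", ", x$meta$class_label,
      ", global load ", round(mean(x$meta$amyloid_load), 3), "\n", sep = "")
  invisible(x)
}
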