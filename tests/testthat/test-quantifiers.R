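# The five quantifiers: arithmetic oracles, interface compliance,
# invariances, degeneracies.

test_that("roi_mean is the arithmetic mean over the mask and rejects empty masks", {
  v <- array(7, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
  expect_equal(roi_mean(v, m), 7)
  v[1, 1, 1] <- 1; v[2, 1, 1] <- 3
  expect_equal(roi_mean(v, m), 2)
  expect_error(roi_mean(v, array(FALSE, c(4, 4, 4)), "frontal_L"), "frontal_L")

  # against an independent voxel loop on a simulated subject
  s <- clean_subject(a = 0.3)
  lab <- s$atlas$label_map
  code <- s$atlas$label_codes[["parietal_R"]]
  acc <- 0; nn <- 0
  for (i in which(lab == code)) { acc <- acc + s$late[i]; nn <- nn + 1 }
  expect_equal(roi_mean(s$late, region_mask(s$atlas, "parietal_R")), acc / nn)
})

test_that("SUVr is 1 on a uniform late volume and follows the closed form at zero load", {
  s <- clean_subject(a = 0, psf_fwhm_mm = 0)
  s$late[] <- 3.2
  for (r in c("global", "frontal_L", "central_R")) {
    expect_equal(suvr(s, r)$value, 1)
  }
  s0 <- clean_subject(a = 0, psf_fwhm_mm = 0)
  p <- s0$meta$params
  atl <- s0$atlas
  cnt <- atlas_label_counts(atl)
  cereb_mean <- (p$s_gm_nonspec * cnt[["cerebellum_gm"]] +
                 p$s_wm_nonspec * cnt[["cerebellum_wm"]]) /
    (cnt[["cerebellum_gm"]] + cnt[["cerebellum_wm"]])
  expect_equal(suvr(s0, "global")$value, p$s_gm_nonspec / cereb_mean)
})

test_that("ELBA matches brute-force pair enumeration and its extremes", {
  # GM = {1, 3}, WM = {2}: U = 1 of 2 pairs -> score 0
  sc <- toy_scan(labels = c(11L, 11L, 2L), early = c(1, 1, 1),
                 late = c(1, 3, 2))
  expect_equal(elba_score(sc, "frontal_L")$value, 0)
  # all GM above all WM -> +1; all below -> -1
  sc2 <- toy_scan(labels = c(11L, 11L, 2L, 2L), early = 1,
                  late = c(5, 6, 1, 2))
  expect_equal(elba_score(sc2, "frontal_L")$value, 1)
  sc3 <- toy_scan(labels = c(11L, 11L, 2L, 2L), early = 1,
                  late = c(1, 2, 5, 6))
  expect_equal(elba_score(sc3, "frontal_L")$value, -1)
  # identical distributions -> 0 in expectation (symmetry; exact for equal values)
  sc4 <- toy_scan(labels = c(11L, 11L, 2L, 2L), early = 1, late = c(4, 4, 4, 4))
  expect_equal(elba_score(sc4, "frontal_L")$value, 0)
})

test_that("TDr reproduces the hand-enumerated hotspot example and the ratio identity", {
  # region GM early {1,2,3,4}, late {10,10,20,20}, percentile 75:
  # hotspot = the early-4 voxel (late 20); WM ref late 10 -> TDr = 2
  sc <- toy_scan(labels = c(rep(11L, 4), rep(2L, 4)),
                 early = c(1, 2, 3, 4, 5, 5, 5, 5),
                 late = c(10, 10, 20, 20, 10, 10, 10, 10))
  cfg <- quantifier_config(hotspot_percentile = 75, wm_core_erosion_mm = 0)
  res <- tdr(sc, "frontal_L", cfg)
  expect_equal(res$value, 2)
  expect_equal(res$diagnostics[[1]]$n_hotspot, 1)

  # uniform late volume -> 1 regardless of hotspot placement
  s <- clean_subject(a = 0.5)
  s$late[] <- 4.4
  expect_equal(tdr(s, "global")$value, 1)

  # hotspot size tracks the percentile within rounding
  s2 <- clean_subject(a = 0)
  d <- tdr(s2, "global")$diagnostics[[1]]
  n_gm <- sum(region_mask(s2$atlas, "global"))
  expect_lt(abs(d$n_hotspot - 0.1 * n_gm), 0.02 * n_gm)
})

test_that("WMR follows its difference-ratio arithmetic and flags the degenerate denominator", {
  # late target 2, late WM 1, early target 3, early WM 1 -> 0.5
  sc <- toy_scan(labels = c(11L, 2L), early = c(3, 1), late = c(2, 1))
  expect_equal(wmr(sc, "frontal_L")$value, 0.5)

  # equal early means -> flagged unstable, value missing, no error
  sc2 <- toy_scan(labels = c(11L, 2L), early = c(1, 1), late = c(2, 1))
  res <- wmr(sc2, "frontal_L")
  expect_true(is.na(res$value))
  expect_identical(res$flag, "unstable_denominator")

  # noise-free phantom at zero load: numerator < 0, denominator > 0
  s <- clean_subject(a = 0)
  expect_lt(wmr(s, "global")$value, 0)
  expect_lt(wmr(s, "global")$value, wmr(clean_subject(a = 0.8), "global")$value)
})

test_that("PVE correction recovers the plateau and reduces to identity in the small-PSF limit", {
  # 1D slab phantom at 8 mm FWHM
  n <- 41
  gm <- array(FALSE, c(n, 1, 1)); gm[15:27, 1, 1] <- TRUE
  true_gm <- 0.8
  vol <- array(0, c(n, 1, 1)); vol[gm] <- true_gm
  blurred <- smooth_gaussian_3d(vol, 8, c(3, 3, 3))
  corr <- pve_correct(blurred, gm, 8, c(3, 3, 3))
  inside <- which(!is.na(corr))
  expect_true(all(abs(corr[inside] - true_gm) / true_gm < 0.05))

  # psf -> 0: corrected equals original on the mask
  tiny <- pve_correct(blurred, gm, 1e-6, c(3, 3, 3))
  expect_equal(tiny[gm], blurred[gm], tolerance = 1e-6)

  # uniform image: corrected = original / smoothed mask, voxelwise
  u <- array(2, c(n, 1, 1))
  sm <- smooth_gaussian_3d(array(as.numeric(gm), dim(gm)), 8, c(3, 3, 3))
  corr_u <- pve_correct(u, gm, 8, c(3, 3, 3))
  keep <- !is.na(corr_u)
  expect_equal(corr_u[keep], 2 / sm[keep], tolerance = 1e-12)

  expect_error(pve_correct(u, array(FALSE, dim(u)), 8, c(3, 3, 3)),
               "inclusion threshold")
})

test_that("the slope index is zero under proportional kinetics and recovers a known slope", {
  # late = 0.7 * early everywhere -> region and calibration slopes match -> 0
  s <- clean_subject(a = 0.4)
  s$late <- 0.7 * s$early
  res <- slope_index(s, "global")
  expect_equal(res$value, 0, tolerance = 1e-10)

  # late = a * early + b + noise over GM: recovered slope within 3 SE of a
  s2 <- clean_subject(a = 0)
  mk <- amyquant:::atlas_masks(s2$atlas, 6)
  core <- mk$wm_core
  e_wm <- mean(s2$early[core])
  slope_true <- 0.6; intercept <- 0.2
  withr::with_seed(21, {
    s2$late <- slope_true * s2$early + intercept +
      array(rnorm(length(s2$early), 0, 0.02), dim(s2$early))
  })
  l_wm <- mean(s2$late[core])
  res2 <- slope_index(s2, "global")
  # closed-form least-squares oracle: lm on the same normalised voxel sets
  fit_of <- function(mask) {
    x <- s2$early[mask] / e_wm; y <- s2$late[mask] / l_wm
    stats::lm(y ~ x)
  }
  fit_g <- fit_of(mk$gm[["global"]])
  fit_c <- fit_of(mk$cerebellum_gm)
  expect_equal(res2$value,
               unname(stats::coef(fit_g)[2] - stats::coef(fit_c)[2]),
               tolerance = 1e-8)
  # the WM normalisation rescales the true slope by e_wm / l_wm
  se <- summary(fit_g)$coefficients[2, 2]
  expect_lt(abs(stats::coef(fit_g)[2] - slope_true * e_wm / l_wm), 3 * se + 0.05)

  # degenerate early frame -> flagged, not an error
  s3 <- clean_subject(a = 0, psf_fwhm_mm = 0)
  res3 <- slope_index(s3, "frontal_L")
  expect_true(is.na(res3$value))
  expect_identical(res3$flag, "degenerate_early_frame")
})

test_that("all five global scores increase strictly with uniform load", {
  vals <- sapply(c(0, 0.5, 1.0), function(a) {
    q <- quantify_subject(clean_subject(a = a), regions = "global")
    stats::setNames(q$value, q$quantifier)
  })
  for (q in rownames(vals)) expect_true(all(diff(vals[q, ]) > 0), label = q)
})

test_that("all five quantifiers are invariant to a common intensity rescaling", {
  s <- simulate_subject(test_atlas(), subject_params(amyloid_load = 0.5), seed = 3)
  q1 <- quantify_subject(s, regions = c("global", "temporal_L"))
  s$early <- 2.7 * s$early
  s$late <- 2.7 * s$late
  q2 <- quantify_subject(s, regions = c("global", "temporal_L"))
  expect_equal(q1$value, q2$value, tolerance = 1e-10)
})

test_that("SUVr and ELBA never read the early frame; ELBA never reads the cerebellum", {
  s <- simulate_subject(test_atlas(), subject_params(amyloid_load = 0.3), seed = 5)
  a <- suvr(s, "global")$value
  b <- elba_score(s, "global")$value
  s$early[] <- NA_real_
  expect_equal(suvr(s, "global")$value, a)
  expect_equal(elba_score(s, "global")$value, b)
  s$late[region_mask(s$atlas, "cerebellum")] <- 99
  expect_equal(elba_score(s, "global")$value, b)
})

test_that("equal grey and white perfusion drives WMR to full instability while SUVr and ELBA stay stable", {
  atl <- test_atlas()
  n_flag <- 0; n <- 6
  for (i in seq_len(n)) {
    # psf 0 so equal tissue perfusion gives genuinely equal early ROI means
    # (with a PSF, boundary dilution alone separates them)
    p <- subject_params(amyloid_load = 0.2, perfusion_gm = 0.8,
                        perfusion_wm = 0.8, psf_fwhm_mm = 0)
    s <- simulate_subject(atl, p, seed = i)
    res <- wmr(s, "global")
    n_flag <- n_flag + identical(res$flag, "unstable_denominator")
    expect_true(is.finite(suvr(s, "global")$value))
    expect_true(is.finite(elba_score(s, "global")$value))
  }
  expect_equal(n_flag, n)
})

test_that("quantify_cohort survives a failing subject and reports the exclusion", {
  coh <- test_cohort_small()
  subjects <- coh$subjects[1:3]
  subjects[[2]]$late <- array(NA_real_, dim(subjects[[2]]$late))
  expect_warning(sc <- quantify_cohort(subjects, regions = "global"),
                 "excluded")
  expect_equal(length(unique(sc$subject_id)), 2)
  expect_length(attr(sc, "excluded"), 1)
})

test_that("cohort scoring is deterministic and covers every cell", {
  coh <- test_cohort_small()
  sc1 <- quantify_cohort(coh)
  sc2 <- quantify_cohort(coh)
  expect_identical(sc1$value, sc2$value)
  expect_equal(nrow(sc1), length(coh$subjects) * 5 * 11)
  # subjects sorted by true load give monotone global columns when clean
  clean <- simulate_cohort(test_atlas_small(),
                           cohort_spec(n_negative = 3, n_positive = 3,
                                       noise_sd = 0, load_jitter_sd = 0,
                                       binding_texture_sd = 0,
                                       perfusion_texture_sd = 0,
                                       flow_factor_sd = 0, perfusion_gm_sd = 0,
                                       perfusion_wm_sd = 0, s_wm_nonspec_sd = 0,
                                       s_gm_nonspec_sd = 0, cereb_binding_sd = 0,
                                       misreg_vox = 0, thickness_noise_sd = 1e-3,
                                       thickness_region_sd = 0, seed = 4))
  scc <- quantify_cohort(clean, regions = "global")
  ord <- order(clean$metadata$true_load_global)
  for (q in c("SUVr", "ELBA", "TDr", "WMR", "SI")) {
    col <- dplyr::filter(scc, quantifier == q)
    vals <- col$value[match(clean$metadata$subject_id[ord], col$subject_id)]
    expect_true(all(diff(vals) > 0), label = q)
  }
})
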