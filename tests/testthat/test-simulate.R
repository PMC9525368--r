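# Dual time-point subject and cohort simulation.

test_that("zero-load noise-free frames reproduce the tissue constants exactly", {
  atl <- test_atlas()
  s <- clean_subject(a = 0, psf_fwhm_mm = 0)
  p <- s$meta$params
  for (r in lobar_regions()) {
    expect_equal(roi_mean(s$late, region_mask(atl, r)), p$s_gm_nonspec)
  }
  expect_equal(roi_mean(s$late, region_mask(atl, "wm")), p$s_wm_nonspec)
  expect_equal(roi_mean(s$early, region_mask(atl, "global")), p$perfusion_gm)
  expect_true(all(is.finite(s$early)) && all(is.finite(s$late)))
})

test_that("late-frame regional means increase strictly with that region's load", {
  atl <- test_atlas()
  loads <- c(0, 0.3, 0.6, 1.0)
  means <- vapply(loads, function(a) {
    s <- clean_subject(a = a)
    roi_mean(s$late, region_mask(atl, "global"))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("the early frame is independent of amyloid load", {
  s0 <- clean_subject(a = 0)
  s1 <- clean_subject(a = 1)
  expect_identical(s0$early, s1$early)
  expect_false(identical(s0$late, s1$late))
})

test_that("simulation is bit-reproducible under a seed, including noise and registration", {
  atl <- test_atlas()
  p <- subject_params(amyloid_load = 0.4)
  s1 <- simulate_subject(atl, p, seed = 99)
  s2 <- simulate_subject(atl, p, seed = 99)
  expect_identical(s1$early, s2$early)
  expect_identical(s1$late, s2$late)
  expect_identical(s1$meta$misreg_shift, s2$meta$misreg_shift)
  s3 <- simulate_subject(atl, p, seed = 100)
  expect_false(identical(s1$late, s3$late))
})

test_that("the PSF produces the partial-volume transition a 1D oracle predicts", {
  # 1D slab: WM plateau 1.0 against GM plateau 0.55, 8 mm FWHM at 3 mm voxels;
  # brute-force convolution oracle vs the separable implementation
  n <- 41
  profile <- c(rep(1, 20), rep(0.55, 21))
  vol <- array(profile, c(n, 1, 1))
  sm <- smooth_gaussian_3d(vol, 8, c(3, 3, 3))
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  half <- ceiling(3 * sigma)
  k <- exp(-(-half:half)^2 / (2 * sigma^2)); k <- k / sum(k)
  brute <- vapply(seq_len(n), function(i) {
    idx <- i + (-half:half)
    keep <- idx >= 1 & idx <= n
    sum(profile[idx[keep]] * k[keep])
  }, 0)
  expect_equal(as.vector(sm), brute, tolerance = 1e-12)
  # boundary voxels sit strictly between the two plateaus
  expect_true(all(sm[19:22, 1, 1] > 0.55 & sm[19:22, 1, 1] < 1))

  # on the phantom: with an 8 mm PSF the mean over the eroded GM mask is
  # pulled from the GM plateau toward the WM plateau
  atl <- test_atlas()
  s <- clean_subject(a = 0, psf_fwhm_mm = 8)
  gm <- region_mask(atl, "global")
  er <- amyquant:::erode_mask(gm, 3, atl$voxel_size_mm)
  m <- roi_mean(s$late, er)
  expect_gt(m, 0.55 * 0.9)
  expect_lt(m, 1)
})

test_that("atrophy below 1 removes outer-shell signal without touching labels", {
  atl <- test_atlas()
  s_full <- clean_subject(a = 0, psf_fwhm_mm = 0)
  s_atro <- clean_subject(a = 0, psf_fwhm_mm = 0, atrophy = 0.7)
  gm <- region_mask(atl, "global")
  expect_lt(roi_mean(s_atro$late, gm), roi_mean(s_full$late, gm))
  expect_identical(s_atro$atlas$label_map, s_full$atlas$label_map)
  expect_true(any(s_atro$atrophied))
})

test_that("invalid subject parameters are rejected", {
  expect_error(subject_params(noise_sd = -1), "nonnegative")
  expect_error(subject_params(psf_fwhm_mm = -2), "nonnegative")
  expect_error(subject_params(amyloid_load = NA), "finite")
  expect_error(subject_params(age = 30), "age")
  expect_error(subject_params(atrophy = 1.5), "atrophy")
})

test_that("cohort simulation is deterministic and honours the class split", {
  atl <- test_atlas_small()
  spec <- cohort_spec(n_negative = 6, n_positive = 4, seed = 5)
  c1 <- simulate_cohort(atl, spec)
  c2 <- simulate_cohort(atl, spec)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$subjects[[3]]$late, c2$subjects[[3]]$late)
  expect_equal(nrow(c1$metadata), 10)
  expect_equal(sum(c1$metadata$class_label == "negative"), 6)
})

test_that("the study-sized cohort has 85 rows with 54 negatives", {
  md <- simulate_cohort(test_atlas_small(),
                        cohort_spec(seed = 1), metadata_only = TRUE)$metadata
  expect_equal(nrow(md), 85)
  expect_equal(sum(md$class_label == "negative"), 54)
  expect_true(all(md$age >= 44 & md$age <= 87))
})

test_that("zero age slope leaves age and ground-truth load uncorrelated in negatives", {
  atl <- test_atlas_small()
  cors <- vapply(1:20, function(s) {
    md <- simulate_cohort(atl, cohort_spec(n_negative = 30, n_positive = 0,
                                           age_slope = 0, seed = s),
                          metadata_only = TRUE)$metadata
    stats::cor(md$age, md$true_load_global)
  }, 0)
  expect_lt(abs(mean(cors)), 3 / sqrt(29 * 20) * 2 + 0.02)
})

test_that("the negative age-thickness correlation lands near its target", {
  cors <- vapply(1:10, function(s) {
    md <- simulate_cohort(test_atlas_small(),
                          cohort_spec(n_negative = 54, n_positive = 0, seed = s),
                          metadata_only = TRUE)$metadata
    stats::cor(md$age, md$thickness_global)
  }, 0)
  expect_lt(mean(cors), -0.2)
  expect_gt(mean(cors), -0.6)
  expect_true(all(abs(cors) < 0.75))
})

test_that("infeasible cohort specifications are rejected", {
  expect_error(cohort_spec(thickness_age_corr = -1.2), "< 1")
  expect_error(cohort_spec(thickness_age_corr = 0.3), "\\(-1, 0\\]")
  expect_error(cohort_spec(n_negative = 1, n_positive = 0), "two subjects")
  expect_error(cohort_spec(age_range = c(90, 44)), "increasing")
})
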