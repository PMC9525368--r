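---
title: "Methods: phantom design and the five-quantifier comparison"
author: "amyquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom design and the five-quantifier comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyquant)
```

## What this package models

Amyloid PET is read clinically as a binary call (amyloid-positive or
-negative), but research and trials need continuous semi-quantification.
Several families of indices exist, differing in which data they require:

* **SUVr** — late-frame target mean over the whole-cerebellum mean; needs
  only the late scan and an atlas.
* **ELBA-style rank contrast** — a reference-free summary of the late
  frame's grey-vs-white intensity distribution contrast; needs the late
  scan alone.
* **TDr** (time-delayed ratio) — the late-frame mean over an individually
  adapted hotspot (the most perfused area of the target, found on the
  early frame) normalised by an early-adapted white-matter reference;
  needs both frames.
* **WMR** — the ratio of late to early (target − WM) mean differences;
  needs both frames plus MRI-guided segmentation.
* **SI** (slope index) — the least-squares slope of WM-normalised late vs
  early intensity over the target grey matter, calibrated to zero on the
  amyloid-free cerebellar grey matter; needs everything, and serves as the
  reference measure throughout.

The interesting scientific questions — how well the cheaper indices agree
with the kinetic reference, whether inverse-dispersion fusion of
independent indices beats any single one, and whether flow-aware indices
can resolve the slow physiological accumulation of amyloid with age in
visually negative subjects — are questions about *cohorts of images*, not
about tables of numbers. The package therefore ships a full synthetic
dual time-point phantom cohort generator, so every downstream statistical
claim is exercised against voxel data with known ground truth.

## The phantom

`make_atlas()` builds a deterministic geometric brain: an ellipsoidal
cerebrum whose cortical shell is divided angularly into eight lobar
sectors (frontal, parietal, temporal, occipital × left/right), two deep
grey nuclei (the `central` regions), a white-matter core with a CSF
ventricle, a thin CSF rim, and a separate inferior cerebellum with its own
grey shell and white core. The default grid is 48³ voxels at 3 mm — coarse
enough that an 85-subject cohort simulates in about half a minute on one
CPU, fine enough that every one of the fifteen labels keeps at least 50
voxels and partial-volume effects are realistic at a 6 mm PSF. The
`global` target region is defined as the exact voxel union of the ten
lobar regions, an invariant the tests assert.

`simulate_subject()` renders the two frames:

* the **early frame** sees only perfusion (grey ~ 1.0, white ~ 0.6 at
  defaults) — it is provably independent of amyloid load;
* the **late frame** assigns nonspecific binding to white matter (1.0)
  and grey matter (0.55), plus `a_r × 0.9` of specific signal in lobar
  region `r` with burden `a_r`; cerebellar grey matter is amyloid-free by
  construction, which is what licenses it as the SUVr reference and the
  slope-index calibration region.

Both frames are blurred with the same separable Gaussian PSF (6 mm FWHM
default), then receive additive Gaussian voxel noise (SD 0.05). The
florbetaben-like appearance — grey matter darker than white on a negative
late scan, converging and crossing as burden grows — emerges from these
constants.

### Error channels: what makes the quantifiers disagree

On a perfectly homogeneous, perfectly registered phantom the five indices
agree almost exactly, which no real dataset does; the interesting
statistics would degenerate. The generator therefore models the
between- and within-subject variability that clinical cohorts show, each
channel hitting the quantifiers asymmetrically, as its real counterpart
does:

* **Atrophy** (`atrophy`, driven by cortical thickness via
  `atrophy_ref_thickness`): the outer `1 − atrophy` fraction of the
  cortical shell becomes CSF-like before intensities are assigned, while
  the atlas labels stay intact. Template-registered quantifiers (SUVr,
  ELBA, TDr) score against the full atlas and are diluted; MRI-guided
  quantifiers (WMR, SI) receive the subject's own segmentation (atlas
  minus the eroded voxels), as FreeSurfer would provide.
* **Nonspecific binding variability** (`s_wm_nonspec_sd`,
  `s_gm_nonspec_sd`): per-subject multiplicative variation of white- and
  grey-matter background binding; the dominant error source of every
  WM-referenced index.
* **Cerebellar reference variability** (`cereb_binding_sd`): per-subject
  scaling of cerebellar binding; the classic SUVr weak point, also felt by
  the slope-index calibration.
* **Global flow factor** (`flow_factor_sd`) with small independent tissue
  draws (`perfusion_gm_sd`, `perfusion_wm_sd`): global cerebral blood flow
  varies much more between subjects than the grey/white contrast does, so
  the two tissues' early intensities are drawn as a shared factor times
  nearly-stable tissue values. WMR divides by an early-frame difference
  and inherits the flow error almost fully.
* **Biological texture** (`binding_texture_sd`, `perfusion_texture_sd`,
  correlation length `texture_fwhm_mm`): smooth multiplicative random
  fields on each frame, emulating spatially structured uptake
  heterogeneity; small adaptive ROIs (the TDr hotspot, the adapted WM
  reference) feel it more than whole-region means.
* **Registration and segmentation error** (`misreg_vox`, `wm_seg_vox`):
  each MRI-free pipeline (SUVr, ELBA, TDr) registers the atlas through a
  generic template, modelled as an independent uniform integer-voxel
  shift of its masks per subject. These independent displacements are
  what give the indices genuinely independent error components — the
  property that score fusion exploits. An analogous independent shift of
  WMR's PET-space white-matter segmentation is available through
  `wm_seg_vox` but is off by default: at 3 mm voxels a one-voxel
  displacement overstates the effect and erases WMR's age sensitivity.

The channel magnitudes were calibrated jointly, once, against two
declared criteria: (i) the standardised separation of the slope index
between the simulated visual-read classes must be at least 3 (the
regime reported for florbetaben cohorts with a clearly bimodal case mix),
and (ii) the global Bland–Altman dispersions of the four candidate
quantifiers from the reference must fall in the pattern clinical
comparisons show — the three cortical-ratio methods comparable to each
other, and the white-matter-referenced ratio distinctly the worst, at
roughly 1.5–2× the best. Without (ii), one index dominates artificially
and the fusion analysis becomes vacuous. After calibration the defaults
were frozen; the tests and the acceptance script run against them
unmodified.

### What the phantom does not model

Poisson emission noise and reconstruction artefacts (additive Gaussian
post-PSF noise stands in), anatomical cortical folding, off-target
binding, longitudinal change, and scanner harmonisation. Consequently,
passing tests demonstrate the *statistical machinery* under a controlled,
honest error model — not clinical performance of any quantifier on real
scans.

## Quantifier design notes

Two of the five indices are operational surrogates, because their
originals are defined by external software stacks rather than formulas:

* The **ELBA surrogate** is the Mann–Whitney rank contrast between the
  target grey voxels and all cerebral white voxels on the late frame,
  rescaled to [−1, 1] with ties at one half. It preserves everything
  asserted of the original — late frame only, no reference region,
  grey/white distribution contrast, monotone in burden — but saturates at
  the extremes as any bounded rank statistic must.
* The **SI surrogate** normalises both frames by the eroded white-matter
  core mean, regresses normalised-late on normalised-early over the
  target grey matter, and subtracts the same slope computed on cerebellar
  grey matter so that a fully negative subject sits near zero.

A Meltzer-style `pve_correct()` (divide by the PSF-smoothed binary GM
mask where its retention exceeds `gm_inclusion_threshold`) is provided
and tested, but is **off by default** in the slope index: on a phantom
whose grey matter is a homogeneous plateau, dividing by the smoothed
global GM mask turns the amyloid term into a constant across grey voxels
and erases the cross-voxel late-vs-early contrast the surrogate slope
measures. The voxelwise slope is in any case largely self-correcting for
partial volume, because dilution attenuates both frames together and
moves points along the regression line rather than off it.

Other defaults the sources leave open: the TDr hotspot percentile (90),
the white-matter core erosion (6 mm, two voxels), and the WMR stability
floor (5% of the white-matter early mean — below it the score is returned
flagged-unstable rather than as an exploding ratio). All are
`quantifier_config()` fields.

## The statistical comparison

All scores are z-scored per (quantifier, region) column over the full
cohort — sample SD, ddof 1 — before agreement analysis, so dispersions are
in comparable units; correlations and AUCs are invariant under this
monotone affine map and are reported from the same table. Agreement with
the reference is the Bland–Altman dispersion σ of the differences, with a
percentile bootstrap CI (1000 resamples by default) and an OLS
proportional-bias check (does the trend CI include a flat line, does the
bias CI include zero). Fusion weights are `(1/σ_i)/Σ(1/σ_j)` computed
from the *global* dispersions only and reused regionally; AVG1 combines
SUVr and ELBA, AVG2 adds TDr, AVG3 adds WMR, and an unweighted mode
reproduces the supplementary re-analysis. Discrimination against the
simulated visual read is the Mann–Whitney AUC with a stratified percentile
bootstrap. The amyloid-negative analysis regresses each score on age and
the matching region's cortical thickness, screens collinearity with VIF,
and adjusts p-values by Benjamini–Hochberg.

Design points worth stating explicitly:

* **BH family**: the default family is every (quantifier × region ×
  covariate) test in the run, the most conservative reading; `bh_family`
  switches to per-covariate or per-region families, and the choice is
  recorded on the result.
* **Missing scores** (flagged-unstable WMR or SI cells) are deleted
  pairwise, never listwise, and counts are carried in `n`/`n_pairs`.
* **Residual independence**: the correlation between OLS residuals and
  their own predictor is identically zero by the normal equations; the
  package reports it as the sanity check it is, and additionally emits
  the informative variant — each model's residuals against every third
  quantifier.
* **Age model**: negative-cluster ages are uniform on 44–87 (the source
  range; no distribution is stated, and uniformity is the declared
  assumption), burden grows linearly at 0.004 load units/year inside the
  negatives, and thickness declines with age at a rate calibrated
  analytically to a −0.4 population correlation.

### What fusion can and cannot achieve on a shared phantom

Inverse-dispersion fusion reliably beats the *weighted average* of its
members and usually sits at or below the best single member, but on this
phantom the "at or below the best member" inequality is a coin toss
rather than a near-certainty, for a structural reason worth spelling
out. Every member's Bland–Altman difference from the reference contains
the reference's own error with a minus sign, so all differences share a
common variance floor; fusion averages away the member-specific parts
but can never go below that floor. Because TDr shares the reference's
dual-time-point, white-matter-normalised construction, its own
difference already sits within a few percent of the floor, leaving the
fused scores nothing to gain on it. Five genuinely distinct clinical
pipelines — different registrations, segmentations, feature sets and
software stacks — carry far more mutually independent error than five
surrogates reading one synthetic image pair, which is exactly the regime
in which fusion dominates every member. The test suite therefore checks
the fusion machinery itself (weights, variance reduction on members with
independent errors) as a sharp property, and reports the phantom-cohort
inequality as the marginal empirical outcome it is.

## Problem sizes

The shipped defaults — 48³ voxels at 3 mm, 85 subjects (54 negative, 31
positive) — run the full simulate–quantify–compare chain in a few minutes
on a single CPU. The test suite exercises repeated-cohort properties
(fusion dispersion, age-association recovery) at 20 cohort replicates
with global-region scoring, null-calibration of the regression at 200
reduced replicates (12-subject cohorts on a 32³ grid), and the bootstrap
interval's coverage at 400 replicates of 85 pairs with 1000 resamples
each — sizes chosen to keep the checks' own Monte-Carlo error well
inside the asserted margins while the whole suite stays desk-scale.

## Known limitations

* The lobar geometry is angular-sector, not anatomical; regional results
  demonstrate the machinery, not regional neurobiology.
* The ELBA surrogate's saturation compresses high-burden subjects; its
  dispersion from the reference is correspondingly the largest of the
  cortical methods, as expected for a bounded statistic.
* The slope-index surrogate derives its signal from boundary
  partial-volume structure; with the PSF disabled entirely its regressor
  has no variance and the score is (deliberately) flagged unstable.
* Integer-voxel registration shifts quantise registration error at 3 mm;
  sub-voxel misregistration is not modelled.
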