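#' Region labels used by the phantom atlas
#'
#' The phantom parcellation mirrors a lobar grouping of a cortical atlas:
#' five lobar regions per hemisphere (frontal, parietal, temporal, occipital
#' and central/deep grey), plus cerebral white matter, cerebellar grey and
#' white matter, CSF and background. The `global` target region is defined
#' as the voxel union of the ten lobar regions.
#'
#' @format A named integer vector mapping label names to codes.
#' @export
atlas_label_codes <- c(
  background    = 0L,
  csf           = 1L,
  wm            = 2L,
  cerebellum_gm = 3L,
  cerebellum_wm = 4L,
  frontal_L     = 11L, frontal_R   = 12L,
  parietal_L    = 13L, parietal_R  = 14L,
  temporal_L    = 15L, temporal_R  = 16L,
  occipital_L   = 17L, occipital_R = 18L,
  central_L     = 19L, central_R   = 20L
)

#' Names of the ten lobar grey-matter regions
#' @return Character vector of the ten lobar region names.
#' @export
lobar_regions <- function() {
  c("frontal_L", "frontal_R", "parietal_L", "parietal_R",
    "temporal_L", "temporal_R", "occipital_L", "occipital_R",
    "central_L", "central_R")
}

#' Names of all target regions (global plus ten lobes)
#' @return Character vector: `"global"` followed by [lobar_regions()].
#' @export
target_regions <- function() c("global", lobar_regions())

#' Build a geometric brain phantom atlas
#'
#' Constructs a deterministic nested geometry: an ellipsoidal cerebrum whose
#' outer grey-matter shell is split angularly into eight cortical sectors
#' (frontal/parietal/temporal/occipital, left/right), an inner white-matter
#' core containing a CSF ventricle and two deep grey nuclei (`central_L/R`),
#' and an inferior cerebellum with its own grey shell and white core. A thin
#' CSF rim surrounds the cerebrum; everything else is background. The seed
#' only perturbs the angular placement of the sector boundaries by a few
#' degrees, so two calls with the same `(shape, seed)` are voxel-identical.
#'
#' @param shape Integer triple, voxel grid dimensions; each must be >= 32.
#' @param voxel_size_mm Positive numeric triple, voxel edge lengths in mm.
#' @param seed Integer seed for the sector-boundary jitter.
#' @return A `phantom_atlas` object: a list with `label_map` (3D integer
#'   array), `voxel_size_mm`, `label_codes`, and `shell_frac` (3D numeric
#'   array giving, for cortical grey-shell voxels, the normalised depth in
#'   the shell from 0 at the white-matter boundary to 1 at the pial surface;
#'   `NA` elsewhere). `shell_frac` is what subject-level atrophy erodes.
#' @examples
#' atl <- make_atlas(shape = c(48, 48, 48), voxel_size_mm = c(3, 3, 3), seed = 1)
#' table(atl$label_map)[as.character(atlas_label_codes[lobar_regions()])]
#' @export
make_atlas <- function(shape = c(48L, 48L, 48L),
                       voxel_size_mm = c(3, 3, 3),
                       seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L)) {
    stop("`shape` must be an integer triple with every dimension >= 32; ",
         "smaller grids cannot host all phantom labels", call. = FALSE)
  }
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (any(voxel_size_mm <= 0)) stop("`voxel_size_mm` must be positive", call. = FALSE)

  jitter_deg <- withr::with_seed(as.integer(seed), stats::runif(1, -5, 5))

  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  ix <- seq_len(n1); iy <- seq_len(n2); iz <- seq_len(n3)

  # cerebrum ellipsoid (fractional geometry so any shape >= 32 works)
  ctr <- c(0.5 * (n1 + 1), 0.52 * (n2 + 1), 0.62 * (n3 + 1))
  rad <- c(0.34 * n1, 0.38 * n2, 0.28 * n3)

  dx <- (ix - ctr[1]) / rad[1]
  dy <- (iy - ctr[2]) / rad[2]
  dz <- (iz - ctr[3]) / rad[3]
  DX <- array(dx, shape)
  DY <- aperm(array(dy, shape[c(2, 1, 3)]), c(2, 1, 3))
  DZ <- aperm(array(dz, shape[c(3, 1, 2)]), c(2, 3, 1))
  U <- sqrt(DX^2 + DY^2 + DZ^2)

  lab <- array(atlas_label_codes[["background"]], shape)
  shell_frac <- array(NA_real_, shape)

  u_vent <- 0.20; u_wm <- 0.78; u_csf <- 1.10

  lab[U <= u_csf] <- atlas_label_codes[["csf"]]
  lab[U <= u_wm]  <- atlas_label_codes[["wm"]]
  lab[U <= u_vent] <- atlas_label_codes[["csf"]]

  # deep grey nuclei inside the white-matter core
  blob_r <- 0.055 * min(shape)
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    bc <- c(ctr[1] + sgn * 0.13 * n1, ctr[2] + 0.02 * n2, ctr[3] - 0.04 * n3)
    BD <- sqrt((DX * rad[1] + ctr[1] - bc[1])^2 +
               (DY * rad[2] + ctr[2] - bc[2])^2 +
               (DZ * rad[3] + ctr[3] - bc[3])^2)
    sel <- BD <= blob_r & lab == atlas_label_codes[["wm"]]
    lab[sel] <- atlas_label_codes[[paste0("central_", side)]]
  }

  # cortical shell, split into 8 angular sectors
  shell <- U > u_wm & U <= 1
  theta <- atan2(DZ, DY) * 180 / pi + jitter_deg  # degrees, anterior = 0
  lobe <- ifelse(theta > -45 & theta <= 45, "frontal",
          ifelse(theta > 45 & theta <= 135, "parietal",
          ifelse(theta > -135 & theta <= -45, "temporal", "occipital")))
  hemi <- ifelse(DX < 0, "L", "R")
  sector <- paste0(lobe, "_", hemi)
  lab[shell] <- atlas_label_codes[sector[shell]]
  shell_frac[shell] <- (U[shell] - u_wm) / (1 - u_wm)

  # cerebellum: inferior sphere with its own GM shell / WM core,
  # written only into background so labels stay mutually exclusive
  cb_ctr <- c(0.5 * (n1 + 1), 0.33 * (n2 + 1), 0.16 * (n3 + 1))
  cb_r <- 0.14 * min(shape)
  CBD <- sqrt((DX * rad[1] + ctr[1] - cb_ctr[1])^2 +
              (DY * rad[2] + ctr[2] - cb_ctr[2])^2 +
              (DZ * rad[3] + ctr[3] - cb_ctr[3])^2) / cb_r
  bg <- lab == atlas_label_codes[["background"]]
  lab[bg & CBD <= 1] <- atlas_label_codes[["cerebellum_gm"]]
  lab[bg & CBD <= 0.58] <- atlas_label_codes[["cerebellum_wm"]]

  atlas <- structure(
    list(label_map = lab,
         voxel_size_mm = as.numeric(voxel_size_mm),
         label_codes = atlas_label_codes,
         shell_frac = shell_frac,
         seed = as.integer(seed),
         cache = new.env(parent = emptyenv())),
    class = "phantom_atlas"
  )

  counts <- atlas_label_counts(atlas)
  if (any(counts == 0)) {
    stop("shape ", paste(shape, collapse = "x"),
         " too small to host all phantom labels (missing: ",
         paste(names(counts)[counts == 0], collapse = ", "), ")",
         call. = FALSE)
  }
  atlas
}

#' Voxel counts per atlas label
#' @param atlas A `phantom_atlas`.
#' @return Named integer vector of voxel counts, one per label code.
#' @export
atlas_label_counts <- function(atlas) {
  vapply(atlas$label_codes, function(code) sum(atlas$label_map == code), 0L)
}

#' Logical voxel mask for a target region
#'
#' @param atlas A `phantom_atlas`.
#' @param region `"global"` (union of the ten lobar regions), a lobar region
#'   name, one of the tissue labels (`"wm"`, `"cerebellum_gm"`, ...), or
#'   `"cerebellum"` for the whole cerebellum (GM + WM, the SUVr reference).
#' @return Logical 3D array.
#' @export
region_mask <- function(atlas, region) {
  codes <- atlas$label_codes
  if (region == "global") {
    return(array(atlas$label_map %in% codes[lobar_regions()], dim(atlas$label_map)))
  }
  if (region == "cerebellum") {
    return(array(atlas$label_map %in% codes[c("cerebellum_gm", "cerebellum_wm")],
                 dim(atlas$label_map)))
  }
  if (!region %in% names(codes)) {
    stop("unknown region: ", region, call. = FALSE)
  }
  atlas$label_map == codes[[region]]
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat("<phantom_atlas> ", paste(dim(x$label_map), collapse = " x "),
      " voxels @ ", paste(x$voxel_size_mm, collapse = "x"), " mm\n", sep = "")
  cnt <- atlas_label_counts(x)
  cat("  labels: ", paste0(names(cnt), "=", cnt, collapse = ", "), "\n", sep = "")
  invisible(x)
}
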