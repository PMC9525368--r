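# Internal numerics shared by the phantom generator and the quantifiers.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' @noRd
gaussian_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0 || n == 1L) return(diag(n))
  half <- min(n - 1L, max(1L, as.integer(ceiling(3 * sigma_vox))))
  taps <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  taps <- taps / sum(taps)
  m <- matrix(0, n, n)
  for (d in seq(-half, half)) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) {
      m[cbind(idx + d, idx)] <- taps[d + half + 1L]
    } else {
      m[cbind(idx, idx - d)] <- taps[d + half + 1L]
    }
  }
  m
}

# Separable 3D Gaussian smoothing with zero (background) padding: activity
# near the edge of the field of view spills out rather than being reflected,
# matching how a PET point-spread function dilutes a finite object.
#' @noRd
smooth_gaussian_3d <- function(vol, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(vol)) == 3L)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (all(fwhm_mm <= 0)) return(vol)
  d <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    if (d[ax] == 1L) next  # singleton axes are treated as homogeneous
    sigma_vox <- fwhm_mm[ax] * FWHM_TO_SIGMA / voxel_size_mm[ax]
    if (sigma_vox <= 0) next
    m <- gaussian_band_matrix(d[ax], sigma_vox)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(out, perm)
    dp <- dim(x)
    x <- m %*% matrix(x, nrow = dp[1])
    dim(x) <- dp
    out <- aperm(x, order(perm))
  }
  out
}

# One step of 6-connectivity binary erosion (face neighbours).
#' @noRd
erode_once <- function(mask) {
  d <- dim(mask)
  out <- mask
  pad_false <- function(m, ax, dir) {
    # neighbour value along axis `ax`, shifted by `dir`, FALSE outside
    if (d[ax] == 1L) return(array(FALSE, d))
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (dir > 0) {
      idx_src[[ax]] <- 2:n
      idx_dst[[ax]] <- 1:(n - 1)
    } else {
      idx_src[[ax]] <- 1:(n - 1)
      idx_dst[[ax]] <- 2:n
    }
    shifted <- array(FALSE, d)
    shifted[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    shifted
  }
  for (ax in 1:3) {
    if (d[ax] == 1L) next  # no neighbours along singleton axes
    out <- out & pad_false(mask, ax, +1L) & pad_false(mask, ax, -1L)
  }
  out
}

# One step of 6-connectivity binary dilation.
#' @noRd
dilate_once <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    idx <- lapply(d, seq_len)
    lo <- idx; hi <- idx
    lo[[ax]] <- 1:(d[ax] - 1); hi[[ax]] <- 2:d[ax]
    out[lo[[1]], lo[[2]], lo[[3]]] <-
      out[lo[[1]], lo[[2]], lo[[3]]] | mask[hi[[1]], hi[[2]], hi[[3]]]
    out[hi[[1]], hi[[2]], hi[[3]]] <-
      out[hi[[1]], hi[[2]], hi[[3]]] | mask[lo[[1]], lo[[2]], lo[[3]]]
  }
  out
}

#' @noRd
erode_mask <- function(mask, mm, voxel_size_mm) {
  n_iter <- as.integer(round(mm / min(voxel_size_mm)))
  m <- mask
  for (i in seq_len(max(0L, n_iter))) {
    nxt <- erode_once(m)
    if (!any(nxt)) break  # never erode a mask away entirely
    m <- nxt
  }
  m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}
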