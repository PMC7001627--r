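#' Separable Gaussian point-spread-function model
#'
#' The lateral width is detection-limited and the axial width is set by the
#' light-sheet thickness; both are given as FWHM in micrometres.
#'
#' @param lateral_fwhm_um lateral FWHM, micrometres
#' @param axial_fwhm_um axial FWHM (sheet thickness), micrometres
#' @return a `psf_model`
#' @export
psf_model <- function(lateral_fwhm_um = 4.2, axial_fwhm_um = 12) {
  stopifnot(lateral_fwhm_um > 0, axial_fwhm_um > 0)
  structure(list(lateral_fwhm_um = lateral_fwhm_um,
                 axial_fwhm_um = axial_fwhm_um, form = "gaussian"),
            class = "psf_model")
}

# per-axis sigma (x, y, z) in micrometres
psf_sigma_um <- function(psf) {
  s <- fwhm_to_sigma(c(psf$lateral_fwhm_um, psf$lateral_fwhm_um,
                       psf$axial_fwhm_um))
  names(s) <- c("x", "y", "z")
  s
}

#' Render a (possibly rotated) PSF as a volume
#'
#' Evaluates the Gaussian with covariance `R S R^T` on the grid (`R` the
#' pose's linear part, `S = diag(sigma^2)`) and normalizes to unit sum.
#' Sampling coarser than two samples per FWHM raises an undersampling
#' warning and sets the `"undersampled"` attribute.
#'
#' @param psf a [psf_model()]
#' @param voxel_um sampling voxel size, micrometres (triple)
#' @param pose optional [view_pose()]; `NULL` means identity
#' @param radius_sigmas support half-width in standard deviations
#' @return an `hr_volume` containing the unit-sum PSF, centred in the volume
#' @export
transform_psf <- function(psf, pose = NULL, voxel_um,
                          radius_sigmas = 3.5) {
  voxel_um <- rep(as.numeric(voxel_um), length.out = 3)
  sig <- psf_sigma_um(psf)
  und <- any(voxel_um > sigma_to_fwhm(sig) / 2)
  if (und)
    warning("transform_psf: PSF undersampled (fewer than 2 samples per FWHM)")
  R <- if (is.null(pose)) diag(3) else pose$rigid$linear
  S <- R %*% diag(sig^2) %*% t(R)
  Sinv <- solve(S)
  # grid extent from the rotated covariance's marginal sd
  msd <- sqrt(diag(S))
  n <- pmax(3L, as.integer(2 * ceiling(radius_sigmas * msd / voxel_um) + 1))
  ctr <- (n - 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(n[a]) - 1 - ctr[a]) * voxel_um[a])
  q11 <- Sinv[1, 1]; q22 <- Sinv[2, 2]; q33 <- Sinv[3, 3]
  q12 <- Sinv[1, 2]; q13 <- Sinv[1, 3]; q23 <- Sinv[2, 3]
  X <- ax[[1]]; Y <- ax[[2]]; Z <- ax[[3]]
  out <- array(0, n)
  for (k in seq_len(n[3])) {
    z <- Z[k]
    tx <- q11 * X^2 + 2 * q13 * X * z
    ty <- q22 * Y^2 + 2 * q23 * Y * z
    qf <- outer(tx, ty, "+") + 2 * q12 * outer(X, Y) + q33 * z^2
    out[, , k] <- exp(-0.5 * qf)
  }
  out <- out / sum(out)
  v <- hr_volume(out, voxel_um,
                 origin_um = -(n / 2) * voxel_um, frame = "sample")
  attr(v, "undersampled") <- und
  v
}
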