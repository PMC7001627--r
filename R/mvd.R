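#' Per-view input to multiview deconvolution
#'
#' The view's registered volume, its PSF (axis-aligned FWHM triple in the
#' view's own frame; the pose rotates it into the reference frame), and a
#' per-voxel content weight in `[0, 1]` (0 = discarded content).
#'
#' @param volume an `hr_volume` resampled onto the common reference grid
#' @param psf_fwhm_um length-3 FWHM (x, y, z) of the view PSF in the view's
#'   own frame, micrometres
#' @param pose the view's [view_pose()] (identity for the reference view)
#' @param weight optional array of weights matching the volume
#' @return a `view_data`
#' @export
view_data <- function(volume, psf_fwhm_um, pose = NULL, weight = NULL) {
  stopifnot(length(psf_fwhm_um) == 3, all(psf_fwhm_um > 0))
  if (!is.null(weight))
    stopifnot(identical(dim(weight), dim(volume$data)),
              min(weight) >= 0, max(weight) <= 1)
  structure(list(volume = volume, psf_fwhm_um = as.numeric(psf_fwhm_um),
                 pose = pose, weight = weight), class = "view_data")
}

# Rotate a volume about the vertical (y) axis through the grid centre, in
# voxel coordinates. Multiples of 90 degrees are exact index permutations
# (requires nx == nz); other angles use trilinear resampling.
rotate_y_vol <- function(vol, angle_deg) {
  d <- vdim(vol)
  a <- ((angle_deg %% 360) + 360) %% 360
  if (isTRUE(all.equal(a, 0))) return(vol)
  if (d[1] == d[3] && isTRUE(all.equal(a %% 90, 0))) {
    q <- round(a / 90) %% 4
    out <- vol
    # +90 about y: out[x, y, z] = in[z, y, nx + 1 - x]; apply q times
    for (i in seq_len(q))
      out <- aperm(out, c(3, 2, 1))[d[1]:1, , , drop = FALSE]
    return(out)
  }
  th <- a * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE) # inverse rotation (pull-back)
  ctr <- (d - 1) / 2
  t0 <- ctr - as.numeric(R %*% ctr)
  res <- cpp_affine3(vol, d, as.numeric(t(R)), t0, d)
  out <- res$data
  dim(out) <- d
  out
}

# Convolve with the view's PSF rotated into the reference frame:
# C_{R K}(psi) = R(C_K(R^-1 psi)). Exact for poses that are multiples of
# 90 degrees. Requires isotropic x/z voxels on the reference grid.
blur_view <- function(vol, sigma_vox, angle_deg, radius = 3) {
  if (isTRUE(all.equal(((angle_deg %% 360) + 360) %% 360, 0)))
    return(conv_gauss(vol, sigma_vox, radius))
  x <- rotate_y_vol(vol, -angle_deg)
  x <- conv_gauss(x, sigma_vox, radius)
  rotate_y_vol(x, angle_deg)
}

#' Content weight mask for one view
#'
#' Weights are 1 where the view still carries usable signal and roll off to
#' 0 (cosine taper) where the modelled transmittance along the view's
#' illumination axis falls below `threshold` — the completely blurred deep
#' content of a view is discarded rather than fused.
#'
#' @param grid the reference [grid3()]
#' @param pose the view's [view_pose()]
#' @param attenuation an [attenuation_model()] (the estimate used for
#'   masking); `NULL` gives all-ones weights
#' @param threshold transmittance below which content is discarded
#' @param taper_um width of the cosine rolloff, micrometres
#' @return array of weights in `[0, 1]` on the grid
#' @export
view_weight_mask <- function(grid, pose = NULL, attenuation = NULL,
                             threshold = 0, taper_um = 5) {
  if (is.null(attenuation) || threshold <= 0)
    return(array(1, grid$dim))
  # depth along the view's illumination axis (+x in the view frame)
  R <- if (is.null(pose)) diag(3) else pose$rigid$linear
  axis_ref <- as.numeric(t(R) %*% c(1, 0, 0))
  n <- grid$dim
  proj <- list(
    (grid$origin_um[1] + (seq_len(n[1]) - 0.5) * grid$voxel_um[1]) * axis_ref[1],
    (grid$origin_um[2] + (seq_len(n[2]) - 0.5) * grid$voxel_um[2]) * axis_ref[2],
    (grid$origin_um[3] + (seq_len(n[3]) - 0.5) * grid$voxel_um[3]) * axis_ref[3])
  s <- outer(outer(proj[[1]], proj[[2]], "+"), proj[[3]], "+")
  depth <- s - min(s)
  d_star <- -attenuation$length_scale_um * log(threshold)
  w <- array(1, n)
  ramp <- depth > d_star - taper_um & depth < d_star
  w[ramp] <- 0.5 * (1 + cos(pi * (depth[ramp] - (d_star - taper_um)) / taper_um))
  w[depth >= d_star] <- 0
  w
}

#' Multiview deconvolution configuration
#'
#' @param max_iterations iteration cap
#' @param rel_tolerance relative-change stopping rule
#' @param scheme `"simultaneous"` (all views per update) or `"sequential"`
#'   (one view at a time within an iteration)
#' @param acceleration `"none"` or `"extrapolate"` (two-step vector
#'   extrapolation of the multiplicative correction, off by default)
#' @param correction_clamp bound on the per-iteration multiplicative
#'   correction (clamped to `[1/c, c]`). The simultaneous update is not a
#'   joint EM scheme, and on mutually inconsistent views (registration
#'   residuals, interpolation halos, noise floors) unbounded corrections
#'   can run away in low-signal regions; the clamp leaves consensus
#'   regions untouched. `Inf` disables.
#' @param background_fraction additive background term in the ratio,
#'   `phi / (pred + b)` with `b` this fraction of the view's maximum. Far
#'   Gaussian tails are exponentially sensitive to any width mismatch
#'   between the modelled and the effective PSF; a small background bounds
#'   their corrections (tail content below `b` is attributed to
#'   background). 0 disables (pure Richardson-Lucy ratio).
#' @param normalization_floor lower bound on the correction normalizer
#'   `sum_v (w_v (x) P_v*)`, as a fraction of its interior value. Near
#'   volume faces and mask edges the normalizer shrinks (kernel mass falls
#'   outside the observed region) and plain Richardson-Lucy amplifies the
#'   truncated content without bound; the floor caps that gain. 0 disables.
#' @return an `mvd_config`
#' @export
mvd_config <- function(max_iterations = 100L, rel_tolerance = 1e-4,
                       scheme = c("simultaneous", "sequential"),
                       acceleration = c("none", "extrapolate"),
                       correction_clamp = 10,
                       background_fraction = 0,
                       normalization_floor = 0.5) {
  stopifnot(rel_tolerance > 0, correction_clamp > 1,
            normalization_floor >= 0, normalization_floor <= 1,
            background_fraction >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_tolerance = rel_tolerance,
                 scheme = match.arg(scheme),
                 acceleration = match.arg(acceleration),
                 correction_clamp = correction_clamp,
                 background_fraction = background_fraction,
                 normalization_floor = normalization_floor),
            class = "mvd_config")
}

mvd_precompute <- function(views, eps) {
  grid <- vol_grid(views[[1]]$volume)
  stopifnot(isTRUE(all.equal(grid$voxel_um[1], grid$voxel_um[3])))
  lapply(views, function(v) {
    sig <- fwhm_to_sigma(v$psf_fwhm_um) / grid$voxel_um
    ang <- if (is.null(v$pose)) 0 else v$pose$angle_deg
    w <- v$weight %||% array(1, grid$dim)
    # the data and the weight support are cached in the view's own frame,
    # so each update needs only two rotations per view (estimate in,
    # correction out) instead of four
    list(phi = v$volume$data, sig = sig, ang = ang, w = w,
         phi_rot = rotate_y_vol(v$volume$data, -ang),
         w_rot = rotate_y_vol(w, -ang) > 0.5,
         wblur = blur_view(w, sig, ang))
  })
}

#' One weighted multiview Richardson-Lucy update
#'
#' Simultaneous scheme:
#' `psi <- psi * [sum_v w_v * ((phi_v / (psi (x) P_v)) (x) P_v*)] /
#'  [sum_v (w_v (x) P_v*)]`
#' with `P_v*` the mirrored PSF (the Gaussian PSFs here are symmetric).
#' The sequential scheme applies one view's correction at a time. Weights
#' multiply the correction and its normalizer jointly, so masked regions
#' neither pull nor bleach the estimate. Non-negativity is preserved.
#'
#' @param psi current estimate (3-D array, non-negative)
#' @param views list of [view_data()]
#' @param config an [mvd_config()]
#' @param precomp internal cache from a previous call (per-view blurred
#'   weights); recomputed when `NULL`
#' @return updated estimate array with the cache in attribute `"precomp"`
#' @export
mvd_iterate <- function(psi, views, config = mvd_config(), precomp = NULL) {
  eps <- 1e-6 * max(mean(psi), 1e-12)
  if (is.null(precomp)) precomp <- mvd_precompute(views, eps)
  kl <- 0
  bgf <- config$background_fraction
  if (config$scheme == "simultaneous") {
    num <- 0
    den <- 0
    for (pv in precomp) {
      psi_v <- rotate_y_vol(psi, -pv$ang)
      pred <- conv_gauss(psi_v, pv$sig, 3)
      bg <- bgf * max(pv$phi)
      m <- pv$w_rot
      kl <- kl + kl_divergence(pv$phi_rot[m], pred[m] + bg)
      ratio <- pv$phi_rot / pmax(pred + bg, eps)
      num <- num + pv$w * rotate_y_vol(conv_gauss(ratio, pv$sig, 3), pv$ang)
      den <- den + pv$wblur
    }
    corr <- num / pmax(den, config$normalization_floor * max(den), 1e-8)
    cl <- config$correction_clamp
    if (is.finite(cl)) corr <- pmin(pmax(corr, 1 / cl), cl)
    psi <- psi * corr
  } else {
    cl <- config$correction_clamp
    for (pv in precomp) {
      psi_v <- rotate_y_vol(psi, -pv$ang)
      pred <- conv_gauss(psi_v, pv$sig, 3)
      bg <- bgf * max(pv$phi)
      m <- pv$w_rot
      kl <- kl + kl_divergence(pv$phi_rot[m], pred[m] + bg)
      ratio <- pv$phi_rot / pmax(pred + bg, eps)
      corr <- pv$w * rotate_y_vol(conv_gauss(ratio, pv$sig, 3), pv$ang) /
        pmax(pv$wblur, config$normalization_floor * max(pv$wblur), 1e-8) +
        (1 - pv$w)
      if (is.finite(cl)) corr <- pmin(pmax(corr, 1 / cl), cl)
      psi <- psi * corr
    }
  }
  if (anyNA(psi) || any(!is.finite(psi)))
    stop("mvd_iterate: non-finite values in the estimate")
  attr(psi, "precomp") <- precomp
  # data-fit divergence of the *incoming* estimate, for convergence logs
  attr(psi, "kl") <- kl
  psi
}

#' Run multiview deconvolution to convergence
#'
#' Initializes from the weighted mean of the views and iterates
#' [mvd_iterate()] until the relative change falls below the tolerance or
#' the iteration cap is reached.
#'
#' @param views list of [view_data()] registered to one grid
#' @param config an [mvd_config()]
#' @param coverage_mask optional logical array marking voxels that some
#'   view actually observes; a voxel inside this mask whose weight is zero
#'   in every view (all its observations discarded) raises a coverage
#'   error, whereas voxels outside it (e.g. padding no view samples) are
#'   simply left at zero. Default: the whole grid.
#' @return list with `estimate` (an `hr_volume`) and `log` (data.frame of
#'   iteration, summed per-view data-fit KL divergence, relative change)
#' @export
run_mvd <- function(views, config = mvd_config(), coverage_mask = NULL) {
  stopifnot(length(views) >= 1)
  grid <- vol_grid(views[[1]]$volume)
  for (v in views)
    stopifnot(identical(dim(v$volume$data), dim(views[[1]]$volume$data)))
  wsum <- 0
  init <- 0
  for (v in views) {
    w <- v$weight %||% array(1, grid$dim)
    wsum <- wsum + w
    init <- init + w * v$volume$data
  }
  uncovered <- wsum <= 0
  if (is.null(coverage_mask)) {
    if (any(uncovered))
      stop("coverage error: some voxels carry zero weight in every view")
  } else if (any(uncovered & coverage_mask)) {
    stop("coverage error: observed voxels carry zero weight in every view")
  }
  psi <- array(0, grid$dim)
  psi[!uncovered] <- init[!uncovered] / wsum[!uncovered]
  psi <- pmax(psi, 1e-6 * max(mean(psi), 1e-12))
  precomp <- mvd_precompute(views, 0)
  log_df <- data.frame(iteration = integer(0), kl = numeric(0),
                       rel_change = numeric(0))
  prev_corr <- NULL
  for (it in seq_len(config$max_iterations)) {
    old <- psi
    psi <- mvd_iterate(psi, views, config, precomp)
    precomp <- attr(psi, "precomp")
    kl_in <- attr(psi, "kl")
    attr(psi, "precomp") <- NULL
    attr(psi, "kl") <- NULL
    if (config$acceleration == "extrapolate" && it > 2) {
      # two-step extrapolation on the multiplicative step
      g1 <- psi - old
      if (!is.null(prev_corr)) {
        num <- sum(g1 * prev_corr)
        den <- sum(prev_corr * prev_corr)
        alpha <- if (den > 0) max(0, min(0.9, num / den)) else 0
        psi <- pmax(psi + alpha * g1, 0)
      }
      prev_corr <- g1
    }
    rel <- sqrt(sum((psi - old)^2) / max(sum(old^2), 1e-300))
    log_df[nrow(log_df) + 1L, ] <- list(it, kl_in, rel)
    if (rel < config$rel_tolerance) break
  }
  est <- hr_volume(psi, grid$voxel_um, grid$origin_um,
                   frame = views[[1]]$volume$frame)
  list(estimate = est, log = log_df)
}
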