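#' SVR iteration configuration
#'
#' @param max_iterations iteration cap
#' @param rel_tolerance stop when the relative L2 change of the estimate
#'   falls below this value
#' @param update `"poisson"` for the multiplicative Richardson-Lucy-type
#'   maximum-likelihood update (default) or `"leastsq"` for the
#'   multiplicative least-squares (ISRA) update
#' @param acceleration exponent `q` in `[1, 2]` applied to the
#'   multiplicative correction (1 = off)
#' @param epsilon_scale positivity floor, as a fraction of the mean intensity
#' @return an `svr_config`
#' @export
svr_config <- function(max_iterations = 200L, rel_tolerance = 1e-4,
                       update = c("poisson", "leastsq"), acceleration = 1,
                       epsilon_scale = 1e-6) {
  stopifnot(rel_tolerance > 0, acceleration >= 1, acceleration <= 2)
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_tolerance = rel_tolerance,
                 update = match.arg(update),
                 acceleration = acceleration,
                 epsilon_scale = epsilon_scale), class = "svr_config")
}

#' Extract decimated low-resolution groups from a raw scan
#'
#' Group `j` collects frames `j, j + M, j + 2M, ...`; all groups are
#' truncated to a common slice count. When the camera oversamples the
#' native lateral voxel, frames are binned down to the LR pixel grid.
#' Each group carries its subvoxel offset in HR-voxel units (sheared-frame
#' convention, see [grouping_plan()]) and the frame indices it came from.
#'
#' @param raw a `raw_sequence`
#' @param plan a [grouping_plan()]
#' @return list of `lr_group`
#' @export
extract_lr_groups <- function(raw, plan) {
  M <- plan$decimation_M
  G <- plan$n_groups_G
  d <- dim(raw$frames)
  if (d[3] < M) stop("extract_lr_groups: fewer frames than the decimation M")
  bin <- as.integer(round(plan$geometry$lr_voxel_um[1:2] / raw$pixel_um))
  bin <- pmax(bin, 1L)
  n_sl <- min(vapply(0:(G - 1), function(j)
    length(seq(j + 1L, d[3], by = M)), integer(1)))
  lapply(0:(G - 1), function(j) {
    idx <- seq(j + 1L, d[3], by = M)[seq_len(n_sl)]
    st <- raw$frames[, , idx, drop = FALSE]
    if (any(bin > 1L)) {
      nb <- (d[1:2] %/% bin) * bin
      st <- st[seq_len(nb[1]), seq_len(nb[2]), , drop = FALSE]
      st <- block_down(st, c(bin, 1L))
    }
    structure(list(stack = st,
                   offset_hr_voxels = plan$offsets_stack[j + 1, ],
                   offset_nominal = plan$offsets[j + 1, ],
                   provenance = idx - 1L,
                   plan = plan),
              class = "lr_group")
  })
}

#' Estimate subvoxel inter-group offsets by correlation
#'
#' Each group is correlated against group 1 (FFT cross-correlation with
#' local log-quadratic peak interpolation, exact for Gaussian-shaped
#' peaks); shifts are returned in HR-voxel units, matching the
#' sheared-frame offset convention. Groups whose normalized correlation
#' peak falls below `min_confidence`, or whose estimate strays more than
#' `max_deviation_vox` from the nominal geometry, fall back to the nominal
#' offsets with a warning.
#'
#' @param groups list of `lr_group` from [extract_lr_groups()]
#' @param min_confidence minimum normalized correlation peak value
#' @param max_deviation_vox trust radius around the nominal offsets
#' @return G x 3 matrix of offsets in HR voxels (row 1 is zero)
#' @export
estimate_offsets <- function(groups, min_confidence = 0.3,
                             max_deviation_vox = 1) {
  stopifnot(length(groups) >= 2)
  enh <- groups[[1]]$plan$geometry$enhancement
  ref <- groups[[1]]$stack
  d <- dim(ref)
  ref <- ref - mean(ref)
  Fr <- fft(ref)
  out <- matrix(0, length(groups), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  fell_back <- FALSE
  for (g in seq_along(groups)[-1]) {
    mov <- groups[[g]]$stack
    mov <- mov - mean(mov)
    Fm <- fft(mov)
    cc <- Re(fft(Fr * Conj(Fm), inverse = TRUE)) / length(Fr)
    cc <- cc / max(sqrt(sum(ref^2) * sum(mov^2)), 1e-12)
    pk <- which.max(cc)
    conf <- cc[pk]
    pi3 <- arrayInd(pk, d)
    # full 3-D (log-)quadratic fit around the peak: the scan shear makes
    # the correlation peak obliquely elongated, so the x-z cross terms
    # matter; the stationary point of the fitted quadratic is the
    # subvoxel peak (exact for Gaussian-shaped peaks)
    nb <- array(0, c(3, 3, 3))
    for (az in -1:1) for (ay in -1:1) for (ax in -1:1)
      nb[ax + 2, ay + 2, az + 2] <-
        cc[(pi3[1] - 1 + ax) %% d[1] + 1,
           (pi3[2] - 1 + ay) %% d[2] + 1,
           (pi3[3] - 1 + az) %% d[3] + 1]
    if (all(nb > 0)) nb <- log(nb)
    grad <- c(nb[3, 2, 2] - nb[1, 2, 2],
              nb[2, 3, 2] - nb[2, 1, 2],
              nb[2, 2, 3] - nb[2, 2, 1]) / 2
    H <- matrix(0, 3, 3)
    H[1, 1] <- nb[3, 2, 2] - 2 * nb[2, 2, 2] + nb[1, 2, 2]
    H[2, 2] <- nb[2, 3, 2] - 2 * nb[2, 2, 2] + nb[2, 1, 2]
    H[3, 3] <- nb[2, 2, 3] - 2 * nb[2, 2, 2] + nb[2, 2, 1]
    H[1, 2] <- H[2, 1] <-
      (nb[3, 3, 2] - nb[3, 1, 2] - nb[1, 3, 2] + nb[1, 1, 2]) / 4
    H[1, 3] <- H[3, 1] <-
      (nb[3, 2, 3] - nb[3, 2, 1] - nb[1, 2, 3] + nb[1, 2, 1]) / 4
    H[2, 3] <- H[3, 2] <-
      (nb[2, 3, 3] - nb[2, 1, 3] - nb[2, 3, 1] + nb[2, 1, 1]) / 4
    frac <- tryCatch({
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (max(ev) < 0) as.numeric(solve(-H, grad)) else numeric(3)
    }, error = function(e) numeric(3))
    frac <- pmax(pmin(frac, 1), -1)
    sh <- numeric(3)
    for (a in 1:3) {
      s <- pi3[a] - 1 + frac[a]
      if (s > d[a] / 2) s <- s - d[a]
      sh[a] <- s
    }
    # correlation shift of group g relative to group 1, LR units -> HR voxels
    est <- sh * c(enh[1], enh[2], enh[3])
    nominal <- groups[[g]]$offset_hr_voxels
    if (conf < min_confidence || any(abs(est - nominal) > max_deviation_vox)) {
      fell_back <- TRUE
      est <- nominal
    }
    out[g, ] <- est
  }
  if (fell_back)
    warning("estimate_offsets: low-confidence correlation; nominal geometry offsets used for some groups")
  out
}

#' Interpolate one LR group onto the high-resolution grid
#'
#' Trilinear interpolation by the integer enhancement factors, plus a small
#' strictly positive floor so multiplicative updates can proceed.
#'
#' @param group an `lr_group`
#' @param enhancement integer triple `(rx, ry, rz)`
#' @param epsilon_scale positivity floor relative to the mean
#' @return 3-D array on the HR grid
#' @export
initial_guess <- function(group, enhancement, epsilon_scale = 1e-6) {
  r <- as.integer(rep(enhancement, length.out = 3))
  st <- group$stack
  d <- vdim(st)
  od <- d * r
  A <- diag(1 / r)
  t0 <- 0.5 / r - 0.5
  res <- cpp_affine3(st, d, as.numeric(t(A)), t0, od)
  x <- res$data
  dim(x) <- od
  # boundary half-voxels extrapolate flat rather than to zero
  eps <- epsilon_scale * max(mean(st), 1e-12)
  x + eps
}

#' Forward projection of the multi-frame imaging model
#'
#' Predicts one LR group from the HR estimate: Gaussian PSF blur, subvoxel
#' shift (sampling the blurred volume at the group's offset), then
#' block-average downsampling by the enhancement factors. Blur and shift
#' commute in the continuous model; blurring first lets one convolution be
#' shared across all groups of a stack, and makes the streamed multi-group
#' update exactly the sum of the per-group operators. The operator is
#' linear and its adjoint is the reverse chain (replicating upsampling,
#' opposite shift, blur).
#'
#' @param hr HR-grid 3-D array
#' @param offset group offset in HR voxels
#' @param psf_sigma_vox per-axis PSF sigma in HR voxels
#' @param enhancement integer triple
#' @return predicted LR stack
#' @export
forward_project <- function(hr, offset, psf_sigma_vox, enhancement) {
  x <- conv_gauss(hr, psf_sigma_vox)
  x <- shift3(x, -as.numeric(offset))
  block_down(x, enhancement)
}

# adjoint of forward_project
back_project <- function(lr, offset, psf_sigma_vox, enhancement) {
  x <- block_up(lr, enhancement) / prod(enhancement)
  x <- shift3(x, as.numeric(offset))
  conv_gauss(x, psf_sigma_vox)
}

#' Subvoxel-resolving maximum-likelihood reconstruction
#'
#' Fuses the mutually shifted LR groups into one HR volume by the
#' multiplicative Poisson-ML (Richardson-Lucy-type) multi-frame update
#' `x <- x * sum_k At_k(y_k / A_k x) / sum_k At_k 1`, iterated until the
#' relative change falls below the tolerance. Non-negativity is preserved
#' by construction. The `"leastsq"` option replaces the ratio update by the
#' ISRA update `x * (At y) / (At A x)`.
#'
#' @param groups list of `lr_group`
#' @param psf a [psf_model()]
#' @param enhancement integer triple `(rx, ry, rz)`
#' @param config an [svr_config()]
#' @param offsets optional G x 3 offset matrix in HR voxels (e.g. from
#'   [estimate_offsets()]); defaults to the groups' sheared-frame offsets
#' @param hr_voxel_um HR voxel size (defaults from the groups' plan:
#'   lateral `lr / r`, axial `lr_axial_spacing / rz`)
#' @return an `hr_volume` in the sheared scan frame, with an
#'   `"iterations"` attribute logging (iteration, data-fit KL, rel. change)
#' @export
run_svr <- function(groups, psf, enhancement, config = svr_config(),
                    offsets = NULL, hr_voxel_um = NULL) {
  stopifnot(length(groups) >= 1)
  enhancement <- as.integer(rep(enhancement, length.out = 3))
  plan <- groups[[1]]$plan
  if (is.null(hr_voxel_um))
    hr_voxel_um <- c(plan$geometry$lr_voxel_um[1:2] / enhancement[1:2],
                     plan$lr_axial_spacing_um / enhancement[3])
  if (is.null(offsets))
    offsets <- do.call(rbind, lapply(groups, `[[`, "offset_hr_voxels"))
  sig_vox <- psf_sigma_um(psf) / hr_voxel_um
  ys <- lapply(groups, `[[`, "stack")
  tot <- sum(vapply(ys, sum, numeric(1)))
  d_lr <- vdim(ys[[1]])
  d_hr <- d_lr * enhancement
  if (tot <= 0) {
    warning("run_svr: all-zero data; returning a zero volume")
    return(hr_volume(array(0, d_hr), hr_voxel_um, frame = "sheared"))
  }
  eps <- config$epsilon_scale * tot / prod(d_hr)
  x <- initial_guess(groups[[1]], enhancement, config$epsilon_scale)
  B <- prod(enhancement)
  # The subvoxel shift and the PSF blur are both translation-invariant and
  # commute, so each iteration needs only two full convolutions: A_k x =
  # D(S_{-off_k}(H x)) and sum_k At_k r_k = H(sum_k S_{+off_k}(U r_k / B)).
  acc_shifted <- function(stacks) {
    acc <- array(0, d_hr)
    for (k in seq_along(groups))
      acc <- acc + shift3(block_up(stacks[[k]], enhancement) / B,
                          offsets[k, ])
    acc
  }
  ones <- array(1, d_lr)
  den <- conv_gauss(acc_shifted(rep(list(ones), length(groups))), sig_vox)
  den <- pmax(den, 1e-8)
  log_df <- data.frame(iteration = integer(0), kl = numeric(0),
                       rel_change = numeric(0))
  for (it in seq_len(config$max_iterations)) {
    blurred <- conv_gauss(x, sig_vox)
    kl <- 0
    rs <- vector("list", length(groups))
    preds <- if (config$update == "leastsq") vector("list", length(groups))
    for (k in seq_along(groups)) {
      pred <- block_down(shift3(blurred, -offsets[k, ]), enhancement)
      kl <- kl + kl_divergence(ys[[k]], pred)
      rs[[k]] <- if (config$update == "poisson") ys[[k]] / pmax(pred, eps)
                 else ys[[k]]
      if (config$update == "leastsq") preds[[k]] <- pred
    }
    num <- conv_gauss(acc_shifted(rs), sig_vox)
    corr <- if (config$update == "poisson") num / den
            else {
              axs <- conv_gauss(acc_shifted(preds), sig_vox)
              num / pmax(axs, eps)
            }
    if (config$acceleration != 1) corr <- corr^config$acceleration
    x_new <- x * corr
    if (anyNA(x_new) || any(!is.finite(x_new)))
      stop("run_svr: non-finite values in the estimate (iteration ", it, ")")
    rel <- sqrt(sum((x_new - x)^2) / max(sum(x^2), 1e-300))
    log_df[nrow(log_df) + 1L, ] <- list(it, kl, rel)
    x <- x_new
    if (rel < config$rel_tolerance) break
  }
  out <- hr_volume(x, hr_voxel_um, frame = "sheared")
  out$origin_um <- c(0, 0, 0)
  attr(out, "iterations") <- log_df
  attr(out, "enhancement") <- enhancement
  out
}

#' Shear-realign a sheared-frame reconstruction
#'
#' Applies the inverse scan shear by interpolating resampling so that
#' structures that are straight along z in the sample become straight along
#' the volume's axial axis; this recovers the true sample shape. The HR
#' axial plane spacing corresponds to `M / rz` frames, so the per-plane
#' lateral correction is `(M / rz) * (dx, dy)` scaled to lateral voxels.
#'
#' @param hr an `hr_volume` in the sheared frame (from [run_svr()])
#' @param geometry the [scan_geometry()] of the acquisition
#' @param frames_per_plane axial plane spacing in frames (defaults to
#'   `M / rz` from the grouping plan that produced `hr`; pass `M` for a raw
#'   LR stack)
#' @return an `hr_volume` in sample-aligned coordinates
#' @export
realign <- function(hr, geometry, frames_per_plane = NULL) {
  if (identical(hr$frame, "sample")) return(hr)
  d <- step_displacement(geometry) / 1000
  if (is.null(frames_per_plane))
    frames_per_plane <- hr$voxel_um[3] / d[["dz"]]
  sx <- frames_per_plane * d[["dx"]] / hr$voxel_um[1]
  sy <- frames_per_plane * d[["dy"]] / hr$voxel_um[2]
  if (sx == 0 && sy == 0) {
    out <- hr
    out$frame <- "sample"
    return(out)
  }
  A <- diag(3)
  A[1, 3] <- sx
  A[2, 3] <- sy
  res <- cpp_affine3(hr$data, vdim(hr$data), as.numeric(t(A)), c(0, 0, 0),
                     vdim(hr$data))
  x <- res$data
  dim(x) <- dim(hr$data)
  msk <- res$inside
  dim(msk) <- dim(hr$data)
  out <- hr_volume(x, hr$voxel_um, hr$origin_um, frame = "sample")
  attr(out, "iterations") <- attr(hr, "iterations")
  attr(out, "inside") <- msk
  out
}
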