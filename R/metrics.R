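# sample a 1-D intensity profile through a point along a coordinate axis
sample_profile <- function(volume, point_um, axis, half_window_um,
                           step_um = NULL) {
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'")
  step_um <- step_um %||% volume$voxel_um[ax]
  t <- seq(-half_window_um, half_window_um, by = step_um)
  g <- vol_grid(volume)
  p0 <- matrix(point_um, nrow = 1)
  v0 <- um_to_grid(g, p0)[1, ]
  # one resampling call: output line i samples v0 + (t_i / voxel) e_ax
  A <- matrix(0, 3, 3)
  A[ax, 1] <- step_um / g$voxel_um[ax]
  t0 <- v0
  t0[ax] <- t0[ax] - half_window_um / g$voxel_um[ax]
  res <- cpp_affine3(volume$data, vdim(volume$data), as.numeric(t(A)), t0,
                     c(length(t), 1L, 1L))
  list(t = t, y = as.numeric(res$data))
}

# trilinear sample at a single 0-based voxel coordinate
trilinear_at <- function(arr, p) {
  d <- dim(arr)
  res <- cpp_affine3(arr, d, as.numeric(t(diag(3))) * 0, p, c(1L, 1L, 1L))
  res$data[1]
}

#' Measure the FWHM of a structure along one axis
#'
#' Extracts a 1-D profile through `point_um`, subtracts the background
#' (median of the outer quartiles of the profile), fits a Gaussian by least
#' squares and reports `FWHM = 2 sqrt(2 ln 2) sigma` in micrometres. A fit
#' with R-squared below `min_r2` raises an unreliable-fit error.
#'
#' @param volume an `hr_volume`
#' @param point_um profile centre, micrometres
#' @param axis `"x"`, `"y"` or `"z"`
#' @param window_um full profile length (default `4 * expected_fwhm_um`)
#' @param expected_fwhm_um prior guess used to size the window
#' @param step_um profile sampling step (default: the voxel size)
#' @param mode `"gauss"` (least-squares fit, default) or `"halfmax"`
#'   (linear interpolation of the half-maximum crossings, for cross-checks)
#' @param min_r2 minimum fit R-squared
#' @return FWHM in micrometres, with the fit R-squared in attribute `"r2"`
#'   and the fitted centre in `"center_um"`
#' @export
measure_fwhm <- function(volume, point_um, axis, window_um = NULL,
                         expected_fwhm_um = NULL, step_um = NULL,
                         mode = c("gauss", "halfmax"), min_r2 = 0.8) {
  mode <- match.arg(mode)
  if (is.null(window_um)) {
    if (is.null(expected_fwhm_um))
      stop("measure_fwhm: give window_um or expected_fwhm_um")
    window_um <- 4 * expected_fwhm_um
  }
  prof <- sample_profile(volume, point_um, axis, window_um / 2, step_um)
  t <- prof$t
  y <- prof$y
  outer_q <- y[t <= quantile(t, 0.25) | t >= quantile(t, 0.75)]
  bg <- median(outer_q)
  y <- y - bg
  if (max(y) <= 0 || sd(y) == 0)
    stop("unreliable-fit: flat profile")
  if (mode == "halfmax") {
    half <- max(y) / 2
    above <- which(y >= half)
    if (!length(above)) stop("unreliable-fit: no half-max crossing")
    lo <- min(above)
    hi <- max(above)
    xl <- if (lo > 1)
      t[lo - 1] + (half - y[lo - 1]) / (y[lo] - y[lo - 1]) * (t[lo] - t[lo - 1])
    else t[1]
    xr <- if (hi < length(y))
      t[hi] + (y[hi] - half) / (y[hi] - y[hi + 1]) * (t[hi + 1] - t[hi])
    else t[length(t)]
    return(structure(xr - xl, r2 = NA_real_, center_um = NA_real_))
  }
  w0 <- max(y)
  mu0 <- t[which.max(y)]
  s0 <- max(sum(y > w0 / 2) * (t[2] - t[1]) / FWHM_PER_SIGMA,
            (t[2] - t[1]) / 2)
  obj <- function(p) {
    s <- exp(p[3])
    sum((y - p[1] * exp(-(t - p[2])^2 / (2 * s^2)))^2)
  }
  fit <- stats::optim(c(w0, mu0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  r2 <- 1 - fit$value / sum((y - mean(y))^2)
  if (!is.finite(r2) || r2 < min_r2)
    stop(sprintf("unreliable-fit: R-squared %.3f below %.2f", r2, min_r2))
  s_hat <- exp(fit$par[3])
  structure(sigma_to_fwhm(s_hat), r2 = r2,
            center_um = point_um[match(axis, c("x", "y", "z"))] +
              fit$par[2])
}

#' Per-bead FWHM report with ensemble aggregates
#'
#' Measures lateral (x, y) and axial (z) FWHM at each bead position by
#' Gaussian profile fits. Beads closer than `separation_factor` times the
#' expected FWHM to another bead, or `boundary_factor` times to the volume
#' face (so that the profile window fits), are flagged and excluded from
#' the aggregates, not silently dropped.
#'
#' @param volume an `hr_volume`
#' @param centers_um bead positions: n x 3 matrix or a data.frame with
#'   x, y, z columns (ground truth or detections)
#' @param expected_fwhm_um length-3 prior FWHM (x, y, z) used for window
#'   sizing and exclusion margins
#' @param separation_factor bead-bead exclusion multiple
#' @param boundary_factor bead-boundary exclusion multiple
#' @return an `fwhm_report`: list with `beads` (per-bead data.frame with
#'   fit diagnostics and exclusion flags), `aggregates` (median and IQR per
#'   axis over included beads) and `isotropy_ratio`
#'   (median axial / median lateral)
#' @export
bead_resolution_report <- function(volume, centers_um, expected_fwhm_um,
                                   separation_factor = 4,
                                   boundary_factor = 2) {
  if (is.data.frame(centers_um))
    centers_um <- as.matrix(centers_um[, c("x", "y", "z")])
  if (!nrow(centers_um)) stop("empty-report: no measurable beads")
  expected_fwhm_um <- rep(expected_fwhm_um, length.out = 3)
  g <- vol_grid(volume)
  lo <- g$origin_um
  hi <- g$origin_um + g$dim * g$voxel_um
  n <- nrow(centers_um)
  df <- data.frame(x = centers_um[, 1], y = centers_um[, 2],
                   z = centers_um[, 3], fwhm_x = NA_real_,
                   fwhm_y = NA_real_, fwhm_z = NA_real_, r2_min = NA_real_,
                   excluded = FALSE, reason = "")
  for (i in seq_len(n)) {
    p <- centers_um[i, ]
    near_edge <- any(p - lo < boundary_factor * expected_fwhm_um) ||
      any(hi - p < boundary_factor * expected_fwhm_um)
    crowd <- FALSE
    if (n > 1) {
      dd <- sqrt(rowSums(sweep(centers_um[-i, , drop = FALSE], 2, p)^2))
      crowd <- min(dd) < separation_factor * max(expected_fwhm_um)
    }
    if (near_edge || crowd) {
      df$excluded[i] <- TRUE
      df$reason[i] <- if (near_edge) "boundary" else "crowded"
      next
    }
    r2s <- numeric(0)
    ok <- TRUE
    for (a in 1:3) {
      ax <- c("x", "y", "z")[a]
      f <- tryCatch(
        measure_fwhm(volume, p, ax, expected_fwhm_um = expected_fwhm_um[a]),
        error = function(e) NULL)
      if (is.null(f)) {
        ok <- FALSE
        break
      }
      df[[paste0("fwhm_", ax)]][i] <- as.numeric(f)
      r2s <- c(r2s, attr(f, "r2"))
    }
    if (!ok) {
      df$excluded[i] <- TRUE
      df$reason[i] <- "fit-failed"
    } else df$r2_min[i] <- min(r2s)
  }
  inc <- df[!df$excluded, , drop = FALSE]
  if (!nrow(inc)) stop("empty-report: all beads excluded")
  agg <- data.frame(
    axis = c("x", "y", "z"),
    median_um = c(median(inc$fwhm_x), median(inc$fwhm_y), median(inc$fwhm_z)),
    iqr_um = c(stats::IQR(inc$fwhm_x), stats::IQR(inc$fwhm_y),
               stats::IQR(inc$fwhm_z)))
  med_lat <- median(c(inc$fwhm_x, inc$fwhm_y))
  med_ax <- agg$median_um[3]
  structure(list(beads = df, aggregates = agg,
                 median_lateral_um = med_lat, median_axial_um = med_ax,
                 isotropy_ratio = med_ax / med_lat,
                 n_included = nrow(inc)), class = "fwhm_report")
}

#' @export
print.fwhm_report <- function(x, ...) {
  cat(sprintf("fwhm_report: %d beads (%d included)\n",
              nrow(x$beads), x$n_included))
  print(x$aggregates)
  cat(sprintf("isotropy ratio (axial/lateral): %.3f\n", x$isotropy_ratio))
  invisible(x)
}

#' Signal-to-noise ratio from signal and background masks
#'
#' `(mean(signal) - mean(background)) / sd(background)`; a zero background
#' variance returns `Inf`.
#'
#' @param volume an `hr_volume` or 3-D array
#' @param signal_mask,background_mask disjoint logical arrays
#' @return SNR (dimensionless)
#' @export
snr <- function(volume, signal_mask, background_mask) {
  x <- if (inherits(volume, "hr_volume")) volume$data else volume
  stopifnot(any(signal_mask), any(background_mask),
            !any(signal_mask & background_mask))
  sb <- sd(x[background_mask])
  dm <- mean(x[signal_mask]) - mean(x[background_mask])
  if (sb == 0) {
    if (dm == 0) return(0)
    return(sign(dm) * Inf)
  }
  dm / sb
}

#' Count blob-like objects, optionally per region
#'
#' Detection-based counting via [detect_features()]; densities are counts
#' per cubic millimetre of region volume.
#'
#' @param volume an `hr_volume`
#' @param region_labels optional integer array matching the volume (0 =
#'   outside every region)
#' @param scales_um,threshold passed to [detect_features()]
#' @return data.frame with `region`, `count`, `volume_mm3`, `density_mm3`
#' @export
count_blobs <- function(volume, region_labels = NULL, scales_um = 2,
                        threshold = 0.1) {
  fts <- detect_features(volume, scales_um, threshold)
  vox_mm3 <- prod(volume$voxel_um) * 1e-9
  if (is.null(region_labels)) {
    vol_mm3 <- length(volume$data) * vox_mm3
    return(data.frame(region = 0L, count = nrow(fts),
                      volume_mm3 = vol_mm3,
                      density_mm3 = nrow(fts) / vol_mm3))
  }
  stopifnot(identical(dim(region_labels), dim(volume$data)))
  g <- vol_grid(volume)
  regions <- sort(unique(as.integer(region_labels[region_labels > 0])))
  lab_at <- if (nrow(fts)) {
    idx <- round(um_to_grid(g, as.matrix(fts[, c("x", "y", "z")]))) + 1
    idx <- pmin(pmax(idx, 1), matrix(rep(g$dim, each = nrow(idx)), ncol = 3))
    region_labels[cbind(idx[, 1], idx[, 2], idx[, 3])]
  } else integer(0)
  do.call(rbind, lapply(regions, function(r) {
    vol_mm3 <- sum(region_labels == r) * vox_mm3
    cnt <- sum(lab_at == r)
    data.frame(region = r, count = cnt, volume_mm3 = vol_mm3,
               density_mm3 = cnt / vol_mm3)
  }))
}
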