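#' Camera model
#'
#' @param pixel_um camera pixel size at the sample, micrometres
#' @param read_noise_sd additive Gaussian read noise, counts
#' @param poisson apply Poisson shot noise to the signal
#' @param seed RNG seed; identical seed and inputs give identical frames
#' @return a `camera_model`
#' @export
camera_model <- function(pixel_um = 1.625, read_noise_sd = 0,
                         poisson = FALSE, seed = 1L) {
  structure(list(pixel_um = pixel_um, read_noise_sd = read_noise_sd,
                 poisson = isTRUE(poisson), seed = as.integer(seed)),
            class = "camera_model")
}

#' Depth-dependent exponential attenuation
#'
#' Transmittance `t(depth) = max(exp(-depth / length_scale_um), floor)`
#' along the illumination axis, emulating scattering and absorption in
#' thick cleared tissue. Depth is measured from the illuminated face of the
#' field in each view's own frame.
#'
#' @param length_scale_um attenuation length, micrometres
#' @param axis illumination axis identifier (only `"x"` in this version)
#' @param floor minimum transmittance in `[0, 1]`
#' @return an `attenuation_model`
#' @export
attenuation_model <- function(length_scale_um, axis = "x", floor = 0) {
  stopifnot(length_scale_um > 0, floor >= 0, floor <= 1, axis == "x")
  structure(list(length_scale_um = length_scale_um, axis = axis,
                 floor = floor), class = "attenuation_model")
}

#' Transmittance at a given depth under an attenuation model
#' @param att an [attenuation_model()]
#' @param depth_um depth along the illumination axis, micrometres
#' @return transmittance in `[floor, 1]`, monotonically non-increasing
#' @export
transmittance <- function(att, depth_um) {
  pmax(exp(-depth_um / att$length_scale_um), att$floor)
}

# Field of view shared by all views of one acquisition: lateral extent of
# the bounds plus the accumulated scan drift and a 3.5 sigma PSF pad; the
# scan covers the axial extent plus the same pad.
scan_fov <- function(phantom, psf, geometry, camera) {
  d <- step_displacement(geometry) / 1000
  sig <- psf_sigma_um(psf)
  pad_lat <- 3.5 * sig[1] + 2 * camera$pixel_um
  pad_ax <- 3.5 * sig[3]
  lo <- phantom$bounds_um$lower
  hi <- phantom$bounds_um$upper
  z0 <- lo[3] - pad_ax
  z1 <- hi[3] + pad_ax
  n_frames <- as.integer(ceiling((z1 - z0) / d[["dz"]]))
  drift <- c(d[["dx"]], d[["dy"]]) * n_frames
  olat <- c(lo[1], lo[2]) - pad_lat - pmax(drift, 0)
  hilat <- c(hi[1], hi[2]) + pad_lat - pmin(drift, 0)
  npix <- as.integer(ceiling((hilat - olat) / camera$pixel_um))
  list(origin_xy = olat, n_pix = npix, z_plane = z1, n_frames = n_frames)
}

#' Simulate one tilted continuous scan
#'
#' Frame `i` is the fixed detection-plane section of the PSF-blurred
#' phantom displaced by `i` scan steps, integrated over camera pixels,
#' attenuated along the illumination axis of the view, with seeded Poisson
#' and read noise. The mid-step sample approximates the continuous
#' integration during one step (second-order accurate for steps much
#' smaller than the sheet thickness).
#'
#' @param phantom a [phantom()]
#' @param psf a [psf_model()]
#' @param geometry a [scan_geometry()]
#' @param camera a [camera_model()]
#' @param attenuation optional [attenuation_model()]
#' @param pose optional [view_pose()]: the phantom is rigidly rotated by the
#'   pose before imaging
#' @param fov optional shared field-of-view (from multiview simulation) so
#'   all views land on one camera grid
#' @param n_frames override the number of frames (default covers the box)
#' @return a `raw_sequence`: list with `frames` (nx x ny x T array),
#'   `geometry`, `pixel_um`, `origin_xy`, `z_plane`, `pose`, metadata
#' @export
simulate_scan <- function(phantom, psf, geometry, camera,
                          attenuation = NULL, pose = NULL, fov = NULL,
                          n_frames = NULL) {
  sig <- psf_sigma_um(psf)
  if (geometry$step_nm / 1000 >= psf$axial_fwhm_um)
    stop("simulate_scan: scan step must oversample the sheet thickness")
  if (is.null(fov)) fov <- scan_fov(phantom, psf, geometry, camera)
  nt <- as.integer(n_frames %||% fov$n_frames)
  d <- step_displacement(geometry) / 1000
  pp <- phantom_points(phantom, ds = camera$pixel_um / 4)
  frames <- array(0, c(fov$n_pix[1], fov$n_pix[2], nt))
  if (nrow(pp$centers)) {
    ctr <- pp$centers
    if (!is.null(pose)) ctr <- affine_apply(pose$rigid, ctr)
    flux <- pp$flux
    if (!is.null(attenuation)) {
      depth <- ctr[, 1] - (phantom$bounds_um$lower[1])
      flux <- flux * transmittance(attenuation, pmax(depth, 0))
    }
    sl <- sqrt(pp$sigma_um^2 + sig[1]^2)
    sa <- sqrt(pp$sigma_um^2 + sig[3]^2)
    # flux is per um^2 of pixel area after lateral integration; scale so
    # that camera counts are flux * (axial density * dz), peak ~ flux
    frames <- cpp_render_frames(c(fov$n_pix, nt), camera$pixel_um,
                                fov$origin_xy, ctr, sl, sa, flux,
                                d, fov$z_plane, 4.5)
    dim(frames) <- c(fov$n_pix, nt)
  }
  if (camera$poisson || camera$read_noise_sd > 0) {
    frames <- with_seed(camera$seed, {
      f <- frames
      if (camera$poisson) f[] <- rpois(length(f), pmax(f, 0))
      if (camera$read_noise_sd > 0)
        f <- f + rnorm(length(f), sd = camera$read_noise_sd)
      pmax(f, 0)
    })
  }
  geometry$n_frames <- nt
  structure(list(frames = frames, geometry = geometry,
                 pixel_um = camera$pixel_um, origin_xy = fov$origin_xy,
                 z_plane = fov$z_plane, pose = pose, camera = camera,
                 attenuation = attenuation,
                 bounds_um = phantom$bounds_um),
            class = "raw_sequence")
}

#' @export
print.raw_sequence <- function(x, ...) {
  cat(sprintf("raw_sequence %s frames, pixel %.4g um, view angle %s\n",
              paste(dim(x$frames), collapse = "x"), x$pixel_um,
              if (is.null(x$pose)) "0 (no pose)" else x$pose$angle_deg))
  invisible(x)
}

#' Simulate a multi-view tilted-scan acquisition
#'
#' View `v` images the phantom rotated by `view_pose(v, n_views)` about the
#' vertical axis through the centre of the bounds. Attenuation acts in each
#' view's own frame, so opposing views darken opposite sides of the sample.
#' Per-view noise seeds are `camera$seed + v`.
#'
#' @inheritParams simulate_scan
#' @param n_views number of views (rotation increment `360 / n_views`)
#' @return list of `raw_sequence`, one per view, each carrying its
#'   ground-truth pose
#' @export
simulate_multiview <- function(phantom, psf, geometry, camera,
                               attenuation = NULL, n_views = 8) {
  stopifnot(n_views >= 1)
  ctr <- (phantom$bounds_um$lower + phantom$bounds_um$upper) / 2
  fov <- scan_fov(phantom, psf, geometry, camera)
  lapply(seq_len(n_views) - 1L, function(v) {
    cam <- camera
    cam$seed <- camera$seed + v
    simulate_scan(phantom, psf, geometry, cam, attenuation = attenuation,
                  pose = view_pose(v, n_views, ctr), fov = fov)
  })
}
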