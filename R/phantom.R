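#' Ground-truth phantom: beads and filaments in a box
#'
#' Beads model sub-resolution fluorescent microspheres (point sources);
#' filaments model neurite-like tubular structures as smooth random-walk
#' polylines with a Gaussian cross-section.
#'
#' @param beads data.frame with columns `x, y, z` (centre, um), `intensity`
#'   (total flux) and `diameter_um`
#' @param filaments list of lists with fields `points` (n x 3 polyline, um),
#'   `radius_um` (half-width at half maximum of the tube cross-section) and
#'   `intensity` (flux per um of length)
#' @param bounds_um axis-aligned box: list with `lower` and `upper`
#'   length-3 vectors (um)
#' @return a `phantom`
#' @export
phantom <- function(beads = NULL, filaments = list(),
                    bounds_um = list(lower = c(0, 0, 0),
                                     upper = c(100, 100, 100))) {
  if (is.null(beads))
    beads <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        intensity = numeric(0), diameter_um = numeric(0))
  stopifnot(all(beads$intensity >= 0))
  pts <- as.matrix(beads[, c("x", "y", "z")])
  if (nrow(pts) &&
      (any(sweep(pts, 2, bounds_um$lower, "<")) ||
       any(sweep(pts, 2, bounds_um$upper, ">"))))
    stop("phantom: bead outside bounds")
  structure(list(beads = beads, filaments = filaments,
                 bounds_um = bounds_um), class = "phantom")
}

#' Random bead phantom with a minimum pairwise separation
#'
#' Beads are placed uniformly (rejection sampling) inside the box, or inside
#' a cylinder about the vertical axis through the box centre when
#' `layout = "cylinder_y"` — the latter keeps every bead inside the field of
#' view of all rotated views.
#'
#' @param n_beads number of beads
#' @param bounds_um box as in [phantom()]
#' @param diameter_um bead diameter (FWHM of the rendered bead), micrometres
#' @param min_separation_um minimum pairwise centre distance
#' @param seed RNG seed (placement is deterministic given the seed)
#' @param intensity total flux per bead
#' @param margin_um keep-out margin from the box faces
#' @param layout `"box"` or `"cylinder_y"`
#' @param cylinder_radius_um radius of the cylinder layout (defaults to the
#'   largest radius respecting `margin_um`)
#' @return a `phantom`
#' @export
make_bead_phantom <- function(n_beads, bounds_um, diameter_um = 0.5,
                              min_separation_um = 10, seed = 1,
                              intensity = 1, margin_um = 0,
                              layout = c("box", "cylinder_y"),
                              cylinder_radius_um = NULL) {
  layout <- match.arg(layout)
  lo <- bounds_um$lower + margin_um
  hi <- bounds_um$upper - margin_um
  if (any(hi < lo)) stop("make_bead_phantom: margin exceeds bounds")
  ctr <- (bounds_um$lower + bounds_um$upper) / 2
  if (is.null(cylinder_radius_um))
    cylinder_radius_um <- min((hi - lo)[c(1, 3)]) / 2
  pts <- matrix(numeric(0), 0, 3)
  with_seed(seed, {
    tries <- 0L
    max_tries <- 4000L * max(n_beads, 1L)
    while (nrow(pts) < n_beads) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("make_bead_phantom: cannot place beads at the requested separation")
      p <- lo + runif(3) * (hi - lo)
      if (layout == "cylinder_y" &&
          (p[1] - ctr[1])^2 + (p[3] - ctr[3])^2 > cylinder_radius_um^2)
        next
      if (nrow(pts) &&
          min(sqrt(rowSums(sweep(pts, 2, p)^2))) < min_separation_um)
        next
      pts <- rbind(pts, p)
    }
  })
  beads <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      intensity = rep(intensity, nrow(pts)),
                      diameter_um = rep(diameter_um, nrow(pts)))
  phantom(beads = beads, bounds_um = bounds_um)
}

#' Random smooth filament phantom
#'
#' Each filament is a random-walk polyline whose direction diffuses slowly
#' (smoothness set by `turn_sd_deg`), clipped to the box.
#'
#' @param n_filaments number of filaments
#' @param bounds_um box as in [phantom()]
#' @param radius_um tube half-width at half maximum, micrometres
#' @param seed RNG seed
#' @param intensity flux per micrometre of filament length
#' @param step_um polyline step length
#' @param n_steps maximum number of steps per filament
#' @param turn_sd_deg per-step angular diffusion of the direction
#' @return a `phantom`
#' @export
make_filament_phantom <- function(n_filaments, bounds_um, radius_um = 0.5,
                                  seed = 1, intensity = 1, step_um = 1,
                                  n_steps = 200, turn_sd_deg = 8) {
  fil <- list()
  with_seed(seed, {
    lo <- bounds_um$lower
    hi <- bounds_um$upper
    for (f in seq_len(n_filaments)) {
      p <- lo + runif(3) * (hi - lo)
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2))
      pts <- matrix(p, 1, 3)
      for (s in seq_len(n_steps)) {
        d <- d + rnorm(3, sd = turn_sd_deg * pi / 180)
        d <- d / sqrt(sum(d^2))
        p2 <- p + step_um * d
        if (any(p2 < lo) || any(p2 > hi)) break
        pts <- rbind(pts, p2)
        p <- p2
      }
      fil[[f]] <- list(points = pts, radius_um = radius_um,
                       intensity = intensity)
    }
  })
  phantom(filaments = fil, bounds_um = bounds_um)
}

# Reduce a phantom to point sources: centres (n x 3 um), per-point Gaussian
# sigma (um, object size only) and flux. Beads contribute one point with
# FWHM = diameter; filaments are sampled every `ds` um with flux
# intensity * ds and cross-section FWHM = 2 * radius.
phantom_points <- function(ph, ds = 0.25) {
  ctr <- matrix(numeric(0), 0, 3)
  sig <- numeric(0)
  flx <- numeric(0)
  if (nrow(ph$beads)) {
    ctr <- rbind(ctr, as.matrix(ph$beads[, c("x", "y", "z")]))
    sig <- c(sig, fwhm_to_sigma(ph$beads$diameter_um))
    flx <- c(flx, ph$beads$intensity)
  }
  for (f in ph$filaments) {
    pts <- f$points
    if (nrow(pts) < 2) next
    seg <- diff(pts)
    len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(len))
    s <- seq(0, cum[length(cum)], by = ds)
    idx <- findInterval(s, cum, rightmost.closed = TRUE)
    idx <- pmin(idx, nrow(seg))
    frac <- (s - cum[idx]) / pmax(len[idx], 1e-12)
    smp <- pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
    ctr <- rbind(ctr, smp)
    sig <- c(sig, rep(fwhm_to_sigma(2 * f$radius_um), nrow(smp)))
    flx <- c(flx, rep(f$intensity * ds, nrow(smp)))
  }
  list(centers = ctr, sigma_um = sig, flux = flx)
}

#' Render a phantom onto a voxel grid
#'
#' Analytic rasterization: every primitive is deposited as a separable
#' integrated Gaussian (error-function integrals over voxel cells), so the
#' flux of interior primitives is exact. With a PSF the object size and the
#' PSF widths add in quadrature.
#'
#' @param phantom a [phantom()]
#' @param voxel_um voxel size, micrometres (scalar or triple)
#' @param psf optional [psf_model()] blurring the rendering
#' @param bounds_um box to rasterize (defaults to the phantom bounds)
#' @return an `hr_volume`; flags `"undersampled"` when the PSF is sampled
#'   at fewer than 2 samples per FWHM
#' @export
render_volume <- function(phantom, voxel_um, psf = NULL,
                          bounds_um = phantom$bounds_um) {
  voxel_um <- rep(as.numeric(voxel_um), length.out = 3)
  und <- FALSE
  psig <- c(0, 0, 0)
  if (!is.null(psf)) {
    psig <- psf_sigma_um(psf)
    und <- any(voxel_um > sigma_to_fwhm(psig) / 2)
    if (und)
      warning("render_volume: PSF undersampled (fewer than 2 samples per FWHM)")
  }
  n <- pmax(1L, as.integer(round((bounds_um$upper - bounds_um$lower) / voxel_um)))
  pp <- phantom_points(phantom, ds = min(voxel_um) / 2)
  out <- array(0, n)
  if (nrow(pp$centers)) {
    sig <- cbind(sqrt(pp$sigma_um^2 + psig[1]^2),
                 sqrt(pp$sigma_um^2 + psig[2]^2),
                 sqrt(pp$sigma_um^2 + psig[3]^2))
    out <- cpp_render_points_vol(n, voxel_um, bounds_um$lower,
                                 pp$centers, sig, pp$flux, 4.5)
    dim(out) <- n
  }
  v <- hr_volume(out, voxel_um, origin_um = bounds_um$lower)
  attr(v, "undersampled") <- und
  v
}

#' Serialize a phantom to JSON
#' @param phantom a [phantom()]
#' @param path optional output file
#' @return JSON string
#' @export
phantom_to_json <- function(phantom, path = NULL) {
  o <- list(beads = phantom$beads,
            filaments = lapply(phantom$filaments, function(f)
              list(points = f$points, radius_um = f$radius_um,
                   intensity = f$intensity)),
            bounds_um = phantom$bounds_um)
  js <- jsonlite::toJSON(o, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  js
}

#' Read a phantom from JSON
#' @param x JSON string or file path
#' @return a [phantom()]
#' @export
phantom_from_json <- function(x) {
  o <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE)
  fil <- lapply(o$filaments, function(f)
    list(points = matrix(unlist(f$points), ncol = 3),
         radius_um = f$radius_um, intensity = f$intensity))
  phantom(beads = as.data.frame(o$beads), filaments = fil,
          bounds_um = list(lower = as.numeric(o$bounds_um$lower),
                           upper = as.numeric(o$bounds_um$upper)))
}
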