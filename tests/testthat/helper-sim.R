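# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# One noise-free tilted scan of a few beads, decimated into LR groups.
tiny_bead_scan <- function(beads = data.frame(x = 20, y = 20, z = 20,
                                              intensity = 1e5,
                                              diameter_um = 0.5),
                           L = 40, psf = psf_model(4.2, 12),
                           geometry = scan_geometry(280, 10, 10),
                           noise = FALSE, seed = 3) {
  bounds <- list(lower = c(0, 0, 0), upper = rep(L, 3))
  ph <- phantom(beads = beads, bounds_um = bounds)
  cam <- camera_model(1.625, read_noise_sd = if (noise) 2 else 0,
                      poisson = noise, seed = seed)
  raw <- simulate_scan(ph, psf, geometry, cam)
  plan <- grouping_plan(geometry)
  M <- plan$decimation_M
  rz <- geometry$enhancement[3]
  keep <- (dim(raw$frames)[3] %/% (M * rz)) * (M * rz)
  raw$frames <- raw$frames[, , seq_len(keep), drop = FALSE]
  groups <- extract_lr_groups(raw, plan)
  # bead positions in realigned stack coordinates (axial axis flipped,
  # half-spacing and half-shear offsets of the slice-centre convention)
  d <- step_displacement(geometry) / 1000
  q2 <- (M / rz) / 2
  truth <- cbind(beads$x - q2 * d[["dx"]], beads$y - q2 * d[["dy"]],
                 raw$z_plane - beads$z + plan$lr_axial_spacing_um / 2)
  list(phantom = ph, raw = raw, plan = plan, groups = groups,
       geometry = geometry, psf = psf, truth_realigned = truth)
}

# dense matrix of the per-group forward operator on a small grid
dense_forward_matrix <- function(d_hr, offset, psf_sigma_vox, enhancement) {
  n <- prod(d_hr)
  cols <- lapply(seq_len(n), function(i) {
    e <- array(0, d_hr)
    e[i] <- 1
    as.numeric(forward_project(e, offset, psf_sigma_vox, enhancement))
  })
  do.call(cbind, cols)
}

expect_monotone_nonincreasing <- function(x, slack = 1e-8) {
  expect_true(all(diff(x) <= slack * max(abs(x[1]), 1)))
}

# exact-model multiview fixture: a point object blurred with each view's
# rotated PSF on an isotropic grid. Odd grid with the point on the
# rotation axis, so every pose keeps the object fixed and the views are
# exactly consistent.
mvd_fixture <- function(angles, psf_fwhm = c(4.2, 4.2, 12), n = 49,
                        flux = 1e4, weights = NULL) {
  truth <- array(0, c(n, n, n))
  truth[(n + 1) / 2, (n + 1) / 2, (n + 1) / 2] <- flux
  sig <- fwhm_to_sigma(psf_fwhm)
  views <- lapply(seq_along(angles), function(v) {
    blurred <- svrmvd:::blur_view(truth, sig, angles[v])
    vd <- view_data(hr_volume(blurred, c(1, 1, 1)), psf_fwhm,
                    pose = view_pose(0, 1),
                    weight = if (is.null(weights)) NULL else weights[[v]])
    vd$pose$angle_deg <- angles[v]
    vd
  })
  list(truth = truth, views = views)
}
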