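box100 <- list(lower = c(0, 0, 0), upper = c(100, 100, 100))

test_that("bead phantoms respect separation, determinism and capacity", {
  expect_equal(nrow(make_bead_phantom(0, box100, seed = 1)$beads), 0)

  ph <- make_bead_phantom(10, box100, min_separation_um = 10, seed = 1)
  pts <- as.matrix(ph$beads[, c("x", "y", "z")])
  expect_equal(nrow(pts), 10)
  expect_gte(min(dist(pts)), 10)
  expect_true(all(pts >= 0 & pts <= 100))

  ph2 <- make_bead_phantom(10, box100, min_separation_um = 10, seed = 1)
  expect_identical(ph$beads, ph2$beads)

  expect_error(make_bead_phantom(10, box100, min_separation_um = 200,
                                 seed = 1),
               "cannot place")
})

test_that("filament phantoms are deterministic and in bounds", {
  expect_length(make_filament_phantom(0, box100, seed = 1)$filaments, 0)
  f1 <- make_filament_phantom(3, box100, seed = 7)
  f2 <- make_filament_phantom(3, box100, seed = 7)
  expect_identical(f1$filaments, f2$filaments)
  for (f in f1$filaments) {
    expect_true(all(f$points >= 0 & f$points <= 100))
    expect_gt(nrow(f$points), 1)
  }
})

test_that("rendering conserves flux and reproduces the PSF widths", {
  expect_true(all(render_volume(phantom(bounds_um = box100), 2)$data == 0))

  b <- list(lower = c(0, 0, 0), upper = c(40, 40, 72))
  ph <- phantom(beads = data.frame(x = 20, y = 20, z = 36, intensity = 1,
                                   diameter_um = 0.5), bounds_um = b)
  v0 <- render_volume(ph, 1)
  expect_equal(sum(v0$data), 1, tolerance = 0.01)

  # voxels integrate flux, so the measured width carries a small
  # voxel-footprint term; sample finely enough to keep it below 2%
  v <- render_volume(ph, c(0.5, 0.5, 1), psf = psf_model(4.2, 12))
  expect_equal(sum(v$data), 1, tolerance = 0.01)
  expect_equal(measure_fwhm(v, c(20, 20, 36), "x", expected_fwhm_um = 4.2),
               4.2, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(measure_fwhm(v, c(20, 20, 36), "z", expected_fwhm_um = 12),
               12, tolerance = 0.02, ignore_attr = TRUE)

  expect_warning(render_volume(ph, c(4, 4, 4), psf = psf_model(4.2, 12)),
                 "undersampled")
})

test_that("filament cross-sections widen with the PSF as expected", {
  b <- list(lower = c(0, 0, 0), upper = c(40, 40, 40))
  fil <- list(list(points = rbind(c(20, 5, 20), c(20, 35, 20)),
                   radius_um = 0.5, intensity = 1))
  ph <- phantom(filaments = fil, bounds_um = b)
  v <- render_volume(ph, 0.5, psf = psf_model(3, 3))
  # tube FWHM = 2 * radius combined in quadrature with the PSF
  expected <- sqrt(1^2 + 3^2)
  got <- measure_fwhm(v, c(20, 20, 20), "x", expected_fwhm_um = expected)
  expect_equal(as.numeric(got), expected, tolerance = 0.05)
})

test_that("rendered and rotated PSFs keep unit mass and rotate widths", {
  pv <- transform_psf(psf_model(4.2, 12), NULL, c(1, 1, 1))
  expect_equal(sum(pv$data), 1, tolerance = 1e-6)
  ctr <- pv$origin_um + dim(pv$data) / 2 * pv$voxel_um
  expect_equal(measure_fwhm(pv, ctr, "x", window_um = 20), 4.2,
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(measure_fwhm(pv, ctr, "z", window_um = 50), 12,
               tolerance = 0.02, ignore_attr = TRUE)

  # a 90-degree pose swaps the lateral and axial widths
  p90 <- transform_psf(psf_model(4.2, 12), view_pose(2, 8), c(1, 1, 1))
  c90 <- p90$origin_um + dim(p90$data) / 2 * p90$voxel_um
  expect_equal(measure_fwhm(p90, c90, "x", window_um = 50), 12,
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(measure_fwhm(p90, c90, "z", window_um = 20), 4.2,
               tolerance = 0.02, ignore_attr = TRUE)

  # a 45-degree pose gives second moments R S R^T
  p45 <- transform_psf(psf_model(4.2, 12), view_pose(1, 8), c(1, 1, 1))
  d <- dim(p45$data)
  ax <- lapply(1:3, function(a) seq_len(d[a]) - (d[a] + 1) / 2)
  w <- p45$data
  mom <- function(i, j) {
    gi <- slice.index(w, i)
    gj <- slice.index(w, j)
    sum(ax[[i]][gi] * ax[[j]][gj] * w)
  }
  S <- diag(fwhm_to_sigma(c(4.2, 4.2, 12))^2)
  R <- view_pose(1, 8)$rigid$linear
  SR <- R %*% S %*% t(R)
  expect_equal(mom(1, 1), SR[1, 1], tolerance = 0.02)
  expect_equal(mom(3, 3), SR[3, 3], tolerance = 0.02)
  expect_equal(mom(1, 3), SR[1, 3], tolerance = 0.05)
})

test_that("scan simulation is deterministic and geometrically consistent", {
  g <- scan_geometry(280, 10, 10)
  psf <- psf_model(4.2, 12)
  b <- list(lower = c(0, 0, 0), upper = c(30, 30, 30))

  empty <- phantom(bounds_um = b)
  cam0 <- camera_model(1.625, read_noise_sd = 0, poisson = FALSE)
  expect_true(all(simulate_scan(empty, psf, g, cam0)$frames == 0))

  ph <- phantom(beads = data.frame(x = 15, y = 15, z = 12, intensity = 1e4,
                                   diameter_um = 0.5), bounds_um = b)
  raw <- simulate_scan(ph, psf, g, cam0)
  tot <- apply(raw$frames, 3, sum)
  imax <- which.max(tot) - 1
  d <- step_displacement(g) / 1000
  z_hat <- raw$z_plane - imax * d[["dz"]]
  expect_lt(abs(z_hat - 12), d[["dz"]] + 1e-9)

  camn <- camera_model(1.625, read_noise_sd = 2, poisson = TRUE, seed = 9)
  r1 <- simulate_scan(ph, psf, g, camn)
  r2 <- simulate_scan(ph, psf, g, camn)
  expect_identical(r1$frames, r2$frames)

  expect_error(simulate_scan(ph, psf, scan_geometry(13000, 10, 10), cam0),
               "oversample")
})

test_that("multiview simulation rotates the sample and attenuates per view", {
  g <- scan_geometry(560, 10, 10)
  psf <- psf_model(4.2, 12)
  b <- list(lower = c(0, 0, 0), upper = c(30, 30, 30))
  cam0 <- camera_model(1.625, read_noise_sd = 0, poisson = FALSE)
  ph <- phantom(beads = data.frame(x = 22, y = 15, z = 15, intensity = 1e4,
                                   diameter_um = 0.5), bounds_um = b)

  one <- simulate_multiview(ph, psf, g, cam0, n_views = 1)
  direct <- simulate_scan(ph, psf, g, cam0,
                          pose = view_pose(0, 1, c(15, 15, 15)))
  expect_equal(one[[1]]$frames, direct$frames, tolerance = 1e-12)

  views <- simulate_multiview(ph, psf, g, cam0, n_views = 8)
  ctr <- c(15, 15, 15)
  d <- step_displacement(g) / 1000
  for (v in c(2, 5, 7)) {
    p_v <- as.numeric(affine_apply(view_pose(v - 1, 8, ctr)$rigid,
                                   c(22, 15, 15)))
    tot <- apply(views[[v]]$frames, 3, sum)
    z_hat <- views[[v]]$z_plane - (which.max(tot) - 1) * d[["dz"]]
    expect_lt(abs(z_hat - p_v[3]), 2 * d[["dz"]])
  }

  att <- attenuation_model(4, floor = 0)
  av <- simulate_multiview(ph, psf, g, cam0, attenuation = att, n_views = 8)
  bright <- vapply(av, function(r) max(r$frames), numeric(1))
  # bead at depth 22 um in view 0 (t = exp(-5.5) < 10%), at 8 um in the
  # opposing view (t = exp(-2) > 10%)
  expect_lt(bright[1] / max(bright), 0.1)
  expect_gt(bright[5] / max(bright), 0.9)
})
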