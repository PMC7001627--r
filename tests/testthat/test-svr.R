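test_that("group extraction partitions frames with disjoint provenance", {
  g <- scan_geometry(280, 10, 10)
  plan <- grouping_plan(g, 4.5)
  raw <- structure(list(frames = array(runif(4 * 4 * 34), c(4, 4, 34)),
                        pixel_um = g$lr_voxel_um[1]),
                   class = "raw_sequence")
  groups <- extract_lr_groups(raw, plan)
  expect_length(groups, 17)
  expect_true(all(vapply(groups, function(x) dim(x$stack)[3], 1L) == 2L))
  prov <- sort(unlist(lapply(groups, `[[`, "provenance")))
  expect_equal(prov, 0:33)

  plan1 <- grouping_plan(scan_geometry(1000, 0, 0,
                                       lr_voxel_um = c(2, 2, 1),
                                       enhancement = c(1, 1, 1)), 1)
  g1 <- extract_lr_groups(raw, plan1)
  expect_length(g1, 1)
  expect_equal(g1[[1]]$stack, raw$frames)
  expect_equal(unname(g1[[1]]$offset_hr_voxels), c(0, 0, 0))

  raw$frames <- raw$frames[, , 1:5, drop = FALSE]
  expect_error(extract_lr_groups(raw, plan), "fewer frames")
})

fx <- tiny_bead_scan()

test_that("decimated groups carry the predicted subvoxel offsets", {
  # a bead's centroid moves by minus the alignment offset between groups
  cent_z <- function(st) sum(slice.index(st, 3) * st) / sum(st)
  rz <- fx$geometry$enhancement[3]
  c1 <- cent_z(fx$groups[[1]]$stack)
  for (j in c(5, 12)) {
    cj <- cent_z(fx$groups[[j]]$stack)
    expect_equal((c1 - cj) * rz, unname(fx$plan$offsets_stack[j, 3]),
                 tolerance = 0.1 / max(fx$plan$offsets_stack[j, 3]))
  }
})

test_that("offset estimation recovers known shifts within 0.1 HR voxel", {
  same <- suppressWarnings(
    estimate_offsets(list(fx$groups[[1]], fx$groups[[1]])))
  expect_equal(unname(same[2, ]), c(0, 0, 0), tolerance = 1e-6)

  est <- estimate_offsets(fx$groups)
  expect_true(all(abs(est - fx$plan$offsets_stack) < 0.1))

  set.seed(2)
  noise <- lapply(fx$groups[1:4], function(gr) {
    gr$stack <- array(abs(rnorm(length(gr$stack))), dim(gr$stack))
    gr
  })
  expect_warning(est2 <- estimate_offsets(noise), "nominal")
  expect_equal(est2[2:4, ], fx$plan$offsets_stack[2:4, ])
})

test_that("initial guess interpolates onto the HR grid and keeps flux", {
  gr <- fx$groups[[1]]
  x1 <- initial_guess(gr, c(1, 1, 1), epsilon_scale = 0)
  expect_equal(x1, unclass(gr$stack), ignore_attr = TRUE, tolerance = 1e-12)

  x <- initial_guess(gr, c(4, 4, 2))
  expect_equal(dim(x), dim(gr$stack) * c(4L, 4L, 2L))
  expect_equal(sum(x) / (4 * 4 * 2), sum(gr$stack), tolerance = 0.01)
  expect_gt(min(x), 0)
})

test_that("forward operator is linear with an exact adjoint", {
  d_hr <- c(8L, 8L, 4L)
  enh <- c(2L, 2L, 2L)
  sig <- c(0.8, 0.8, 0.6)
  off <- c(0.3, -0.2, 0.4)

  expect_true(all(forward_project(array(0, d_hr), off, sig, enh) == 0))
  # identity chain: no blur, no offset, no downsampling
  x <- array(runif(prod(d_hr)), d_hr)
  expect_equal(forward_project(x, c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)), x,
               tolerance = 1e-12)

  A <- dense_forward_matrix(d_hr, off, sig, enh)
  set.seed(1)
  for (i in 1:5) {
    xv <- runif(prod(d_hr))
    yv <- runif(nrow(A))
    lhs <- sum((A %*% xv) * yv)
    x3 <- array(xv, d_hr)
    y3 <- array(yv, d_hr %/% enh)
    rhs <- sum(xv * as.numeric(svrmvd:::back_project(y3, off, sig, enh)))
    expect_equal(lhs, rhs, tolerance = 1e-9)
    # and the dense transpose agrees with the operator adjoint
    expect_equal(as.numeric(t(A) %*% yv),
                 as.numeric(svrmvd:::back_project(y3, off, sig, enh)),
                 tolerance = 1e-9)
  }
})

test_that("the ML update matches a dense-matrix oracle per iteration", {
  d_hr <- c(8L, 8L, 4L)
  enh <- c(2L, 2L, 1L)
  sig <- c(0.7, 0.7, 0.5)
  offs <- rbind(c(0, 0, 0), c(0, 0, 0.5), c(0.25, 0, 0.25))
  set.seed(4)
  x_true <- array(rexp(prod(d_hr)), d_hr)
  As <- lapply(1:3, function(k) dense_forward_matrix(d_hr, offs[k, ], sig, enh))
  groups <- lapply(1:3, function(k) {
    structure(list(stack = array(As[[k]] %*% as.numeric(x_true),
                                 d_hr %/% enh),
                   offset_hr_voxels = offs[k, ]), class = "lr_group")
  })
  n_it <- 4L
  rec <- run_svr(groups, psf_model(sigma_to_fwhm(0.7), sigma_to_fwhm(0.5)),
                 enh, svr_config(max_iterations = n_it,
                                 rel_tolerance = 1e-12),
                 offsets = offs, hr_voxel_um = c(1, 1, 1))
  # dense oracle with the same initialization and epsilon conventions
  x <- as.numeric(initial_guess(groups[[1]], enh, 1e-6))
  tot <- sum(vapply(groups, function(g) sum(g$stack), 1))
  eps <- 1e-6 * tot / prod(d_hr)
  den <- pmax(Reduce(`+`, lapply(As, function(A) as.numeric(t(A) %*%
                                                              rep(1, nrow(A))))),
              1e-8)
  for (it in seq_len(n_it)) {
    num <- 0
    for (k in 1:3) {
      pred <- as.numeric(As[[k]] %*% x)
      num <- num + as.numeric(t(As[[k]]) %*%
                                (as.numeric(groups[[k]]$stack) /
                                   pmax(pred, eps)))
    }
    x <- x * num / den
  }
  expect_equal(as.numeric(rec$data), x, tolerance = 1e-6)
})

test_that("SVR converges, stays non-negative and conserves flux", {
  rec <- run_svr(fx$groups, fx$psf, fx$geometry$enhancement,
                 svr_config(max_iterations = 12, rel_tolerance = 1e-9))
  log <- attr(rec, "iterations")
  expect_equal(nrow(log), 12)
  expect_monotone_nonincreasing(log$kl)
  expect_true(all(rec$data >= 0))
  data_flux <- sum(vapply(fx$groups, function(g) sum(g$stack), 1))
  est_flux <- sum(rec$data) * length(fx$groups) /
    prod(fx$geometry$enhancement)
  expect_equal(est_flux, data_flux, tolerance = 0.02)

  zero <- lapply(fx$groups[1:2], function(g) {
    g$stack[] <- 0
    g
  })
  expect_warning(z <- run_svr(zero, fx$psf, c(4, 4, 2)), "all-zero")
  expect_true(all(z$data == 0))
})

test_that("single group with identity optics is an exact fixed point", {
  st <- array(rexp(6 * 6 * 4) + 0.5, c(6, 6, 4))
  gr <- structure(list(stack = st, offset_hr_voxels = c(0, 0, 0)),
                  class = "lr_group")
  rec <- run_svr(list(gr), psf_model(1e-4, 1e-4), c(1, 1, 1),
                 svr_config(max_iterations = 1, rel_tolerance = 1e-12,
                            epsilon_scale = 1e-12),
                 offsets = matrix(0, 1, 3), hr_voxel_um = c(1, 1, 1))
  expect_equal(rec$data, st, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("shear realignment recovers true shape and round-trips", {
  # untilted: realign is the identity
  v <- hr_volume(array(runif(4^3), c(4, 4, 4)), c(1, 1, 1),
                 frame = "sheared")
  r <- realign(v, scan_geometry(1000, 0, 0), frames_per_plane = 1)
  expect_identical(r$data, v$data)

  # realign(shear(V)) ~ V for a smooth volume, on the region that stays
  # inside the field under both shears (~1 lateral voxel per plane here)
  set.seed(8)
  sm <- conv_gauss(array(runif(40 * 40 * 10), c(40, 40, 10)), c(2, 2, 2))
  g <- scan_geometry(280, 10, 10)
  q <- 17 / 2
  d <- step_displacement(g) / 1000
  sx <- q * d[["dx"]] / 0.40625
  sy <- q * d[["dy"]] / 0.40625
  A <- diag(3)
  A[1, 3] <- -sx
  A[2, 3] <- -sy
  sheared <- svrmvd:::cpp_affine3(sm, dim(sm), as.numeric(t(A)), c(0, 0, 0),
                                  dim(sm))$data
  dim(sheared) <- dim(sm)
  hv <- hr_volume(sheared, c(0.40625, 0.40625, 17 / 2 * d[["dz"]]),
                  frame = "sheared")
  back <- realign(hv, g)
  core <- 13:28
  expect_gt(svrmvd:::psnr(sm[core, core, 3:8], back$data[core, core, 3:8]),
            40)

  # two beads: realignment restores the true separation
  beads <- data.frame(x = c(14, 22), y = c(20, 20), z = c(12, 28),
                      intensity = 1e5, diameter_um = 0.5)
  fx2 <- tiny_bead_scan(beads = beads)
  rec <- run_svr(fx2$groups, fx2$psf, fx2$geometry$enhancement,
                 svr_config(max_iterations = 8, rel_tolerance = 1e-4,
                            acceleration = 2))
  rec$origin_um <- c(fx2$raw$origin_xy, 0)
  rr <- realign(rec, fx2$geometry)
  find2 <- function(vol) {
    dt <- detect_features(vol, scales_um = 3, threshold = 0.3)
    as.matrix(dt[1:2, c("x", "y", "z")])
  }
  sep_true <- sqrt(sum((c(22, 20, 28) - c(14, 20, 12))^2))
  sep_post <- dist(find2(rr))[1]
  sep_pre <- dist(find2(rec))[1]
  expect_lt(abs(sep_post - sep_true), 0.41)
  expect_gt(abs(sep_pre - sep_true), abs(sep_post - sep_true))
})

test_that("SVR improves the FWHM of the raw data in every axis", {
  est <- estimate_offsets(fx$groups)
  rec <- run_svr(fx$groups, fx$psf, fx$geometry$enhancement,
                 svr_config(max_iterations = 25, rel_tolerance = 1e-4,
                            acceleration = 2), offsets = est)
  rec$origin_um <- c(fx$raw$origin_xy, 0)
  rr <- realign(rec, fx$geometry)
  lr <- hr_volume(fx$groups[[1]]$stack,
                  c(1.625, 1.625, fx$plan$lr_axial_spacing_um),
                  origin_um = c(fx$raw$origin_xy, 0), frame = "sheared")
  lrr <- realign(lr, fx$geometry, frames_per_plane = fx$plan$decimation_M)
  p <- fx$truth_realigned[1, ]
  for (ax in c("x", "y", "z")) {
    exp_raw <- if (ax == "z") 12 else 4.2
    raw_f <- measure_fwhm(lrr, p, ax, expected_fwhm_um = exp_raw * 1.2)
    svr_f <- measure_fwhm(rr, p, ax, expected_fwhm_um = exp_raw * 0.8)
    expect_lt(as.numeric(svr_f), as.numeric(raw_f))
  }
})

test_that("SVR improves SNR over the raw input on a noisy acquisition", {
  fxn <- tiny_bead_scan(noise = TRUE, seed = 5)
  est <- estimate_offsets(fxn$groups)
  rec <- run_svr(fxn$groups, fxn$psf, fxn$geometry$enhancement,
                 svr_config(max_iterations = 10, rel_tolerance = 1e-4),
                 offsets = est)
  rec$origin_um <- c(fxn$raw$origin_xy, 0)
  rr <- realign(rec, fxn$geometry)
  lr <- hr_volume(fxn$groups[[1]]$stack,
                  c(1.625, 1.625, fxn$plan$lr_axial_spacing_um),
                  origin_um = c(fxn$raw$origin_xy, 0), frame = "sheared")
  lrr <- realign(lr, fxn$geometry, frames_per_plane = fxn$plan$decimation_M)
  snr_of <- function(vol, p) {
    g <- grid3(dim(vol$data), vol$voxel_um, vol$origin_um)
    idx <- round(svrmvd:::um_to_grid(g, matrix(p, 1))) + 1
    d <- dim(vol$data)
    sig <- array(FALSE, d)
    sig[max(1, idx[1] - 1):min(d[1], idx[1] + 1),
        max(1, idx[2] - 1):min(d[2], idx[2] + 1),
        max(1, idx[3] - 1):min(d[3], idx[3] + 1)] <- TRUE
    # background away from the bead and from the realignment wedges
    bgm <- array(FALSE, d)
    bgm[1:5, (d[2] - 4):d[2], ] <- TRUE
    snr(vol, sig, bgm)
  }
  p <- fxn$truth_realigned[1, ]
  expect_gt(snr_of(rr, p), snr_of(lrr, p))
})
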