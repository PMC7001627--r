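render_beads <- function(pts, L = 48, voxel = 1, psf = psf_model(3, 3),
                         intensity = 1) {
  b <- list(lower = c(0, 0, 0), upper = rep(L, 3))
  ph <- phantom(beads = data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                   intensity = intensity,
                                   diameter_um = 0.5), bounds_um = b)
  render_volume(ph, voxel, psf = psf)
}

test_that("blob detection localizes beads to subvoxel accuracy", {
  zeros <- hr_volume(array(0, c(20, 20, 20)), c(1, 1, 1))
  expect_equal(nrow(detect_features(zeros, 3, 0.1)), 0)

  set.seed(21)
  pts <- make_bead_phantom(10, list(lower = c(0, 0, 0),
                                    upper = c(60, 60, 60)),
                           min_separation_um = 12, seed = 21,
                           margin_um = 8)$beads[, c("x", "y", "z")]
  v <- render_beads(as.matrix(pts), L = 60)
  det <- detect_features(v, scales_um = 3, threshold = 0.2)
  expect_equal(nrow(det), 10)
  for (i in seq_len(10)) {
    dd <- sqrt(rowSums(sweep(as.matrix(det[, 1:3]), 2,
                             as.numeric(pts[i, ]))^2))
    expect_lt(min(dd), 0.5)
  }
})

test_that("detection separates blobs at 3x FWHM but not at 0.3x", {
  two <- function(sep) {
    ctr <- c(24, 24, 24)
    render_beads(rbind(ctr - c(sep / 2, 0, 0), ctr + c(sep / 2, 0, 0)))
  }
  expect_equal(nrow(detect_features(two(9), scales_um = 3,
                                    threshold = 0.2)), 2)
  expect_equal(nrow(detect_features(two(0.9), scales_um = 3,
                                    threshold = 0.2)), 1)
})

test_that("detection is equivariant under integer voxel shifts", {
  set.seed(3)
  pts <- rbind(c(20, 22, 18), c(30, 14, 28))
  v <- render_beads(pts)
  det0 <- detect_features(v, 3, 0.2)
  sh <- c(3L, -2L, 4L)
  v2 <- v
  v2$data <- shift3(v$data, sh)
  det1 <- detect_features(v2, 3, 0.2)
  o0 <- order(det0$x)
  o1 <- order(det1$x)
  expect_equal(as.matrix(det1[o1, 1:3]),
               as.matrix(det0[o0, 1:3]) +
                 matrix(sh, 2, 3, byrow = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)
})

fake_features <- function(pts) {
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], scale_um = 3,
             intensity = 1)
}

test_that("constellation matching survives rotation and rejects noise", {
  set.seed(31)
  pts <- matrix(runif(36, 5, 55), ncol = 3)
  fa <- fake_features(pts)
  m_id <- match_features(fa, fa)
  expect_true(all(m_id$inlier))
  expect_lt(max(m_id$residual_um), 1e-9)

  pose <- view_pose(1, 8, c(30, 30, 30))
  perm <- sample(nrow(pts))
  fb <- fake_features(affine_apply(pose$rigid, pts)[perm, ])
  m <- match_features(fa, fb, inlier_um = 1)
  good <- mean(perm[m$index_b] == m$index_a)
  expect_gte(good, 0.9)
  expect_lt(median(m$residual_um[m$inlier]), 0.5)

  set.seed(32)
  fc <- fake_features(matrix(runif(36, 5, 55), ncol = 3))
  expect_error(match_features(fa, fc, inlier_um = 0.5), "no-consensus")
})

test_that("rigid fits recover known poses exactly and flag degeneracy", {
  set.seed(41)
  pts <- matrix(runif(24, 0, 50), ncol = 3)
  tf_true <- rotation_y(45, c(25, 25, 25))
  a <- fake_features(affine_apply(tf_true, pts))
  b <- fake_features(pts)
  cc <- data.frame(index_a = 1:8, index_b = 1:8)
  tf <- fit_affine(cc, a, b, model = "rigid")
  expect_equal(tf$linear, tf_true$linear, tolerance = 1e-9)
  expect_equal(tf$translation, tf_true$translation, tolerance = 1e-6)

  tfa <- fit_affine(cc, a, b, model = "affine")
  expect_equal(tfa$linear, tf_true$linear, tolerance = 1e-6)

  line <- fake_features(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  cl <- data.frame(index_a = 1:5, index_b = 1:5)
  expect_error(fit_affine(cl, line, line, model = "affine"), "degenerate")
})

test_that("fit residuals follow the expected noise scaling", {
  set.seed(51)
  sigma <- 0.1
  n <- 30
  rms <- replicate(8, {
    pts <- matrix(runif(3 * n, 0, 50), ncol = 3)
    tf_true <- rotation_y(30, c(25, 25, 25))
    a <- fake_features(affine_apply(tf_true, pts) +
                         matrix(rnorm(3 * n, sd = sigma), ncol = 3))
    b <- fake_features(pts)
    cc <- data.frame(index_a = 1:n, index_b = 1:n)
    tf <- fit_affine(cc, a, b, model = "rigid")
    res <- affine_apply(tf, pts) - as.matrix(a[, 1:3])
    sqrt(mean(res^2))
  })
  expect_equal(mean(rms), sigma * sqrt(1 - 6 / (3 * n)), tolerance = 0.12)
})

test_that("resampling is exact for identity and accurate under rotation", {
  v <- hr_volume(array(runif(16^3), c(16, 16, 16)), c(1, 1, 1))
  same <- resample(v, affine_identity(), grid3(c(16, 16, 16), c(1, 1, 1)))
  expect_equal(same$data, v$data, tolerance = 1e-12)
  expect_true(all(attr(same, "inside") == 1))

  set.seed(61)
  sm <- conv_gauss(array(runif(48^3), c(48, 48, 48)), c(2.5, 2.5, 2.5))
  vol <- hr_volume(sm, c(1, 1, 1))
  g <- grid3(c(48, 48, 48), c(1, 1, 1))
  ctr <- c(24, 24, 24)
  fwd <- resample(vol, rotation_y(45, ctr), g)
  back <- resample(fwd, rotation_y(-45, ctr), g)
  core <- 16:33
  expect_gt(svrmvd:::psnr(sm[core, core, core],
                          back$data[core, core, core]), 40)

  pts <- rbind(c(20, 22, 18), c(30, 14, 28))
  bv <- render_beads(pts)
  pose <- rotation_y(45, c(24, 24, 24))
  moved <- resample(bv, affine_invert(pose), g)
  det <- detect_features(moved, 3, 0.2)
  pred <- affine_apply(affine_invert(pose), pts)
  for (i in 1:2) {
    dd <- sqrt(rowSums(sweep(as.matrix(det[, 1:3]), 2, pred[i, ])^2))
    expect_lt(min(dd), 0.5)
  }
})
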