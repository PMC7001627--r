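test_that("weight masks follow the attenuation model", {
  g <- grid3(c(40, 40, 40), c(1, 1, 1))
  expect_true(all(view_weight_mask(g) == 1))
  expect_true(all(view_weight_mask(g, attenuation =
                                     attenuation_model(10)) == 1))

  att <- attenuation_model(10, floor = 0)
  thr <- exp(-2) # cutoff depth = 20 um
  w <- view_weight_mask(g, pose = view_pose(0, 1), attenuation = att,
                        threshold = thr, taper_um = 4)
  expect_equal(w[3, 20, 20], 1)
  expect_equal(w[30, 20, 20], 0)
  # the 0 -> 1 boundary sits at -l * log(threshold) within one taper width
  prof <- w[, 20, 20]
  edge <- max(which(prof > 0)) - 0.5
  expect_lt(abs(edge - 20), 4 + 1)

  # opposing views cover every voxel
  w180 <- view_weight_mask(g, pose = view_pose(4, 8, c(20, 20, 20)),
                           attenuation = att, threshold = thr,
                           taper_um = 4)
  expect_true(all(w + w180 > 0))
})

test_that("a single all-ones view reduces to the classical RL update", {
  set.seed(71)
  n <- 20
  psi <- array(rexp(n^3) + 0.1, c(n, n, n))
  phi <- conv_gauss(psi, fwhm_to_sigma(c(3, 3, 5)), 3) * 1.1
  vd <- view_data(hr_volume(phi, c(1, 1, 1)), c(3, 3, 5),
                  pose = view_pose(0, 1))
  cfg <- mvd_config(correction_clamp = Inf, normalization_floor = 0)
  got <- mvd_iterate(psi, list(vd), cfg)
  attr(got, "precomp") <- NULL
  attr(got, "kl") <- NULL

  sig <- fwhm_to_sigma(c(3, 3, 5))
  eps <- 1e-6 * max(mean(psi), 1e-12)
  pred <- conv_gauss(psi, sig, 3)
  ref <- psi * conv_gauss(phi / pmax(pred, eps), sig, 3) /
    pmax(conv_gauss(array(1, dim(psi)), sig, 3), 1e-8)
  expect_equal(got, ref, tolerance = 1e-12)

  seq_got <- mvd_iterate(psi, list(vd),
                         mvd_config(scheme = "sequential",
                                    correction_clamp = Inf,
                                    normalization_floor = 0))
  attr(seq_got, "precomp") <- NULL
  attr(seq_got, "kl") <- NULL
  expect_equal(seq_got, ref, tolerance = 1e-12)
})

test_that("fusing two orthogonal views beats the axial width everywhere", {
  fx <- mvd_fixture(c(0, 90))
  res <- run_mvd(fx$views, mvd_config(max_iterations = 50,
                                      rel_tolerance = 1e-7))
  ctr <- rep(24.5, 3)
  f <- vapply(c("x", "y", "z"), function(ax)
    as.numeric(measure_fwhm(res$estimate, ctr, ax, expected_fwhm_um = 8)),
    numeric(1))
  expect_true(all(f < 12))
  # isotropy strictly improves over any single view (12 / 4.2 = 2.86)
  iso_fused <- max(f) / min(f)
  expect_lt(iso_fused, 12 / 4.2)
})

test_that("noise-free multiview RL decreases the data fit monotonically", {
  fx <- mvd_fixture(c(0, 90, 180, 270))
  res <- run_mvd(fx$views, mvd_config(max_iterations = 25,
                                      rel_tolerance = 1e-9))
  expect_monotone_nonincreasing(res$log$kl)
  expect_true(all(res$estimate$data >= 0))
  # unweighted interior fusion conserves flux
  expect_equal(sum(res$estimate$data), sum(fx$truth), tolerance = 0.02)
})

test_that("the sequential scheme converges on the same fixture", {
  fx <- mvd_fixture(c(0, 90))
  res <- run_mvd(fx$views, mvd_config(max_iterations = 20,
                                      rel_tolerance = 1e-9,
                                      scheme = "sequential"))
  expect_true(all(res$estimate$data >= 0))
  ctr <- rep(24.5, 3)
  fz <- measure_fwhm(res$estimate, ctr, "z", expected_fwhm_um = 8)
  expect_lt(as.numeric(fz), 12)
})

test_that("zero weight everywhere at an observed voxel is a coverage error", {
  fx <- mvd_fixture(c(0, 180))
  w <- array(1, c(49, 49, 49))
  w[10, 10, 10] <- 0
  for (v in 1:2) fx$views[[v]]$weight <- w
  expect_error(run_mvd(fx$views, mvd_config(max_iterations = 2)),
               "coverage error")
  # but an explicit coverage mask can mark it as unobserved padding
  cov <- array(TRUE, c(49, 49, 49))
  cov[10, 10, 10] <- FALSE
  expect_no_error(run_mvd(fx$views, mvd_config(max_iterations = 2),
                          coverage_mask = cov))
})

test_that("masked content neither pulls nor bleaches the estimate", {
  # views disagree only inside a masked region; the fusion should follow
  # the unmasked view there
  n <- 32
  truth <- array(0, c(n, n, n))
  truth[16, 16, 16] <- 1e4
  sig <- fwhm_to_sigma(c(3, 3, 3))
  phi <- conv_gauss(truth, sig, 3)
  bad <- phi
  bad[1:16, , ] <- 0 # half the data lost in view 2
  w2 <- array(1, c(n, n, n))
  w2[1:18, , ] <- 0
  views <- list(
    view_data(hr_volume(phi, c(1, 1, 1)), c(3, 3, 3), view_pose(0, 1)),
    view_data(hr_volume(bad, c(1, 1, 1)), c(3, 3, 3), view_pose(0, 1),
              weight = w2))
  res <- run_mvd(views, mvd_config(max_iterations = 15,
                                   rel_tolerance = 1e-9))
  f <- measure_fwhm(res$estimate, c(15.5, 15.5, 15.5), "x",
                    expected_fwhm_um = 4)
  expect_lt(as.numeric(f), 3)
  expect_equal(sum(res$estimate$data), 1e4, tolerance = 0.05)
})
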