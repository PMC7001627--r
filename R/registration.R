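#' Detect point features (beads / cell bodies) in a volume
#'
#' Multi-scale difference-of-Gaussians blob detection with strict
#' 26-neighbourhood maxima, quadratic subvoxel localization, and
#' suppression of duplicates within one scale radius (the strongest
#' response wins). Scales are physical (micrometres) and are converted to
#' per-axis voxel sigmas, so anisotropic grids are handled.
#'
#' @param volume an `hr_volume`
#' @param scales_um blob diameters (FWHM) to search, micrometres
#' @param threshold minimum difference-of-Gaussians response, as a fraction
#'   of the maximum response when `relative = TRUE` (default), absolute
#'   otherwise
#' @param relative interpret `threshold` relative to the peak response
#' @param k ratio between the two Gaussian scales
#' @return data.frame with columns `x, y, z` (um, subvoxel), `scale_um`,
#'   `intensity` (peak response); zero rows when nothing is found
#' @export
detect_features <- function(volume, scales_um, threshold = 0.1,
                            relative = TRUE, k = 1.6) {
  stopifnot(length(scales_um) >= 1, threshold > 0)
  vox <- volume$voxel_um
  d <- vdim(volume$data)
  all <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    scale_um = numeric(0), intensity = numeric(0))
  for (sc in scales_um) {
    s1 <- fwhm_to_sigma(sc) / vox
    g1 <- conv_gauss(volume$data, s1)
    g2 <- conv_gauss(volume$data, s1 * k)
    dog <- g1 - g2
    thr <- if (relative) threshold * max(dog, 0) else threshold
    if (max(dog) <= 0 || thr <= 0) next
    pk <- cpp_local_maxima(dog, d, thr)
    if (ncol(pk) == 0) next
    for (j in seq_len(ncol(pk))) {
      i <- pk[, j]
      # quadratic subvoxel refinement along each axis
      off <- numeric(3)
      for (a in 1:3) {
        im <- i
        ip <- i
        im[a] <- i[a] - 1L
        ip[a] <- i[a] + 1L
        ym <- dog[im[1], im[2], im[3]]
        y0 <- dog[i[1], i[2], i[3]]
        yp <- dog[ip[1], ip[2], ip[3]]
        den <- ym - 2 * y0 + yp
        if (den < 0) off[a] <- max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
      }
      pos <- volume$origin_um + (i - 1 + 0.5 + off) * vox
      all[nrow(all) + 1L, ] <- list(pos[1], pos[2], pos[3], sc,
                                    dog[i[1], i[2], i[3]])
    }
  }
  if (!nrow(all)) return(all)
  # non-maximum suppression across and within scales
  ord <- order(-all$intensity)
  keep <- logical(nrow(all))
  pts <- as.matrix(all[, c("x", "y", "z")])
  for (j in ord) {
    if (any(keep)) {
      dd <- sqrt(rowSums(sweep(pts[keep, , drop = FALSE], 2, pts[j, ])^2))
      if (min(dd) < fwhm_to_sigma(all$scale_um[j]) * 2) next
    }
    keep[j] <- TRUE
  }
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$intensity), , drop = FALSE]
}

#' Refine feature positions by per-axis Gaussian profile fits
#'
#' Quadratic interpolation of the difference-of-Gaussians peak is accurate
#' to ~0.2 voxel; on coarse axial grids that is the registration error
#' budget. Fitting a 1-D Gaussian through each feature along each axis
#' recovers the centre to a small fraction of a voxel for blob-like
#' structures. Features whose fit fails keep their detected position.
#'
#' @param volume the `hr_volume` the features came from
#' @param features data.frame from [detect_features()]
#' @param expected_fwhm_um length-3 prior blob FWHM, used to size windows
#' @return the features with refined `x, y, z`
#' @export
refine_features <- function(volume, features, expected_fwhm_um) {
  expected_fwhm_um <- rep(expected_fwhm_um, length.out = 3)
  for (i in seq_len(nrow(features))) {
    p <- as.numeric(features[i, c("x", "y", "z")])
    for (a in 1:3) {
      ax <- c("x", "y", "z")[a]
      f <- tryCatch(
        measure_fwhm(volume, p, ax, window_um = 3 * expected_fwhm_um[a]),
        error = function(e) NULL)
      if (!is.null(f) && is.finite(attr(f, "center_um")) &&
          abs(attr(f, "center_um") - p[a]) < expected_fwhm_um[a])
        features[i, ax] <- attr(f, "center_um")
    }
  }
  features
}

# rotation/translation-invariant descriptor: sorted distances to the k
# nearest neighbours
feature_descriptors <- function(pts, k = 4) {
  n <- nrow(pts)
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(pts))
  t(vapply(seq_len(n), function(i) sort(D[i, -i])[seq_len(k)],
           numeric(k)))
}

kabsch <- function(A, B) {
  # rigid transform T with A ~ R B + t (proper rotation)
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- t(sweep(B, 2, cb)) %*% sweep(A, 2, ca)
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  affine3d(R, ca - as.numeric(R %*% cb))
}

#' Match feature constellations between two views
#'
#' Candidate correspondences come from rotation-invariant local descriptors
#' (sorted distances to the `k` nearest neighbours, nearest-descriptor with
#' a ratio test); a random-sample rigid consensus prunes them to a
#' geometrically consistent inlier set. An optional initial transform seeds
#' the consensus instead of random sampling.
#'
#' @param a,b feature data.frames from [detect_features()] (reference and
#'   moving view); each needs at least 4 features
#' @param init optional `affine3d` seeding the consensus (maps b into a)
#' @param k neighbours per descriptor
#' @param ratio nearest/second-nearest descriptor ratio test
#' @param inlier_um consensus inlier radius, micrometres
#' @param min_inlier_frac minimum inlier fraction before failing
#' @param n_draws random draws
#' @param seed RNG seed for the draws
#' @return data.frame with columns `index_a`, `index_b`, `inlier`,
#'   `residual_um`; the fitted consensus transform is attached as the
#'   `"transform"` attribute
#' @export
match_features <- function(a, b, init = NULL, k = 4, ratio = 0.8,
                           inlier_um = 2, min_inlier_frac = 0.5,
                           n_draws = 1000, seed = 1) {
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  if (nrow(pa) < 4 || nrow(pb) < 4)
    stop("match_features: need at least 4 features in each view")
  da <- feature_descriptors(pa, k)
  db <- feature_descriptors(pb, k)
  cand <- integer(nrow(pa))
  cand_d <- numeric(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    dd <- sqrt(colSums((t(db) - da[i, ])^2))
    o <- order(dd)
    if (length(o) >= 2 && dd[o[1]] > ratio * dd[o[2]]) {
      cand[i] <- NA_integer_
    } else {
      cand[i] <- o[1]
      cand_d[i] <- dd[o[1]]
    }
  }
  # one-to-one: if several reference features claim the same moving feature,
  # keep the best descriptor match
  for (j in unique(stats::na.omit(cand))) {
    hits <- which(!is.na(cand) & cand == j)
    if (length(hits) > 1)
      cand[hits[hits != hits[which.min(cand_d[hits])]]] <- NA_integer_
  }
  pairs <- cbind(which(!is.na(cand)), cand[!is.na(cand)])
  if (nrow(pairs) < 3)
    stop("no-consensus: too few descriptor candidates")
  score <- function(tf) {
    pred <- affine_apply(tf, pb[pairs[, 2], , drop = FALSE])
    sqrt(rowSums((pred - pa[pairs[, 1], , drop = FALSE])^2))
  }
  best <- NULL
  best_n <- -1L
  consider <- function(tf) {
    r <- score(tf)
    n_in <- sum(r < inlier_um)
    if (n_in > best_n) {
      best_n <<- n_in
      best <<- list(tf = tf, inl = r < inlier_um)
    }
  }
  if (!is.null(init)) consider(init)
  with_seed(seed, {
    for (dr in seq_len(n_draws)) {
      s <- sample(nrow(pairs), 3)
      if (length(unique(pairs[s, 2])) < 3) next
      tf <- tryCatch(kabsch(pa[pairs[s, 1], , drop = FALSE],
                            pb[pairs[s, 2], , drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(tf)) consider(tf)
    }
  })
  if (is.null(best) || best_n < 3 ||
      best_n / nrow(pairs) < min_inlier_frac)
    stop("no-consensus: inlier fraction below the configured minimum")
  # refit on inliers and refresh the inlier set once
  tf <- kabsch(pa[pairs[best$inl, 1], , drop = FALSE],
               pb[pairs[best$inl, 2], , drop = FALSE])
  r <- score(tf)
  out <- data.frame(index_a = pairs[, 1], index_b = pairs[, 2],
                    inlier = r < inlier_um, residual_um = r)
  if (sum(out$inlier) / nrow(out) < min_inlier_frac)
    stop("no-consensus: inlier fraction below the configured minimum")
  attr(out, "transform") <- tf
  out
}

#' Fit a rigid or affine transform from correspondences
#'
#' Least-squares transform mapping the moving features `b` onto the
#' reference features `a`. Rigid mode solves the orthogonal alignment
#' problem exactly (SVD); affine mode solves the normal equations and
#' requires non-coplanar points.
#'
#' @param correspondences data.frame with `index_a`, `index_b` and
#'   optionally `inlier` (only inliers are used)
#' @param a,b feature data.frames
#' @param model `"rigid"` or `"affine"`
#' @return an `affine3d` with `affine_apply(tf, b) ~ a`
#' @export
fit_affine <- function(correspondences, a, b,
                       model = c("rigid", "affine")) {
  model <- match.arg(model)
  cc <- correspondences
  if (!is.null(cc$inlier)) cc <- cc[cc$inlier, , drop = FALSE]
  pa <- as.matrix(a[cc$index_a, c("x", "y", "z")])
  pb <- as.matrix(b[cc$index_b, c("x", "y", "z")])
  need <- if (model == "rigid") 3 else 4
  if (nrow(pa) < need)
    stop("fit_affine: need at least ", need, " correspondences")
  ctr <- sweep(pb, 2, colMeans(pb))
  rk <- sum(svd(ctr)$d > 1e-9 * max(dim(pb)))
  if ((model == "rigid" && rk < 2) || (model == "affine" && rk < 3))
    stop("fit_affine: degenerate (rank-deficient) point configuration")
  if (model == "rigid") return(kabsch(pa, pb))
  X <- cbind(pb, 1)
  beta <- tryCatch(solve(t(X) %*% X, t(X) %*% pa),
                   error = function(e)
                     stop("fit_affine: degenerate (rank-deficient) point configuration"))
  affine3d(t(beta[1:3, ]), beta[4, ])
}
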