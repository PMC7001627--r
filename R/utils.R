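# Internal helpers shared across modules.

# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards so seeded simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

vdim <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a 3-D array")
  as.integer(d)
}

# Discrete 1-D Gaussian kernel (unit sum), sigma in voxel units. Taps are
# cell-integrated (pnorm differences) so the rendered kernel keeps its FWHM
# even at modest sampling. sigma below ~0.05 voxel collapses to a delta.
gauss_kernel1 <- function(sigma_vox, radius_sigmas = 3.5) {
  if (sigma_vox < 0.05) return(1)
  r <- max(1L, as.integer(ceiling(radius_sigmas * sigma_vox)))
  i <- (-r):r
  k <- stats::pnorm((i + 0.5) / sigma_vox) - stats::pnorm((i - 0.5) / sigma_vox)
  k / sum(k)
}

# Separable Gaussian blur with zero boundary; sigma_vox is per-axis (x, y, z)
# in voxel units. The kernel is symmetric, so the operator is self-adjoint.
conv_gauss <- function(vol, sigma_vox, radius_sigmas = 3.5) {
  d <- vdim(vol)
  out <- vol
  for (ax in 1:3) {
    k <- gauss_kernel1(sigma_vox[ax], radius_sigmas)
    if (length(k) > 1L) out <- cpp_conv_axis(out, d, k, ax - 1L)
  }
  dim(out) <- d
  out
}

# Trilinear subvoxel shift, zero boundary: out(p) = in(p - shift_vox).
shift3 <- function(vol, shift_vox) {
  d <- vdim(vol)
  out <- cpp_shift3(vol, d, as.numeric(shift_vox))
  dim(out) <- d
  out
}

block_down <- function(vol, f) {
  d <- vdim(vol)
  f <- as.integer(f)
  stopifnot(all(d %% f == 0L))
  out <- cpp_block_down(vol, d, f)
  dim(out) <- d %/% f
  out
}

block_up <- function(vol, f) {
  d <- vdim(vol)
  f <- as.integer(f)
  out <- cpp_block_up(vol, d, f)
  dim(out) <- d * f
  out
}

# Peak signal-to-noise ratio in dB between two equally shaped arrays.
psnr <- function(x, y) {
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(x)^2 / mse)
}

# Kullback-Leibler data-fit divergence KL(y || p) = sum y log(y/p) - y + p,
# with the y = 0 terms contributing p.
kl_divergence <- function(y, p, eps = 1e-12) {
  p <- pmax(p, eps)
  pos <- y > 0
  sum(y[pos] * log(y[pos] / p[pos])) - sum(y) + sum(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
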