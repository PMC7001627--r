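#' Sampling grid of a volume
#'
#' Axis order is (x, y, z) with x varying fastest in storage; voxel `i`
#' (0-based) is centred at `origin_um + (i + 0.5) * voxel_um`.
#'
#' @param dim integer triple (nx, ny, nz)
#' @param voxel_um voxel size per axis, micrometres
#' @param origin_um physical position of the low corner of voxel (0,0,0)
#' @return a `grid3` object
#' @export
grid3 <- function(dim, voxel_um, origin_um = c(0, 0, 0)) {
  structure(list(dim = as.integer(dim), voxel_um = as.numeric(voxel_um),
                 origin_um = as.numeric(origin_um)), class = "grid3")
}

# physical coordinates (um) of 0-based voxel indices (n x 3)
grid_to_um <- function(grid, idx) {
  sweep(sweep(idx + 0.5, 2, grid$voxel_um, "*"), 2, grid$origin_um, "+")
}

# 0-based voxel coordinates of physical points (n x 3)
um_to_grid <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin_um, "-"), 2, grid$voxel_um, "/") - 0.5
}

grid_center_um <- function(grid) grid$origin_um + grid$dim * grid$voxel_um / 2

#' Intensity volume with physical voxel size
#'
#' @param data 3-D numeric array, dim (nx, ny, nz), x fastest
#' @param voxel_um voxel size per axis in micrometres
#' @param origin_um physical position of the volume's low corner
#' @param frame `"sample"` for Cartesian sample coordinates or `"sheared"`
#'   for the tilted scan frame (frame index as axial coordinate)
#' @return an `hr_volume`
#' @export
hr_volume <- function(data, voxel_um, origin_um = c(0, 0, 0),
                      frame = "sample") {
  stopifnot(length(dim(data)) == 3, length(voxel_um) == 3,
            all(voxel_um > 0))
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 origin_um = as.numeric(origin_um), frame = frame),
            class = "hr_volume")
}

#' @export
print.hr_volume <- function(x, ...) {
  cat(sprintf("hr_volume %s, voxel %s um, frame '%s', range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_um, 4), collapse = "x"),
              x$frame, min(x$data), max(x$data)))
  invisible(x)
}

vol_grid <- function(vol) grid3(dim(vol$data), vol$voxel_um, vol$origin_um)

# Total flux = sum(data) * voxel volume (um^3).
vol_flux <- function(vol) sum(vol$data) * prod(vol$voxel_um)

#' Resample a volume onto a target grid under an affine transform
#'
#' Pull-back trilinear interpolation: the output voxel at physical position
#' `p` (in the reference frame) takes the value of the input volume at
#' `transform^-1(p)`. Voxels whose source point falls outside the input
#' volume are zero and flagged in the `"inside"` attribute.
#'
#' @param volume an `hr_volume` (the moving volume)
#' @param transform `affine3d` mapping moving-volume coordinates (um) into
#'   the reference frame; use [affine_identity()] for plain regridding
#' @param target_grid a [grid3()] describing the output sampling
#' @return an `hr_volume` on the target grid with an `"inside"` mask attribute
#' @export
resample <- function(volume, transform, target_grid) {
  src <- vol_grid(volume)
  inv <- affine_invert(transform)
  # voxel-coordinate map: p_src_vox = A p_tgt_vox + t
  Sv <- diag(1 / src$voxel_um)
  Tv <- diag(target_grid$voxel_um)
  A <- Sv %*% inv$linear %*% Tv
  t0 <- as.numeric(
    Sv %*% (inv$linear %*% (target_grid$origin_um +
                              0.5 * target_grid$voxel_um) +
              inv$translation - src$origin_um)) - 0.5
  res <- cpp_affine3(volume$data, vdim(volume$data),
                     as.numeric(t(A)), t0, as.integer(target_grid$dim))
  out <- res$data
  dim(out) <- target_grid$dim
  msk <- res$inside
  dim(msk) <- target_grid$dim
  src_mask <- attr(volume, "inside")
  if (!is.null(src_mask)) {
    # carry the source's own validity through the resampling
    res_m <- cpp_affine3(as.numeric(src_mask), vdim(volume$data),
                         as.numeric(t(A)), t0, as.integer(target_grid$dim))
    msk <- msk * as.integer(res_m$data > 0.999)
    dim(msk) <- target_grid$dim
  }
  v <- hr_volume(out, target_grid$voxel_um, target_grid$origin_um,
                 frame = volume$frame)
  attr(v, "inside") <- msk
  v
}
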