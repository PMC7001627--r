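#' Tilted continuous-scan geometry
#'
#' Encodes the non-axial scan: the stage translates the sample along a unit
#' direction obtained by tilting the detection axis z first about the
#' horizontal lateral axis (x) by `tilt_first_deg`, then about the vertical
#' axis (y) by `tilt_second_deg`. With a per-frame step much smaller than
#' the light-sheet thickness, consecutive frames carry sub-voxel lateral and
#' axial offsets that the subvoxel-resolving reconstruction exploits.
#'
#' @param step_nm stage step per frame along the scan direction, nanometres
#' @param tilt_first_deg tilt about the horizontal lateral axis, degrees,
#'   in `[0, 90)`
#' @param tilt_second_deg tilt about the vertical axis, degrees, in `[0, 90)`
#' @param n_frames number of frames in one scan
#' @param lr_voxel_um native low-resolution voxel size `(vx, vy, vz)` in
#'   micrometres; `vz` is the target axial spacing of the decimated groups
#' @param enhancement integer resolution-enhancement factors `(rx, ry, rz)`
#' @return a `scan_geometry` object
#' @export
scan_geometry <- function(step_nm, tilt_first_deg = 0, tilt_second_deg = 0,
                          n_frames = 1L, lr_voxel_um = c(1.625, 1.625, 4.5),
                          enhancement = c(4L, 4L, 2L)) {
  if (step_nm <= 0) stop("invalid-geometry: step_nm must be > 0")
  if (tilt_first_deg < 0 || tilt_first_deg >= 90 ||
      tilt_second_deg < 0 || tilt_second_deg >= 90)
    stop("invalid-geometry: tilt angles must lie in [0, 90)")
  if (any(lr_voxel_um <= 0)) stop("invalid-geometry: voxel sizes must be > 0")
  enhancement <- as.integer(enhancement)
  if (any(enhancement < 1L)) stop("invalid-geometry: enhancement must be >= 1")
  structure(list(step_nm = step_nm, tilt_first_deg = tilt_first_deg,
                 tilt_second_deg = tilt_second_deg,
                 n_frames = as.integer(n_frames),
                 lr_voxel_um = as.numeric(lr_voxel_um),
                 enhancement = enhancement),
            class = "scan_geometry")
}

#' Per-frame displacement of the tilted scan
#'
#' The scan direction is `Ry(tilt_second) Rx(tilt_first) z_hat`; the
#' displacement is that unit vector times the step. Components are in the
#' detection frame: x, y lateral and z axial.
#'
#' @param geometry a [scan_geometry()]
#' @return named numeric `(dx, dy, dz)` in nanometres, with
#'   `sqrt(dx^2+dy^2+dz^2) == step_nm`
#' @export
step_displacement <- function(geometry) {
  t1 <- geometry$tilt_first_deg * pi / 180
  t2 <- geometry$tilt_second_deg * pi / 180
  u <- c(sin(t2) * cos(t1), -sin(t1), cos(t2) * cos(t1))
  d <- geometry$step_nm * u
  names(d) <- c("dx", "dy", "dz")
  d
}

#' Decimation plan: low-resolution groups and their subvoxel offsets
#'
#' Every `M`-th frame (fixed phase `j`) forms one low-resolution stack whose
#' axial spacing matches the system optics; the `G` phases are mutually
#' shifted by the per-frame displacement. Offsets are reported in
#' high-resolution voxel units (HR voxel = `lr_voxel_um / enhancement`).
#'
#' `offsets` is the full per-step displacement `j * d` per the nominal
#' geometry. `offsets_stack` is the offset actually seen between decimated
#' stacks in the sheared scan frame, where the lateral component of `j * d`
#' is absorbed by the shear and only the axial part `j * rz / M` remains;
#' the SVR forward model and offset estimation use `offsets_stack`.
#'
#' @param geometry a [scan_geometry()]
#' @param target_axial_spacing_um desired axial spacing of the decimated
#'   stacks (defaults to `lr_voxel_um[3]`)
#' @param n_periods number of axial decimation periods to span (G =
#'   `n_periods * M` groups); more than one period reuses phases with larger
#'   axial baselines
#' @return a `grouping_plan` with fields `decimation_M`, `n_groups_G`,
#'   `offsets`, `offsets_stack` (G x 3 matrices, HR voxels),
#'   `lr_axial_spacing_um`, `hr_voxel_um`
#' @export
grouping_plan <- function(geometry,
                          target_axial_spacing_um = geometry$lr_voxel_um[3],
                          n_periods = 1L) {
  d <- step_displacement(geometry)
  dz_nm <- d["dz"]
  if (target_axial_spacing_um * 1000 < dz_nm)
    stop("grouping_plan: target axial spacing is below one scan step")
  M <- max(1L, as.integer(round(target_axial_spacing_um * 1000 / dz_nm)))
  rz <- geometry$enhancement[3]
  if (M < max(rz, 1L))
    stop(sprintf(
      "insufficient-oversampling: M = %d cannot support axial enhancement %d",
      M, rz))
  G <- M * as.integer(n_periods)
  hr_voxel <- geometry$lr_voxel_um / geometry$enhancement
  j <- 0:(G - 1)
  offsets <- outer(j, d / 1000) / rep(hr_voxel, each = G)
  offsets_stack <- cbind(0, 0, j * rz / M)
  colnames(offsets) <- colnames(offsets_stack) <- c("x", "y", "z")
  structure(list(decimation_M = M, n_groups_G = G,
                 offsets = offsets, offsets_stack = offsets_stack,
                 lr_axial_spacing_um = as.numeric(M * dz_nm / 1000),
                 hr_voxel_um = hr_voxel,
                 geometry = geometry),
            class = "grouping_plan")
}

#' Shear between the tilted scan frame and Cartesian sample coordinates
#'
#' In the scan frame the frame index is treated as the axial coordinate;
#' advancing one frame displaces the sample laterally by `(dx, dy)`. The
#' returned transform maps scan-frame voxel coordinates
#' `(x_vox, y_vox, w_frames)` to sample-aligned coordinates by adding the
#' accumulated lateral drift `w * (dx, dy) / h_lat` (in lateral HR voxels
#' per frame). An untilted geometry yields the identity.
#'
#' @param geometry a [scan_geometry()]
#' @param hr_lateral_voxel_um lateral high-resolution voxel size; defaults
#'   to `lr_voxel_um[1:2] / enhancement[1:2]`
#' @return an `affine3d` acting on (x, y, w) voxel/frame coordinates
#' @export
shear_matrix <- function(geometry,
                         hr_lateral_voxel_um =
                           geometry$lr_voxel_um[1:2] / geometry$enhancement[1:2]) {
  d <- step_displacement(geometry) / 1000
  L <- diag(3)
  L[1, 3] <- d[["dx"]] / hr_lateral_voxel_um[1]
  L[2, 3] <- d[["dy"]] / hr_lateral_voxel_um[2]
  affine3d(L, c(0, 0, 0))
}

#' Rigid pose of one acquisition view
#'
#' View `i` of `n` images the sample rotated by `i * 360 / n` degrees about
#' the vertical (y) axis through `center_um`.
#'
#' @param view_index 0-based view index in `[0, n_views)`
#' @param n_views number of views (>= 1)
#' @param center_um rotation centre, micrometres
#' @return a `view_pose` with fields `view_index`, `angle_deg`, `rigid`
#'   (an [affine3d()]), `center_um`
#' @export
view_pose <- function(view_index, n_views, center_um = c(0, 0, 0)) {
  if (n_views < 1) stop("view_pose: n_views must be >= 1")
  if (view_index < 0 || view_index >= n_views)
    stop("view_pose: view_index out of range")
  ang <- view_index * 360 / n_views
  structure(list(view_index = as.integer(view_index), angle_deg = ang,
                 rigid = rotation_y(ang, center_um),
                 center_um = as.numeric(center_um)),
            class = "view_pose")
}

#' Serialize scan geometry to JSON
#' @param geometry a [scan_geometry()]
#' @param path optional output file
#' @return JSON string
#' @export
geometry_to_json <- function(geometry, path = NULL) {
  js <- jsonlite::toJSON(unclass(geometry), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  js
}

#' Read scan geometry from JSON
#' @param x JSON string or file path
#' @return a [scan_geometry()]
#' @export
geometry_from_json <- function(x) {
  o <- jsonlite::fromJSON(x)
  scan_geometry(o$step_nm, o$tilt_first_deg, o$tilt_second_deg,
                o$n_frames, o$lr_voxel_um, o$enhancement)
}

#' High-resolution voxel size from the native voxel and enhancement
#'
#' @param lr_voxel_um native voxel size (scalar or triple), micrometres
#' @param enhancement integer enhancement factor (scalar or triple)
#' @param digits rounding used for reporting (summaries print e.g. 0.41)
#' @return `lr_voxel_um / enhancement`, rounded to `digits` when given
#' @export
hr_voxel_um <- function(lr_voxel_um, enhancement, digits = NULL) {
  v <- lr_voxel_um / enhancement
  if (!is.null(digits)) v <- round(v, digits)
  v
}
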