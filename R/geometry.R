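#' Circular cone-beam acquisition geometry
#'
#' Describes a flat-panel circular cone-beam scan: source-axis and
#' source-detector distances, the detector grid, a detector offset
#' (non-zero row offset realizes the half-cone / offset-detector layout),
#' and the ordered view angles.
#'
#' Coordinates are right-handed with the isocenter at the origin; the
#' source rotates counter-clockwise viewed from +z and all positions are
#' in mm. At view angle b the source sits at `sad*(cos b, sin b, 0)`.
#'
#' @param source_axis_dist_mm distance source to rotation axis (SAD).
#' @param source_detector_dist_mm distance source to detector (SDD), must
#'   exceed SAD.
#' @param det_rows,det_cols detector pixel counts (rows are axial).
#' @param det_pitch_mm detector pixel size (isotropic).
#' @param det_offset_mm length-2 vector `(row, col)` offset of the
#'   detector center from the central ray, in mm at the detector.
#' @param angles_deg ordered view angles in degrees.
#' @return An object of class `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(source_axis_dist_mm, source_detector_dist_mm,
                               det_rows, det_cols, det_pitch_mm,
                               det_offset_mm = c(0, 0), angles_deg) {
  if (!(source_detector_dist_mm > source_axis_dist_mm &&
        source_axis_dist_mm > 0))
    stop("require source_detector_dist > source_axis_dist > 0")
  stopifnot(det_rows >= 1, det_cols >= 1, det_pitch_mm > 0,
            length(det_offset_mm) == 2, length(angles_deg) >= 1)
  structure(list(sad = source_axis_dist_mm, sdd = source_detector_dist_mm,
                 det_rows = as.integer(det_rows),
                 det_cols = as.integer(det_cols),
                 det_pitch_mm = det_pitch_mm,
                 det_offset_mm = as.numeric(det_offset_mm),
                 angles_deg = as.numeric(angles_deg)),
            class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf(
    "<cone_beam_geometry> SAD %.0f / SDD %.0f mm, %dx%d px @ %.3f mm, %d views over %.1f deg\n",
    x$sad, x$sdd, x$det_rows, x$det_cols, x$det_pitch_mm,
    length(x$angles_deg), angular_span_deg(x)))
  invisible(x)
}

#' @rdname cone_beam_geometry
#' @param geom a `cone_beam_geometry`.
#' @export
angular_span_deg <- function(geom) {
  a <- geom$angles_deg
  if (length(a) < 2) return(0)
  diff(range(a)) + abs(a[2] - a[1])  # span including one step closure
}

# signed detector column / row center coordinates (mm, including offset)
det_u_coords <- function(geom) {
  (seq_len(geom$det_cols) - 1 - 0.5 * (geom$det_cols - 1)) * geom$det_pitch_mm +
    geom$det_offset_mm[2]
}
det_v_coords <- function(geom) {
  (seq_len(geom$det_rows) - 1 - 0.5 * (geom$det_rows - 1)) * geom$det_pitch_mm +
    geom$det_offset_mm[1]
}

#' Full fan angle of the detector (degrees)
#' @param geom a [cone_beam_geometry()].
#' @export
fan_angle_deg <- function(geom) {
  u <- det_u_coords(geom) * geom$sad / geom$sdd
  2 * max(abs(atan(u / geom$sad))) * 180 / pi
}

#' Isotropic voxel grid
#'
#' @param nx,ny,nz voxel counts.
#' @param voxel_mm isotropic voxel size (mm).
#' @param origin_mm position of the center of voxel (1,1,1); default
#'   centers the grid on the isocenter.
#' @export
voxel_grid <- function(nx, ny = nx, nz = nx, voxel_mm, origin_mm = NULL) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, voxel_mm > 0)
  if (is.null(origin_mm))
    origin_mm <- -voxel_mm * (c(nx, ny, nz) - 1) / 2
  stopifnot(length(origin_mm) == 3)
  structure(list(n = as.integer(c(nx, ny, nz)), voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %dx%dx%d @ %.3f mm\n", x$n[1], x$n[2], x$n[3],
              x$voxel_mm))
  invisible(x)
}

# voxel center coordinates along one axis (1 = x, 2 = y, 3 = z)
voxel_centers <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$n[axis]) - 1) * grid$voxel_mm
}

#' Projection stack
#'
#' A set of per-view 2-D detector arrays with an explicit domain tag:
#' `"intensity"` (flood-normalized, in (0, 1]) or `"line_integral"`
#' (values of -log I, non-negative up to noise).
#'
#' @param values array of dim `(det_rows, det_cols, n_views)`.
#' @param domain `"intensity"` or `"line_integral"`.
#' @param geometry the [cone_beam_geometry()] the stack was acquired with.
#' @export
projection_stack <- function(values, domain = c("line_integral", "intensity"),
                             geometry) {
  domain <- match.arg(domain)
  stopifnot(inherits(geometry, "cone_beam_geometry"))
  d <- dim(values)
  if (is.null(d) || length(d) != 3)
    stop("projection values must be a 3-D array (rows, cols, views)")
  if (d[1] != geometry$det_rows || d[2] != geometry$det_cols ||
      d[3] != length(geometry$angles_deg))
    stop("projection array dimensions do not match the geometry")
  structure(list(values = values, domain = domain, geometry = geometry),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> %dx%dx%d [%s], range [%.4g, %.4g]\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$domain, min(x$values), max(x$values)))
  invisible(x)
}

#' Convert a projection stack between intensity and line-integral domain
#'
#' @param ps a [projection_stack()].
#' @param min_intensity intensities are clamped to this floor before the
#'   log to guard against zero-count pixels.
#' @export
as_line_integrals <- function(ps, min_intensity = 1e-9) {
  stopifnot(inherits(ps, "projection_stack"))
  if (ps$domain == "line_integral") return(ps)
  projection_stack(-log(pmax(ps$values, min_intensity)), "line_integral",
                   ps$geometry)
}

#' @rdname as_line_integrals
#' @export
as_intensity <- function(ps) {
  stopifnot(inherits(ps, "projection_stack"))
  if (ps$domain == "intensity") return(ps)
  projection_stack(exp(-ps$values), "intensity", ps$geometry)
}

#' Volume image
#'
#' A 3-D image over a [voxel_grid()], tagged with its unit: linear
#' attenuation (`"mm^-1"`), Hounsfield units (`"HU"`), energy (`"keV"`),
#' or dimensionless.
#'
#' @param values array matching the grid dimensions.
#' @param grid a [voxel_grid()].
#' @param unit unit tag.
#' @export
volume_image <- function(values, grid, unit = "mm^-1") {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(values)
  if (is.null(d) || length(d) != 3 || any(d != grid$n))
    stop("volume dimensions do not match the grid")
  if (any(!is.finite(values))) stop("volume contains non-finite values")
  structure(list(values = values, grid = grid, unit = unit),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %dx%dx%d @ %.3f mm [%s], range [%.4g, %.4g]\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3], x$grid$voxel_mm,
              x$unit, min(x$values), max(x$values)))
  invisible(x)
}
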