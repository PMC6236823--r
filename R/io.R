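#' Read and write projection stacks
#'
#' Projection stacks are stored as a 3-D NIfTI array (rows, cols, views;
#' double precision, bit-exact round trip) with a YAML sidecar
#' (`<path>.yaml`) carrying the acquisition geometry and the domain tag.
#'
#' @param ps a [projection_stack()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_projections <- function(ps, path) {
  stopifnot(inherits(ps, "projection_stack"))
  RNifti::writeNifti(RNifti::asNifti(ps$values, datatype = "double"), path)
  g <- ps$geometry
  yaml::write_yaml(list(
    domain = ps$domain,
    geometry = list(source_axis_dist_mm = g$sad,
                    source_detector_dist_mm = g$sdd,
                    det_rows = g$det_rows, det_cols = g$det_cols,
                    det_pitch_mm = g$det_pitch_mm,
                    det_offset_mm = g$det_offset_mm,
                    angles_deg = g$angles_deg)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_projections
#' @param path input path written by [write_projections()].
#' @export
read_projections <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("missing geometry sidecar: ", side)
  meta <- yaml::read_yaml(side)
  g <- meta$geometry
  for (f in c("source_axis_dist_mm", "source_detector_dist_mm", "det_rows",
              "det_cols", "det_pitch_mm", "det_offset_mm", "angles_deg"))
    if (is.null(g[[f]]))
      stop("geometry sidecar lacks required attribute '", f, "': ", side)
  geom <- cone_beam_geometry(g$source_axis_dist_mm, g$source_detector_dist_mm,
                             g$det_rows, g$det_cols, g$det_pitch_mm,
                             unlist(g$det_offset_mm), unlist(g$angles_deg))
  vals <- array(as.numeric(RNifti::readNifti(path)),
                c(geom$det_rows, geom$det_cols, length(geom$angles_deg)))
  projection_stack(vals, meta$domain, geom)
}

#' Read and write volume images
#'
#' Volumes are stored as NIfTI with the voxel size in the header and the
#' grid origin in a small YAML sidecar (NIfTI stores orientation, but the
#' package keeps its own isotropic-grid convention).
#'
#' @param vol a [volume_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  RNifti::writeNifti(RNifti::asNifti(vol$values, datatype = "double"), path)
  yaml::write_yaml(list(unit = vol$unit, voxel_mm = vol$grid$voxel_mm,
                        origin_mm = vol$grid$origin_mm),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("missing volume sidecar: ", side)
  meta <- yaml::read_yaml(side)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  grid <- voxel_grid(d[1], d[2], d[3], voxel_mm = meta$voxel_mm,
                     origin_mm = unlist(meta$origin_mm))
  volume_image(array(as.numeric(img), d), grid, unit = meta$unit)
}

#' Read a bowtie profile from a two-column text file
#'
#' Columns: detector column index (1-based) or u-coordinate, and filter
#' path (mm). Only the second column is used; one row per detector
#' column.
#'
#' @param path file path.
#' @param det_cols expected number of columns.
#' @export
read_bowtie <- function(path, det_cols) {
  tab <- utils::read.table(path, comment.char = "#")
  prof <- tab[[ncol(tab)]]
  if (length(prof) != det_cols)
    stop(sprintf("bowtie file has %d rows but the detector has %d columns",
                 length(prof), det_cols))
  as.numeric(prof)
}

#' Write a metrics report as JSON
#'
#' @param report list, e.g. from [catphan_report()].
#' @param path output path.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
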