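#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`.
#'
#' @param volume a [volume_image()] in mm^-1 (or a plain numeric).
#' @param mu_water_ref water reference attenuation (mm^-1), typically
#'   [effective_mu()] of water under the acquisition spectrum.
#' @export
to_hu <- function(volume, mu_water_ref) {
  if (!(is.numeric(mu_water_ref) && mu_water_ref > 0))
    stop("mu_water_ref must be positive")
  if (inherits(volume, "volume_image"))
    return(volume_image(1000 * (volume$values - mu_water_ref) / mu_water_ref,
                        volume$grid, unit = "HU"))
  1000 * (volume - mu_water_ref) / mu_water_ref
}

#' Region of interest specification
#'
#' A cylindrical (circle x slice-range) ROI in volume coordinates.
#'
#' @param center_mm length-2 (x, y) center.
#' @param radius_mm circle radius.
#' @param z_range_mm length-2 axial extent.
#' @export
roi_spec <- function(center_mm, radius_mm, z_range_mm) {
  stopifnot(length(center_mm) == 2, radius_mm > 0, length(z_range_mm) == 2)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 z_range_mm = sort(as.numeric(z_range_mm))),
            class = "roi_spec")
}

# logical array selecting the ROI voxels
roi_mask <- function(grid, roi) {
  g <- grid_fields(grid)
  (g$x - roi$center_mm[1])^2 + (g$y - roi$center_mm[2])^2 <= roi$radius_mm^2 &
    g$z >= roi$z_range_mm[1] & g$z <= roi$z_range_mm[2]
}

#' ROI statistics
#' @param volume a [volume_image()].
#' @param roi a [roi_spec()].
#' @return list with `mean`, `sd`, `n`.
#' @export
roi_stats <- function(volume, roi) {
  sel <- volume$values[roi_mask(volume$grid, roi)]
  if (length(sel) == 0) stop("ROI contains no voxels")
  list(mean = mean(sel), sd = stats::sd(sel), n = length(sel))
}

#' Contrast-to-noise ratio
#'
#' `(mean_signal - mean_background) / sd_background`; the denominator is
#' the background standard deviation only.
#'
#' @param volume a [volume_image()].
#' @param roi_signal,roi_background non-overlapping [roi_spec()]s with at
#'   least 20 voxels each.
#' @export
cnr <- function(volume, roi_signal, roi_background) {
  s <- roi_stats(volume, roi_signal)
  b <- roi_stats(volume, roi_background)
  if (s$n < 20 || b$n < 20)
    stop("ROIs must contain at least 20 voxels each")
  if (b$sd == 0) stop("background ROI has zero standard deviation")
  (s$mean - b$mean) / b$sd
}

#' CT-number linearity regression
#'
#' Ordinary least squares of measured insert CT numbers on the true
#' values.
#'
#' @param measured_hu,true_hu paired per-insert values (>= 3 inserts).
#' @return list with `slope`, `intercept`, `r`.
#' @export
linearity_slope <- function(measured_hu, true_hu) {
  if (length(measured_hu) != length(true_hu))
    stop("measured and true vectors differ in length")
  if (length(true_hu) < 3) stop("need at least 3 inserts")
  if (stats::sd(true_hu) == 0) stop("true values are constant")
  fit <- stats::lm(measured_hu ~ true_hu)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(measured_hu, true_hu))
}

#' Mean absolute CT-number error
#'
#' @inheritParams linearity_slope
#' @return Mean of `|measured - true|` in HU.
#' @export
mean_abs_ct_error <- function(measured_hu, true_hu) {
  if (length(measured_hu) != length(true_hu))
    stop("measured and true vectors differ in length")
  mean(abs(measured_hu - true_hu))
}

#' Insert ROIs of a sensitometry phantom
#'
#' Builds the standard measurement ROIs from a phantom's insert table:
#' per-insert circles of 3/4 the rod radius over the central slices, and
#' a background ROI of the same area in the uniform (water) region on the
#' insert circle, rotated halfway between two inserts.
#'
#' @param phantom a [labeled_phantom()] with an `inserts` field.
#' @param insert optional insert name; if given, returns
#'   `list(signal, background)` for that insert, else a named list of all
#'   insert ROIs plus `$background`.
#' @param z_margin_mm axial margin excluded at both phantom ends.
#' @export
catphan_rois <- function(phantom, insert = NULL, z_margin_mm = 8) {
  ins <- phantom$inserts
  if (is.null(ins)) stop("phantom has no insert table")
  zr <- c(-1, 1) * (ins$half_length_mm[1] - z_margin_mm)
  mk <- function(i) roi_spec(c(ins$x_mm[i], ins$y_mm[i]),
                             0.75 * ins$radius_mm[i], zr)
  rois <- lapply(seq_len(nrow(ins)), mk)
  names(rois) <- ins$name
  # background between the last and first insert on the same circle
  ang <- atan2(ins$y_mm, ins$x_mm)
  gap <- ang[1] + (2 * pi / nrow(ins)) / 2
  rc <- sqrt(ins$x_mm[1]^2 + ins$y_mm[1]^2)
  bg <- roi_spec(rc * c(cos(gap), sin(gap)), 0.75 * ins$radius_mm[1], zr)
  if (!is.null(insert)) {
    if (!insert %in% names(rois)) stop("unknown insert: ", insert)
    return(list(signal = rois[[insert]], background = bg))
  }
  c(rois, list(background = bg))
}

# measured vs true HU per insert (shared by calibration and reports)
insert_means <- function(recon, phantom, spectrum) {
  mu_w <- effective_mu(cbct_material("water"), spectrum)
  hu <- to_hu(recon, mu_w)
  rois <- catphan_rois(phantom)
  ins <- phantom$inserts
  measured <- vapply(ins$name, function(nm) roi_stats(hu, rois[[nm]])$mean,
                     numeric(1))
  true_mu <- vapply(ins$label, function(l)
    effective_mu(phantom$material_of_label[[as.character(l)]], spectrum),
    numeric(1))
  data.frame(name = ins$name, measured_hu = unname(measured),
             true_hu = to_hu(true_mu, mu_w))
}

#' Sensitometry report: per-insert CT numbers, linearity, accuracy
#'
#' Measures each insert's mean CT number against the spectrum-weighted
#' truth and summarizes linearity slope, intercept, correlation and mean
#' absolute CT-number error. True CT numbers use the spectrum-weighted
#' attenuation of each insert material referenced to water under the same
#' spectrum; the reference is recorded in the output.
#'
#' @param recon reconstructed [volume_image()] (mm^-1).
#' @param phantom the sensitometry [labeled_phantom()].
#' @param spectrum the acquisition [energy_spectrum()].
#' @return list with `inserts` (data frame), `slope`, `intercept`, `r`,
#'   `mae_hu`, `mu_water_ref`.
#' @export
catphan_report <- function(recon, phantom, spectrum) {
  tab <- insert_means(recon, phantom, spectrum)
  fit <- linearity_slope(tab$measured_hu, tab$true_hu)
  list(inserts = tab, slope = fit$slope, intercept = fit$intercept,
       r = fit$r, mae_hu = mean_abs_ct_error(tab$measured_hu, tab$true_hu),
       mu_water_ref = effective_mu(cbct_material("water"), spectrum))
}
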