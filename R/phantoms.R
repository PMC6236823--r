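#' Labeled digital phantom
#'
#' An integer label volume plus a label-to-material mapping. Label 0 is
#' always the air background; every other label present in the volume must
#' have a material.
#'
#' @param labels integer array over `grid`.
#' @param material_of_label named list of [material_table()]s; names are
#'   the label integers (as character), and must include `"0"` (air).
#' @param grid a [voxel_grid()].
#' @param inserts optional data frame describing rod inserts
#'   (name, x_mm, y_mm, radius_mm, half_length_mm) used to derive ROIs.
#' @export
labeled_phantom <- function(labels, material_of_label, grid, inserts = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(labels), as.integer(grid$n)))
    stop("label array does not match the grid")
  present <- sort(unique(as.integer(labels)))
  missing <- setdiff(as.character(present), names(material_of_label))
  if (length(missing))
    stop("labels without a material: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, material_of_label = material_of_label,
                 grid = grid, inserts = inserts),
            class = "labeled_phantom")
}

#' @export
print.labeled_phantom <- function(x, ...) {
  cat(sprintf("<labeled_phantom> %dx%dx%d, %d labels\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3],
              length(unique(as.integer(x$labels)))))
  invisible(x)
}

# helper: squared in-plane radius field and coordinate fields of a grid
grid_fields <- function(grid) {
  x <- voxel_centers(grid, 1); y <- voxel_centers(grid, 2)
  z <- voxel_centers(grid, 3)
  list(x = array(rep(x, times = grid$n[2] * grid$n[3]), grid$n),
       y = array(rep(rep(y, each = grid$n[1]), times = grid$n[3]), grid$n),
       z = array(rep(z, each = grid$n[1] * grid$n[2]), grid$n))
}

#' Digital sensitometry phantom
#'
#' A digital twin of a sensitometry image-quality module: a cylindrical
#' acrylic shell with water-equivalent interior, seven 12.2 mm rod inserts
#' (air, PMP, LDPE, polystyrene, acrylic, Delrin, Teflon) on a 58.4 mm
#' radius circle, and three small acrylic spheres on an inner circle.
#' Insert positions and diameters are conventional fixture constants.
#'
#' @param grid a [voxel_grid()]; must accommodate the body diameter.
#' @param body_diameter_mm outer diameter of the phantom body.
#' @param shell_mm acrylic shell thickness.
#' @param length_mm axial length of the phantom; the default (`NULL`)
#'   spans the whole grid, emulating a phantom body that continues beyond
#'   the imaged field of view (as the physical multi-module phantom
#'   does), so no end face falls inside the scan.
#' @param insert_circle_radius_mm radius of the insert circle.
#' @param insert_diameter_mm insert rod diameter.
#' @return A [labeled_phantom()] whose `inserts` field tabulates the rod
#'   centers and radii.
#' @export
make_catphan_sensitometry <- function(grid, body_diameter_mm = 150,
                                      shell_mm = 8, length_mm = NULL,
                                      insert_circle_radius_mm = 58.4,
                                      insert_diameter_mm = 12.2) {
  ext <- (grid$n[1:2] - 1) * grid$voxel_mm
  if (any(ext < body_diameter_mm))
    stop(sprintf("grid (%.0f mm) too small for a %.0f mm phantom",
                 min(ext), body_diameter_mm))
  if (is.null(length_mm)) length_mm <- grid$n[3] * grid$voxel_mm + 2
  g <- grid_fields(grid)
  r2 <- g$x^2 + g$y^2
  rb <- body_diameter_mm / 2
  inz <- abs(g$z) <= length_mm / 2
  labels <- array(0L, grid$n)
  labels[r2 <= rb^2 & inz] <- 1L                      # acrylic shell
  labels[r2 <= (rb - shell_mm)^2 & inz] <- 2L         # water interior
  insert_names <- c("air", "pmp", "ldpe", "polystyrene", "acrylic",
                    "delrin", "teflon")
  ang <- (seq_along(insert_names) - 1) * 2 * pi / length(insert_names) + pi / 2
  cx <- insert_circle_radius_mm * cos(ang)
  cy <- insert_circle_radius_mm * sin(ang)
  ri <- insert_diameter_mm / 2
  for (i in seq_along(insert_names)) {
    sel <- (g$x - cx[i])^2 + (g$y - cy[i])^2 <= ri^2 & inz
    labels[sel] <- 2L + i
  }
  # small acrylic spheres on an inner circle (z = 0 plane)
  sph_r <- c(3, 4, 5); sph_ang <- c(0, 2 * pi / 3, 4 * pi / 3) + pi / 7
  for (i in seq_along(sph_r)) {
    sel <- (g$x - 30 * cos(sph_ang[i]))^2 + (g$y - 30 * sin(sph_ang[i]))^2 +
      g$z^2 <= sph_r[i]^2
    labels[sel] <- 10L
  }
  mats <- list("0" = cbct_material("air"),
               "1" = cbct_material("acrylic"),
               "2" = cbct_material("water"),
               "3" = cbct_material("air"),
               "4" = cbct_material("pmp"),
               "5" = cbct_material("ldpe"),
               "6" = cbct_material("polystyrene"),
               "7" = cbct_material("acrylic"),
               "8" = cbct_material("delrin"),
               "9" = cbct_material("teflon"),
               "10" = cbct_material("acrylic"))
  inserts <- data.frame(name = insert_names, label = 3:9,
                        x_mm = cx, y_mm = cy, radius_mm = ri,
                        half_length_mm = length_mm / 2)
  labeled_phantom(labels, mats, grid, inserts = inserts)
}

#' Digital head phantom
#'
#' An ellipsoidal cortical-bone skull enclosing brain tissue with
#' low-contrast ventricle lobes (water/CSF-like, about -1.5% attenuation
#' contrast), a thin vessel, and optionally four titanium frame pins at
#' the skull periphery.
#'
#' @param grid a [voxel_grid()].
#' @param with_metal add four titanium pin cylinders (default `FALSE`).
#' @param semi_axes_mm outer skull semi-axes (x, y, z).
#' @param skull_mm skull shell thickness.
#' @return A [labeled_phantom()]. Labels: 1 skull, 2 brain, 3 ventricles,
#'   4 vessel, 5 metal pins (if present).
#' @export
make_head_phantom <- function(grid, with_metal = FALSE,
                              semi_axes_mm = c(55, 65, 55), skull_mm = 6) {
  g <- grid_fields(grid)
  a <- semi_axes_mm
  labels <- array(0L, grid$n)
  ell <- function(ax) (g$x / ax[1])^2 + (g$y / ax[2])^2 + (g$z / ax[3])^2
  labels[ell(a) <= 1] <- 1L                            # skull
  labels[ell(a - skull_mm) <= 1] <- 2L                 # brain
  # two ventricle lobes, small CSF-like negative contrast
  for (s in c(-1, 1)) {
    sel <- ((g$x - s * 12) / 8)^2 + (g$y / 25)^2 + ((g$z - 5) / 12)^2 <= 1
    labels[sel & labels == 2L] <- 3L
  }
  # thin vessel running axially, slightly bright
  sel <- (g$x - 25)^2 + (g$y - 10)^2 <= 1.6^2 & abs(g$z) <= 30
  labels[sel & labels == 2L] <- 4L
  mats <- list("0" = cbct_material("air"),
               "1" = cbct_material("cortical_bone"),
               "2" = cbct_material("brain"),
               "3" = cbct_material("water"),
               "4" = cbct_material("acrylic"))
  if (with_metal) {
    pin_ang <- c(45, 135, 225, 315) * pi / 180
    pr <- c(a[1], a[2]) + 7     # external posts just beyond the skull
    for (p in pin_ang) {
      sel <- (g$x - pr[1] * cos(p))^2 + (g$y - pr[2] * sin(p))^2 <= 4.5^2 &
        abs(g$z) <= 12
      labels[sel] <- 5L
    }
    mats[["5"]] <- cbct_material("titanium")
  }
  labeled_phantom(labels, mats, grid)
}

#' Attenuation volume of a labeled phantom
#'
#' Renders the phantom as linear attenuation, either monochromatic (at
#' `energy_keV`) or on the spectrum-weighted mean attenuation scale.
#'
#' @param phantom a [labeled_phantom()].
#' @param spectrum an [energy_spectrum()] (used unless `energy_keV` given).
#' @param energy_keV optional single energy for a monochromatic rendering.
#' @export
phantom_to_mu_volume <- function(phantom, spectrum = NULL, energy_keV = NULL) {
  stopifnot(inherits(phantom, "labeled_phantom"))
  labs <- as.integer(names(phantom$material_of_label))
  mu <- vapply(phantom$material_of_label, function(m) {
    if (!is.null(energy_keV)) mu_at(m, energy_keV) else effective_mu(m, spectrum)
  }, numeric(1))
  lut <- numeric(max(labs) + 1)
  lut[labs + 1] <- mu
  volume_image(array(lut[as.integer(phantom$labels) + 1], phantom$grid$n),
               phantom$grid, unit = "mm^-1")
}
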