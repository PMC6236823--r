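#' Histogram-based three-class segmentation
#'
#' Segments a reconstructed attenuation volume into air, soft tissue and
#' dense (bone-like) classes. The air/soft threshold is Otsu's threshold
#' on the full histogram (robust to the dominant air background); the
#' soft/dense threshold is Otsu's threshold on the object voxels. When
#' `basis_mus` is supplied, the object-internal split is accepted only if
#' it shows a genuinely bone-like separation (dense-class mean at least
#' halfway between the soft and bone basis attenuations above the
#' soft-class mean); otherwise the soft/dense threshold falls back to the
#' midpoint of the soft and bone basis attenuations. This keeps the
#' class-to-material assignment consistent when the scanned object
#' contains no bone (e.g. a plastic sensitometry phantom).
#'
#' @param volume a [volume_image()] (mm^-1).
#' @param basis_mus optional increasing mean attenuations (air, soft,
#'   bone) anchoring the dense class.
#' @param min_separation minimum spread (mm^-1) between the air and
#'   object class means below which the histogram is considered unimodal
#'   (e.g. an empty scan) and an error is raised.
#' @return An object of class `segmentation_map`: `labels` (integer array,
#'   0 air / 1 soft / 2 dense) and `thresholds` (length 2).
#' @export
segment_by_histogram <- function(volume, basis_mus = NULL,
                                 min_separation = 5e-3) {
  v <- as.numeric(volume$values)
  if (any(!is.finite(v))) stop("volume must be finite")
  ot <- otsu_two_thresholds(v)
  t1 <- ot$t[1]; t2 <- ot$t[2]
  if (!is.finite(ot$means[3]) || !is.finite(ot$means[1]) ||
      ot$means[3] - ot$means[1] < min_separation)
    stop("histogram appears unimodal; cannot separate air from tissue")
  if (!is.null(basis_mus)) {
    stopifnot(length(basis_mus) == 3, all(diff(basis_mus) > 0))
    # accept the histogram split only if the class means are plausible
    # for the basis materials assigned to them
    ok <- ot$means[1] < 0.5 * basis_mus[2] &&
      ot$means[2] > 0.5 * basis_mus[2] && ot$means[2] < 1.5 * basis_mus[2] &&
      ot$means[3] > 0.5 * (basis_mus[2] + basis_mus[3])
    if (!ok) {
      t1 <- (basis_mus[1] + basis_mus[2]) / 2
      t2 <- (basis_mus[2] + basis_mus[3]) / 2
    }
  }
  lab <- integer(length(v))
  lab[v > t1] <- 1L; lab[v > t2] <- 2L
  structure(list(labels = array(lab, volume$grid$n),
                 thresholds = c(t1, t2), grid = volume$grid),
            class = "segmentation_map")
}

# exact two-threshold Otsu (maximal 3-class between-class variance) on a
# 256-bin histogram; returns thresholds and the three class means
otsu_two_thresholds <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) <= 0)
    return(list(t = c(rng[1], rng[1]), means = rep(rng[1], 3)))
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2] + 1e-12 * max(1, abs(rng[2])),
                                      length.out = n_bins + 1), plot = FALSE)
  w <- h$counts / sum(h$counts)
  W <- c(0, cumsum(w)); M <- c(0, cumsum(w * h$mids))
  best <- -Inf; bi <- c(1L, 2L)
  for (i in 1:(n_bins - 2)) {
    w1 <- W[i + 1]
    if (w1 <= 0) next
    mu1 <- M[i + 1] / w1
    for (j in (i + 1):(n_bins - 1)) {
      w2 <- W[j + 1] - W[i + 1]
      if (w2 <= 0) next
      w3 <- 1 - W[j + 1]
      if (w3 <= 0) break
      mu2 <- (M[j + 1] - M[i + 1]) / w2
      mu3 <- (M[n_bins + 1] - M[j + 1]) / w3
      bcv <- w1 * mu1^2 + w2 * mu2^2 + w3 * mu3^2
      if (bcv > best) { best <- bcv; bi <- c(i, j) }
    }
  }
  t <- h$breaks[bi + 1]
  m <- c(mean(x[x <= t[1]]), mean(x[x > t[1] & x <= t[2]]), mean(x[x > t[2]]))
  list(t = t, means = m)
}

# Relabel the partial-volume "skin" at air/bone interfaces: voxels blurred
# across an air-to-dense surface read above the air/soft threshold and get
# labeled soft, painting a spurious soft-tissue shell outside the skull.
# Soft voxels that touch the air class and lie within two voxels of the
# dense class, with values below the air/dense midpoint, are returned to
# air before the segmentation is re-projected.
refine_pv_skin <- function(seg, volume, basis_mus) {
  dil <- function(m, k = 1) {
    d <- dim(m)
    for (s in seq_len(k)) {
      e <- m
      e[-1, , ] <- e[-1, , ] | m[-d[1], , ]
      e[-d[1], , ] <- e[-d[1], , ] | m[-1, , ]
      e[, -1, ] <- e[, -1, ] | m[, -d[2], ]
      e[, -d[2], ] <- e[, -d[2], ] | m[, -1, ]
      e[, , -1] <- e[, , -1] | m[, , -d[3]]
      e[, , -d[3]] <- e[, , -d[3]] | m[, , -1]
      m <- e
    }
    m
  }
  skin <- seg$labels == 1L & dil(seg$labels == 0L) & dil(seg$labels == 2L, 2) &
    volume$values < (basis_mus[1] + basis_mus[3]) / 2
  seg$labels[skin] <- 0L
  seg
}

# reset non-air components below min_frac of the largest to air; removes
# spurious tissue blobs (cone-region or streak residue) before the
# segmentation is re-projected
drop_small_components <- function(seg, min_frac = 0.01) {
  obj <- seg$labels > 0L
  if (!any(obj)) return(seg)
  comp <- cpp_label_components(obj, seg$grid$n)
  sizes <- tabulate(comp[comp > 0])
  drop <- which(sizes < min_frac * max(sizes))
  if (length(drop)) seg$labels[array(comp %in% drop, dim(comp))] <- 0L
  seg
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> thresholds %.4g / %.4g mm^-1; class counts: %s\n",
              x$thresholds[1], x$thresholds[2],
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Ideal re-projection of a segmentation
#'
#' Renders each segmentation class as its basis material at the
#' spectrum-weighted mean attenuation and evaluates the polychromatic
#' projector, producing the idealized (scatter- and flood-error-free)
#' projections the low-frequency correction compares against. When a
#' bowtie profile is given, each detector column uses its post-bowtie
#' spectrum, so the ideal projections carry the same spectral signature
#' as the acquisition and the measured-minus-ideal residual isolates the
#' additive degradations.
#'
#' @param seg a `segmentation_map` from [segment_by_histogram()].
#' @param spectrum an [energy_spectrum()].
#' @param materials list of three [material_table()]s for classes
#'   (air, soft, dense), in that order.
#' @param geom a [cone_beam_geometry()].
#' @param bowtie optional per-column filter path (mm).
#' @param filter_material bowtie material.
#' @param antialias smooth the class indicator maps with a one-voxel
#'   boxcar before projection (default). The hard-thresholded surface is
#'   only accurate to half a voxel; the softened indicators (which still
#'   sum to one) match the reconstruction's edge profile and avoid
#'   spurious silhouette structure in the measured-minus-ideal residual.
#' @param step_mm projector step.
#' @return A line-integral [projection_stack()].
#' @export
ideal_projections <- function(seg, spectrum, materials, geom, bowtie = NULL,
                              filter_material = cbct_material("aluminum"),
                              antialias = TRUE, step_mm = NULL) {
  classes <- sort(unique(as.integer(seg$labels)))
  if (length(materials) < max(classes) + 1)
    stop("segmentation contains label ", max(classes),
         " with no material mapped")
  s <- normalize_spectrum(spectrum)
  mu_bar <- vapply(materials, effective_mu, numeric(1), spectrum = s)
  # flood-normalized projections measure attenuation in excess of the air
  # column, so the air class contributes identically zero
  mu_render <- mu_bar
  mu_render[1] <- 0
  maps <- lapply(seq_along(materials), function(i) {
    ind <- array(as.numeric(seg$labels == (i - 1)), seg$grid$n)
    if (antialias) ind <- box_smooth3(ind)
    volume_image(ind * mu_render[i], seg$grid)
  })
  g <- lapply(maps, function(m) forward_project_mono(m, geom, step_mm)$values)
  sig <- lapply(materials, sigma_hat, spectrum = s)
  nr <- geom$det_rows; nc <- geom$det_cols; nv <- length(geom$angles_deg)
  if (is.null(bowtie)) {
    wcol <- matrix(s$weights, length(s$weights), nc)
  } else {
    if (length(bowtie) != nc)
      stop("bowtie profile must have one entry per detector column")
    tr <- exp(-outer(mu_at(filter_material, s$energies_keV), bowtie))
    wcol <- s$weights * tr
  }
  wcol <- sweep(wcol, 2, colSums(wcol), `/`)
  acc <- array(0, c(nr, nc, nv))
  for (e in seq_along(s$energies_keV)) {
    expo <- array(0, c(nr, nc, nv))
    for (i in seq_along(g)) expo <- expo + sig[[i]][e] * g[[i]]
    acc <- acc + rep(rep(wcol[e, ], each = nr), nv) * exp(-expo)
  }
  ps <- projection_stack(-log(acc), "line_integral", geom)
  attr(ps, "g") <- g
  ps
}

# separable 3-point boxcar (replicated borders)
box_smooth3 <- function(v) {
  d <- dim(v)
  sm <- function(a, ax) {
    lo <- a; hi <- a
    if (ax == 1) { lo[-1, , ] <- a[-d[1], , ]; hi[-d[1], , ] <- a[-1, , ] }
    if (ax == 2) { lo[, -1, ] <- a[, -d[2], ]; hi[, -d[2], ] <- a[, -1, ] }
    if (ax == 3) { lo[, , -1] <- a[, , -d[3]]; hi[, , -d[3]] <- a[, , -1] }
    (lo + a + hi) / 3
  }
  sm(sm(sm(v, 1), 2), 3)
}

#' Subtract the smooth measured-minus-ideal residual
#'
#' The shading correction step: the difference between measured and ideal
#' projections is TV-smoothed per view (preserving large edges, removing
#' small structures such as mis-segmented inserts) and subtracted from
#' the measured projections. The difference and subtraction are carried
#' out in the intensity domain, where additive scatter and flood-field
#' errors are additive and therefore removed without biasing the
#' attenuation contrast of structures; the corrected intensities are
#' returned as line integrals (`-log I_C`). Because the residual to keep
#' is low-frequency by construction, the ROF smoothing runs on a
#' `scale`-fold down-sampled view (where it converges in few iterations)
#' and is bilinearly up-sampled; structures narrower than about
#' `5 * scale` detector pixels are removed.
#'
#' @param measured,ideal [projection_stack()]s of identical shape, either
#'   domain (converted internally).
#' @param tv_weight ROF weight at the coarse scale, in intensity units
#'   (see [tv_denoise2d()]).
#' @param n_iter TV iterations.
#' @param scale down-sampling factor for the smoothing (1 = full
#'   resolution).
#' @param max_correction largest fraction of the measured intensity the
#'   subtraction may remove (the scatter estimate cannot exceed the
#'   signal; capping prevents log blow-ups behind strongly attenuating
#'   paths).
#' @param edge_threshold per-pixel intensity step in the ideal
#'   projections above which a pixel is treated as object silhouette.
#'   The residual there is dominated by the prior's half-voxel surface
#'   error, so it is interpolated across the (dilated) silhouette band
#'   before smoothing rather than trusted.
#' @return Corrected line-integral [projection_stack()]; the smoothed
#'   intensity residual is attached as attribute `"residual"`.
#' @export
lfac_correct <- function(measured, ideal, tv_weight = 0.05, n_iter = 600,
                         scale = 4, max_correction = 0.98,
                         edge_threshold = 0.1) {
  stopifnot(inherits(measured, "projection_stack"),
            inherits(ideal, "projection_stack"))
  if (!identical(dim(measured$values), dim(ideal$values)))
    stop("measured and ideal projections differ in shape")
  im <- as_intensity(measured)$values
  ii <- as_intensity(ideal)$values
  d <- im - ii
  band <- silhouette_band(ii, edge_threshold)
  if (any(band) && !all(band))
    d <- tv_inpaint(d, band, n_sweeps = 200, eps = 0.05)
  ds <- array(0, dim(d))
  for (a in seq_len(dim(d)[3]))
    ds[, , a] <- tv_smooth_coarse(d[, , a], tv_weight, n_iter, scale)
  ds <- pmin(ds, max_correction * im)
  out <- projection_stack(-log(im - ds), "line_integral", measured$geometry)
  attr(out, "residual") <- ds
  out
}

# detector pixels on steep edges of the ideal intensities (object
# silhouette), dilated by one pixel in-plane
silhouette_band <- function(ii, threshold) {
  d <- dim(ii)
  g <- array(0, d)
  g[-1, , ] <- pmax(g[-1, , ], abs(ii[-1, , ] - ii[-d[1], , ]))
  g[-d[1], , ] <- pmax(g[-d[1], , ], abs(ii[-1, , ] - ii[-d[1], , ]))
  g[, -1, ] <- pmax(g[, -1, ], abs(ii[, -1, ] - ii[, -d[2], ]))
  g[, -d[2], ] <- pmax(g[, -d[2], ], abs(ii[, -1, ] - ii[, -d[2], ]))
  band <- g > threshold
  e <- band
  e[-1, , ] <- e[-1, , ] | band[-d[1], , ]
  e[-d[1], , ] <- e[-d[1], , ] | band[-1, , ]
  e[, -1, ] <- e[, -1, ] | band[, -d[2], ]
  e[, -d[2], ] <- e[, -d[2], ] | band[, -1, ]
  e
}

# Structural smoothing at a down-sampled scale: block-average, running
# median (removes narrow structures regardless of their amplitude, which
# pure ROF cannot: mis-segmented silhouette bands are much stronger than
# the shading field to keep), ROF polish, bilinear up-sample.
tv_smooth_coarse <- function(m, weight, n_iter, scale, median_px = 1) {
  if (scale <= 1) return(tv_denoise2d(m, weight, n_iter))
  nr <- nrow(m); nc <- ncol(m)
  cr <- max(2, floor(nr / scale)); ccol <- max(2, floor(nc / scale))
  fi <- ceiling(seq_len(nr) / (nr / cr)); fj <- ceiling(seq_len(nc) / (nc / ccol))
  cnt <- tabulate(fi, cr) %o% tabulate(fj, ccol)
  coarse <- rowsum(t(rowsum(m, fi)), fj)
  coarse <- t(coarse) / cnt
  coarse <- median2d(coarse, median_px)
  u <- tv_denoise2d(coarse, weight, n_iter)
  # bilinear up-sample at block centers
  xi <- (seq_len(nr) - 0.5) / (nr / cr) + 0.5
  yj <- (seq_len(nc) - 0.5) / (nc / ccol) + 0.5
  i0 <- pmin(pmax(floor(xi), 1), cr - 1); wi <- pmin(pmax(xi - i0, 0), 1)
  j0 <- pmin(pmax(floor(yj), 1), ccol - 1); wj <- pmin(pmax(yj - j0, 0), 1)
  u[i0, j0] * outer(1 - wi, 1 - wj) + u[i0 + 1, j0] * outer(wi, 1 - wj) +
    u[i0, j0 + 1] * outer(1 - wi, wj) + u[i0 + 1, j0 + 1] * outer(wi, wj)
}

# running 2-D median with replicated borders
median2d <- function(m, w) {
  if (w <= 1) return(m)
  r <- w %/% 2
  nr <- nrow(m); nc <- ncol(m)
  idx <- function(n, s) pmin(pmax(seq_len(n) + s, 1), n)
  stack <- array(0, c(nr, nc, w * w))
  k <- 0
  for (di in -r:r) for (dj in -r:r) {
    k <- k + 1
    stack[, , k] <- m[idx(nr, di), idx(nc, dj)]
  }
  array(apply(stack, c(1, 2), stats::median), c(nr, nc))
}

#' TV in-painting of a masked volume region
#'
#' Replaces the voxels under `mask` (typically the cone-artifact region)
#' with TV-interpolated values; all other voxels are unchanged bit-exact.
#'
#' @param volume a [volume_image()].
#' @param mask logical array over the same grid.
#' @param n_sweeps,eps see [tv_inpaint()].
#' @export
inpaint_cone_region <- function(volume, mask, n_sweeps = 400, eps = 1e-4) {
  stopifnot(inherits(volume, "volume_image"))
  if (all(mask)) stop("mask covers the entire volume")
  volume_image(tv_inpaint(volume$values, mask, n_sweeps, eps),
               volume$grid, volume$unit)
}

#' Low-frequency (shading) artifact correction
#'
#' The full projection-domain shading correction pipeline: FDK
#' reconstruction, cone-artifact masking and in-painting (so the cone
#' region does not propagate through the re-projection), histogram
#' segmentation, ideal polychromatic re-projection, and TV-smoothed
#' residual subtraction.
#'
#' @param measured a [projection_stack()] (intensity or line-integral).
#' @param spectrum an [energy_spectrum()].
#' @param materials basis materials for classes (air, soft, dense).
#' @param geom,grid acquisition geometry and reconstruction grid.
#' @param bowtie optional per-column bowtie filter path (mm) used in the
#'   ideal re-projection (see [ideal_projections()]).
#' @param tv_weight smoothing weight of the intensity residual.
#' @param cone_mask optional precomputed [cone_artifact_mask()]; computed
#'   on the fly when `NULL`.
#' @param step_mm projector step.
#' @return Corrected line-integral [projection_stack()] with attributes
#'   `"seg"` (the segmentation) and `"cone_mask"`.
#' @export
run_lfac <- function(measured, spectrum, materials, geom, grid,
                     bowtie = NULL, tv_weight = 0.05, cone_mask = NULL,
                     step_mm = NULL) {
  li <- as_line_integrals(measured)
  rec <- fdk_reconstruct(li, grid)
  fov <- fov_mask(geom, grid)
  if (is.null(cone_mask)) cone_mask <- cone_artifact_mask(geom, grid, step_mm = step_mm)
  if (any(cone_mask & fov)) rec <- inpaint_cone_region(rec, cone_mask & fov)
  rec$values[!fov] <- 0
  basis_mus <- vapply(materials, effective_mu, numeric(1), spectrum = spectrum)
  seg <- segment_by_histogram(rec, basis_mus = basis_mus)
  seg <- refine_pv_skin(seg, rec, basis_mus)
  seg <- drop_small_components(seg)
  ideal <- ideal_projections(seg, spectrum, materials, geom, bowtie = bowtie,
                             step_mm = step_mm)
  out <- lfac_correct(li, ideal, tv_weight = tv_weight)
  attr(out, "seg") <- seg
  attr(out, "cone_mask") <- cone_mask
  out
}
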