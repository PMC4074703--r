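#' Specification of a synthetic brain phantom
#'
#' Describes a ground-truthed miniature brain used to exercise the whole
#' measurement chain: a FLAIR-like structural volume with hyperintense
#' lesion patches, and a complex GRE/SWI volume whose phase carries a smooth
#' background field plus narrow hypointense vein structures. Geometry is
#' specified in physical mm in a space shared by both grids, so the FLAIR
#' side (default 5.0 mm slices) and the GRE side (default 2.0 mm slices)
#' describe the same head. Geometry is deterministic; only the noise draws
#' depend on `seed`.
#'
#' Voxel spacing defaults follow a 3-T protocol: 0.4688 mm in-plane for both
#' sequences, 5.0 mm FLAIR and 2.0 mm SWI slices. The parenchyma intensity
#' scale (`parenchyma_mean`, `parenchyma_sd`) is an arbitrary phantom
#' convention (no patient intensity statistics exist to copy), stated here
#' as configuration.
#'
#' @param shape_swi integer length-3: GRE/SWI grid (voxels per axis).
#' @param spacing_swi mm per axis for the GRE/SWI grid.
#' @param shape_flair,spacing_flair same for the FLAIR grid. The two grids
#'   should cover the same physical extent when both sides are generated.
#' @param parenchyma_mean,parenchyma_sd FLAIR parenchyma Gaussian (image units).
#' @param brain_radii_mm,icv_radii_mm ellipsoid semi-axes of the brain and
#'   intracranial envelopes, centred in the field of view.
#' @param ventricle_offset_mm lateral (x) offset of each lateral-ventricle
#'   ellipsoid from the midline.
#' @param ventricle_radii_mm semi-axes of each lateral ventricle.
#' @param lesions list of lesions, each `list(center = mm xyz, radius = mm,
#'   offset_sd = multiple of parenchyma SD)`. An offset above 3 is needed for
#'   a lesion that the mean + 3 SD threshold is meant to recover.
#' @param veins list of veins, each `list(polyline = n x 3 matrix of mm
#'   points, radius = mm, depth = phase dip in radians, in (0, pi])`.
#' @param background_phase named or plain numeric vector of polynomial
#'   coefficients for the smooth background field, terms
#'   `(1, u, v, w, u^2, v^2, w^2, uv, uw, vw)` on coordinates normalised to
#'   \[-1, 1\] over the field of view; radians.
#' @param phase_noise_sd,magnitude_noise_sd Gaussian noise SDs (radians /
#'   magnitude units).
#' @param csf_offset_sd FLAIR CSF intensity, as a (negative) multiple of the
#'   parenchyma SD relative to the parenchyma mean.
#' @param wrap logical; wrap summed phase into (-pi, pi]. If `FALSE`, a
#'   summed phase exceeding the principal interval is an error.
#' @param seed integer RNG seed fixing the noise realisation.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_swi = c(96L, 96L, 25L),
                         spacing_swi = c(0.4688, 0.4688, 2.0),
                         shape_flair = c(96L, 96L, 10L),
                         spacing_flair = c(0.4688, 0.4688, 5.0),
                         parenchyma_mean = 100,
                         parenchyma_sd = 10,
                         brain_radii_mm = c(19, 19, 22),
                         icv_radii_mm = c(21, 21, 24),
                         ventricle_offset_mm = 4.5,
                         ventricle_radii_mm = c(2.5, 7, 9),
                         lesions = list(),
                         veins = list(),
                         background_phase = c(0.2, 0.3, -0.25, 0.1, 0.45,
                                              -0.35, 0.15, 0.2, 0, 0),
                         phase_noise_sd = 0.08,
                         magnitude_noise_sd = 0.02,
                         csf_offset_sd = -6,
                         wrap = TRUE,
                         seed = 1L) {
  spec <- list(shape_swi = as.integer(shape_swi), spacing_swi = as.numeric(spacing_swi),
               shape_flair = as.integer(shape_flair), spacing_flair = as.numeric(spacing_flair),
               parenchyma_mean = parenchyma_mean, parenchyma_sd = parenchyma_sd,
               brain_radii_mm = as.numeric(brain_radii_mm),
               icv_radii_mm = as.numeric(icv_radii_mm),
               ventricle_offset_mm = ventricle_offset_mm,
               ventricle_radii_mm = as.numeric(ventricle_radii_mm),
               lesions = lesions, veins = veins,
               background_phase = as.numeric(background_phase),
               phase_noise_sd = phase_noise_sd,
               magnitude_noise_sd = magnitude_noise_sd,
               csf_offset_sd = csf_offset_sd,
               wrap = isTRUE(wrap),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$brain_radii_mm <= 0) || any(spec$icv_radii_mm <= 0) ||
      any(spec$ventricle_radii_mm <= 0))
    stop("all phantom radii must be > 0", call. = FALSE)
  if (any(spec$icv_radii_mm < spec$brain_radii_mm))
    stop("intracranial envelope must contain the brain ellipsoid", call. = FALSE)
  if (spec$parenchyma_sd <= 0) stop("parenchyma SD must be > 0", call. = FALSE)
  for (l in spec$lesions) {
    if (is.null(l$center) || is.null(l$radius) || is.null(l$offset_sd))
      stop("each lesion needs center, radius, offset_sd", call. = FALSE)
    if (l$radius <= 0) stop("lesion radius must be > 0", call. = FALSE)
  }
  for (v in spec$veins) {
    if (is.null(v$polyline) || is.null(v$radius) || is.null(v$depth))
      stop("each vein needs polyline, radius, depth", call. = FALSE)
    if (v$radius <= 0) stop("vein radius must be > 0", call. = FALSE)
    if (v$depth <= 0 || v$depth > pi)
      stop("vein phase depth must lie in (0, pi]", call. = FALSE)
  }
  if (length(spec$background_phase) > 10)
    stop("background polynomial supports terms up to order 2 (10 coefficients)",
         call. = FALSE)
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> SWI %s @ (%s) mm | FLAIR %s @ (%s) mm\n",
              paste(x$shape_swi, collapse = "x"),
              paste(format(x$spacing_swi), collapse = ", "),
              paste(x$shape_flair, collapse = "x"),
              paste(format(x$spacing_flair), collapse = ", ")))
  cat(sprintf("  %d lesion(s), %d vein(s), seed %d\n",
              length(x$lesions), length(x$veins), x$seed))
  invisible(x)
}

# --- rasterization helpers (all in mm, voxel centers at (i - 0.5) * sp) ----

ellipsoid_mask <- function(shape, spacing, center, radii) {
  a <- ((axis_coords_mm(shape[1], spacing[1]) - center[1]) / radii[1])^2
  b <- ((axis_coords_mm(shape[2], spacing[2]) - center[2]) / radii[2])^2
  c2 <- ((axis_coords_mm(shape[3], spacing[3]) - center[3]) / radii[3])^2
  outer(outer(a, b, "+"), c2, "+") <= 1
}

sphere_mask <- function(shape, spacing, center, radius) {
  ellipsoid_mask(shape, spacing, center, rep(radius, 3))
}

# distance-to-segment rasterization of a tubular structure, bounding-box limited
rasterize_tube <- function(shape, spacing, polyline, radius) {
  mask <- array(FALSE, shape)
  polyline <- matrix(as.numeric(polyline), ncol = 3)
  nseg <- nrow(polyline) - 1L
  if (nseg < 1L) stop("vein polyline needs at least 2 points", call. = FALSE)
  for (s in seq_len(nseg)) {
    p <- polyline[s, ]; q <- polyline[s + 1L, ]
    lo <- pmin(p, q) - radius; hi <- pmax(p, q) + radius
    idx <- lapply(1:3, function(a) {
      r <- which(axis_coords_mm(shape[a], spacing[a]) >= lo[a] &
                 axis_coords_mm(shape[a], spacing[a]) <= hi[a])
      r
    })
    if (any(lengths(idx) == 0)) next
    xs <- axis_coords_mm(shape[1], spacing[1])[idx[[1]]]
    ys <- axis_coords_mm(shape[2], spacing[2])[idx[[2]]]
    zs <- axis_coords_mm(shape[3], spacing[3])[idx[[3]]]
    g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
    d <- q - p
    len2 <- sum(d^2)
    if (len2 == 0) {
      dist2 <- (g$x - p[1])^2 + (g$y - p[2])^2 + (g$z - p[3])^2
    } else {
      t <- ((g$x - p[1]) * d[1] + (g$y - p[2]) * d[2] + (g$z - p[3]) * d[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      dist2 <- (g$x - (p[1] + t * d[1]))^2 + (g$y - (p[2] + t * d[2]))^2 +
               (g$z - (p[3] + t * d[3]))^2
    }
    inside <- dist2 <= radius^2
    if (any(inside)) {
      cells <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]],
                                     KEEP.OUT.ATTRS = FALSE))
      mask[cells[inside, , drop = FALSE]] <- TRUE
    }
  }
  mask
}

# polynomial background field on coordinates normalised to [-1, 1] per axis
poly_background <- function(shape, spacing, coef) {
  coef <- c(coef, rep(0, 10 - length(coef)))
  fov <- shape * spacing
  u <- (2 * axis_coords_mm(shape[1], spacing[1]) - fov[1]) / fov[1]
  v <- (2 * axis_coords_mm(shape[2], spacing[2]) - fov[2]) / fov[2]
  w <- (2 * axis_coords_mm(shape[3], spacing[3]) - fov[3]) / fov[3]
  one_x <- rep(1, shape[1]); one_y <- rep(1, shape[2]); one_z <- rep(1, shape[3])
  term <- function(fx, fy, fz) outer(outer(fx, fy), fz)
  coef[1] * term(one_x, one_y, one_z) +
    coef[2] * term(u, one_y, one_z) +
    coef[3] * term(one_x, v, one_z) +
    coef[4] * term(one_x, one_y, w) +
    coef[5] * term(u^2, one_y, one_z) +
    coef[6] * term(one_x, v^2, one_z) +
    coef[7] * term(one_x, one_y, w^2) +
    coef[8] * term(u, v, one_z) +
    coef[9] * term(u, one_y, w) +
    coef[10] * term(one_x, v, w)
}

phantom_geometry <- function(spec, side = c("flair", "swi")) {
  side <- match.arg(side)
  shape <- if (side == "flair") spec$shape_flair else spec$shape_swi
  spacing <- if (side == "flair") spec$spacing_flair else spec$spacing_swi
  fov <- shape * spacing
  center <- fov / 2
  brain <- ellipsoid_mask(shape, spacing, center, spec$brain_radii_mm)
  icv <- ellipsoid_mask(shape, spacing, center, spec$icv_radii_mm)
  voff <- spec$ventricle_offset_mm
  vent <- ellipsoid_mask(shape, spacing, center + c(-voff, 0, 0), spec$ventricle_radii_mm) |
          ellipsoid_mask(shape, spacing, center + c(voff, 0, 0), spec$ventricle_radii_mm)
  vent <- vent & brain
  list(shape = shape, spacing = spacing, fov = fov, center = center,
       brain = brain, icv = icv, ventricles = vent, midline_mm = fov[1] / 2)
}

#' Generate the FLAIR side of a phantom
#'
#' Parenchyma intensities are Gaussian, lesion voxels are offset by their
#' stated multiple of the parenchyma SD, ventricles and the CSF rim get a
#' CSF-like low intensity. Geometry (all masks, including the WMH truth
#' mask) is independent of the seed; only noise changes with it.
#'
#' @param spec a [phantom_spec()].
#' @return list (class `phantom_bundle`) with `flair` ([image_volume()]),
#'   masks `brain`, `ventricles`, `icv`, `wmh_truth`, plus `midline_mm`.
#' @export
generate_structural_phantom <- function(spec) {
  validate_phantom_spec(spec)
  g <- phantom_geometry(spec, "flair")
  wmh <- array(FALSE, g$shape)
  for (l in spec$lesions) {
    lm <- sphere_mask(g$shape, g$spacing, l$center, l$radius)
    if (any(lm & !g$brain))
      stop(sprintf("geometry error: lesion at (%s) mm extends outside the brain mask",
                   paste(format(l$center), collapse = ", ")), call. = FALSE)
    wmh <- wmh | lm
  }
  wmh <- wmh & !g$ventricles
  set.seed(spec$seed)
  mu <- spec$parenchyma_mean; sd <- spec$parenchyma_sd
  dat <- array(rnorm(prod(g$shape), 0, sd), g$shape)    # one draw, reused per class
  img <- array(0, g$shape)
  img[!g$icv] <- abs(dat[!g$icv]) * 0.2                  # air: near-zero
  csf <- (g$icv & !g$brain) | g$ventricles
  img[csf] <- mu + spec$csf_offset_sd * sd + dat[csf] * 0.5
  par_vox <- g$brain & !g$ventricles
  img[par_vox] <- mu + dat[par_vox]
  for (l in spec$lesions) {
    lm <- sphere_mask(g$shape, g$spacing, l$center, l$radius) & !g$ventricles
    img[lm] <- img[lm] + l$offset_sd * sd
  }
  structure(list(flair = image_volume(img, g$spacing, "flair"),
                 brain = g$brain, ventricles = g$ventricles, icv = g$icv,
                 wmh_truth = wmh, midline_mm = g$midline_mm,
                 spec = spec),
            class = "phantom_bundle")
}

#' Generate the GRE/SWI side of a phantom
#'
#' Phase = smooth polynomial background + vein dips (each vein subtracts its
#' stated depth inside its tube) + Gaussian noise inside the intracranial
#' envelope, wrapped into (-pi, pi]. Magnitude is near-uniform inside the
#' envelope and zero outside. The complex volume is
#' `magnitude * exp(1i * phase)`.
#'
#' @param spec a [phantom_spec()].
#' @return list (class `phantom_bundle`) with `gre` (complex-pair list of
#'   class `complex_gre_volume`), GRE-grid masks `brain`, `ventricles`,
#'   `icv`, `vein_truth`, the basal-ganglia top slice index `bg_top_slice`,
#'   and `midline_mm`.
#' @export
generate_swi_phantom <- function(spec) {
  validate_phantom_spec(spec)
  g <- phantom_geometry(spec, "swi")
  vein <- array(FALSE, g$shape)
  phase <- poly_background(g$shape, g$spacing, spec$background_phase)
  for (v in spec$veins) {
    tm <- rasterize_tube(g$shape, g$spacing, v$polyline, v$radius)
    if (any(tm & !g$brain))
      stop("geometry error: vein extends outside the brain mask", call. = FALSE)
    vein <- vein | tm
    phase[tm] <- phase[tm] - v$depth
  }
  vein <- vein & !g$ventricles
  set.seed(spec$seed + 1L)
  if (spec$phase_noise_sd > 0)
    phase[g$icv] <- phase[g$icv] + rnorm(sum(g$icv), 0, spec$phase_noise_sd)
  if (spec$wrap) {
    phase <- wrap_phase(phase)
  } else if (any(phase > pi | phase <= -pi)) {
    stop("summed phase exceeds (-pi, pi] and wrapping is disabled", call. = FALSE)
  }
  mag <- array(0, g$shape)
  mag[g$icv] <- 1
  if (spec$magnitude_noise_sd > 0)
    mag[g$icv] <- pmax(mag[g$icv] + rnorm(sum(g$icv), 0, spec$magnitude_noise_sd), 0)
  gre <- complex_gre_volume(image_volume(mag, g$spacing, "magnitude"),
                            image_volume(phase, g$spacing, "phase"))
  vz <- which(apply(g$ventricles, 3, any))
  bg_top <- if (length(vz)) min(vz) + 1L else NA_integer_
  structure(list(gre = gre,
                 brain = g$brain, ventricles = g$ventricles, icv = g$icv,
                 vein_truth = vein, bg_top_slice = bg_top,
                 midline_mm = g$midline_mm, spec = spec),
            class = "phantom_bundle")
}

#' Generate both sides of a phantom as one bundle
#'
#' Convenience wrapper running [generate_structural_phantom()] and
#' [generate_swi_phantom()] on the same spec. FLAIR-grid masks keep their
#' names; GRE-grid masks get a `_gre` suffix.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_bundle` with both image volumes and all masks.
#' @export
generate_phantom_bundle <- function(spec) {
  s <- generate_structural_phantom(spec)
  w <- generate_swi_phantom(spec)
  structure(list(flair = s$flair, gre = w$gre,
                 brain = s$brain, ventricles = s$ventricles, icv = s$icv,
                 wmh_truth = s$wmh_truth,
                 brain_gre = w$brain, ventricles_gre = w$ventricles,
                 icv_gre = w$icv, vein_truth = w$vein_truth,
                 bg_top_slice = w$bg_top_slice, midline_mm = s$midline_mm,
                 spec = spec),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle>\n")
  if (!is.null(x$flair)) cat("  FLAIR:", paste(dim(x$flair$data), collapse = "x"),
                             " WMH truth voxels:", sum(x$wmh_truth), "\n")
  if (!is.null(x$gre)) cat("  GRE:  ", paste(dim(x$gre$magnitude$data), collapse = "x"),
                           " vein truth voxels:", sum(x$vein_truth), "\n")
  invisible(x)
}

#' Build a radial set of in-plane deep-medullary-vein centerlines
#'
#' Deep medullary veins run within axial slices, roughly radially toward the
#' lateral ventricles. This helper lays `n_per_slice` straight spokes per
#' hemisphere around each ventricle on each requested slice, from just
#' outside the ventricle wall outward. Deterministic (no RNG): spoke angles
#' are evenly spaced with a fixed per-slice rotation so consecutive slices
#' differ.
#'
#' @param spec a [phantom_spec()] (geometry is read from it).
#' @param slices integer vector of GRE slice indices to populate.
#' @param n_per_slice spokes per hemisphere per slice.
#' @param length_mm spoke length.
#' @param radius_mm tube radius.
#' @param depth phase dip depth in radians.
#' @return list of vein descriptors suitable for `phantom_spec(veins = ...)`.
#' @export
dmv_vein_set <- function(spec, slices, n_per_slice = 10, length_mm = 9,
                         radius_mm = 0.6, depth = 0.8) {
  g_fov <- spec$shape_swi * spec$spacing_swi
  center <- g_fov / 2
  dz <- spec$spacing_swi[3]
  veins <- list()
  for (si in seq_along(slices)) {
    z <- (slices[si] - 0.5) * dz
    for (hemi in c(-1, 1)) {
      vx <- center[1] + hemi * spec$ventricle_offset_mm
      for (k in seq_len(n_per_slice)) {
        ang <- 2 * pi * (k - 1) / n_per_slice + 0.35 * si + (hemi + 1) * 0.17
        dir <- c(cos(ang), sin(ang))
        # start just outside the ventricle wall, run outward
        r0 <- max(spec$ventricle_radii_mm[1:2]) + 1.2
        p0 <- c(vx + r0 * dir[1], center[2] + r0 * dir[2], z)
        p1 <- p0 + c(dir * length_mm, 0)
        # keep inside the brain ellipsoid (with margin for the tube radius)
        keep <- function(p) {
          sum(((p - c(center[1:2], center[3])) /
                 (spec$brain_radii_mm - radius_mm - 0.5))^2) < 1
        }
        if (!keep(p1)) {
          # shrink until inside
          for (f in seq(0.9, 0.3, by = -0.1)) {
            p1 <- p0 + c(dir * length_mm * f, 0)
            if (keep(p1)) break
          }
          if (!keep(p1)) next
        }
        if (!keep(p0)) next
        veins[[length(veins) + 1L]] <-
          list(polyline = rbind(p0, p1), radius = radius_mm, depth = depth)
      }
    }
  }
  veins
}
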