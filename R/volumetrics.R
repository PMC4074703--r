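#' Mask volume in millilitres
#'
#' Voxel count times voxel volume (mm^3), divided by 1000.
#'
#' @param mask logical mask (array or [image_volume()]).
#' @param spacing mm spacing triple.
#' @return volume in ml.
#' @export
mask_volume_ml <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  sum(as_mask(mask)) * voxel_volume_mm3(spacing) / 1000
}

#' ICV-corrected volume
#'
#' `CWMHV = WMHV * meanICV / ICV`: each subject's lesion volume is rescaled
#' by the ratio of the cohort mean intracranial volume to the subject's own,
#' removing head-size differences. The cohort mean is bound at cohort
#' analysis time (see [run_cohort()]).
#'
#' @param wmhv raw volume (ml).
#' @param icv subject intracranial volume (ml), > 0.
#' @param mean_icv cohort mean intracranial volume (ml), > 0.
#' @return corrected volume (ml).
#' @export
corrected_volume <- function(wmhv, icv, mean_icv) {
  if (any(icv <= 0) || any(mean_icv <= 0))
    stop("ICV and mean ICV must be positive", call. = FALSE)
  if (any(wmhv < 0)) stop("volume must be non-negative", call. = FALSE)
  wmhv * mean_icv / icv
}

#' Intracranial volume from its mask
#'
#' The intracranial envelope is an input (phantom ground truth or external
#' preprocessing), never derived from images here. Warns when the claimed
#' envelope is smaller than a supplied parenchyma volume, since the
#' intracranial space must contain the CSF as well.
#'
#' @param intracranial logical intracranial mask.
#' @param spacing mm spacing triple.
#' @param parenchyma_ml optional parenchyma volume (ml) for the sanity check.
#' @return ICV in ml.
#' @export
compute_icv <- function(intracranial, spacing, parenchyma_ml = NULL) {
  intracranial <- as_mask(intracranial)
  if (!any(intracranial)) stop("intracranial mask is empty", call. = FALSE)
  icv <- mask_volume_ml(intracranial, spacing)
  if (!is.null(parenchyma_ml) && icv < parenchyma_ml)
    warning(sprintf("ICV (%.1f ml) is smaller than the parenchyma volume (%.1f ml); the intracranial mask should include CSF",
                    icv, parenchyma_ml), call. = FALSE)
  icv
}

# ---------------------------------------------------------------------------
# Anisotropy-aware Euclidean distance transform: separable squared-distance
# lower-envelope algorithm (one 1D parabola-envelope pass per axis), with the
# physical spacing entering each pass. No image-processing package in the
# dependency set provides this.
# ---------------------------------------------------------------------------

# 1D squared distance transform (parabola lower envelope) of sampled
# function f at sample step h; f must be finite (use a large sentinel for
# "no seed", far above any attainable squared distance)
edt_1d <- function(f, h) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); zl <- numeric(n + 1L)
  k <- 1L
  v[1] <- 1L; zl[1] <- -Inf; zl[2] <- Inf
  h2 <- h^2
  for (q in 2:n) {
    s <- ((f[q] + h2 * q^2) - (f[v[k]] + h2 * v[k]^2)) / (2 * h2 * (q - v[k]))
    while (k > 1L && s <= zl[k]) {
      k <- k - 1L
      s <- ((f[q] + h2 * q^2) - (f[v[k]] + h2 * v[k]^2)) / (2 * h2 * (q - v[k]))
    }
    k <- k + 1L
    v[k] <- q
    zl[k] <- s
    zl[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (zl[k + 1L] < q) k <- k + 1L
    d[q] <- h2 * (q - v[k])^2 + f[v[k]]
  }
  d
}

edt_big <- 1e12  # sentinel squared distance, far above any grid extent

#' Euclidean distance transform from a mask, in mm
#'
#' For every voxel, the Euclidean distance (mm, voxel-center to
#' voxel-center, anisotropy-aware) to the nearest `TRUE` voxel of `mask`.
#'
#' @param mask logical seed mask.
#' @param spacing mm spacing triple.
#' @return numeric array of distances (0 inside the mask; `Inf` if the mask
#'   is empty).
#' @export
distance_transform_mm <- function(mask, spacing) {
  mask <- as_mask(mask)
  d <- dim(mask)
  f <- array(ifelse(mask, 0, edt_big), d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2]))
    f[, y, z] <- edt_1d(f[, y, z], spacing[1])
  for (z in seq_len(d[3])) for (x in seq_len(d[1]))
    f[x, , z] <- edt_1d(f[x, , z], spacing[2])
  for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    f[x, y, ] <- edt_1d(f[x, y, ], spacing[3])
  out <- sqrt(f)
  out[out > sqrt(edt_big) / 2] <- Inf
  out
}

#' Partition WMH into periventricular and deep components
#'
#' WMH voxels within `distance_mm` (default 10 mm, inclusive) of the lateral
#' ventricles — omnidirectional Euclidean distance in mm — are classed
#' periventricular (PVH); the rest are deep (DWMH). The two masks partition
#' the input exactly. The 10-mm rule is applied uniformly to all lesions
#' (the simple, monotone choice; the original usage applied it to confluent
#' lesions only).
#'
#' @param wmh logical WMH mask.
#' @param ventricles logical lateral-ventricle mask, same grid.
#' @param spacing mm spacing triple.
#' @param distance_mm cutoff, default 10.
#' @return list `pvh`, `dwmh` (logical masks), `distance_mm`.
#' @export
partition_pvh_dwmh <- function(wmh, ventricles, spacing, distance_mm = 10) {
  wmh <- as_mask(wmh); ventricles <- as_mask(ventricles)
  check_same_grid(wmh, ventricles, "WMH and ventricle masks")
  if (distance_mm <= 0) stop("distance_mm must be > 0", call. = FALSE)
  if (!any(ventricles)) {
    warning("ventricle mask is empty; all WMH classed as deep", call. = FALSE)
    return(list(pvh = array(FALSE, dim(wmh)), dwmh = wmh, distance_mm = distance_mm))
  }
  dist <- distance_transform_mm(ventricles, spacing)
  pvh <- wmh & (dist <= distance_mm)
  list(pvh = pvh, dwmh = wmh & !pvh, distance_mm = distance_mm)
}

#' Select the periventricular slab for the vein measurement
#'
#' Returns `n_slices` consecutive axial slice indices starting at the first
#' ventricle-containing slice strictly above the basal-ganglia top slice —
#' the span from the ventricles just above the basal ganglia up to where
#' they disappear. With 2.0 mm slices the default 5 slices cover 10 mm.
#'
#' @param ventricles logical ventricle mask (slices along the 3rd axis).
#' @param basal_ganglia_top_slice reference slice index; the slab starts
#'   strictly above it. Supplied explicitly, never inferred from images.
#' @param n_slices number of slices, default 5.
#' @return integer vector of slice indices (length `n_slices`).
#' @export
select_periventricular_slab <- function(ventricles, basal_ganglia_top_slice,
                                        n_slices = 5L) {
  ventricles <- as_mask(ventricles)
  n_slices <- as.integer(n_slices)
  vz <- which(apply(ventricles, 3, any))
  avail <- vz[vz > basal_ganglia_top_slice]
  if (length(avail) == 0)
    stop(sprintf("no ventricle-containing slices above slice %d (ventricles span %s)",
                 basal_ganglia_top_slice,
                 if (length(vz)) paste(range(vz), collapse = "-") else "none"),
         call. = FALSE)
  start <- min(avail)
  slab <- start:(start + n_slices - 1L)
  if (!all(slab %in% vz))
    stop(sprintf("need %d consecutive ventricle-containing slices from slice %d; ventricles present on slices %s",
                 n_slices, start, paste(vz, collapse = ", ")), call. = FALSE)
  slab
}

#' Mask restricted to slab slices
#' @param mask logical mask, @param slab slice indices (3rd axis).
#' @return logical mask zeroed outside the slab.
#' @export
restrict_to_slab <- function(mask, slab) {
  mask <- as_mask(mask)
  out <- array(FALSE, dim(mask))
  slab <- slab[slab >= 1 & slab <= dim(mask)[3]]
  out[, , slab] <- mask[, , slab]
  out
}

#' Regional (slab-restricted) corrected WMH volume
#'
#' The WMH volume around the veins: the coregistered WMH mask on the phase
#' grid is restricted to the slab slices used for the vein measurement, its
#' volume computed and ICV-corrected.
#'
#' @param wmh_on_phase_grid logical WMH mask already on the phase grid.
#' @param slab slice indices from [select_periventricular_slab()].
#' @param icv,mean_icv ml, for [corrected_volume()].
#' @param spacing phase-grid spacing (mm).
#' @return corrected regional volume (ml).
#' @export
regional_wmh_volume <- function(wmh_on_phase_grid, slab, icv, mean_icv, spacing) {
  wmh_on_phase_grid <- as_mask(wmh_on_phase_grid)
  if (any(slab < 1) || any(slab > dim(wmh_on_phase_grid)[3]))
    stop("slab indices outside the grid", call. = FALSE)
  v <- mask_volume_ml(restrict_to_slab(wmh_on_phase_grid, slab), spacing)
  corrected_volume(v, icv, mean_icv)
}
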