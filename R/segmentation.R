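#' Fit the parenchyma intensity distribution
#'
#' Fits a Gaussian to the intensity histogram of the voxels inside `region`.
#' The default `"robust"` method performs a least-squares fit of a Gaussian
#' curve to the histogram restricted to bins between the 2nd and 90th
#' percentile of the region intensities, so that lesions (far upper tail on
#' FLAIR) or veins (lower tail on filtered phase) do not inflate the fitted
#' SD; `"moments"` uses the plain sample mean and SD for comparison. Bins
#' use the Freedman-Diaconis width by default.
#'
#' @param vol an [image_volume()] (or bare array).
#' @param region logical mask of voxels to use; same grid as `vol`.
#' @param method `"robust"` (histogram least squares, default) or `"moments"`.
#' @param min_voxels minimum region size (default 100).
#' @param quantile_range percentile window of the robust fit, default
#'   `c(0.02, 0.90)`.
#' @param bin_width histogram bin width override (default Freedman-Diaconis).
#' @return object of class `intensity_model`: `mu`, `sigma`, `method`,
#'   `n_voxels`, `gof` (R-squared of the histogram fit; `NA` for moments).
#' @export
fit_parenchyma_distribution <- function(vol, region,
                                        method = c("robust", "moments"),
                                        min_voxels = 100L,
                                        quantile_range = c(0.02, 0.90),
                                        bin_width = NULL) {
  method <- match.arg(method)
  dat <- if (is_image_volume(vol)) vol$data else vol
  region <- as_mask(region)
  check_same_grid(dat, region, "volume and region")
  x <- as.numeric(dat[region])
  n <- length(x)
  if (n < min_voxels)
    stop(sprintf("region has %d voxels, below the floor of %d", n, min_voxels),
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("region intensities have zero variance; cannot fit a distribution",
         call. = FALSE)
  if (method == "moments") {
    mdl <- list(mu = mean(x), sigma = stats::sd(x), method = "moments",
                n_voxels = n, gof = NA_real_)
    class(mdl) <- "intensity_model"
    return(mdl)
  }
  q <- stats::quantile(x, quantile_range, names = FALSE)
  if (is.null(bin_width)) {
    iqr <- stats::IQR(x)
    bin_width <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(range(x)) / 100
  }
  breaks <- seq(min(x) - bin_width, max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  sel <- centers >= q[1] & centers <= q[2]
  if (sum(sel) < 5)
    stop("too few histogram bins inside the fit window; widen quantile_range",
         call. = FALSE)
  xc <- centers[sel]; yc <- counts[sel]
  # trimmed-sample moments as starting values
  body <- x[x >= q[1] & x <= q[2]]
  start <- c(A = max(yc), mu = mean(body), sigma = stats::sd(body))
  obj <- function(p) {
    if (p[3] <= 0) return(Inf)
    sum((yc - p[1] * exp(-(xc - p[2])^2 / (2 * p[3]^2)))^2)
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  p <- fit$par
  ss_tot <- sum((yc - mean(yc))^2)
  gof <- if (ss_tot > 0) 1 - fit$value / ss_tot else NA_real_
  mdl <- list(mu = unname(p[2]), sigma = unname(abs(p[3])), method = "robust",
              n_voxels = n, gof = gof)
  class(mdl) <- "intensity_model"
  mdl
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model> mu = %.4g, sigma = %.4g (%s fit, %d voxels",
              x$mu, x$sigma, x$method, x$n_voxels))
  if (!is.na(x$gof)) cat(sprintf(", R^2 = %.3f", x$gof))
  cat(")\n")
  invisible(x)
}

#' Segmentation threshold from a fitted intensity model
#'
#' `mu + k * sigma` for direction `"above"` (WMH on FLAIR uses k = 3),
#' `mu - k * sigma` for `"below"` (DMVs on filtered phase use k = 2).
#'
#' @param model an `intensity_model`.
#' @param k positive SD multiplier.
#' @param direction `"above"` or `"below"`.
#' @return threshold in image units.
#' @export
compute_threshold <- function(model, k, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "intensity_model"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive number", call. = FALSE)
  if (direction == "above") model$mu + k * model$sigma else model$mu - k * model$sigma
}

# left/right voxel counts about a midline given in mm along x
hemisphere_counts <- function(mask, spacing, midline_mm) {
  if (is.null(midline_mm) || is.na(midline_mm))
    return(c(left = NA_integer_, right = NA_integer_))
  xs <- axis_coords_mm(dim(mask)[1], spacing[1])
  per_x <- apply(mask, 1, sum)
  c(left = sum(per_x[xs < midline_mm]), right = sum(per_x[xs >= midline_mm]))
}

new_segmentation_result <- function(mask, threshold, k, direction, model,
                                    spacing, midline_mm, region) {
  hemi <- hemisphere_counts(mask, spacing, midline_mm)
  structure(list(mask = mask, threshold = threshold, k = k,
                 direction = direction, model = model, spacing = spacing,
                 midline_mm = midline_mm, region = region,
                 n_voxels = sum(mask),
                 n_left = unname(hemi["left"]), n_right = unname(hemi["right"])),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s threshold %.4g (k = %g): %d voxels",
              x$direction, x$threshold, x$k, x$n_voxels))
  if (!is.na(x$n_left)) cat(sprintf(" (L %d / R %d)", x$n_left, x$n_right))
  cat("\n")
  invisible(x)
}

#' Segment white matter hyperintensities on FLAIR
#'
#' Voxels inside the brain mask whose intensity strictly exceeds
#' `mu + k * sigma` of the fitted parenchyma distribution. The default
#' k = 3 is the a-priori hyperintensity threshold; ventricles/CSF must
#' already be excluded from `brain`. Ties at the threshold are not
#' segmented (strict inequality, fixed for reproducibility).
#'
#' @param flair an [image_volume()].
#' @param brain logical parenchyma mask (CSF excluded).
#' @param model `intensity_model` fitted on this volume's parenchyma.
#' @param k SD multiplier, default 3.
#' @param midline_mm optional x-position of the mid-sagittal plane for
#'   left/right counting.
#' @return a `segmentation_result`.
#' @export
segment_wmh <- function(flair, brain, model, k = 3, midline_mm = NULL) {
  stopifnot(is_image_volume(flair), inherits(model, "intensity_model"))
  brain <- as_mask(brain)
  check_same_grid(flair, brain, "FLAIR and brain mask")
  thr <- compute_threshold(model, k, "above")
  mask <- brain & (flair$data > thr)
  new_segmentation_result(mask, thr, k, "above", model, flair$spacing,
                          midline_mm, brain)
}

#' Segment deep medullary veins on filtered phase
#'
#' Voxels inside the periventricular slab whose corrected phase is strictly
#' below `mu - k * sigma` of the slab parenchyma phase model (default
#' k = 2), optionally minus an exclusion mask (manually drawn or produced by
#' [flag_false_dmv_candidates()]). Counts are reported in total and per
#' hemisphere (bilateral veins).
#'
#' @param fphase a `filtered_phase_volume` (or [image_volume()] of phase).
#' @param slab logical mask restricting the analysis to the periventricular
#'   slab (see [select_periventricular_slab()]).
#' @param model `intensity_model` fitted on slab parenchyma phase values.
#' @param k SD multiplier, default 2.
#' @param exclusion optional logical mask of false-vein voxels to remove.
#' @param midline_mm optional mid-sagittal plane position (mm).
#' @return a `segmentation_result`.
#' @export
segment_dmv <- function(fphase, slab, model, k = 2, exclusion = NULL,
                        midline_mm = NULL) {
  vol <- if (inherits(fphase, "filtered_phase_volume")) fphase$phase else fphase
  stopifnot(is_image_volume(vol), inherits(model, "intensity_model"))
  slab <- as_mask(slab)
  check_same_grid(vol, slab, "phase and slab mask")
  if (!any(slab)) stop("slab mask is empty", call. = FALSE)
  thr <- compute_threshold(model, k, "below")
  mask <- slab & (vol$data < thr)
  if (!is.null(exclusion)) {
    exclusion <- as_mask(exclusion)
    check_same_grid(vol, exclusion, "phase and exclusion mask")
    mask <- mask & !exclusion
  }
  new_segmentation_result(mask, thr, k, "below", model, vol$spacing,
                          midline_mm, slab)
}

# 26-connected component labelling via an adjacency graph
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0) return(list(labels = labels, n = 0L))
  pos <- arrayInd(idx, d)
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # only half the offsets needed for an undirected graph
  offsets <- offsets[1:(nrow(offsets) / 2), , drop = FALSE]
  edges <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    np <- pos + matrix(offsets[r, ], nrow(pos), 3, byrow = TRUE)
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
          np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    nid <- id_of[np[ok, , drop = FALSE]]
    has <- nid > 0L
    if (any(has)) {
      from <- which(ok)[has]
      edges <- c(edges, rbind(from, nid[has]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, n = comp$no)
}

#' Flag false-vein candidates by shape rules
#'
#' The visual identification and manual removal of false vein areas is
#' replaced here by an automated surrogate: 26-connected components of the
#' segmentation that violate vein-like shape rules are flagged, and the
#' resulting mask can be passed back to [segment_dmv()] as `exclusion`. The
#' flag mask is never applied automatically by this function.
#'
#' Rules (each can be disabled with `NULL`/`Inf`):
#' * `min_voxels`: components smaller than this are speckle, not veins.
#' * `max_volume_mm3`: components larger than this cap are lesions/artifacts.
#' * `min_elongation`: components whose principal-axis elongation
#'   (sqrt of largest/smallest eigenvalue of the voxel-coordinate covariance,
#'   mm) falls below this are near-spherical (e.g. microbleeds).
#' * `boundary`: flag components touching the outer boundary of the analysis
#'   region (cortical rim of the slab).
#'
#' @param seg a `segmentation_result` from [segment_dmv()].
#' @param rules list of rule settings; see details. `dmv_shape_rules()` gives
#'   the defaults.
#' @return logical exclusion mask (possibly empty), same grid as the input.
#' @export
flag_false_dmv_candidates <- function(seg, rules = dmv_shape_rules()) {
  stopifnot(inherits(seg, "segmentation_result"))
  d <- dim(seg$mask)
  flag <- array(FALSE, d)
  if (!any(seg$mask)) return(flag)
  enabled <- function(x) !is.null(x) && is.finite(x)
  if (!enabled(rules$min_voxels) && !enabled(rules$max_volume_mm3) &&
      !enabled(rules$min_elongation) && !isTRUE(rules$boundary))
    return(flag)
  lab <- label_components_26(seg$mask)
  vox_vol <- voxel_volume_mm3(seg$spacing)
  boundary_ring <- NULL
  if (isTRUE(rules$boundary) && !is.null(seg$region)) {
    boundary_ring <- region_boundary(seg$region)
  }
  idx_all <- which(seg$mask)
  comp_vox <- split(idx_all, lab$labels[idx_all])
  for (ci in seq_len(lab$n)) {
    vox <- comp_vox[[as.character(ci)]]
    nvox <- length(vox)
    bad <- FALSE
    if (enabled(rules$min_voxels) && nvox < rules$min_voxels) bad <- TRUE
    if (!bad && enabled(rules$max_volume_mm3) && nvox * vox_vol > rules$max_volume_mm3)
      bad <- TRUE
    if (!bad && enabled(rules$min_elongation)) {
      if (nvox < 3) {
        bad <- TRUE   # too small to be an elongated tube
      } else {
        pts <- arrayInd(vox, d)
        pts_mm <- sweep(pts - 0.5, 2, seg$spacing, "*")
        ev <- eigen(stats::cov(pts_mm), symmetric = TRUE, only.values = TRUE)$values
        ev <- pmax(ev, 1e-8)
        if (sqrt(ev[1] / ev[3]) < rules$min_elongation) bad <- TRUE
      }
    }
    if (!bad && !is.null(boundary_ring) && any(boundary_ring[vox])) bad <- TRUE
    if (bad) flag[vox] <- TRUE
  }
  flag
}

#' @rdname flag_false_dmv_candidates
#' @param min_voxels,max_volume_mm3,min_elongation,boundary rule settings.
#' @export
dmv_shape_rules <- function(min_voxels = 10L, max_volume_mm3 = Inf,
                            min_elongation = 3, boundary = FALSE) {
  list(min_voxels = min_voxels, max_volume_mm3 = max_volume_mm3,
       min_elongation = min_elongation, boundary = boundary)
}

# voxels of a region whose 6-neighbourhood leaves the region
region_boundary <- function(region) {
  region <- as_mask(region)
  d <- dim(region)
  interior <- region
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    if (by > 0) { src[[ax]] <- 1:(d[ax] - by); dst[[ax]] <- (1 + by):d[ax] }
    else { src[[ax]] <- (1 - by):d[ax]; dst[[ax]] <- 1:(d[ax] + by) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1))
    interior <- interior & shift_and(region, ax, by)
  region & !interior
}
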