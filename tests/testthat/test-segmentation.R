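# FLAIR-side spec with room for a ~500-voxel (+6 SD) lesion
seg_flair_spec <- function(lesions, seed = 3L) {
  phantom_spec(shape_flair = c(64L, 64L, 8L), shape_swi = c(64L, 64L, 20L),
               brain_radii_mm = c(13, 13, 18), icv_radii_mm = c(14, 14, 19),
               ventricle_offset_mm = 4, ventricle_radii_mm = c(1.5, 3, 8),
               lesions = lesions, seed = seed)
}

test_that("robust Gaussian fit recovers (mu, sigma) from 1e6 samples", {
  set.seed(42)
  x <- array(rnorm(1e6, 100, 10), c(100, 100, 100))
  m <- fit_parenchyma_distribution(x, array(TRUE, dim(x)))
  expect_gte(m$mu, 99.9); expect_lte(m$mu, 100.1)
  expect_gte(m$sigma, 9.9); expect_lte(m$sigma, 10.1)
  expect_gt(m$gof, 0.99)
})

test_that("robust fit shrugs off a 2% lesion tail at +6 SD; moments do not", {
  set.seed(7)
  x <- array(rnorm(5e5, 100, 10), c(100, 100, 50))
  idx <- sample(length(x), 1e4)
  x[idx] <- rnorm(1e4, 160, 10)
  reg <- array(TRUE, dim(x))
  mr <- fit_parenchyma_distribution(x, reg)
  expect_lt(abs(mr$mu - 100) / 100, 0.02)
  expect_lt(abs(mr$sigma - 10) / 10, 0.02)
  mm <- fit_parenchyma_distribution(x, reg, method = "moments")
  expect_gt(abs(mm$sigma - 10) / 10, 0.02)   # documented failure of naive moments
})

test_that("fit contracts: small regions and constant images are rejected", {
  x <- array(rnorm(1000), c(10, 10, 10))
  small <- array(FALSE, dim(x)); small[1:3, 1, 1] <- TRUE
  expect_error(fit_parenchyma_distribution(x, small), "floor")
  expect_error(fit_parenchyma_distribution(array(5, c(10, 10, 10)),
                                           array(TRUE, c(10, 10, 10))),
               "zero variance")
})

test_that("threshold arithmetic is mu +/- k sigma with k > 0 enforced", {
  m <- structure(list(mu = 100, sigma = 10, method = "moments",
                      n_voxels = 1000, gof = NA_real_), class = "intensity_model")
  expect_equal(compute_threshold(m, 3, "above"), 130)
  m2 <- structure(list(mu = 0, sigma = 0.3, method = "moments",
                       n_voxels = 1000, gof = NA_real_), class = "intensity_model")
  expect_equal(compute_threshold(m2, 2, "below"), -0.6)
  expect_error(compute_threshold(m, 0, "above"), "positive")
})

test_that("no-lesion phantom segments close to the Gaussian 3-sigma tail mass", {
  b <- generate_structural_phantom(phantom_spec(seed = 17L))
  parenchyma <- b$brain & !b$ventricles
  model <- fit_parenchyma_distribution(b$flair, parenchyma)
  seg <- segment_wmh(b$flair, parenchyma, model, k = 3)
  frac <- seg$n_voxels / sum(parenchyma)
  expect_gt(frac, 0.00135 * 0.5)
  expect_lt(frac, 0.00135 * 1.5)
})

test_that("a +6 SD lesion is recovered at the 3-sigma threshold", {
  lesion <- list(center = c(15, 23, 20), radius = 5, offset_sd = 6)
  b <- generate_structural_phantom(seg_flair_spec(list(lesion)))
  parenchyma <- b$brain & !b$ventricles
  model <- fit_parenchyma_distribution(b$flair, parenchyma)
  seg <- segment_wmh(b$flair, parenchyma, model, k = 3, midline_mm = b$midline_mm)
  truth <- sum(b$wmh_truth)
  expect_lt(abs(seg$n_voxels - truth) / truth, 0.05)
  # a threshold far above all signal yields an empty mask
  seg_hi <- segment_wmh(b$flair, parenchyma, model, k = 10)
  expect_equal(seg_hi$n_voxels, 0)
})

test_that("segmented count is monotone in k and hemispheres sum to the total", {
  b <- generate_structural_phantom(
    seg_flair_spec(list(list(center = c(15, 23, 20), radius = 5, offset_sd = 6))))
  parenchyma <- b$brain & !b$ventricles
  model <- fit_parenchyma_distribution(b$flair, parenchyma)
  counts <- vapply(c(1, 2, 3, 4, 6), function(k)
    segment_wmh(b$flair, parenchyma, model, k = k)$n_voxels, numeric(1))
  expect_true(all(diff(counts) <= 0))
  seg <- segment_wmh(b$flair, parenchyma, model, k = 3, midline_mm = b$midline_mm)
  expect_equal(seg$n_left + seg$n_right, seg$n_voxels)
})

# --- DMV segmentation on a directly constructed filtered-phase volume ------

make_dmv_phase <- function(seed = 5L, n_truth_target = 3000L, noise = 0.1,
                           dip = 0.4) {
  set.seed(seed)
  d <- c(40L, 40L, 8L)
  ph <- array(rnorm(prod(d), 0, noise), d)
  truth <- array(FALSE, d)
  truth[6:35, 11:30, 2:6] <- TRUE           # 30 x 20 x 5 = 3000 voxels
  ph[truth] <- ph[truth] - dip
  list(phase = image_volume(ph, c(0.4688, 0.4688, 2.0), "filtered_phase"),
       truth = truth, slab = array(TRUE, d))
}

test_that("a 4-sigma vein dip is counted within 10% of the 3000-voxel truth", {
  px <- make_dmv_phase()
  model <- fit_parenchyma_distribution(px$phase, px$slab & !px$truth)
  seg <- segment_dmv(px$phase, px$slab, model, k = 2)
  expect_lt(abs(seg$n_voxels - 3000) / 3000, 0.10)
})

test_that("exclusion-mask subtraction is exact set subtraction", {
  px <- make_dmv_phase()
  model <- fit_parenchyma_distribution(px$phase, px$slab & !px$truth)
  seg <- segment_dmv(px$phase, px$slab, model, k = 2)
  excl <- array(FALSE, dim(px$phase$data)); excl[10:20, 15:25, 3:4] <- TRUE
  seg2 <- segment_dmv(px$phase, px$slab, model, k = 2, exclusion = excl)
  expect_equal(seg2$n_voxels, seg$n_voxels - sum(seg$mask & excl))
  expect_true(!any(seg2$mask & excl))
})

test_that("zero-vein phase segments close to the 2-sigma lower tail mass", {
  set.seed(8)
  d <- c(40L, 40L, 8L)
  ph <- image_volume(array(rnorm(prod(d), 0, 0.1), d), c(0.4688, 0.4688, 2.0))
  slab <- array(TRUE, d)
  model <- fit_parenchyma_distribution(ph, slab)
  seg <- segment_dmv(ph, slab, model, k = 2)
  frac <- seg$n_voxels / sum(slab)
  expect_gt(frac, 0.02275 * 0.5)
  expect_lt(frac, 0.02275 * 1.5)
})

test_that("segment_dmv contracts: empty slab and off-grid exclusion error", {
  px <- make_dmv_phase()
  model <- fit_parenchyma_distribution(px$phase, px$slab)
  expect_error(segment_dmv(px$phase, array(FALSE, dim(px$phase$data)), model),
               "empty")
  expect_error(segment_dmv(px$phase, px$slab, model,
                           exclusion = array(FALSE, c(2, 2, 2))), "mismatch")
})

test_that("shape rules flag a near-spherical blob but keep thin tubes", {
  d <- c(64L, 64L, 10L)
  sp <- c(0.5, 0.5, 2.0)
  blob <- dmvq:::sphere_mask(d, sp, c(10, 10, 10), 5)        # ~10-mm blob
  tube1 <- dmvq:::rasterize_tube(d, sp, rbind(c(20, 4, 5), c(20, 19, 5)), 0.5)
  tube2 <- dmvq:::rasterize_tube(d, sp, rbind(c(26, 6, 9), c(30, 20, 9)), 0.5)
  set.seed(1)
  ph <- array(rnorm(prod(d), 0, 0.05), d)
  ph[blob | tube1 | tube2] <- -1
  vol <- image_volume(ph, sp, "filtered_phase")
  slab <- array(TRUE, d)
  model <- fit_parenchyma_distribution(vol, slab & !(blob | tube1 | tube2))
  seg <- segment_dmv(vol, slab, model, k = 2)
  flags <- flag_false_dmv_candidates(seg, dmv_shape_rules())
  expect_gte(sum(flags & blob) / sum(blob), 0.95)
  expect_equal(sum(flags & (tube1 | tube2)), 0)
  # empty segmentation flags nothing
  seg_empty <- segment_dmv(vol, slab, model, k = 25)
  expect_equal(sum(flag_false_dmv_candidates(seg_empty, dmv_shape_rules())), 0)
  # all rules disabled: identity configuration
  off <- dmv_shape_rules(min_voxels = NULL, max_volume_mm3 = NULL,
                         min_elongation = NULL, boundary = FALSE)
  expect_equal(sum(flag_false_dmv_candidates(seg, off)), 0)
})
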