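# A compact FLAIR-side spec whose geometry leaves room for a 5-mm lesion
# clear of the ventricles (30 x 30 x 40 mm field of view).
lesion_spec <- function(lesions, seed = 3L) {
  phantom_spec(shape_flair = c(64L, 64L, 8L), spacing_flair = c(0.4688, 0.4688, 5.0),
               shape_swi = c(64L, 64L, 20L), spacing_swi = c(0.4688, 0.4688, 2.0),
               brain_radii_mm = c(13, 13, 18), icv_radii_mm = c(14, 14, 19),
               ventricle_offset_mm = 4, ventricle_radii_mm = c(1.5, 3, 8),
               lesions = lesions, seed = seed)
}

test_that("structural phantom: no lesions means empty truth and Gaussian parenchyma", {
  b <- generate_structural_phantom(lesion_spec(list()))
  expect_equal(sum(b$wmh_truth), 0)
  vals <- b$flair$data[b$brain & !b$ventricles]
  expect_equal(mean(vals), 100, tolerance = 0.5)
  expect_equal(sd(vals), 10, tolerance = 0.5)
  # normality of the parenchyma body: sample quantiles track Gaussian ones
  qs <- quantile(vals, c(0.25, 0.75))
  expect_equal(unname(qs[2] - qs[1]), 2 * qnorm(0.75) * 10, tolerance = 0.5)
})

test_that("voxelized 5-mm sphere volume matches the analytic volume within 15%", {
  # center z between slice centers so both neighbouring 5-mm slices sample it
  lesion <- list(center = c(15, 23, 20), radius = 5, offset_sd = 6)
  b <- generate_structural_phantom(lesion_spec(list(lesion)))
  vol_mm3 <- sum(b$wmh_truth) * voxel_volume_mm3(b$flair$spacing)
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.15)
})

test_that("phantom geometry is seed-independent; noise is not", {
  lesion <- list(center = c(15, 23, 20), radius = 5, offset_sd = 6)
  b1 <- generate_structural_phantom(lesion_spec(list(lesion), seed = 1L))
  b2 <- generate_structural_phantom(lesion_spec(list(lesion), seed = 2L))
  expect_identical(b1$wmh_truth, b2$wmh_truth)
  expect_identical(b1$brain, b2$brain)
  expect_false(identical(b1$flair$data, b2$flair$data))
  # and full determinism under the same seed
  b1b <- generate_structural_phantom(lesion_spec(list(lesion), seed = 1L))
  expect_identical(b1$flair$data, b1b$flair$data)
})

test_that("tissue classes partition the intracranial mask exactly", {
  b <- generate_structural_phantom(lesion_spec(list()))
  parenchyma <- b$brain & !b$ventricles
  rim <- b$icv & !b$brain
  expect_equal(sum(parenchyma) + sum(b$ventricles) + sum(rim), sum(b$icv))
  expect_true(all(b$wmh_truth | !b$wmh_truth))  # masks are logical
  expect_true(!any(b$wmh_truth & b$ventricles))
  expect_true(all(which(b$brain) %in% which(b$icv)))
})

test_that("a lesion poking outside the brain is a geometry error", {
  bad <- list(center = c(28, 15, 20), radius = 5, offset_sd = 6)
  expect_error(generate_structural_phantom(lesion_spec(list(bad))), "geometry")
})

test_that("SWI phantom: zero background and noise leaves exactly the vein dips", {
  vein <- list(polyline = rbind(c(10, 22, 19), c(20, 22, 19)),
               radius = 0.5, depth = 0.8)
  spec <- phantom_spec(shape_swi = c(64L, 64L, 20L),
                       brain_radii_mm = c(13, 13, 18), icv_radii_mm = c(14, 14, 19),
                       ventricle_offset_mm = 4, ventricle_radii_mm = c(1.5, 3, 8),
                       background_phase = rep(0, 10), phase_noise_sd = 0,
                       magnitude_noise_sd = 0, veins = list(vein), seed = 5L)
  b <- generate_swi_phantom(spec)
  expect_gt(sum(b$vein_truth), 0)
  expect_equal(b$gre$phase$data, -0.8 * b$vein_truth, ignore_attr = TRUE)
})

test_that("a 0.5-mm vein rasterizes 1-2 voxels wide in-plane", {
  vein <- list(polyline = rbind(c(10, 22, 19), c(20, 22, 19)),
               radius = 0.5, depth = 0.8)
  spec <- phantom_spec(shape_swi = c(64L, 64L, 20L),
                       brain_radii_mm = c(13, 13, 18), icv_radii_mm = c(14, 14, 19),
                       ventricle_offset_mm = 4, ventricle_radii_mm = c(1.5, 3, 8),
                       phase_noise_sd = 0, veins = list(vein), seed = 5L)
  b <- generate_swi_phantom(spec)
  z <- 10L  # slice containing the vein (z = 19 mm, 2-mm slices)
  sl <- b$vein_truth[, , z]
  widths <- rowSums(sl)[rowSums(sl) > 0]   # voxels across the vein per x column
  expect_true(all(widths %in% 1:3))
  expect_gte(mean(widths %in% 1:2), 0.9)
})

test_that("background-only spec yields an empty vein truth mask", {
  spec <- phantom_spec(shape_swi = c(64L, 64L, 20L),
                       brain_radii_mm = c(13, 13, 18), icv_radii_mm = c(14, 14, 19),
                       ventricle_offset_mm = 4, ventricle_radii_mm = c(1.5, 3, 8))
  b <- generate_swi_phantom(spec)
  expect_equal(sum(b$vein_truth), 0)
  expect_true(all(b$gre$phase$data > -pi & b$gre$phase$data <= pi))
})

test_that("phase outside the principal interval errors when wrapping is off", {
  spec <- phantom_spec(shape_swi = c(64L, 64L, 20L),
                       brain_radii_mm = c(13, 13, 18), icv_radii_mm = c(14, 14, 19),
                       ventricle_offset_mm = 4, ventricle_radii_mm = c(1.5, 3, 8),
                       background_phase = c(-3.0, rep(0, 9)),
                       veins = list(list(polyline = rbind(c(10, 22, 19), c(20, 22, 19)),
                                         radius = 0.5, depth = 0.8)),
                       phase_noise_sd = 0, wrap = FALSE)
  expect_error(generate_swi_phantom(spec), "wrap")
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(brain_radii_mm = c(0, 10, 10)), "radii")
  expect_error(phantom_spec(veins = list(list(polyline = rbind(c(0, 0, 0), c(1, 1, 1)),
                                              radius = 0.5, depth = 4))), "0, pi")
  expect_error(phantom_spec(lesions = list(list(center = c(1, 1, 1), radius = -2,
                                                offset_sd = 6))), "radius")
})

# ---------------------------------------------------------------------------

test_that("cohort generator hits a zero partial correlation at n = 5000", {
  spec <- cohort_spec(n = 5000L, target_partial_r = 0, seed = 9L)
  tab <- generate_cohort_table(spec)
  Z <- tab[, c("age", "sex", "education", "microbleeds", "lacunes")]
  res <- partial_pearson(log(tab$cwmhv), tab$dmv_count, Z)
  expect_lt(abs(res$r), 0.04)
})

test_that("cohort generator hits a 0.5 partial correlation within its 95% CI", {
  spec <- cohort_spec(n = 2000L, target_partial_r = 0.5, seed = 21L)
  tab <- generate_cohort_table(spec)
  Z <- tab[, c("age", "sex", "education", "microbleeds", "lacunes")]
  res <- partial_pearson(log(tab$cwmhv), tab$dmv_count, Z)
  halfwidth <- 1.96 / sqrt(res$n - length(Z) - 3)
  expect_lt(abs(atanh(res$r) - atanh(0.5)), halfwidth)
})

test_that("generating correlation structure implies the target analytically", {
  for (target in c(-0.4, 0, 0.506, 0.8)) {
    spec <- cohort_spec(n = 100L, target_partial_r = target)
    expect_equal(population_partial_correlation(spec), target, tolerance = 1e-12)
  }
})

test_that("cohort spec rejects degenerate configurations", {
  expect_error(cohort_spec(n = 7L), "n >= #covariates \\+ 3")
  expect_error(cohort_spec(target_partial_r = 1), "\\(-1, 1\\)")
  expect_error(cohort_spec(x_loadings = c(age = 0.9, sex = 0.5, education = 0,
                                          microbleeds = 0, lacunes = 0.5)),
               "positive definite")
})

test_that("cohort tables are deterministic under the seed and well-formed", {
  t1 <- generate_cohort_table(cohort_spec(n = 50L, seed = 4L))
  t2 <- generate_cohort_table(cohort_spec(n = 50L, seed = 4L))
  expect_identical(t1, t2)
  expect_false(anyDuplicated(t1$subject_id) > 0)
  expect_true(all(t1$cwmhv > 0))
  expect_true(all(t1$dmv_count >= 0))
  expect_true(all(t1$microbleeds == round(t1$microbleeds) & t1$microbleeds >= 0))
  expect_equal(t1$dmv_left + t1$dmv_right, t1$dmv_count)
})
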