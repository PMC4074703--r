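# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# compact two-sided phantom spec used by several pipeline-level tests
small_subject_spec <- function(seed = 11L, veins = TRUE, lesions = TRUE,
                               n_inplane = 96L) {
  base <- phantom_spec(shape_swi = c(n_inplane, n_inplane, 25L),
                       shape_flair = c(n_inplane, n_inplane, 10L),
                       seed = seed)
  vl <- if (veins) dmv_vein_set(base, slices = 11:15, n_per_slice = 6,
                                length_mm = 7) else list()
  fov <- base$shape_flair * base$spacing_flair
  ll <- if (lesions) list(
    list(center = fov / 2 + c(-9, 9, 0), radius = 5, offset_sd = 6),
    list(center = fov / 2 + c(10, -8, -5), radius = 4, offset_sd = 6)
  ) else list()
  phantom_spec(shape_swi = base$shape_swi, shape_flair = base$shape_flair,
               veins = vl, lesions = ll, seed = seed)
}

# multivariate normal draw via Cholesky (avoids extra dependencies)
rmvn <- function(n, R) {
  Z <- matrix(stats::rnorm(n * ncol(R)), n)
  Z %*% chol(R)
}

# brute-force O(n^2) distance from every voxel to the nearest seed voxel (mm)
brute_force_distance <- function(seeds, shape, spacing) {
  seed_idx <- which(seeds)
  sp <- arrayInd(seed_idx, shape)
  sp_mm <- sweep(sp - 0.5, 2, spacing, "*")
  out <- array(Inf, shape)
  all_idx <- seq_len(prod(shape))
  pp <- arrayInd(all_idx, shape)
  pp_mm <- sweep(pp - 0.5, 2, spacing, "*")
  for (i in seq_len(nrow(sp_mm))) {
    d <- sqrt((pp_mm[, 1] - sp_mm[i, 1])^2 + (pp_mm[, 2] - sp_mm[i, 2])^2 +
              (pp_mm[, 3] - sp_mm[i, 3])^2)
    out[all_idx] <- pmin(out[all_idx], d)
  }
  out
}

# independent two-sided Fisher p for a 2x2 table from the hypergeometric pmf
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
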