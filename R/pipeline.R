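#' Pipeline configuration
#'
#' Collects the measurement-chain constants. The defaults are the published
#' protocol constants: WMH threshold k = 3 (above), DMV threshold k = 2
#' (below), 32 x 32 filter central matrix, 5 periventricular slices, 10 mm
#' PVH distance.
#'
#' @param k_wmh SD multiplier for the FLAIR hyperintensity threshold.
#' @param k_dmv SD multiplier for the phase hypointensity threshold.
#' @param central_matrix homodyne filter central matrix size.
#' @param n_slices periventricular slab size (slices).
#' @param pvh_distance_mm periventricular/deep cutoff distance.
#' @param auto_exclude apply [flag_false_dmv_candidates()] automatically as
#'   the exclusion mask (the automated surrogate for manual false-vein
#'   removal).
#' @param shape_rules rule list for the flagger, see [dmv_shape_rules()].
#' @param coregistration `"identity"` (FLAIR and phase already aligned, as
#'   for same-geometry phantoms) or `"estimate"` (run [rigid_coregister()]
#'   with FLAIR moving and phase fixed).
#' @param coreg_metric similarity metric when estimating, `"nmi"` or `"mse"`.
#' @param min_cohort minimum cohort size for the statistics layer.
#' @param seed RNG seed recorded with the run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_wmh = 3, k_dmv = 2, central_matrix = 32L,
                            n_slices = 5L, pvh_distance_mm = 10,
                            auto_exclude = TRUE,
                            shape_rules = dmv_shape_rules(),
                            coregistration = c("identity", "estimate"),
                            coreg_metric = "nmi",
                            min_cohort = 10L, seed = 1L) {
  coregistration <- match.arg(coregistration)
  structure(list(k_wmh = k_wmh, k_dmv = k_dmv,
                 central_matrix = as.integer(central_matrix),
                 n_slices = as.integer(n_slices),
                 pvh_distance_mm = pvh_distance_mm,
                 auto_exclude = isTRUE(auto_exclude),
                 shape_rules = shape_rules,
                 coregistration = coregistration,
                 coreg_metric = coreg_metric,
                 min_cohort = as.integer(min_cohort),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_error <- function(stage, e) {
  stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the subject-level measurement chain
#'
#' Executes filter -> fit -> segment (DMV and WMH) -> coregister ->
#' volumetrics on one subject and returns the derived quantities. The
#' corrected volumes (CWMHV etc.) need the cohort mean ICV and are bound
#' later by [run_cohort()].
#'
#' @param subject a `phantom_bundle` (see [generate_phantom_bundle()]) or a
#'   list with the same fields: `flair`, `gre`, FLAIR-grid masks `brain`,
#'   `ventricles`, `icv`, GRE-grid masks `brain_gre`, `ventricles_gre`,
#'   `bg_top_slice`, `midline_mm`, and optionally `exclusion` (manual
#'   false-vein mask on the GRE grid) and `subject_id`.
#' @param config a [pipeline_config()].
#' @return object of class `subject_measurements`: raw volumes (ml)
#'   `wmhv`, `icv`, `pvh`, `dwmh`, `regional_wmhv`, counts `dmv_count`,
#'   `dmv_left`, `dmv_right`, `slab` slice indices, and the intermediate
#'   segmentations (`seg_wmh`, `seg_dmv`).
#' @export
run_subject <- function(subject, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("flair", "gre", "brain", "ventricles", "icv",
            "brain_gre", "ventricles_gre", "bg_top_slice")
  for (f in need)
    if (is.null(subject[[f]]))
      stop(sprintf("[stage inputs] subject is missing `%s`%s", f,
                   if (f == "ventricles_gre")
                     " (the ventricle mask on the phase grid is required for slab selection)"
                   else ""), call. = FALSE)
  midline <- subject$midline_mm
  # -- phase filtering ------------------------------------------------------
  fphase <- tryCatch(
    homodyne_highpass_filter(subject$gre, config$central_matrix),
    error = function(e) stage_error("filter", e))
  # -- slab selection -------------------------------------------------------
  slab <- tryCatch(
    select_periventricular_slab(subject$ventricles_gre, subject$bg_top_slice,
                                config$n_slices),
    error = function(e) stage_error("slab-selection", e))
  slab_mask <- restrict_to_slab(subject$brain_gre & !subject$ventricles_gre, slab)
  # -- DMV segmentation -----------------------------------------------------
  seg_dmv <- tryCatch({
    model_phase <- fit_parenchyma_distribution(fphase$phase, slab_mask)
    seg0 <- segment_dmv(fphase, slab_mask, model_phase, k = config$k_dmv,
                        midline_mm = midline)
    excl <- subject$exclusion
    if (config$auto_exclude) {
      flags <- flag_false_dmv_candidates(seg0, config$shape_rules)
      excl <- if (is.null(excl)) flags else (as_mask(excl) | flags)
    }
    if (is.null(excl)) seg0
    else segment_dmv(fphase, slab_mask, model_phase, k = config$k_dmv,
                     exclusion = excl, midline_mm = midline)
  }, error = function(e) stage_error("segment-dmv", e))
  # -- WMH segmentation -----------------------------------------------------
  seg_wmh <- tryCatch({
    parenchyma <- subject$brain & !subject$ventricles
    model_flair <- fit_parenchyma_distribution(subject$flair, parenchyma)
    segment_wmh(subject$flair, parenchyma, model_flair, k = config$k_wmh,
                midline_mm = midline)
  }, error = function(e) stage_error("segment-wmh", e))
  # -- volumetrics ----------------------------------------------------------
  sp_flair <- subject$flair$spacing
  sp_gre <- subject$gre$spacing
  wmhv <- mask_volume_ml(seg_wmh$mask, sp_flair)
  icv_ml <- tryCatch(
    compute_icv(subject$icv, sp_flair,
                parenchyma_ml = mask_volume_ml(subject$brain, sp_flair)),
    error = function(e) stage_error("icv", e))
  part <- tryCatch(
    partition_pvh_dwmh(seg_wmh$mask, subject$ventricles, sp_flair,
                       config$pvh_distance_mm),
    error = function(e) stage_error("pvh-partition", e))
  # -- coregistration of the WMH mask onto the phase grid -------------------
  wmh_on_phase <- tryCatch({
    tr <- if (config$coregistration == "estimate") {
      rigid_coregister(subject$flair,
                       subject$gre$magnitude,
                       metric = config$coreg_metric)
    } else rigid_transform()
    resample_mask(seg_wmh$mask, tr,
                  target_shape = dim(subject$gre$magnitude$data),
                  target_spacing = sp_gre, spacing = sp_flair)
  }, error = function(e) stage_error("coregister", e))
  regional_raw <- mask_volume_ml(restrict_to_slab(wmh_on_phase, slab), sp_gre)
  structure(list(subject_id = subject$subject_id %||% "subject",
                 wmhv = wmhv, icv = icv_ml,
                 pvh = mask_volume_ml(part$pvh, sp_flair),
                 dwmh = mask_volume_ml(part$dwmh, sp_flair),
                 regional_wmhv = regional_raw,
                 dmv_count = seg_dmv$n_voxels,
                 dmv_left = seg_dmv$n_left, dmv_right = seg_dmv$n_right,
                 slab = slab,
                 seg_wmh = seg_wmh, seg_dmv = seg_dmv,
                 config = config),
            class = "subject_measurements")
}

#' @export
print.subject_measurements <- function(x, ...) {
  cat(sprintf("<subject_measurements> %s\n", x$subject_id))
  cat(sprintf("  WMHV %.2f ml (PVH %.2f + DWMH %.2f), ICV %.1f ml, regional %.2f ml\n",
              x$wmhv, x$pvh, x$dwmh, x$icv, x$regional_wmhv))
  cat(sprintf("  DMV voxels %d (L %d / R %d), slab slices %s\n",
              x$dmv_count, x$dmv_left, x$dmv_right,
              paste(range(x$slab), collapse = "-")))
  invisible(x)
}

measurements_to_table <- function(measurements) {
  rows <- lapply(measurements, function(m)
    data.frame(subject_id = m$subject_id, wmhv = m$wmhv, icv = m$icv,
               pvh = m$pvh, dwmh = m$dwmh, regional_wmhv = m$regional_wmhv,
               dmv_count = m$dmv_count, dmv_left = m$dmv_left,
               dmv_right = m$dmv_right, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Run the cohort-level analysis
#'
#' Binds the cohort mean ICV (always recomputed from the cohort at hand,
#' never cached), derives the corrected volumes
#' `CWMHV = WMHV x meanICV / ICV` (and corrected PVH / DWMH / regional
#' volumes when available), and runs the statistical plan: median split of
#' CWMHV, group comparisons (Welch t-test for continuous variables,
#' Fisher's exact test for categorical ones), partial Pearson correlation
#' between log-CWMHV and DMV count given the adjustment covariates (raw and
#' Bonferroni-adjusted p side by side), and backward stepwise logistic
#' regression for large CWMHV with age forced and MMSE excluded.
#'
#' @param cohort either a list of `subject_measurements` (from
#'   [run_subject()]), optionally with a data.frame of covariates attached
#'   via `covariates`, or a `cohort_table` data.frame (e.g. from
#'   [generate_cohort_table()]). A table must carry either `cwmhv` or both
#'   `wmhv` and `icv`.
#' @param config a [pipeline_config()].
#' @param covariates optional covariate data.frame joined by row order when
#'   `cohort` is a measurements list.
#' @return object of class `cohort_report`: `table` (with corrected
#'   volumes), `mean_icv`, `split` (median dichotomization), `group_tests`,
#'   `associations` (partial correlations with raw/adjusted p),
#'   `stepwise` (when covariates allow it).
#' @export
run_cohort <- function(cohort, config = pipeline_config(), covariates = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.list(cohort) && !is.data.frame(cohort) &&
      all(vapply(cohort, inherits, logical(1), "subject_measurements"))) {
    tab <- measurements_to_table(cohort)
    if (!is.null(covariates)) {
      stopifnot(nrow(covariates) == nrow(tab))
      tab <- cbind(tab, covariates[, setdiff(colnames(covariates), colnames(tab)),
                                   drop = FALSE])
    }
  } else {
    tab <- as.data.frame(cohort)
  }
  if (anyDuplicated(tab$subject_id))
    stop("duplicated subject ids", call. = FALSE)
  n <- nrow(tab)
  if (n < config$min_cohort)
    stop(sprintf("cohort has %d subjects, below the floor of %d", n,
                 config$min_cohort), call. = FALSE)
  mean_icv <- NA_real_
  if (all(c("wmhv", "icv") %in% colnames(tab))) {
    mean_icv <- mean(tab$icv)
    tab$cwmhv <- corrected_volume(tab$wmhv, tab$icv, mean_icv)
    for (col in c("pvh", "dwmh", "regional_wmhv")) {
      if (col %in% colnames(tab))
        tab[[paste0("c", col)]] <- corrected_volume(tab[[col]], tab$icv, mean_icv)
    }
  }
  if (!"cwmhv" %in% colnames(tab))
    stop("cohort table needs `cwmhv` or both `wmhv` and `icv`", call. = FALSE)
  split <- dichotomize_at_median(tab$cwmhv)
  grp <- split$labels
  # --- group comparisons (Table-1 layout) ---------------------------------
  continuous <- intersect(c("age", "education", "mmse", "sbp", "dbp", "glucose",
                            "tc", "thcy", "hscrp", "microbleeds", "lacunes",
                            "dmv_count"), colnames(tab))
  categorical <- intersect(c("sex", "hypertension", "diabetes", "hyperlipidemia"),
                           colnames(tab))
  group_tests <- list()
  for (v in continuous) {
    tt <- two_sample_t_test(tab[[v]][grp == "low"], tab[[v]][grp == "high"])
    group_tests[[v]] <- data.frame(variable = v, type = "t",
                                   low = tt$mean_a, high = tt$mean_b,
                                   statistic = tt$t, p = tt$p,
                                   stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    ct <- table(grp, tab[[v]])
    if (ncol(ct) < 2) next
    p <- fisher_exact(ct)
    group_tests[[v]] <- data.frame(variable = v, type = "fisher",
                                   low = NA_real_, high = NA_real_,
                                   statistic = NA_real_, p = p,
                                   stringsAsFactors = FALSE)
  }
  group_tests <- do.call(rbind, group_tests)
  # --- partial correlations -----------------------------------------------
  adjust_cols <- intersect(c("age", "sex", "education", "microbleeds", "lacunes"),
                           colnames(tab))
  associations <- NULL
  if ("dmv_count" %in% colnames(tab) && length(adjust_cols)) {
    Z <- tab[, adjust_cols, drop = FALSE]
    targets <- c(cwmhv = "cwmhv",
                 cpvh = "cpvh", cdwmh = "cdwmh",
                 cregional = "cregional_wmhv")
    targets <- targets[targets %in% colnames(tab)]
    res <- lapply(targets, function(col) {
      ok <- tab[[col]] > 0
      partial_pearson(natural_log_transform(tab[[col]][ok]),
                      tab$dmv_count[ok], Z[ok, , drop = FALSE])
    })
    raw_p <- vapply(res, `[[`, numeric(1), "p")
    associations <- data.frame(volume = names(targets),
                               partial_r = vapply(res, `[[`, numeric(1), "r"),
                               plain_r = vapply(res, `[[`, numeric(1), "plain_r"),
                               df = vapply(res, `[[`, numeric(1), "df"),
                               p = raw_p,
                               p_bonferroni = bonferroni_adjust(raw_p),
                               stringsAsFactors = FALSE)
  }
  # --- stepwise logistic regression ---------------------------------------
  stepwise <- NULL
  cand_pool <- intersect(c("sex", "education", "dmv_k", "sbp", "dbp", "glucose",
                           "tc", "thcy", "hscrp", "microbleeds", "lacunes"),
                         c(colnames(tab), "dmv_k"))
  if ("age" %in% colnames(tab) && "dmv_count" %in% colnames(tab)) {
    Xs <- tab[, intersect(cand_pool, colnames(tab)), drop = FALSE]
    Xs$dmv_k <- tab$dmv_count / 1000   # per-10^3-voxel odds ratio convention
    Xs$age <- tab$age
    y <- as.integer(grp == "high")
    # demographics and the vein count enter regardless of the univariate
    # screen; the remaining clinical variables must pass it (p < 0.1)
    always_in <- intersect(c("sex", "education", "dmv_k"), colnames(Xs))
    screened <- setdiff(colnames(Xs), c("age", always_in))
    keep <- vapply(screened, function(v) {
      full <- fit_logistic(y, Xs[, v, drop = FALSE])
      null <- fit_logistic(y, NULL)
      stats::pchisq(2 * (full$log_lik - null$log_lik), 1, lower.tail = FALSE) < 0.1
    }, logical(1))
    stepwise <- tryCatch(
      backward_stepwise_logistic(
        y, Xs, forced = "age",
        candidates = c(always_in, screened[keep]),
        p_remove = 0.10, p_screen = NULL),
      error = function(e) { warning(conditionMessage(e), call. = FALSE); NULL })
  }
  structure(list(table = tab, n = n, mean_icv = mean_icv, split = split,
                 group_tests = group_tests, associations = associations,
                 stepwise = stepwise, config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d, median CWMHV cutoff = %.2f ml", x$n,
              x$split$cutoff))
  if (!is.na(x$mean_icv)) cat(sprintf(", mean ICV = %.1f ml", x$mean_icv))
  cat("\n")
  if (!is.null(x$associations)) {
    cat("  partial correlations with DMV count (adjusted):\n")
    print(within(x$associations, {
      partial_r <- round(partial_r, 3); plain_r <- round(plain_r, 3)
      p <- signif(p, 3); p_bonferroni <- signif(p_bonferroni, 3)
    }), row.names = FALSE)
  }
  if (!is.null(x$stepwise)) {
    cat("  stepwise model retained:", paste(x$stepwise$retained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cohort report as JSON
#'
#' @param report a `cohort_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  out <- list(n = report$n, mean_icv = report$mean_icv,
              median_cutoff = report$split$cutoff,
              group_tests = report$group_tests,
              associations = report$associations)
  if (!is.null(report$stepwise)) {
    out$stepwise <- list(retained = report$stepwise$retained,
                         coefficients = report$stepwise$model$coefficients,
                         trace = report$stepwise$trace)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
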