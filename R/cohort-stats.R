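#' Natural log transform of positive values
#'
#' Volume distributions are right-skewed; the correlation analysis works on
#' natural-log-transformed volumes.
#'
#' @param values numeric vector, all > 0.
#' @return `log(values)`.
#' @export
natural_log_transform <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop(sprintf("non-positive value at row %s; cannot log-transform",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  log(values)
}

#' Dichotomize at the sample median
#'
#' Splits at the sample median with ties going to the low group
#' (low: value <= cutoff, high: value > cutoff), the \code{<=}/\code{>}
#' convention of a median split such as small (<= 25 ml) versus large
#' (> 25 ml) corrected WMH volume.
#'
#' @param values numeric vector, length >= 2.
#' @return list: `labels` (factor `low`/`high`), `cutoff`, `n_low`, `n_high`.
#' @export
dichotomize_at_median <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("all values identical; median split is degenerate", call. = FALSE)
  cutoff <- stats::median(values)
  labels <- factor(ifelse(values <= cutoff, "low", "high"), levels = c("low", "high"))
  list(labels = labels, cutoff = cutoff,
       n_low = sum(labels == "low"), n_high = sum(labels == "high"))
}

#' Partial Pearson correlation by residualization
#'
#' Correlation between `x` and `y` with the linear effect of a covariate set
#' removed from both: each of `x` and `y` is residualized on
#' `[intercept + covariates]` by ordinary least squares and the partial r is
#' the Pearson correlation of the residual vectors. The p-value comes from
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - k - 2` (k covariates),
#' two-sided. With an empty covariate set this reduces to the plain Pearson
#' correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame (n rows).
#' @return object of class `association_result`: `r` (partial), `plain_r`,
#'   `df`, `p`, `n`, `covariates` (names).
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0 || length(covariates) == 0) {
    Z <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) stop("covariate rows must match length(x)", call. = FALSE)
  }
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > #covariates + 2", call. = FALSE)
  X <- cbind(`(intercept)` = 1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient (collinear: ",
         paste(drop, collapse = ", "), ")", call. = FALSE)
  }
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, plain_r = stats::cor(x, y), df = df, t = tval, p = p,
                 n = n, covariates = colnames(Z)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> partial r = %.3f (plain r = %.3f), df = %d, p = %.3g\n",
              x$r, x$plain_r, x$df, x$p))
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Two-sample t-test (Welch by default)
#'
#' Independent-samples two-tailed t-test. Welch (unequal variances) is the
#' default; `var_equal = TRUE` gives the pooled-variance variant. The
#' degenerate case of zero variance in both groups with equal means is the
#' defined limit t = 0, p = 1.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal pooled-variance variant if `TRUE`.
#' @return list `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

# log multivariate-hypergeometric probability of a full r x c table given margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# enumerate all r x c tables with the given margins, applying FUN(tab)
enumerate_margin_tables <- function(row_margins, col_margins, fun) {
  r <- length(row_margins); cc <- length(col_margins)
  tab <- matrix(0L, r, cc)
  rec_row <- function(i, col_left) {
    if (i == r) {
      tab[r, ] <<- col_left
      fun(tab)
      return(invisible(NULL))
    }
    fill_cell <- function(j, row_left, col_left) {
      if (j == cc) {
        if (row_left <= col_left[cc]) {
          tab[i, cc] <<- row_left
          rec_row(i + 1L, col_left - tab[i, ])
        }
        return(invisible(NULL))
      }
      for (v in 0:min(row_left, col_left[j])) {
        tab[i, j] <<- v
        fill_cell(j + 1L, row_left - v, col_left)
      }
    }
    fill_cell(1L, row_margins[i], col_left)
  }
  rec_row(1L, col_margins)
  invisible(NULL)
}

#' Fisher's exact test by full enumeration
#'
#' Two-sided exact test for an r x c contingency table of counts with both
#' margins fixed: every table with the observed margins is enumerated, its
#' conditional (multivariate hypergeometric) probability computed, and the
#' p-value is the sum of the probabilities of all tables no more probable
#' than the observed one (the probability method). Enumeration is budgeted
#' at `r * c <= 12` cells; larger tables raise an error suggesting a
#' chi-square approximation instead (not applied automatically).
#'
#' @param table matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (length(tab) > 12)
    stop(sprintf("table has %d cells, beyond the enumeration budget of 12; use a chi-square approximation",
                 length(tab)), call. = FALSE)
  rm <- rowSums(tab); cm <- colSums(tab)
  if (sum(rm) == 0) return(1)
  lp_obs <- log_table_prob(tab)
  total <- 0
  enumerate_margin_tables(rm, cm, function(t2) {
    lp <- log_table_prob(t2)
    if (lp <= lp_obs + 1e-7) total <<- total + exp(lp)
  })
  min(total, 1)
}

#' Logistic regression fit (maximum likelihood)
#'
#' Binomial GLM with logit link, fitted by iteratively reweighted least
#' squares, with explicit guards for the failure modes that matter in a
#' stepwise procedure: both outcome classes must be present, the design
#' must be full rank (collinear columns are named), and (quasi-)separation
#' is detected from diverging coefficients / degenerate fitted
#' probabilities and raised as an error.
#'
#' @param y 0/1 (or logical/2-level factor) outcome.
#' @param X numeric design matrix or data.frame of predictors (no
#'   intercept column; one is added).
#' @return object of class `dmv_logistic`: `coefficients` data.frame
#'   (estimate, se, or, ci_low, ci_high, z, p per term), `log_lik`,
#'   `converged`, `n`.
#' @export
fit_logistic <- function(y, X = NULL) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("both outcome classes must be present", call. = FALSE)
  if (is.null(X) || NCOL(X) == 0) {
    Xm <- matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    Xm <- as.matrix(X)
    if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
  }
  design <- cbind(`(Intercept)` = 1, Xm)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("collinear predictors: ", paste(drop, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100)))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  if (any(abs(beta) > 15) || all(mu > 1 - 1e-8 | mu < 1e-8))
    stop("separation detected: coefficients diverge (|beta| > 15)", call. = FALSE)
  w <- mu * (1 - mu)
  info <- crossprod(design * sqrt(w))
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  coefs <- data.frame(term = colnames(design), estimate = unname(beta),
                      se = unname(se), or = exp(unname(beta)),
                      ci_low = exp(unname(beta - 1.96 * se)),
                      ci_high = exp(unname(beta + 1.96 * se)),
                      z = unname(z), p = unname(p),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, log_lik = ll,
                 converged = fit$converged, n = length(y)),
            class = "dmv_logistic")
}

#' @export
print.dmv_logistic <- function(x, ...) {
  cat(sprintf("<dmv_logistic> n = %d, logLik = %.3f\n", x$n, x$log_lik))
  co <- x$coefficients
  co[, -1] <- lapply(co[, -1], function(v) signif(v, 4))
  print(co, row.names = FALSE)
  invisible(x)
}

#' Backward stepwise logistic regression with forced covariates
#'
#' Realizes the backward elimination plan: candidates are screened by
#' univariate logistic regression (kept when p < `p_screen`), the full
#' model (forced variables + surviving candidates) is fitted, and the
#' non-forced variable with the largest likelihood-ratio removal p-value is
#' removed while that p exceeds `p_remove` (exact refit LR tests, not the
#' conditional-estimate approximation). Forced variables are never removed.
#'
#' @param y binary outcome.
#' @param X data.frame / matrix of all variables (columns named).
#' @param forced character vector of variables always kept (e.g. age).
#' @param candidates character vector of removable candidate variables;
#'   default: all non-forced columns of `X`.
#' @param p_remove removal threshold on the LR p-value, default 0.10.
#' @param p_screen univariate screen threshold, default 0.10; `NULL` skips
#'   the screen and enters all candidates.
#' @return object of class `dmv_stepwise`: final `model` (a
#'   `dmv_logistic`), `retained`, `trace` (data.frame of removals: variable,
#'   step, p), `screen` (data.frame of univariate screen results).
#' @export
backward_stepwise_logistic <- function(y, X, forced = character(),
                                       candidates = NULL,
                                       p_remove = 0.10, p_screen = 0.10) {
  X <- as.data.frame(X)
  if (is.null(candidates)) candidates <- setdiff(colnames(X), forced)
  missing_cols <- setdiff(c(forced, candidates), colnames(X))
  if (length(missing_cols))
    stop("variables not in X: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  screen_tab <- NULL
  if (!is.null(p_screen) && length(candidates)) {
    sp <- vapply(candidates, function(v) {
      full <- fit_logistic(y, X[, v, drop = FALSE])
      null <- fit_logistic(y, NULL)
      stats::pchisq(2 * (full$log_lik - null$log_lik), df = 1, lower.tail = FALSE)
    }, numeric(1))
    screen_tab <- data.frame(variable = candidates, p_univariate = unname(sp),
                             kept = unname(sp < p_screen), stringsAsFactors = FALSE)
    candidates <- candidates[sp < p_screen]
  }
  vars <- unique(c(forced, candidates))
  if (length(vars) == 0)
    stop("no variables survive the screen and none are forced", call. = FALSE)
  trace <- data.frame(variable = character(), step = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  step <- 0L
  model <- fit_logistic(y, X[, vars, drop = FALSE])
  repeat {
    removable <- setdiff(vars, forced)
    if (length(removable) == 0) break
    pvals <- vapply(removable, function(v) {
      reduced_vars <- setdiff(vars, v)
      reduced <- if (length(reduced_vars))
        fit_logistic(y, X[, reduced_vars, drop = FALSE]) else fit_logistic(y, NULL)
      stats::pchisq(2 * (model$log_lik - reduced$log_lik), df = 1,
                    lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= p_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(variable = removable[worst], step = step,
                                     p = unname(pvals[worst]),
                                     stringsAsFactors = FALSE))
    vars <- setdiff(vars, removable[worst])
    model <- if (length(vars)) fit_logistic(y, X[, vars, drop = FALSE])
             else fit_logistic(y, NULL)
  }
  structure(list(model = model, retained = vars, forced = forced,
                 trace = trace, screen = screen_tab),
            class = "dmv_stepwise")
}

#' @export
print.dmv_stepwise <- function(x, ...) {
  cat("<dmv_stepwise> retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$trace)) {
    cat("  removed:\n")
    print(x$trace, row.names = FALSE)
  } else cat("  nothing removed\n")
  invisible(x)
}

#' Intraclass correlation coefficient (two-way, single measures)
#'
#' Inter-rater reliability from the two-way ANOVA decomposition of a
#' complete subjects x raters matrix into subject, rater and error mean
#' squares. `"agreement"` (absolute agreement, ICC(2,1)) includes the rater
#' variance in the denominator; `"consistency"` (ICC(3,1)) excludes it, so
#' a constant shift between raters leaves consistency at 1 but lowers
#' agreement.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (n >= 5 subjects, k >= 2 raters, complete).
#' @param form `"agreement"` (default) or `"consistency"`.
#' @return object of class `icc_result`: `icc`, `form`, mean squares
#'   (`ms_subjects`, `ms_raters`, `ms_error`), variance components
#'   (`var_subjects`, `var_raters`, `var_error`), `n`, `k`.
#' @export
icc <- function(ratings, form = c("agreement", "consistency")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must be complete", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_rater <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  msr <- ss_subj / (n - 1)      # subjects
  msc <- ss_rater / (k - 1)     # raters
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 || ss_subj < 1e-12 * max(ss_tot, 1))
    stop("no between-subject variance; ICC undefined", call. = FALSE)
  icc_val <- if (form == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  structure(list(icc = icc_val, form = form, model = "two-way, single measures",
                 ms_subjects = msr, ms_raters = msc, ms_error = mse,
                 var_subjects = (msr - mse) / k,
                 var_raters = max((msc - mse) / n, 0),
                 var_error = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (%s, %s; %d subjects x %d raters)\n",
              x$icc, x$model, x$form, x$n, x$k))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for each of the m p-values; order-preserving.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, pvalues * length(pvalues))
}
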