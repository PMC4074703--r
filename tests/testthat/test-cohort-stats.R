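test_that("natural log transform is exact and inverts", {
  expect_equal(natural_log_transform(1), 0)
  expect_equal(natural_log_transform(exp(1)), 1)
  set.seed(1)
  v <- rlnorm(5000, 1, 0.8)
  lt <- natural_log_transform(v)
  expect_equal(exp(lt), v)
  skw <- mean((lt - mean(lt))^3) / sd(lt)^3
  expect_lt(abs(skw), 0.2)            # lognormal becomes symmetric
  expect_error(natural_log_transform(c(2, 0, 3)), "row 2")
})

test_that("median dichotomization uses the <=/> tie rule", {
  d <- dichotomize_at_median(c(1, 2, 3, 4))
  expect_equal(d$cutoff, 2.5)
  expect_equal(as.character(d$labels), c("low", "low", "high", "high"))
  d2 <- dichotomize_at_median(c(1, 2, 2, 5, 9))
  expect_equal(d2$cutoff, 2)
  expect_equal(as.character(d2$labels)[2:3], c("low", "low"))  # ties go low
  expect_error(dichotomize_at_median(rep(7, 10)), "identical")
  expect_error(dichotomize_at_median(5), "at least 2")
})

test_that("partial correlation reduces to plain Pearson without covariates", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  res <- partial_pearson(x, y)
  expect_equal(res$r, 1)
  set.seed(2)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  expect_equal(partial_pearson(a, b)$r, cor(a, b))
})

test_that("partial correlation equals the closed-form matrix expression", {
  # trivariate normal with generating partial correlation 0.5:
  # r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
  r_xz <- 0.5; r_yz <- 0.5
  r_xy <- 0.5 * sqrt((1 - r_xz^2) * (1 - r_yz^2)) + r_xz * r_yz  # = 0.625
  R <- matrix(c(1, r_xy, r_xz, r_xy, 1, r_yz, r_xz, r_yz, 1), 3)
  closed_form <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(closed_form, 0.5)
  set.seed(11)
  X <- rmvn(2000, R)
  res <- partial_pearson(X[, 1], X[, 2], X[, 3, drop = FALSE])
  expect_lt(abs(atanh(res$r) - atanh(0.5)), 1.96 / sqrt(2000 - 1 - 3))
  # residualization identity: partial r is the correlation of OLS residuals
  rx <- resid(lm(X[, 1] ~ X[, 3])); ry <- resid(lm(X[, 2] ~ X[, 3]))
  expect_equal(res$r, cor(rx, ry))
  expect_equal(res$df, 2000 - 1 - 2)
})

test_that("partial correlation contracts: df floor and collinearity", {
  expect_error(partial_pearson(1:4, 1:4, cbind(1:4, 4:1)), "n >")
  Z <- cbind(a = rnorm(30), b = 1:30)
  Z <- cbind(Z, c = Z[, 1] * 2)
  expect_error(partial_pearson(rnorm(30), rnorm(30), Z), "collinear")
})

test_that("t-test: degenerate limits, near-separation, Welch default", {
  same <- two_sample_t_test(rep(3, 5), rep(3, 5))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  set.seed(3)
  jit <- two_sample_t_test(rep(0, 4) + rnorm(4, 0, 1e-6), rep(1, 4) + rnorm(4, 0, 1e-6))
  expect_lt(jit$p, 1e-4)
  a <- rnorm(40); b <- rnorm(40, 0, 3)
  expect_equal(two_sample_t_test(a, b)$p, t.test(a, b)$p.value)
  expect_equal(two_sample_t_test(a, b, var_equal = TRUE)$p,
               t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("t-test type-I error is calibrated at alpha = 0.05", {
  set.seed(99)
  reps <- 10000
  rej <- 0L
  for (i in seq_len(reps)) {
    if (two_sample_t_test(rnorm(30), rnorm(30))$p < 0.05) rej <- rej + 1L
  }
  rate <- rej / reps
  expect_gte(rate, 0.04); expect_lte(rate, 0.06)
})

test_that("Fisher exact p matches the hypergeometric enumeration oracle", {
  expect_equal(round(fisher_exact(matrix(c(3, 1, 1, 3), 2)), 4), 0.4857)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2)),
               fisher_2x2_oracle(3, 1, 1, 3))
  expect_equal(fisher_exact(matrix(c(5, 5, 2, 2), 2)), 1)  # identical rows
  # 2x3 table (3-level exposure) against stats::fisher.test
  t23 <- matrix(c(8, 3, 5, 9, 2, 7), nrow = 2)
  expect_equal(fisher_exact(t23), fisher.test(t23)$p.value, tolerance = 1e-9)
  expect_error(fisher_exact(matrix(1, 4, 4)), "budget")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("logistic fit reproduces closed forms and recovers parameters", {
  # intercept-only: logit of the prevalence
  y <- c(rep(1, 30), rep(0, 70))
  f0 <- fit_logistic(y)
  expect_equal(f0$coefficients$estimate[1], log(0.3 / 0.7), tolerance = 1e-7)
  # single binary predictor: OR = ad/bc on the 2x2 (a,b;c,d) layout
  x <- c(rep(1, 40), rep(0, 60))
  y2 <- c(rep(1, 25), rep(0, 15), rep(1, 20), rep(0, 40))  # a=25 b=15 c=20 d=40
  f1 <- fit_logistic(y2, cbind(exposure = x))
  expect_equal(f1$coefficients$or[2], (25 * 40) / (15 * 20), tolerance = 1e-6)
  # parameter recovery at n = 1e4
  set.seed(5)
  X <- cbind(x1 = rnorm(1e4), x2 = rbinom(1e4, 1, 0.4))
  eta <- -0.5 + 0.8 * X[, 1] - 0.6 * X[, 2]
  yy <- rbinom(1e4, 1, plogis(eta))
  f2 <- fit_logistic(yy, X)
  est <- f2$coefficients$estimate; se <- f2$coefficients$se
  expect_true(all(abs(est - c(-0.5, 0.8, -0.6)) < 3 * se))
  # error contracts
  expect_error(fit_logistic(rep(1, 20), cbind(rnorm(20))), "classes")
  sep_x <- c(rnorm(20, -5), rnorm(20, 5))
  expect_error(fit_logistic(c(rep(0, 20), rep(1, 20)), cbind(sep_x)), "separation")
  Xc <- cbind(a = rnorm(50), b = 0)
  Xc <- cbind(Xc, c = Xc[, "a"])
  expect_error(fit_logistic(rbinom(50, 1, 0.5), Xc), "collinear")
})

test_that("stepwise elimination matches a brute-force removal oracle", {
  set.seed(31)
  n <- 600
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 1.0 * X$x1 + 0.15 * X$x3))
  res <- backward_stepwise_logistic(y, X, forced = "x1", p_screen = NULL)
  # forced variable survives every path
  expect_true("x1" %in% res$retained)
  expect_false("x1" %in% res$trace$variable)
  # brute-force replay: recompute every removal decision independently
  lr_p <- function(vars, drop_var) {
    full <- fit_logistic(y, X[, vars, drop = FALSE])
    red <- fit_logistic(y, X[, setdiff(vars, drop_var), drop = FALSE])
    pchisq(2 * (full$log_lik - red$log_lik), 1, lower.tail = FALSE)
  }
  vars <- c("x1", "x2", "x3", "x4")
  for (k in seq_len(nrow(res$trace))) {
    ps <- vapply(setdiff(vars, "x1"), function(v) lr_p(vars, v), numeric(1))
    expect_equal(res$trace$variable[k], names(which.max(ps)))
    expect_equal(res$trace$p[k], unname(max(ps)), tolerance = 1e-8)
    expect_gt(max(ps), 0.10)
    vars <- setdiff(vars, res$trace$variable[k])
  }
  # termination condition: all remaining removable p <= 0.10
  remaining <- setdiff(res$retained, "x1")
  if (length(remaining)) {
    ps <- vapply(remaining, function(v) lr_p(res$retained, v), numeric(1))
    expect_true(all(ps <= 0.10))
  }
  # all candidates forced: the full model comes back untouched
  resf <- backward_stepwise_logistic(y, X, forced = c("x1", "x2", "x3", "x4"),
                                     p_screen = NULL)
  expect_equal(sort(resf$retained), c("x1", "x2", "x3", "x4"))
  expect_equal(nrow(resf$trace), 0L)
})

test_that("ICC: identical raters, shifted raters, and the ANOVA identity", {
  set.seed(6)
  base <- rnorm(30, 50, 8)
  same <- cbind(base, base, base)
  expect_equal(icc(same, "agreement")$icc, 1, tolerance = 1e-12)
  expect_equal(icc(same, "consistency")$icc, 1, tolerance = 1e-12)
  shifted <- cbind(base, base + 5)
  expect_equal(icc(shifted, "consistency")$icc, 1, tolerance = 1e-12)
  expect_lt(icc(shifted, "agreement")$icc, 1)
  # ANOVA identity: mean squares recompose the total sum of squares
  set.seed(7)
  r <- matrix(rnorm(40 * 3, 10, 2), 40, 3)
  out <- icc(r)
  n <- 40; k <- 3
  ss_tot <- sum((r - mean(r))^2)
  expect_equal(out$ms_subjects * (n - 1) + out$ms_raters * (k - 1) +
                 out$ms_error * (n - 1) * (k - 1), ss_tot)
  expect_error(icc(matrix(5, 10, 2)), "variance")
  expect_error(icc(matrix(rnorm(8), 4, 2)), "5 subjects")
})

test_that("Bonferroni adjustment caps at 1 and preserves order", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.02, 0.03, 0.5)), c(0.06, 0.09, 1.0))
  set.seed(8)
  p <- runif(20)
  adj <- bonferroni_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))   # monotone in the raw p
  expect_equal(adj, p.adjust(p, "bonferroni"))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
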