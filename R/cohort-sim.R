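#' Specification of a synthetic cohort
#'
#' Describes a cohort table with the covariate structure of an elderly
#' WMH cohort (age, sex, education, blood pressure, labs, microbleed and
#' lacune counts, MMSE) and a tunable partial correlation between
#' log-corrected-WMH-volume and DMV voxel count given the adjustment
#' covariates (age, sex, education, microbleeds, lacunes).
#'
#' Construction: the adjustment covariates are drawn from their stated
#' marginal distributions and standardized; the latent pair behind
#' log(CWMHV) and the DMV count is built as
#' `x = a'z + sqrt(1 - |a|^2) e_x`, `y = b'z + sqrt(1 - |b|^2) e_y` with
#' `cor(e_x, e_y) = target_partial_r`, so the population partial correlation
#' of x and y given z equals the target exactly. Default covariate means/SDs
#' follow the published cohort description (age 66.5 +/- 12.8 y, CWMHV
#' mean 35.3 +/- 28.3 ml, DMV count 3676 +/- 1071, etc.).
#'
#' @param n number of subjects (default 158).
#' @param target_partial_r target partial correlation in (-1, 1); default
#'   0.506, the magnitude reported for the whole-brain association.
#' @param x_loadings,y_loadings named numeric loadings of log-CWMHV (x) and
#'   DMV count (y) on the standardized adjustment covariates
#'   (age, sex, education, microbleeds, lacunes); squared norms must be < 1.
#' @param cwmhv_ml mean/sd of the corrected WMH volume (ml) on the natural
#'   scale (converted internally to a lognormal).
#' @param dmv_count mean/sd of the DMV voxel count.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 158L,
                        target_partial_r = 0.506,
                        x_loadings = c(age = 0.05, sex = 0, education = 0.05,
                                       microbleeds = 0.15, lacunes = 0.30),
                        y_loadings = c(age = 0.02, sex = 0, education = 0.03,
                                       microbleeds = 0.20, lacunes = 0.25),
                        cwmhv_ml = c(mean = 35.32, sd = 28.25),
                        dmv_count = c(mean = 3675.79, sd = 1071.29),
                        seed = 1L) {
  if (abs(target_partial_r) >= 1)
    stop("target partial correlation must lie in (-1, 1)", call. = FALSE)
  adj <- c("age", "sex", "education", "microbleeds", "lacunes")
  x_loadings <- x_loadings[adj]; names(x_loadings) <- adj
  y_loadings <- y_loadings[adj]; names(y_loadings) <- adj
  x_loadings[is.na(x_loadings)] <- 0; y_loadings[is.na(y_loadings)] <- 0
  if (sum(x_loadings^2) >= 1)
    stop("correlation matrix not positive definite: x (log-CWMHV) loadings have squared norm >= 1",
         call. = FALSE)
  if (sum(y_loadings^2) >= 1)
    stop("correlation matrix not positive definite: y (DMV count) loadings have squared norm >= 1",
         call. = FALSE)
  n <- as.integer(n)
  if (n < length(adj) + 3)
    stop(sprintf("n = %d too small: need n >= #covariates + 3 = %d (df = n - covariates - 2 must be positive)",
                 n, length(adj) + 3), call. = FALSE)
  structure(list(n = n, target_partial_r = target_partial_r,
                 adjustment = adj,
                 x_loadings = x_loadings, y_loadings = y_loadings,
                 cwmhv_ml = cwmhv_ml, dmv_count = dmv_count,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d, target partial r = %.3f, seed %d\n",
              x$n, x$target_partial_r, x$seed))
  invisible(x)
}

#' Population partial correlation implied by a cohort spec
#'
#' Assembles the generating covariance matrix of (x, y, z1..z5) and computes
#' the partial correlation of x and y given z from its precision matrix
#' (`-P_xy / sqrt(P_xx P_yy)`); by construction this equals the spec's
#' target to machine precision, which the tests assert.
#'
#' @param spec a [cohort_spec()].
#' @return the implied population partial correlation.
#' @export
population_partial_correlation <- function(spec) {
  a <- spec$x_loadings; b <- spec$y_loadings
  rho <- spec$target_partial_r
  k <- length(a)
  S <- diag(k + 2)
  S[1, 2] <- S[2, 1] <- sum(a * b) + rho * sqrt((1 - sum(a^2)) * (1 - sum(b^2)))
  S[1, 3:(k + 2)] <- S[3:(k + 2), 1] <- a
  S[2, 3:(k + 2)] <- S[3:(k + 2), 2] <- b
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# one draw of a negative-binomial count vector (mean m, dispersion size)
rcount <- function(n, m, size) stats::rnbinom(n, size = size, mu = m)

#' Generate a synthetic cohort table
#'
#' Draws the covariates, builds the latent log-CWMHV / DMV-count pair with
#' the spec's partial-correlation structure, and returns one row per
#' subject. Deterministic under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` (class `cohort_table`) with columns `subject_id`,
#'   `age`, `sex` (0/1), `education`, `hypertension` (0/1/2), `diabetes`,
#'   `hyperlipidemia`, `sbp`, `dbp`, `glucose`, `tc`, `thcy`, `hscrp`,
#'   `microbleeds`, `lacunes`, `mmse`, `cwmhv`, `dmv_count`, `dmv_left`,
#'   `dmv_right`.
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  age <- stats::rnorm(n, 66.51, 12.76)
  sex <- stats::rbinom(n, 1, 0.494)
  education <- pmax(stats::rnorm(n, 7.26, 4.57), 0)
  hypertension <- sample(0:2, n, replace = TRUE, prob = c(0.24, 0.56, 0.20))
  diabetes <- stats::rbinom(n, 1, 0.24)
  hyperlipidemia <- stats::rbinom(n, 1, 0.335)
  sbp <- stats::rnorm(n, 143.98, 19.2)
  dbp <- stats::rnorm(n, 82.82, 10.8)
  glucose <- pmax(stats::rnorm(n, 5.52, 1.93), 2.5)
  tc <- pmax(stats::rnorm(n, 4.45, 1.17), 1.5)
  thcy <- pmax(stats::rnorm(n, 14.0, 6.0), 3)
  hscrp <- stats::rlnorm(n, log(9.37) - 0.247, 0.703)
  microbleeds <- rcount(n, 8.28, 0.35)
  lacunes <- rcount(n, 1.89, 0.6)
  mmse <- pmin(pmax(round(stats::rnorm(n, 25.8, 3.5)), 0), 30)
  zscale <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  Z <- cbind(age = zscale(age), sex = zscale(sex), education = zscale(education),
             microbleeds = zscale(microbleeds), lacunes = zscale(lacunes))
  rho <- spec$target_partial_r
  e_x <- stats::rnorm(n)
  e_y <- rho * e_x + sqrt(1 - rho^2) * stats::rnorm(n)
  a <- spec$x_loadings; b <- spec$y_loadings
  x_lat <- as.numeric(Z %*% a) + sqrt(1 - sum(a^2)) * e_x
  y_lat <- as.numeric(Z %*% b) + sqrt(1 - sum(b^2)) * e_y
  # lognormal CWMHV matching the stated natural-scale mean/sd
  cv <- spec$cwmhv_ml["sd"] / spec$cwmhv_ml["mean"]
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(spec$cwmhv_ml["mean"]) - sdlog^2 / 2
  cwmhv <- exp(meanlog + sdlog * x_lat)
  dmv_count <- pmax(round(spec$dmv_count["mean"] + spec$dmv_count["sd"] * y_lat), 0)
  dmv_left <- stats::rbinom(n, dmv_count, 0.5)
  tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    age = age, sex = sex, education = education,
                    hypertension = hypertension, diabetes = diabetes,
                    hyperlipidemia = hyperlipidemia, sbp = sbp, dbp = dbp,
                    glucose = glucose, tc = tc, thcy = thcy, hscrp = hscrp,
                    microbleeds = microbleeds, lacunes = lacunes, mmse = mmse,
                    cwmhv = as.numeric(cwmhv),
                    dmv_count = as.numeric(dmv_count),
                    dmv_left = dmv_left,
                    dmv_right = as.numeric(dmv_count) - dmv_left,
                    stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  attr(tab, "spec") <- spec
  tab
}
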