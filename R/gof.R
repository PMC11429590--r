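# Goodness-of-fit of a fitted mixture, generation by generation: the
# probability integral transform (PIT) through the fitted mixture CDF should
# be Uniform(0,1) under a correct model, which is examined with three
# moment-based uniformity statistics (first, second and third orthogonal
# moments, each referred to chi-square with 1 df), the Cramer-von Mises
# statistic nW^2 and the Kolmogorov statistic Dn.

#' Probability integral transform through a fitted mixture
#'
#' `y_i = sum_c pi_c * Phi((x_i - mu_c) / sigma_c)` — the exact mixture CDF,
#' no Monte Carlo.
#'
#' @param values Numeric vector of observations.
#' @param mixture List with `weights`, `means`, `variance` (one shared
#'   component variance, as fitted) — the per-generation element of a
#'   `segfit`'s `components`.
#' @return Vector of CDF values in \[0, 1\], same order as `values`.
#' @export
pit_transform <- function(values, mixture) {
  sdv <- sqrt(mixture$variance)
  y <- vapply(values, function(x) {
    sum(mixture$weights * stats::pnorm(x, mixture$means, sdv))
  }, numeric(1))
  pmin(pmax(y, 0), 1)
}

#' Moment-based uniformity statistics
#'
#' Tests of Uniform(0,1) built on the first three orthogonal (shifted
#' Legendre) moments of the PIT values:
#' `U1^2 = 3/n (sum(2y - 1))^2 = 12 n (ybar - 1/2)^2`,
#' `U2^2 = 5/n (sum(6y^2 - 6y + 1))^2`,
#' `U3^2 = 7/n (sum(20y^3 - 30y^2 + 12y - 1))^2`;
#' each is asymptotically chi-square with 1 df under uniformity, which gives
#' the reported probability values.
#'
#' @param y PIT values in \[0, 1\], n >= 5.
#' @return Data frame with one row per statistic: `statistic` (`U1sq`,
#'   `U2sq`, `U3sq`), `value`, `p_value`.
#' @export
uniformity_stats <- function(y) {
  n <- length(y)
  if (n < 5L) stop("need at least 5 values", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("PIT values must lie in [0, 1]", call. = FALSE)
  u1 <- 3 / n * sum(2 * y - 1)^2
  u2 <- 5 / n * sum(6 * y^2 - 6 * y + 1)^2
  u3 <- 7 / n * sum(20 * y^3 - 30 * y^2 + 12 * y - 1)^2
  v <- c(U1sq = u1, U2sq = u2, U3sq = u3)
  data.frame(statistic = names(v), value = unname(v),
             p_value = stats::pchisq(unname(v), df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# Asymptotic Cramer-von Mises survival probability P(W^2 > x) via the
# classical Bessel-function series for the limiting distribution
# (Anderson & Darling 1952, eq. for a1(z)); accurate for x >= 0.02.
.cvm_pvalue <- function(x) {
  if (x < 0.02) return(1)
  if (x > 10) return(0)
  j <- 0:10
  z <- (4 * j + 1)^2 / (16 * x)
  terms <- exp(lgamma(j + 0.5) - lgamma(0.5) - lfactorial(j)) *
    sqrt(4 * j + 1) * exp(-z) * besselK(z, 0.25)
  cdf <- sum(terms) / (pi * sqrt(x))
  min(max(1 - cdf, 0), 1)
}

#' Cramer-von Mises statistic of uniformity
#'
#' `nW^2 = 1/(12n) + sum_i (y_(i) - (2i - 1)/(2n))^2` computed on the sorted
#' PIT values, with the significance level from the asymptotic limiting
#' distribution (5% critical value about 0.461).
#'
#' @param y PIT values in \[0, 1\].
#' @return Data frame row: `statistic = "nWsq"`, `value`, `p_value`.
#' @export
smirnov_nW2 <- function(y) {
  if (any(y < 0 | y > 1)) stop("PIT values must lie in [0, 1]", call. = FALSE)
  n <- length(y)
  ys <- sort(y)
  w <- 1 / (12 * n) + sum((ys - (2 * seq_len(n) - 1) / (2 * n))^2)
  data.frame(statistic = "nWsq", value = w, p_value = .cvm_pvalue(w),
             stringsAsFactors = FALSE)
}

#' Kolmogorov statistic of uniformity
#'
#' `Dn = max_i max(i/n - y_(i), y_(i) - (i - 1)/n)` on the sorted PIT
#' values, with the significance level from the asymptotic Kolmogorov
#' distribution of `sqrt(n) Dn`.
#'
#' @param y PIT values in \[0, 1\].
#' @return Data frame row: `statistic = "Dn"`, `value`, `p_value`.
#' @export
kolmogorov_Dn <- function(y) {
  if (any(y < 0 | y > 1)) stop("PIT values must lie in [0, 1]", call. = FALSE)
  n <- length(y)
  ys <- sort(y)
  i <- seq_len(n)
  d <- max(pmax(i / n - ys, ys - (i - 1) / n))
  t <- sqrt(n) * d
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  data.frame(statistic = "Dn", value = d, p_value = min(max(p, 0), 1),
             stringsAsFactors = FALSE)
}

#' Goodness-of-fit table for a fitted model
#'
#' For each generation, transforms the observed values through the fitted
#' mixture CDF and reports the five adequacy statistics with their
#' probability values — the suitability-test layer of a joint segregation
#' analysis.
#'
#' @param fit A [fit_model()] result.
#' @param dataset The [six_gen_dataset()] the model was fitted to.
#' @return Data frame with columns `model`, `generation`, `statistic`,
#'   `value`, `p_value` (5 rows per generation).
#' @export
gof_test <- function(fit, dataset) {
  stopifnot(inherits(fit, "segfit"), inherits(dataset, "six_gen_dataset"))
  out <- do.call(rbind, lapply(GENERATIONS, function(g) {
    y <- pit_transform(dataset$samples[[g]]$values, fit$components[[g]])
    rows <- rbind(uniformity_stats(y), smirnov_nW2(y), kolmogorov_Dn(y))
    cbind(model = fit$model, generation = g, rows,
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
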