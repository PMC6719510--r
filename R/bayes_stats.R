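#' Group summary of per-subject measures
#'
#' @param values Numeric vector of per-subject measures (n >= 2).
#' @return A `group_summary`: list with `mean`, `se`, `ci_lower`,
#'   `ci_upper` (95%, t-based), `n`, `df`, `degenerate` (TRUE when the
#'   sample variance is zero).
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(0.975, n - 1L)
  structure(list(mean = m, se = se, ci_lower = m - tq * se,
                 ci_upper = m + tq * se, n = n, df = n - 1L,
                 degenerate = se == 0),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("mean %.3f, 95%% CI [%.3f, %.3f], n = %d%s\n", x$mean,
              x$ci_lower, x$ci_upper, x$n,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' Recover the standard error from a printed 95% confidence interval
#'
#' Inverts the t-based interval: `se = width / (2 t(0.975, df))`. Used to
#' reproduce published Bayes factors from printed group summaries.
#'
#' @param ci_lower,ci_upper Interval bounds.
#' @param df Degrees of freedom (n − 1).
#' @return The standard error.
#' @export
se_from_ci <- function(ci_lower, ci_upper, df) {
  if (ci_upper <= ci_lower) stop("CI must have positive width", call. = FALSE)
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  (ci_upper - ci_lower) / (2 * stats::qt(0.975, df))
}

#' Evidence label for a Bayes factor
#'
#' Labels the dominant direction on the conventional thresholds 1, 3, 10,
#' 30, 100 (anecdotal, moderate, strong, very strong, extreme); a BF10
#' below 1 is labeled symmetrically through BF01, and exactly 1 is "no
#' evidence".
#'
#' @param bf10 Bayes factor for the alternative over the null.
#' @return A character label.
#' @export
interpret_bf <- function(bf10) {
  if (!is.finite(bf10) || bf10 <= 0) stop("`bf10` must be positive",
                                          call. = FALSE)
  if (bf10 == 1) return("no evidence")
  side <- if (bf10 > 1) "H1" else "H0"
  b <- max(bf10, 1 / bf10)
  grade <- if (b < 3) "anecdotal" else if (b < 10) "moderate" else
    if (b < 30) "strong" else if (b < 100) "very strong" else "extreme"
  sprintf("%s evidence for %s", grade, side)
}

new_bf_result <- function(log_bf10, prior) {
  bf10 <- exp(log_bf10)
  structure(list(bf10 = bf10, bf01 = exp(-log_bf10), log_bf10 = log_bf10,
                 prior = prior, label = interpret_bf(bf10)),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (BF01 = %.4g), prior uniform [%g, %g]: %s\n",
              x$bf10, x$bf01, x$prior$lower, x$prior$upper, x$label))
  invisible(x)
}

#' Uniform-prior Bayes factor with a t likelihood
#'
#' The alternative hypothesis models the true effect `delta` as uniform on
#' `[lower, upper]` uV; the likelihood of the observed mean is a scaled
#' central t with `df` degrees of freedom evaluated at `(m - delta)/se`
#' (the convention of the Dienes Bayes-factor calculator). The marginal
#' likelihood under the alternative is computed by adaptive quadrature in
#' log space, so far-tail ratios (|t| > 8) do not underflow; the null
#' likelihood is the density at `delta = 0`.
#'
#' @param m Observed mean effect in uV.
#' @param se Standard error of the mean.
#' @param df Degrees of freedom (n − 1).
#' @param lower,upper Prior bounds in uV.
#' @param rel_tol Relative tolerance of the quadrature.
#' @return A `bf_result` with `bf10`, `bf01` (= 1/bf10), `log_bf10`,
#'   `prior`, `label`.
#' @export
bf_uniform <- function(m, se, df, lower = -1.5, upper = 1.5,
                       rel_tol = 1e-8) {
  if (se <= 0) stop("`se` must be positive", call. = FALSE)
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  if (lower >= upper) stop("`lower` must be below `upper`", call. = FALSE)
  log_lik <- function(delta) {
    stats::dt((m - delta) / se, df, log = TRUE) - log(se)
  }
  ## shift by the in-interval maximum before exponentiating
  peak <- log_lik(min(max(m, lower), upper))
  q <- stats::integrate(function(d) exp(log_lik(d) - peak), lower, upper,
                        rel.tol = rel_tol, abs.tol = 0)
  if (q$message != "OK" || q$value <= 0) {
    stop(sprintf("quadrature failed: %s (value %g)", q$message, q$value),
         call. = FALSE)
  }
  log_marg1 <- peak + log(q$value) - log(upper - lower)
  new_bf_result(log_marg1 - log_lik(0),
                list(form = "uniform", lower = lower, upper = upper))
}

#' Directional uniform-prior Bayes factor
#'
#' The prior is `[0, bound]` for a hypothesized positive effect and
#' `[-bound, 0]` for a negative one.
#'
#' @inheritParams bf_uniform
#' @param bound Magnitude of the non-zero prior bound in uV.
#' @param direction `"positive"` or `"negative"`, the hypothesized
#'   direction of the effect.
#' @return A `bf_result`.
#' @export
bf_directional <- function(m, se, df, bound = 1.5,
                           direction = c("positive", "negative"),
                           rel_tol = 1e-8) {
  direction <- match.arg(direction)
  if (bound <= 0) stop("`bound` must be positive", call. = FALSE)
  if (direction == "positive") {
    bf_uniform(m, se, df, 0, bound, rel_tol = rel_tol)
  } else {
    bf_uniform(m, se, df, -bound, 0, rel_tol = rel_tol)
  }
}

#' Central 95% credible interval for a mean under a flat prior
#'
#' With an improper uniform prior on the mean and a scaled-t likelihood,
#' the posterior is the t location family, so the central credible
#' interval coincides with the frequentist t interval `m +/- t(0.975, df)
#' se`.
#'
#' @inheritParams bf_uniform
#' @return Numeric vector `c(lower, upper)`.
#' @export
credible_interval_mean <- function(m, se, df) {
  if (se <= 0) stop("`se` must be positive", call. = FALSE)
  tq <- stats::qt(0.975, df)
  c(lower = m - tq * se, upper = m + tq * se)
}

## log Gauss hypergeometric 2F1(a, b; c; z) by series (convergent for
## 0 <= z < 1 with positive parameters, as used here).
log_2f1 <- function(a, b, cc, z) {
  if (z < 0 || z >= 1) stop("series requires 0 <= z < 1", call. = FALSE)
  if (z == 0) return(0)
  lt <- 0
  s <- 1
  for (k in seq_len(200000L)) {
    lt <- lt + log(a + k - 1) + log(b + k - 1) - log(cc + k - 1) -
      log(k) + log(z)
    term <- exp(lt)
    s <- s + term
    if (term < s * 1e-16) break
  }
  log(s)
}

## log density ratio p(r | rho, n) / p(r | 0, n) using the exact sampling
## density of the Pearson correlation (Hotelling's form); the
## rho-independent factors cancel in the ratio.
log_r_density_ratio <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log_2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2) -
    log_2f1(0.5, 0.5, n - 0.5, 0.5)
}

#' Bayes factor and credible interval for a Pearson correlation
#'
#' Two-sided test of rho = 0 against a symmetric stretched-beta prior on
#' (−1, 1); `beta = 1` gives the flat prior. The likelihood is the exact
#' sampling density of the observed correlation coefficient. The Bayes
#' factor integral uses adaptive quadrature on the density ratio; the
#' credible interval comes from the normalized posterior evaluated on a
#' 4001-point grid (central interval by trapezoid-integrated CDF).
#'
#' @param r Observed Pearson correlation (|r| < 1).
#' @param n Sample size (>= 4).
#' @param beta Stretched-beta shape; 1 is flat.
#' @return A `correlation_bf`: list with `r`, `n`, `bf10`, `bf01`,
#'   `ci_lower`, `ci_upper`, `prior_beta`, `label`.
#' @export
correlation_bf <- function(r, n, beta = 1) {
  if (abs(r) >= 1) stop("|r| must be below 1", call. = FALSE)
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  log_prior <- function(rho) {
    (beta - 1) * (log1p(rho) + log1p(-rho)) -
      (lbeta(beta, beta) + (2 * beta - 1) * log(2))
  }
  f <- Vectorize(function(rho) {
    exp(log_r_density_ratio(rho, r, n) + log_prior(rho))
  })
  q <- stats::integrate(f, -1, 1, rel.tol = 1e-9)
  if (q$message != "OK") stop("correlation BF quadrature failed", call. = FALSE)
  bf10 <- q$value
  grid <- seq(-1 + 5e-5, 1 - 5e-5, length.out = 4001L)
  lp <- vapply(grid, function(p) log_r_density_ratio(p, r, n) + log_prior(p),
               0)
  w <- exp(lp - max(lp))
  dg <- diff(grid)
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * dg))
  cdf <- cdf / cdf[length(cdf)]
  ci <- stats::approx(cdf, grid, c(0.025, 0.975), ties = "ordered")$y
  structure(list(r = r, n = n, bf10 = bf10, bf01 = 1 / bf10,
                 ci_lower = ci[1], ci_upper = ci[2], prior_beta = beta,
                 label = interpret_bf(bf10)),
            class = "correlation_bf")
}

#' @export
print.correlation_bf <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d), BF10 = %.4g, 95%% CrI [%.3f, %.3f]: %s\n",
              x$r, x$n, x$bf10, x$ci_lower, x$ci_upper, x$label))
  invisible(x)
}

#' Pearson correlation with input validation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return The sample correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Operation-span partial credit unit (PCU) score
#'
#' The proportion of letters recalled in the correct serial position is
#' computed per sequence; the PCU score is the mean proportion across all
#' sequences.
#'
#' @param lengths Sequence lengths.
#' @param correct Number of letters recalled in correct position per
#'   sequence.
#' @return The PCU score, a proportion in \[0, 1\].
#' @export
pcu_score <- function(lengths, correct) {
  if (!length(lengths)) stop("no sequences supplied", call. = FALSE)
  if (length(lengths) != length(correct)) {
    stop("`lengths` and `correct` must have equal length", call. = FALSE)
  }
  if (any(correct < 0 | correct > lengths)) {
    stop("`correct` must lie in [0, length] for each sequence", call. = FALSE)
  }
  mean(correct / lengths)
}
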