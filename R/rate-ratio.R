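#' Tail probability utilities
#'
#' Thin validated wrappers around the standard normal and chi-square
#' survival functions used by every test in the pipeline.
#'
#' @param z a z statistic.
#' @param x a chi-square statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @examples
#' chisq_sf(5.44, 1)  # 0.020 to 3 decimals
#' @export
normal_sf <- function(z) {
  if (!is.numeric(z) || anyNA(z)) stop_domain("'z' must be numeric")
  stats::pnorm(z, lower.tail = FALSE)
}

#' @rdname normal_sf
#' @export
chisq_sf <- function(x, df) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop_domain("'x' must be a non-negative number")
  if (!is.numeric(df) || anyNA(df) || any(df < 1))
    stop_domain("'df' must be >= 1")
  stats::pchisq(x, df, lower.tail = FALSE)
}

rate_and_se <- function(x, se, what) {
  if (inherits(x, "rate_estimate")) return(c(x$mu_hat, x$se_mu))
  c(check_scalar(x, what), check_scalar(se, paste0("se_", what), lower = 0))
}

#' Low-to-high mutation-rate ratio with sigma-method variance
#'
#' Forms the ratio `R = a / b` of two independent rate estimates (by
#' convention, low-glucose over high-glucose) and its first-order
#' delta-method ("sigma method") variance
#' \deqn{\mathrm{var}(R) = R^2\left(\frac{se_a^2}{a^2} +
#'   \frac{se_b^2}{b^2}\right),}
#' with a normal 95% confidence interval `R +- 1.96 sqrt(var_R)`.
#' A ratio near 1 indicates no plastic response of the mutation rate to the
#' environment; R > 1 means a higher rate in the numerator condition.
#'
#' @param a,b the two rates (`rate_estimate` objects or positive numbers);
#'   `a` is the numerator.
#' @param se_a,se_b standard errors (ignored when `a`/`b` are
#'   `rate_estimate` objects).
#' @param labels optional length-2 character vector naming the conditions.
#' @return object of class `rate_ratio`: `R`, `var_R`, `ci95`, `labels`.
#' @examples
#' sigma_ratio(2, 1, se_a = 0.2, se_b = 0.1)
#' @export
sigma_ratio <- function(a, b, se_a = 0, se_b = 0,
                        labels = c("low", "high")) {
  av <- rate_and_se(a, se_a, "a")
  bv <- rate_and_se(b, se_b, "b")
  if (av[1] <= 0 || bv[1] <= 0)
    stop_domain("rates must be strictly positive to form a ratio")
  R <- av[1] / bv[1]
  var_R <- R^2 * ((av[2] / av[1])^2 + (bv[2] / bv[1])^2)
  half <- 1.96 * sqrt(var_R)
  structure(list(R = R, var_R = var_R,
                 ci95 = c(lower = R - half, upper = R + half),
                 labels = labels),
            class = "rate_ratio")
}

#' z-test of a rate ratio against 1
#'
#' @param ratio a `rate_ratio` object (or the ratio value).
#' @param var_R variance of the ratio (ignored when `ratio` is a
#'   `rate_ratio`).
#' @param sidedness `"two.sided"`, `"greater"` (upper tail) or `"less"`.
#' @return list with `z`, `p`, `sidedness`.
#' @examples
#' z_ratio_vs_1(sigma_ratio(1.2, 1, 0.05, 0.04))
#' @export
z_ratio_vs_1 <- function(ratio, var_R = NULL,
                         sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  if (inherits(ratio, "rate_ratio")) {
    R <- ratio$R; v <- ratio$var_R
  } else {
    R <- check_scalar(ratio, "ratio"); v <- check_scalar(var_R, "var_R")
  }
  if (v <= 0) stop_domain("degenerate test: var_R must be > 0")
  z <- (R - 1) / sqrt(v)
  list(z = z, p = p_from_z(z, sidedness), sidedness = sidedness)
}

#' z-test comparing two independent rate ratios
#'
#' Contrast of two strains' low-to-high ratios:
#' `z = (R1 - R2) / sqrt(var_R1 + var_R2)`. The default is the upper-tail
#' one-sided test (directional hypothesis that the first ratio exceeds the
#' second); this default is recorded in the result.
#'
#' @param r1,r2 `rate_ratio` objects (or ratio values).
#' @param var_R1,var_R2 variances when `r1`/`r2` are numeric.
#' @param sidedness `"greater"`, `"two.sided"` or `"less"`.
#' @return object of class `ratio_contrast`: `z`, `p`, `sidedness`.
#' @examples
#' wt <- sigma_ratio(1.6, 1, 0.15, 0.1)
#' del <- sigma_ratio(1.06, 1, 0.15, 0.1)
#' z_ratio_diff(wt, del)
#' @export
z_ratio_diff <- function(r1, r2, var_R1 = NULL, var_R2 = NULL,
                         sidedness = c("greater", "two.sided", "less")) {
  sidedness <- match.arg(sidedness)
  if (inherits(r1, "rate_ratio")) { R1 <- r1$R; v1 <- r1$var_R }
  else { R1 <- check_scalar(r1, "r1"); v1 <- check_scalar(var_R1, "var_R1") }
  if (inherits(r2, "rate_ratio")) { R2 <- r2$R; v2 <- r2$var_R }
  else { R2 <- check_scalar(r2, "r2"); v2 <- check_scalar(var_R2, "var_R2") }
  if (v1 + v2 <= 0) stop_domain("degenerate test: both variances are zero")
  z <- (R1 - R2) / sqrt(v1 + v2)
  structure(list(z = z, p = p_from_z(z, sidedness), sidedness = sidedness),
            class = "ratio_contrast")
}

p_from_z <- function(z, sidedness) {
  switch(sidedness,
         two.sided = 2 * normal_sf(abs(z)),
         greater = normal_sf(z),
         less = stats::pnorm(z))
}

#' @export
print.rate_ratio <- function(x, ...) {
  cat(sprintf("%s-to-%s rate ratio: %.3f (95%% CI %.3f, %.3f)\n",
              x$labels[1], x$labels[2], x$R, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
print.ratio_contrast <- function(x, ...) {
  cat(sprintf("Ratio contrast: Z = %.2f, P = %s (%s)\n",
              x$z, format_p(x$p), x$sidedness))
  invisible(x)
}
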