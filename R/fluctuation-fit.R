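#' Maximum-likelihood fluctuation-test estimator
#'
#' Fits the Lea-Coulson mutant-count model to the counts of one fluctuation
#' experiment and returns the expected number of mutation events per culture
#' (`m`) with a standard error from the inverse observed information.
#' Mutant relative fitness can either be held fixed (default, at 1) or
#' estimated jointly with `m`.
#'
#' All-zero count vectors sit on the boundary of the parameter space: the
#' estimate is `m = 0` and the standard error is reported as `NA` with a
#' diagnostic flag rather than an error.
#'
#' @param counts non-negative integer vector of mutant counts per parallel
#'   culture (length >= 2).
#' @param fitness mutant relative fitness used when `fitness_mode = "fixed"`,
#'   and the starting value when `"joint"`.
#' @param fitness_mode `"fixed"` holds fitness at `fitness`; `"joint"`
#'   maximises over `(m, fitness)` together.
#' @param winsor_cap winsorization cap applied to counts during likelihood
#'   evaluation (see [ld_loglik()]).
#' @return an object of class `fluctuation_fit` with components `m_hat`,
#'   `se_m`, `fitness`, `se_fitness` (joint mode only), `logLik`,
#'   `n_cultures`, `converged`, `boundary`, `note`, `method = "ml"`.
#' @seealso [fluctuation_p0()], [rate_from_m()]
#' @examples
#' counts <- simulate_counts(182, m = 1.5, seed = 42)
#' fit <- fluctuation_ml(counts)
#' summary(fit)
#' @export
fluctuation_ml <- function(counts, fitness = 1,
                           fitness_mode = c("fixed", "joint"),
                           winsor_cap = 1024) {
  counts <- check_counts(counts, min_len = 2L)
  fitness_mode <- match.arg(fitness_mode)
  check_scalar(winsor_cap, "winsor_cap", lower = 1)

  out <- structure(list(
    m_hat = NA_real_, se_m = NA_real_,
    fitness = fitness, se_fitness = NA_real_,
    fitness_mode = fitness_mode, winsor_cap = winsor_cap,
    counts = counts, n_cultures = length(counts),
    logLik = NA_real_, converged = TRUE, boundary = FALSE,
    note = NULL, method = "ml"), class = "fluctuation_fit")

  if (all(counts == 0)) {
    out$m_hat <- 0
    out$logLik <- 0
    out$boundary <- TRUE
    out$note <- "all counts zero: m on boundary, standard error undefined"
    return(out)
  }

  cw <- pmin(counts, winsor_cap)
  if (fitness_mode == "fixed") {
    nll <- function(logm) -ld_loglik(cw, exp(logm), fitness, winsor_cap)
    upper <- log(max(5, 2 * mean(cw) + 5))
    opt <- stats::optimize(nll, c(log(1e-5), upper), tol = 1e-9)
    # fall back to the lower bound if the optimum hugs it
    m_hat <- exp(opt$minimum)
    if (abs(opt$minimum - upper) < 1e-6) {
      out$converged <- FALSE
      out$note <- "optimizer at upper bracket: estimate unreliable"
    }
    out$m_hat <- m_hat
    out$logLik <- -opt$objective
    h <- max(1e-6, 1e-4 * m_hat)
    ll <- function(m) ld_loglik(cw, m, fitness, winsor_cap)
    info <- -(ll(m_hat + h) - 2 * ll(m_hat) + ll(m_hat - h)) / h^2
    if (is.finite(info) && info > 0) {
      out$se_m <- 1 / sqrt(info)
    } else {
      out$converged <- FALSE
      out$note <- c(out$note, "observed information not positive")
    }
  } else {
    nll2 <- function(par) -ld_loglik(cw, exp(par[1]), exp(par[2]), winsor_cap)
    start <- c(log(max(mean(cw == 0), 1e-3)), log(fitness))
    start[1] <- log(max(-log(max(mean(cw == 0), 1e-8)), 0.05))
    opt <- stats::optim(start, nll2, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (opt$convergence != 0) {
      out$converged <- FALSE
      out$note <- paste("optim convergence code", opt$convergence)
    }
    out$m_hat <- exp(opt$par[1])
    out$fitness <- exp(opt$par[2])
    out$logLik <- -opt$value
    hess <- stats::optimHess(opt$par, nll2)
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
      # delta method back from the log scale
      out$se_m <- sqrt(vc[1, 1]) * out$m_hat
      out$se_fitness <- sqrt(vc[2, 2]) * out$fitness
    } else {
      out$converged <- FALSE
      out$note <- c(out$note, "observed information not positive definite")
    }
  }
  out
}

#' P0 estimator of the expected mutation number
#'
#' Classical zero-class estimator: `m = -log(p0)` where `p0` is the fraction
#' of cultures with no mutants, with a delta-method standard error
#' `sqrt((1 - p0) / (n * p0))`.
#'
#' @inheritParams fluctuation_ml
#' @return a `fluctuation_fit` object with `method = "p0"`.
#' @examples
#' fluctuation_p0(c(rep(0, 50), rep(3, 50)))$m_hat  # log(2)
#' @export
fluctuation_p0 <- function(counts) {
  counts <- check_counts(counts, min_len = 1L)
  n <- length(counts)
  n0 <- sum(counts == 0)
  if (n0 == 0)
    stop_domain("P0 estimator undefined: no culture has a zero count")
  p0 <- n0 / n
  structure(list(
    m_hat = -log(p0),
    se_m = sqrt((1 - p0) / (n * p0)),
    fitness = NA_real_, se_fitness = NA_real_,
    fitness_mode = "none", winsor_cap = NA_real_,
    counts = counts, n_cultures = n,
    logLik = NA_real_, converged = TRUE,
    boundary = n0 == n,
    note = if (n0 == n) "all counts zero: m on boundary" else NULL,
    method = "p0"), class = "fluctuation_fit")
}

#' Convert a mutation-number estimate into a mutation rate
#'
#' The final population size `Nt` is the arithmetic mean of the replicate
#' CFU totals; the rate is `mu = m / Nt` per cell per generation. By default
#' `Nt` is treated as fixed (`se_mu = se_m / Nt`); setting
#' `propagate_nt = TRUE` adds the CFU sampling variance by the delta method.
#'
#' @param fit a `fluctuation_fit` object, or a numeric `m` estimate.
#' @param cfu_totals positive numeric vector of final viable-cell totals
#'   from replicate cultures.
#' @param se_m standard error of `m` (only when `fit` is numeric).
#' @param propagate_nt if `TRUE`, propagate CFU replicate error into
#'   `se_mu` (requires >= 2 replicates).
#' @return an object of class `rate_estimate` with fields `m_hat`, `se_m`,
#'   `Nt`, `mu_hat`, `se_mu`, `n_cultures`, `method`, `fitness_mode`.
#' @examples
#' rate_from_m(fluctuation_p0(c(0, 0, 1, 5)), cfu_totals = c(1e8, 1.2e8, 0.8e8))
#' @export
rate_from_m <- function(fit, cfu_totals, se_m = NA_real_,
                        propagate_nt = FALSE) {
  if (!is.numeric(cfu_totals) || length(cfu_totals) < 1 ||
      any(!is.finite(cfu_totals)) || any(cfu_totals <= 0))
    stop_domain("'cfu_totals' must be positive numbers")
  if (inherits(fit, "fluctuation_fit")) {
    m_hat <- fit$m_hat; se <- fit$se_m
    n_cultures <- fit$n_cultures
    method <- fit$method; fitness_mode <- fit$fitness_mode
  } else {
    m_hat <- check_scalar(fit, "m", lower = 0)
    se <- se_m; n_cultures <- NA_integer_
    method <- "external"; fitness_mode <- NA_character_
  }
  Nt <- mean(cfu_totals)
  mu <- m_hat / Nt
  se_mu <- se / Nt
  if (propagate_nt) {
    if (length(cfu_totals) < 2)
      stop_domain("propagate_nt requires >= 2 CFU replicates")
    se_nt <- stats::sd(cfu_totals) / sqrt(length(cfu_totals))
    se_mu <- if (m_hat > 0)
      mu * sqrt((se / m_hat)^2 + (se_nt / Nt)^2) else se / Nt
  }
  structure(list(m_hat = m_hat, se_m = se, Nt = Nt,
                 mu_hat = mu, se_mu = se_mu,
                 n_cultures = n_cultures, method = method,
                 fitness_mode = fitness_mode),
            class = "rate_estimate")
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat("Fluctuation-test fit (", x$method,
      if (x$method == "ml") paste0(", fitness ", x$fitness_mode), ")\n",
      sep = "")
  cat(sprintf("  cultures: %d   m = %.4g (se %.3g)\n",
              x$n_cultures, x$m_hat, x$se_m))
  if (x$fitness_mode == "joint")
    cat(sprintf("  fitness = %.4g (se %.3g)\n", x$fitness, x$se_fitness))
  if (!is.null(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.fluctuation_fit <- function(object, ...) {
  ci <- confint(object)
  structure(list(fit = object, ci = ci), class = "summary.fluctuation_fit")
}

#' @export
print.summary.fluctuation_fit <- function(x, ...) {
  print(x$fit)
  if (all(is.finite(x$ci)))
    cat(sprintf("  95%% CI for m: [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  cat(sprintf("  zero-count fraction: %.3f   max count: %d\n",
              mean(x$fit$counts == 0), max(x$fit$counts)))
  invisible(x)
}

#' @export
coef.fluctuation_fit <- function(object, ...) {
  if (object$fitness_mode == "joint")
    c(m = object$m_hat, fitness = object$fitness)
  else c(m = object$m_hat)
}

#' @export
vcov.fluctuation_fit <- function(object, ...) {
  if (object$fitness_mode == "joint") {
    # diagonal only: off-diagonal covariance not retained
    diag(c(object$se_m, object$se_fitness)^2)
  } else {
    matrix(object$se_m^2, dimnames = list("m", "m"))
  }
}

#' @export
confint.fluctuation_fit <- function(object, parm = "m", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = object$m_hat - z * object$se_m,
    upper = object$m_hat + z * object$se_m)
}

#' @export
logLik.fluctuation_fit <- function(object, ...) {
  structure(object$logLik,
            df = if (object$fitness_mode == "joint") 2L else 1L,
            class = "logLik")
}

#' @export
simulate.fluctuation_fit <- function(object, nsim = 1, seed = 0, ...) {
  fitness <- if (is.na(object$fitness)) 1 else object$fitness
  lapply(seq_len(nsim), function(i)
    simulate_counts(object$n_cultures, object$m_hat, fitness,
                    seed = seed + i - 1))
}

#' @export
plot.fluctuation_fit <- function(x, n_max = NULL, ...) {
  if (is.null(n_max)) n_max <- min(max(x$counts), 30)
  obs <- tabulate(pmin(x$counts, n_max) + 1, n_max + 1) / x$n_cultures
  fitness <- if (is.na(x$fitness)) 1 else x$fitness
  th <- ld_pmf(x$m_hat, n_max, fitness)
  th[n_max + 1] <- max(0, 1 - sum(th[1:n_max]))  # pool the tail
  bp <- graphics::barplot(obs, names.arg = c(0:(n_max - 1), paste0(">=", n_max)),
                          ylab = "frequency", xlab = "mutants per culture",
                          main = "Observed vs fitted mutant-count distribution",
                          ...)
  graphics::points(bp, th, pch = 19)
  invisible(x)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Mutation rate: mu = %.4g (se %.3g) per cell per generation\n",
              x$mu_hat, x$se_mu))
  cat(sprintf("  m = %.4g (se %.3g), Nt = %.4g, method %s\n",
              x$m_hat, x$se_m, x$Nt, x$method))
  invisible(x)
}
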