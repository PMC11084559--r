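#' Baseline-category multinomial logistic model for the spectrum
#'
#' Fits log(P(category k) / P(baseline)) = X beta_k for the eight-category
#' spectrum over the strain and glucose factors, on grouped counts, by
#' Newton-Raphson with step halving (convergence when the log-likelihood
#' kernel moves by < 1e-8, maximum 500 iterations; in practice machine
#' precision is reached). Categories with zero total count carry no
#' information and are dropped from the likelihood (recorded in the result).
#' The baseline is the first canonical category present (AT>GC); likelihood
#' ratios are invariant to this choice.
#'
#' @param table a `spectrum_table`.
#' @param formula model formula over `glucose` and `strain`, e.g.
#'   `~ glucose * strain` (default) or `~ 1`.
#' @return object of class `spectrum_multinom`: `coef` (matrix, one column
#'   per non-baseline category), `logLik` (kernel, up to the multinomial
#'   constant), `fitted` (per-cell category probabilities), `categories`,
#'   `dropped`, `converged`, `iterations`, `separation`.
#' @export
fit_multinomial <- function(table, formula = ~ glucose * strain) {
  stopifnot(inherits(table, "spectrum_table"))
  d <- multinom_data(table)
  if (length(d$categories) < 2)
    stop_domain("need at least 2 observed categories")
  X <- stats::model.matrix(formula, d$cells)
  fit <- multinom_newton(X, d$Y)
  structure(c(fit, list(categories = d$categories, dropped = d$dropped,
                        cells = d$cells, formula = formula, X = X)),
            class = "spectrum_multinom")
}

# long spectrum table -> per-cell count matrix over observed categories
multinom_data <- function(table) {
  cats <- mutation_categories()
  key <- interaction(table$strain, table$glucose, drop = TRUE, sep = "\r")
  cells <- unique(data.frame(strain = table$strain,
                             glucose = table$glucose,
                             key = as.character(key),
                             stringsAsFactors = FALSE))
  Y <- matrix(0, nrow(cells), length(cats),
              dimnames = list(cells$key, cats))
  for (r in seq_len(nrow(table)))
    Y[as.character(key)[r], as.character(table$category)[r]] <-
      Y[as.character(key)[r], as.character(table$category)[r]] +
      table$count[r]
  keep <- colSums(Y) > 0
  list(Y = Y[, keep, drop = FALSE],
       categories = cats[keep], dropped = cats[!keep],
       cells = cells[, c("strain", "glucose"), drop = FALSE])
}

multinom_loglik <- function(B, X, Y) {
  eta <- cbind(0, X %*% B)
  eta <- eta - apply(eta, 1, max)
  logZ <- log(rowSums(exp(eta)))
  sum(Y * (eta - logZ))
}

multinom_probs <- function(B, X) {
  eta <- cbind(0, X %*% B)
  eta <- eta - apply(eta, 1, max)
  e <- exp(eta)
  e / rowSums(e)
}

multinom_newton <- function(X, Y, tol = 1e-8, max_iter = 500) {
  K <- ncol(Y); p <- ncol(X); nc <- nrow(X)
  B <- matrix(0, p, K - 1)
  ll <- multinom_loglik(B, X, Y)
  n_i <- rowSums(Y)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    P <- multinom_probs(B, X)
    P2 <- P[, -1, drop = FALSE]
    Y2 <- Y[, -1, drop = FALSE]
    grad <- as.vector(crossprod(X, Y2 - n_i * P2))   # vec over categories
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (i in seq_len(nc)) {
      xi <- X[i, ]
      W <- diag(P2[i, ], K - 1) - tcrossprod(P2[i, ])
      H <- H + n_i[i] * kronecker(W, tcrossprod(xi))
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      Bn <- B + matrix(lambda * step, p, K - 1)
      lln <- multinom_loglik(Bn, X, Y)
      if (is.finite(lln) && lln >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    moved <- lln - ll
    B <- Bn
    ll <- lln
    if (abs(moved) < tol * (1 + abs(ll)) && max(abs(grad)) < 1e-6) {
      converged <- TRUE
      break
    }
  }
  separation <- any(abs(B) > 15)
  if (!converged && max(abs(B)) <= 15)
    warning("multinomial fit did not converge in ", max_iter, " iterations")
  if (separation)
    warning("possible separation: some coefficients diverge; ",
            "likelihood-ratio statistics remain usable")
  list(coef = B, logLik = ll, fitted = multinom_probs(B, X),
       converged = converged, iterations = iter, separation = separation)
}

#' @export
print.spectrum_multinom <- function(x, ...) {
  cat("Multinomial spectrum model (baseline ", x$categories[1], ")\n",
      sep = "")
  cat("  log-likelihood kernel:", format(x$logLik), "\n")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  if (length(x$dropped) > 0)
    cat("  dropped (zero counts):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.spectrum_multinom <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coef), class = "logLik")
}

#' Type-II likelihood-ratio tests for the multinomial spectrum model
#'
#' Follows the marginality principle: each main effect (glucose, strain) is
#' tested by dropping it from the additive model; the interaction is tested
#' by dropping it from the full model. With all 8 categories observed and
#' binary predictors every term has 7 degrees of freedom.
#'
#' @param table a `spectrum_table` with both strains and both glucose
#'   levels.
#' @return data.frame with columns `term`, `lr_stat`, `df`, `p`, `model`.
#' @export
type2_tests_multinomial <- function(table) {
  stopifnot(inherits(table, "spectrum_table"))
  fits <- list(
    full = fit_multinomial(table, ~ glucose * strain),
    add = fit_multinomial(table, ~ glucose + strain),
    no_glucose = fit_multinomial(table, ~ strain),
    no_strain = fit_multinomial(table, ~ glucose))
  K1 <- length(fits$full$categories) - 1
  lr <- function(big, small) {
    stat <- max(0, 2 * (fits[[big]]$logLik - fits[[small]]$logLik))
    df <- (ncol(fits[[big]]$X) - ncol(fits[[small]]$X)) * K1
    data.frame(term = NA_character_, lr_stat = stat, df = df,
               p = chisq_sf(stat, df), model = "multinomial",
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    within(lr("add", "no_glucose"), term <- "glucose"),
    within(lr("add", "no_strain"), term <- "strain"),
    within(lr("full", "add"), term <- "interaction"))
  rownames(out) <- NULL
  out
}

#' Per-class binomial logistic model with Type-II LR tests
#'
#' Collapses the spectrum to "is this category vs any other" and fits
#' logistic regressions (via [stats::glm()] with a binomial family) under
#' the same Type-II protocol; every term has 1 degree of freedom.
#'
#' @param table a `spectrum_table`.
#' @param category one of [mutation_categories()].
#' @return data.frame with `term`, `lr_stat`, `df`, `p`, `model`; if the
#'   category was never observed the statistics are `NA` and the result is
#'   flagged through a `degenerate` attribute plus a warning.
#' @export
fit_binomial_class <- function(table, category) {
  stopifnot(inherits(table, "spectrum_table"))
  if (!category %in% mutation_categories())
    stop_domain("unknown category: ", category)
  d <- multinom_data(table)
  cells <- d$cells
  tot <- rowSums(d$Y)
  succ <- if (category %in% colnames(d$Y)) d$Y[, category] else rep(0, nrow(cells))
  dat <- cbind(cells, s = succ, f = tot - succ)
  if (sum(succ) == 0 || sum(succ) == sum(tot)) {
    warning("category '", category,
            "' degenerate (never or always observed): tests undefined")
    out <- data.frame(term = c("glucose", "strain", "interaction"),
                      lr_stat = NA_real_, df = 1L, p = NA_real_,
                      model = paste0("binomial:", category),
                      stringsAsFactors = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  dev <- function(f)
    stats::glm(f, family = stats::binomial(),
               data = dat, control = list(epsilon = 1e-12, maxit = 200))$deviance
  has_glu <- length(unique(dat$glucose)) > 1
  has_str <- length(unique(dat$strain)) > 1
  if (has_glu && has_str) {
    d_full <- dev(cbind(s, f) ~ glucose * strain)
    d_add <- dev(cbind(s, f) ~ glucose + strain)
    lr <- c(glucose = max(0, dev(cbind(s, f) ~ strain) - d_add),
            strain = max(0, dev(cbind(s, f) ~ glucose) - d_add),
            interaction = max(0, d_add - d_full))
  } else if (has_glu) {           # single-strain table: one-predictor model
    lr <- c(glucose = max(0, dev(cbind(s, f) ~ 1) -
                            dev(cbind(s, f) ~ glucose)))
  } else if (has_str) {
    lr <- c(strain = max(0, dev(cbind(s, f) ~ 1) -
                           dev(cbind(s, f) ~ strain)))
  } else {
    stop_domain("need at least two conditions to test")
  }
  out <- data.frame(term = names(lr), lr_stat = unname(lr), df = 1L,
                    p = chisq_sf(unname(lr), 1),
                    model = paste0("binomial:", category),
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- FALSE
  out
}

#' All spectrum hypothesis tests
#'
#' Runs the multinomial Type-II tests plus the per-class binomial tests for
#' every canonical category. P-values are reported without multiplicity
#' correction (each model answers one planned comparison).
#'
#' @param table a `spectrum_table`.
#' @param classes categories for the per-class models (default all 8).
#' @return data.frame stacking all test rows.
#' @export
test_spectrum <- function(table, classes = mutation_categories()) {
  res <- list(type2_tests_multinomial(table))
  for (cl in classes) {
    r <- suppressWarnings(fit_binomial_class(table, cl))
    res[[length(res) + 1]] <- r
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
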