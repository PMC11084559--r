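#' Lea-Coulson clone-size distribution
#'
#' Probability that a single mutation event, arising at a random time during
#' exponential growth, founds a resistant clone of final size `k`. With mutant
#' relative fitness \eqn{\rho} the law is
#' \deqn{q_k = \rho\,\Gamma(k)\,\Gamma(\rho+1)/\Gamma(k+\rho+1),}
#' which reduces to the classical \eqn{1/(k(k+1))} when \eqn{\rho = 1}.
#'
#' @param k vector of clone sizes (positive integers).
#' @param fitness mutant growth rate relative to the wild type
#'   (\eqn{\rho > 0}); 1 means mutants grow as fast as non-mutants.
#' @return numeric vector of probabilities, same length as `k`.
#' @examples
#' clone_size_pmf(1:5, fitness = 1)   # 1/2, 1/12, ...
#' @export
clone_size_pmf <- function(k, fitness = 1) {
  fitness <- check_scalar(fitness, "fitness", lower = 0, strict = TRUE)
  if (!is.numeric(k) || any(is.na(k)) || any(k < 1) || any(k != floor(k)))
    stop_domain("'k' must contain positive integers")
  fitness * exp(lgamma(k) + lgamma(fitness + 1) - lgamma(k + fitness + 1))
}

# Survival function P(K > k) of the clone-size law; telescoping sum of q_k
# gives S_k = Gamma(rho+1) Gamma(k+1) / Gamma(k+rho+1), with S_0 = 1.
clone_size_sf <- function(k, fitness) {
  exp(lgamma(fitness + 1) + lgamma(k + 1) - lgamma(k + fitness + 1))
}

# Exact inverse-CDF sampler for clone sizes: smallest k with S_k <= 1 - U,
# found by vectorised binary search on the closed-form survival function.
sample_clone_sizes <- function(n, fitness = 1, cap = Inf) {
  if (n == 0L) return(integer(0))
  tail_target <- 1 - runif(n)           # in (0, 1]
  if (fitness == 1) {
    # S_k = 1/(k+1): k = ceiling(1/T - 1)
    k <- pmax(1, ceiling(1 / tail_target - 1))
  } else {
    lo <- rep(1, n)                      # S_1 = 1/(rho+1) may already be <= T
    hi <- rep(2, n)
    while (any(grow <- clone_size_sf(hi, fitness) > tail_target)) {
      hi[grow] <- hi[grow] * 2
      if (max(hi) > 2^62) break
    }
    while (any(hi > lo + 0.5)) {
      mid <- floor((lo + hi) / 2)
      below <- clone_size_sf(mid, fitness) <= tail_target
      hi[below] <- mid[below]
      lo[!below] <- mid[!below]
      eq <- hi == lo
      lo[eq] <- hi[eq]
    }
    done <- clone_size_sf(1, fitness) <= tail_target
    k <- ifelse(done, 1, hi)
  }
  pmin(k, cap)
}

#' Luria-Delbruck mutant-count probabilities
#'
#' Probability mass function of the number of resistant mutants per culture
#' under the compound-Poisson (Lea-Coulson) model: the number of mutation
#' events is Poisson with mean `m` and each event founds a clone with sizes
#' following [clone_size_pmf()]. Computed by the Panjer-type recursion
#' \deqn{p_0 = e^{-m}, \qquad p_n = \frac{m}{n}\sum_{k=1}^{n} k\,q_k\,p_{n-k}.}
#'
#' @param m expected number of mutation events per culture (>= 0).
#' @param n_max largest count for which a probability is returned.
#' @param fitness mutant relative fitness \eqn{\rho}.
#' @return numeric vector of length `n_max + 1`: probabilities of counts
#'   `0:n_max`.
#' @examples
#' ld_pmf(1, 5)         # p_0 = exp(-1), p_1 = exp(-1)/2, ...
#' sum(ld_pmf(2, 500))  # close to 1
#' @export
ld_pmf <- function(m, n_max, fitness = 1) {
  m <- check_scalar(m, "m", lower = 0)
  n_max <- check_scalar(n_max, "n_max", lower = 0)
  p <- numeric(n_max + 1)
  p[1] <- exp(-m)
  if (n_max >= 1 && m > 0) {
    kq <- (1:n_max) * clone_size_pmf(1:n_max, fitness)
    for (n in 1:n_max)
      p[n + 1] <- (m / n) * sum(kq[1:n] * p[n:1])
  }
  p
}

#' Simulate fluctuation-test mutant counts
#'
#' Draws the number of mutation events per culture from a Poisson
#' distribution with mean `m`, then a clone size for each event from the
#' Lea-Coulson law with relative fitness `fitness`, truncating every clone at
#' `nt_cap` (a clone cannot outgrow the culture). The mutant count of a
#' culture is the sum of its clone sizes.
#'
#' @param n_cultures number of parallel cultures.
#' @param m expected mutation events per culture.
#' @param fitness mutant relative fitness.
#' @param nt_cap maximum size of any single clone (default 1e9 cells).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return numeric vector of mutant counts, one per culture.
#' @examples
#' counts <- simulate_counts(182, m = 1, seed = 1)
#' mean(counts == 0)  # about exp(-1)
#' @export
simulate_counts <- function(n_cultures, m, fitness = 1, nt_cap = 1e9,
                            seed = 0) {
  n_cultures <- check_scalar(n_cultures, "n_cultures", lower = 1)
  m <- check_scalar(m, "m", lower = 0)
  check_scalar(nt_cap, "nt_cap", lower = 0, strict = TRUE)
  local_seed(seed, {
    events <- stats::rpois(n_cultures, m)
    total <- sum(events)
    counts <- numeric(n_cultures)
    if (total > 0) {
      sizes <- sample_clone_sizes(total, fitness, cap = nt_cap)
      owner <- rep.int(seq_len(n_cultures), events)
      agg <- rowsum(as.numeric(sizes), owner)
      counts[as.integer(rownames(agg))] <- agg[, 1]
    }
    counts
  })
}

#' Log-likelihood of mutant counts under the Luria-Delbruck model
#'
#' Counts are winsorized at `winsor_cap` before evaluation: any count above
#' the cap is replaced by the cap. This stabilises the heavy-tailed
#' likelihood against jackpot cultures and makes the likelihood invariant to
#' the exact size of extreme counts.
#'
#' @param counts non-negative integer vector of mutant counts.
#' @param m expected mutation events per culture.
#' @param fitness mutant relative fitness.
#' @param winsor_cap winsorization cap (positive integer, default 1024).
#' @return the log-likelihood (a single number; `-Inf` when `m = 0` and any
#'   count is positive).
#' @examples
#' ld_loglik(c(0, 0), m = 1)  # -2
#' @export
ld_loglik <- function(counts, m, fitness = 1, winsor_cap = 1024) {
  counts <- check_counts(counts)
  m <- check_scalar(m, "m", lower = 0)
  check_scalar(winsor_cap, "winsor_cap", lower = 1)
  cw <- pmin(counts, winsor_cap)
  if (m == 0) return(if (all(cw == 0)) 0 else -Inf)
  p <- ld_pmf(m, max(cw), fitness)
  sum(log(p[cw + 1]))
}
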