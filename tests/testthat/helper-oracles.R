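# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# clone-size sampler by table inversion of the directly-evaluated pmf
# q_k = rho * Gamma(k) Gamma(rho+1) / Gamma(k+rho+1), table to k_max with the
# tail lumped into k_max + 1
oracle_sample_clones <- function(n, fitness, k_max = 1e5) {
  k <- seq_len(k_max)
  q <- fitness * exp(lgamma(k) + lgamma(fitness + 1) - lgamma(k + fitness + 1))
  cdf <- cumsum(q)
  findInterval(runif(n), cdf) + 1
}

# simulate Luria-Delbruck mutant counts from first principles (independent
# of fluctspec::simulate_counts)
oracle_simulate_ld <- function(n_cultures, m, fitness) {
  events <- rpois(n_cultures, m)
  sizes <- oracle_sample_clones(sum(events), fitness)
  counts <- numeric(n_cultures)
  if (sum(events) > 0) {
    agg <- rowsum(sizes, rep.int(seq_len(n_cultures), events))
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  counts
}

# brute-force grid-search maximizer of the LD likelihood
oracle_grid_mle <- function(counts, grid = seq(0.001, 2, by = 0.001)) {
  ll <- vapply(grid, function(m) ld_loglik(counts, m), numeric(1))
  grid[which.max(ll)]
}

# classical G statistic (likelihood-ratio chi-square) of a contingency table
oracle_g_stat <- function(M) {
  E <- outer(rowSums(M), colSums(M)) / sum(M)
  2 * sum(ifelse(M > 0, M * log(M / E), 0))
}

# a small spectrum table fixture builder
make_spectrum <- function(counts_by_condition) {
  cats <- mutation_categories()
  rows <- lapply(names(counts_by_condition), function(key) {
    parts <- strsplit(key, "\\.")[[1]]
    data.frame(category = cats, strain = parts[1], glucose = parts[2],
               count = counts_by_condition[[key]],
               stringsAsFactors = FALSE)
  })
  as_spectrum_table(do.call(rbind, rows))
}
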