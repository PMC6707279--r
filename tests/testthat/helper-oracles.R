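# Independent oracles used by the tests.  Each re-derives its quantity from
# first principles (direct formulas, grids, enumeration) without touching
# the package's implementation path.

# Efron partial log-likelihood of a univariate Cox model, written directly
# from the definition: at each distinct event time with tied event set D
# (size d) and risk set R,
#   l(b) += sum_{i in D} x_i b - sum_{l=0}^{d-1}
#             log( sum_{R} e^{xb} - (l/d) sum_{D} e^{xb} ).
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumR <- sum(exp(x[R] * beta))
    sumD <- sum(exp(x[D] * beta))
    ll <- ll + sum(x[D]) * beta -
      sum(log(sumR - (seq_len(d) - 1) / d * sumD))
  }
  ll
}

# grid-search maximizer of the Efron partial likelihood: four nested grids,
# each 100x finer than the last (final resolution ~6e-10 over [-10, 10])
grid_cox_beta <- function(time, event, x, lo = -10, hi = 10) {
  centre <- 0
  width <- hi - lo
  for (stage in 1:4) {
    grid <- seq(centre - width / 2, centre + width / 2, length.out = 401L)
    ll <- vapply(grid, efron_loglik, 0, time = time, event = event, x = x)
    centre <- grid[which.max(ll)]
    width <- width / 100
  }
  centre
}

# direct O(N) weighted-KS running sum: walk the ranked list, track the
# signed maximum deviation from zero
brute_force_es <- function(ranked_genes, scores, gene_set, p = 1) {
  N <- length(ranked_genes)
  hit <- ranked_genes %in% gene_set
  k <- sum(hit)
  stopifnot(k >= 1)
  a <- abs(scores)^p
  denom <- sum(a[hit])
  running <- 0
  best <- 0
  for (i in seq_len(N)) {
    running <- running +
      if (hit[i]) {
        if (denom > 0) a[i] / denom else 1 / k
      } else -1 / (N - k)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# two-group log-rank chi-square from the observed-vs-expected summation
logrank_chi2_oracle <- function(time, event, group) {
  g1 <- group == unique(group)[1L]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# textbook sum-formula Pearson coefficient
sum_formula_r <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# small survival fixtures (n <= 8) covering ties and censoring, used for
# the Cox oracle-equivalence checks
cox_small_fixtures <- function() {
  list(
    list(time = 1:6, event = rep(1L, 6), x = c(0.2, -1, 0.5, 1.2, -0.3, 0.8)),
    list(time = c(2, 2, 3, 5, 7), event = c(1L, 1L, 0L, 1L, 1L),
         x = c(1.5, -0.5, 0.3, -1.2, 0.9)),
    list(time = c(1, 1, 1, 4, 6, 6, 9, 12), event = c(1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L),
         x = c(0.4, 1.1, -0.7, 0.2, -1.5, 0.6, 1.3, -0.2)),
    list(time = c(3, 5, 5, 8), event = c(1L, 1L, 1L, 0L),
         x = c(-0.8, 0.1, 1.4, -0.4)),
    list(time = c(1, 2, 3, 4, 5, 6, 7), event = c(0L, 1L, 1L, 0L, 1L, 1L, 1L),
         x = c(0.9, -0.2, 1.8, 0.3, -1.1, 0.5, -0.6))
  )
}

# deterministic scratch cohort shared by several module tests
small_cohort <- function(rng_seed = 42, ...) {
  generate_cohort(sim_config(n_samples = 250, module_sizes = c(15, 15),
                             n_noise_genes = 40, rng_seed = rng_seed, ...))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
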