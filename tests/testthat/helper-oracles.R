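# Independent oracles used across the suite. These deliberately take the
# naive route (direct summation, normal equations) so they share no code
# with the implementation paths they check.

# P(X >= k), X ~ Binomial(r, p), by direct term summation
oracle_binom_tail <- function(k, r, p) {
  if (k == 0) return(1)
  t <- k:r
  sum(choose(r, t) * p^t * (1 - p)^(r - t))
}

# two-sided exact binomial p-value by enumeration (minimum-likelihood rule)
oracle_binom_twosided <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# genotype t-statistic by brute-force normal equations on the full design
oracle_ols_t <- function(y, g, covariates = NULL) {
  D <- cbind(1, covariates, g)
  beta <- solve(crossprod(D), crossprod(D, y))
  res <- y - D %*% beta
  df <- length(y) - ncol(D)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(crossprod(D))[ncol(D), ncol(D)])
  as.numeric(beta[ncol(D)] / se)
}

# a small fully-null genotype dataset
null_dataset <- function(N = 120, J = 60, seed = 1, missing_rate = 0.01) {
  generate_dataset(synth_config(N = N, J = J, n_causal = 0,
                                missing_rate = missing_rate, seed = seed))
}

expect_rel_equal <- function(actual, expected, rel = 1e-10) {
  expect_true(all(abs(actual - expected) <= rel * pmax(abs(expected), 1e-300)),
              label = sprintf("max rel err %.3g", max(abs(actual - expected) /
                                                        pmax(abs(expected), 1e-300))))
}
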