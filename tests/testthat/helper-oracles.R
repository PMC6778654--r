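# Independent oracles used by the estimator tests. These reimplement the
# target quantities directly from their definitions (plain dbinom sums and
# exhaustive grids) and share no code with the package's search paths.

# Exhaustive-grid maximum-likelihood beta: the folded two-component
# binomial mixture evaluated literally at every grid value.
oracle_beta_mle <- function(af, cov, step = 1e-4) {
  k <- round(af * cov)
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(b) {
    sum(log(0.5 * dbinom(k, cov, b / 2) + 0.5 * dbinom(k, cov, 1 - b / 2)))
  }, numeric(1))
  grid[which.max(ll)]
}

# Exhaustive-grid clonality fit: every integer state, clonality on a fine
# grid, literal cell-mixture signal expressions, with the same per-copy
# parsimony penalty the fit's selection objective defines.
oracle_clonality_fit <- function(beta, logRp, G, max_cn = 8, w = 0.25,
                                 lambda = 2e-3, c_step = 1e-4) {
  cl_grid <- seq(0, 1, by = c_step)
  best <- list(value = Inf)
  for (a in 0:max_cn) for (b in 0:a) {
    if (a == 1 && b == 1) next
    rA <- G + (1 - G) * (cl_grid * a + 1 - cl_grid)
    rB <- G + (1 - G) * (cl_grid * b + 1 - cl_grid)
    tot <- rA + rB
    beta_exp <- ifelse(tot > 0, 2 * pmin(rA, rB) / tot, 1)
    logR_exp <- ifelse(tot > 0, log2(tot / 2), -Inf)
    val <- (beta_exp - beta)^2 + w * (logR_exp - logRp)^2 + lambda * (a + b)
    i <- which.min(val)
    if (val[i] < best$value) {
      best <- list(value = val[i], cnA = a, cnB = b, clonality = cl_grid[i])
    }
  }
  best
}
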