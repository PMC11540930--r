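# Shared fixtures and independent oracles used across the suite.

# full severity formula over the covariates carrying generative effects
severity_formula <- fatal ~ ems_time + truck + other_vehicle +
  non_local_vehicle + curvature + grade + afternoon + rear_end_crash +
  angle_crash + precipitation

quick_control <- function(n_iter = 4000, n_burnin = 2000, ...) {
  mcmc_control(n_iter = n_iter, n_burnin = n_burnin, ...)
}

# Independent oracle: conditional law of one component of a zero-mean
# Gaussian from its joint precision, by direct partitioning.
conditional_from_precision <- function(Q, m, x) {
  v <- 1 / Q[m, m]
  list(mean = -v * sum(Q[m, -m] * x[-m]), variance = v)
}

# Independent oracle: dense multivariate normal log-density at zero mean.
dense_mvn_logdensity <- function(x, Q) {
  -0.5 * length(x) * log(2 * pi) + 0.5 * determinant(Q)$modulus[1] -
    0.5 * drop(crossprod(x, Q %*% x))
}

# Independent oracle: exact posterior mean of an intercept-only logistic
# model by 1-D quadrature under the N(0, 1e4) coefficient prior.
intercept_posterior_mean <- function(n_fatal, n_total) {
  lp <- function(b) n_fatal * b - n_total * log1p(exp(b)) - b^2 / 2e4
  g <- seq(-12, 2, length.out = 40001)
  w <- exp(lp(g) - max(lp(g)))
  sum(g * w) / sum(w)
}

# 1414-crash dataset with exactly 36 fatalities (the observed 2.5% rate)
make_rate_dataset <- function(seed = 1) {
  set.seed(seed)
  data.frame(fatal = sample(c(rep(1, 36), rep(0, 1378))))
}
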