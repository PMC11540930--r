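test_that("defaults follow the estimation protocol", {
  ctl <- mcmc_control()
  expect_equal(ctl$n_iter, 100000L)
  expect_equal(ctl$n_burnin, 50000L)
  pri <- prior_control()
  expect_equal(pri$beta_var, 1e4)
  expect_equal(c(pri$scale_lower, pri$scale_upper), c(0.01, 10))
  expect_error(mcmc_control(n_iter = 100, n_burnin = 100), "smaller")
  expect_error(prior_control(scale_lower = -1), "positive")
})

test_that("identical seeds give identical chains", {
  sim <- simulate_crash_data(n = 250, m = 10, seed = 71)
  fml <- fatal ~ ems_time + truck
  f1 <- spatlogit(fml, sim$data, network = sim$network, family = "rp_spatial",
                  random = "truck", control = quick_control(), seed = 99)
  f2 <- spatlogit(fml, sim$data, network = sim$network, family = "rp_spatial",
                  random = "truck", control = quick_control(), seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- spatlogit(fml, sim$data, network = sim$network, family = "rp_spatial",
                  random = "truck", control = quick_control(), seed = 100)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("family/argument inconsistencies are rejected", {
  sim <- simulate_crash_data(n = 100, m = 5, seed = 72)
  expect_error(spatlogit(fatal ~ ems_time, sim$data, family = "spatial",
                         control = quick_control()), "network")
  expect_error(spatlogit(fatal ~ ems_time, sim$data, network = sim$network,
                         family = "rp_spatial", control = quick_control()),
               "random")
  expect_error(spatlogit(fatal ~ ems_time, sim$data, network = sim$network,
                         family = "rp_spatial", random = "nope",
                         control = quick_control()), "not in the model")
  expect_error(spatlogit(fatal ~ ems_time, sim$data, family = "logistic",
                         random = "ems_time", control = quick_control()),
               "only allowed")
})

test_that("prior-only sampling recovers the priors", {
  d <- data.frame(fatal = rbinom(40, 1, 0.5), x = rnorm(40),
                  section_id = as.character(sample(1:3, 40, TRUE)))
  net <- build_adjacency(3)
  fit <- spatlogit(fatal ~ x, d, network = net, family = "rp_spatial",
                   random = "x",
                   control = mcmc_control(n_iter = 40000, n_burnin = 15000,
                                          prior_only = TRUE),
                   seed = 8)
  dr <- fit$draws
  # N(0, 1e4) coefficients: sd near 100
  expect_gt(sd(dr[, "x"]), 80)
  expect_lt(sd(dr[, "x"]), 120)
  # U(0.01, 10) scales: mean near 5.005, within support
  expect_equal(mean(dr[, "sd_x"]), 5.005, tolerance = 0.1)
  expect_true(all(dr[, "sd_x"] >= 0.01 & dr[, "sd_x"] <= 10))
  expect_true(all(dr[, "delta"] >= 0.01 & dr[, "delta"] <= 10))
  # U(0, 1) spatial correlation: mean 0.5, variance 1/12
  expect_equal(mean(dr[, "rho"]), 0.5, tolerance = 0.05)
  expect_equal(var(dr[, "rho"]), 1 / 12, tolerance = 0.15)
  expect_true(all(dr[, "rho"] >= 0 & dr[, "rho"] <= 1))
})

test_that("prior-only section effects sample the Leroux joint", {
  # with no likelihood the phi draws target the joint CAR prior, so their
  # sample covariance must converge to the inverse precision
  d <- data.frame(fatal = rbinom(30, 1, 0.5),
                  section_id = as.character(sample(1:3, 30, TRUE)))
  net <- build_adjacency(3)
  fit <- spatlogit(fatal ~ 1, d, network = net, family = "spatial",
                   control = mcmc_control(n_iter = 60000, n_burnin = 10000,
                                          prior_only = TRUE,
                                          fix_rho = 0.62, fix_delta = 0.74,
                                          phi_keep_max = 50000),
                   seed = 9)
  want <- solve(leroux_precision(0.62, 0.74, net))
  expect_equal(unname(cov(fit$phi_draws)), unname(want), tolerance = 0.12)
  # per-section conditional moments match the analytic conditional law:
  # regression of phi_2 on its neighbors has the Eq.-style coefficients
  c2 <- leroux_conditional(2, c(1, 0, 1), 0.62, 0.74, net)
  # conditional variance = 1/Q[2,2]
  Q <- leroux_precision(0.62, 0.74, net)
  expect_equal(c2$variance, 1 / Q[2, 2], tolerance = 1e-12)
})

test_that("intercept-only posterior matches the quadrature oracle", {
  d <- make_rate_dataset(seed = 5)
  fit <- spatlogit(fatal ~ 1, d, family = "logistic",
                   control = mcmc_control(n_iter = 12000, n_burnin = 4000),
                   seed = 5)
  draws <- fit$draws[, "(Intercept)"]
  oracle <- intercept_posterior_mean(sum(d$fatal), nrow(d))
  expect_lt(abs(mean(draws) - oracle), 3 * mc_error(draws))
})

test_that("posterior SD of the EMS effect shrinks at roughly the root-n rate", {
  fml <- fatal ~ ems_time + truck
  sds <- vapply(c(700, 2800), function(n) {
    sim <- simulate_crash_data(n = n, m = 20, seed = 73)
    fit <- spatlogit(fml, sim$data, family = "logistic",
                     control = quick_control(6000, 3000), seed = 73)
    summarize_posterior(fit$draws)$sd[2]
  }, 0)
  ratio <- sds[1] / sds[2]   # expect about sqrt(4) = 2
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.0)
})

test_that("genuine heterogeneity is retained by the collapse rule", {
  # the detectable half of the retain-or-collapse decision: data generated
  # with real truck heterogeneity keep their random coefficient (the
  # undetectable null half is discussed in the methods vignette)
  verdicts <- vapply(1:2, function(s) {
    sim <- simulate_crash_data(seed = s)
    fit <- spatlogit(severity_formula, sim$data, network = sim$network,
                     family = "rp_spatial", random = "truck",
                     control = mcmc_control(n_iter = 8000, n_burnin = 4000),
                     seed = s)
    classify_random_parameter(fit, covariate = "truck")
  }, "")
  expect_true(all(verdicts == "random"))
})

test_that("model methods expose the fit coherently", {
  sim <- simulate_crash_data(n = 300, m = 12, seed = 74)
  fit <- spatlogit(fatal ~ ems_time + truck, sim$data, network = sim$network,
                   family = "rp_spatial", random = "truck",
                   control = quick_control(), seed = 74)
  expect_named(coef(fit), c("(Intercept)", "ems_time", "truck"))
  expect_equal(fitted(fit), plogis(fit$eta_mean))
  expect_equal(residuals(fit), fit$y - fitted(fit))
  expect_length(predict(fit, sim$data[1:5, ]), 5)
  expect_true(all(predict(fit, sim$data[1:5, ]) >= 0))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(300L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  s <- summary(fit)
  expect_s3_class(s, "summary.spatlogit")
  expect_output(print(s), "DIC")
  expect_output(print(fit), "spatial logistic")
  # DIC identity on a real fit
  expect_equal(fit$dic$dic, fit$dic$dbar + fit$dic$pd)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, parameters = c("ems_time", "rho")))
})
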