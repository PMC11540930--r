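test_that("posterior summaries flag significance by interval exclusion", {
  # degenerate chain at a nonzero constant
  s <- summarize_posterior(matrix(rep(2.5, 200), ncol = 1,
                                  dimnames = list(NULL, "c")))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 0)
  expect_true(s$sig90 && s$sig95)

  set.seed(1)
  z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z"))
  s2 <- summarize_posterior(z)
  expect_equal(s2$lower95, -1.96, tolerance = 0.03)
  expect_equal(s2$upper95, 1.96, tolerance = 0.03)
  expect_false(s2$sig90 || s2$sig95)
  # null case: symmetric draws give an odds-ratio point estimate of 1
  expect_equal(exp(s2$mean), 1, tolerance = 0.03)
  expect_error(summarize_posterior(matrix(numeric(), 0, 1)), "no posterior")
})

test_that("the 90% interval is nested in the 95% interval", {
  set.seed(2)
  s <- summarize_posterior(matrix(rnorm(5000, 1, 2), ncol = 1,
                                  dimnames = list(NULL, "p")))
  expect_gte(s$lower90, s$lower95)
  expect_lte(s$upper90, s$upper95)
  # significance at 95% implies significance at 90%
  s3 <- summarize_posterior(matrix(rnorm(5000, 5, 1), ncol = 1,
                                   dimnames = list(NULL, "p")))
  expect_true(!s3$sig95 || s3$sig90)
})

test_that("convergence rule is strict and degenerate chains are indeterminate", {
  set.seed(3)
  iid <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "ok"))
  expect_true(convergence_check(iid)$pass)
  walk <- matrix(cumsum(rnorm(10000)), ncol = 1, dimnames = list(NULL, "rw"))
  expect_false(convergence_check(walk)$pass)
  flat <- matrix(rep(1, 10000), ncol = 1, dimnames = list(NULL, "const"))
  expect_true(is.na(convergence_check(flat)$pass))
  # batch-means error of an iid chain is close to sd/sqrt(n)
  x <- rnorm(20000)
  expect_equal(mc_error(x), sd(x) / sqrt(length(x)), tolerance = 0.25)
})

test_that("heterogeneity share reproduces the truck-effect split", {
  expect_equal(round(heterogeneity_share(0.51, 1.23)), 66)
  expect_equal(heterogeneity_share(0.51, 1.23), 100 * pnorm(0.51 / 1.23))
  expect_equal(heterogeneity_share(0, 2), 50)
  expect_equal(heterogeneity_share(0.3, 1e-12), 100)
  # invariant to common rescaling
  expect_equal(heterogeneity_share(0.51, 1.23),
               heterogeneity_share(5.1, 12.3))
  expect_error(heterogeneity_share(1, 0), "positive")
})

test_that("marginal effects match brute-force finite differences", {
  X <- cbind("(Intercept)" = 1, ems = c(5, 20, 60), truck = c(0, 1, 1))
  beta <- c("(Intercept)" = -4, ems = 0.03, truck = 0.5)
  eta <- drop(X %*% beta)
  want <- mean(plogis(eta + 0.03 * 10) - plogis(eta))
  expect_equal(ame_profile(X, beta, "ems", delta = 10), want,
               tolerance = 1e-12)
  expect_error(ame_profile(X, beta, "nope", 1), "unknown covariate")
})

test_that("fit-level AME is zero when the coefficient is null", {
  sim <- simulate_crash_data(n = 200, m = 8, seed = 51)
  fit <- spatlogit(fatal ~ ems_time + truck, sim$data, family = "logistic",
                   control = quick_control(1500, 500), seed = 51)
  fit$draws[, "ems_time"] <- 0
  fit$eta_mean <- drop(fit$X %*% colMeans(fit$draws[, colnames(fit$X)]))
  expect_equal(average_marginal_effect(fit, "ems_time", 10), 0)
  expect_equal(average_marginal_effect(fit, "ems_time", 10,
                                       method = "plugin"), 0)
  expect_error(average_marginal_effect(fit, "truck", 1), "indicator")
})

test_that("DIC bookkeeping holds its identity on every reported column", {
  cols <- list(c(285, 18, 303), c(259, 28, 287), c(236, 35, 271))
  for (cc in cols) {
    r <- dic_report(cc[1], cc[2])
    expect_equal(r$dic, cc[3])
    expect_equal(r$dic - r$dbar - r$pd, 0)
  }
  # point-mass posterior: no effective parameters
  r0 <- dic_report(100, 0)
  expect_equal(r0$dic, r0$dbar)
  expect_error(dic_report(NaN, 1), "finite")
})

test_that("DIC comparison applies the strict >10 superiority rule", {
  cmp <- compare_models(logistic = dic_report(285, 18),
                        spatial = dic_report(259, 28))
  expect_equal(cmp$model[1], "spatial")
  expect_equal(cmp$dic, c(287, 303))
  sup <- attr(cmp, "superior")
  expect_true(sup["spatial", "logistic"])   # delta = 16 > 10
  expect_false(sup["logistic", "spatial"])

  # boundary: a difference of exactly 10 is not decisive
  cmp10 <- compare_models(a = dic_report(290, 10), b = dic_report(280, 10))
  expect_false(any(attr(cmp10, "superior")))

  # ties carry no verdict
  cmpeq <- compare_models(a = dic_report(280, 10), b = dic_report(280, 10))
  expect_false(any(attr(cmpeq, "superior")))
  expect_error(compare_models(dic_report(1, 1)), "at least two")
})

test_that("fits on different datasets refuse DIC comparison", {
  s1 <- simulate_crash_data(n = 150, m = 5, seed = 61)
  s2 <- simulate_crash_data(n = 160, m = 5, seed = 62)
  f1 <- spatlogit(fatal ~ ems_time, s1$data, family = "logistic",
                  control = quick_control(1200, 400), seed = 1)
  f2 <- spatlogit(fatal ~ ems_time, s2$data, family = "logistic",
                  control = quick_control(1200, 400), seed = 1)
  expect_error(compare_models(f1, f2), "different datasets")
})

test_that("random-parameter classification follows the lower-quantile rule", {
  set.seed(4)
  concentrated <- rnorm(5000, 1.23, 0.16)
  expect_equal(classify_random_parameter(concentrated), "random")
  piled <- abs(rnorm(5000, 0, 0.005)) + 0.01
  expect_equal(classify_random_parameter(piled), "collapse_to_fixed")
  expect_error(classify_random_parameter(numeric()), "empty")
})
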