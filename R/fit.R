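#' Prior settings
#'
#' Diffuse priors used for all model families: N(0, `beta_var`) on the fixed
#' coefficients and random-coefficient means (variance parameterization, so
#' the default is SD 100), U(0, 1) on the spatial-correlation strength `rho`,
#' and U(`scale_lower`, `scale_upper`) on the conditional spatial scale
#' `delta` and the random-coefficient standard deviations `sigma_j`.
#'
#' @param beta_var Prior variance of the normal coefficient prior.
#' @param scale_lower,scale_upper Support of the uniform prior on scale
#'   parameters.
#' @return A list of class `spatlogit_priors`.
#' @export
prior_control <- function(beta_var = 1e4, scale_lower = 0.01,
                          scale_upper = 10) {
  if (beta_var <= 0) stop("'beta_var' must be positive")
  if (scale_lower <= 0 || scale_upper <= scale_lower)
    stop("scale prior bounds must be positive and ordered")
  structure(list(beta_var = beta_var, scale_lower = scale_lower,
                 scale_upper = scale_upper),
            class = "spatlogit_priors")
}

#' MCMC settings
#'
#' Defaults follow the estimation protocol the models were designed for: one
#' chain of 100,000 iterations with the first 50,000 discarded as burn-in and
#' no thinning. Proposal scales are tuned by diminishing adaptation during
#' burn-in only.
#'
#' @param n_iter Total iterations.
#' @param n_burnin Burn-in iterations (must be < `n_iter`).
#' @param thin Thinning interval for retained draws.
#' @param adapt_interval Iterations between proposal-scale adaptations.
#' @param target_accept Target acceptance rate of the scalar random-walk
#'   updates.
#' @param prior_only Switch off the likelihood so the sampler targets the
#'   prior (used for sampler validation).
#' @param fix_rho,fix_delta Optionally hold a spatial hyper-parameter fixed.
#' @param init Optional named list overriding initial values (`beta`, `phi`,
#'   `rho`, `delta`, `sigma`); defaults: coefficients and section effects at
#'   0, `rho` at 0.5, `delta` and `sigma` at 1.
#' @param phi_keep_max Maximum number of retained joint draws of the section
#'   effects (they are thinned to this count; means/SDs use every draw).
#' @return A list of class `spatlogit_control`.
#' @export
mcmc_control <- function(n_iter = 100000, n_burnin = 50000, thin = 1,
                         adapt_interval = 100, target_accept = 0.44,
                         prior_only = FALSE, fix_rho = NULL, fix_delta = NULL,
                         init = list(), phi_keep_max = 1000) {
  if (n_burnin >= n_iter) stop("'n_burnin' must be smaller than 'n_iter'")
  if (thin < 1) stop("'thin' must be >= 1")
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept, prior_only = prior_only,
                 fix_rho = fix_rho, fix_delta = fix_delta, init = init,
                 phi_keep_max = as.integer(phi_keep_max)),
            class = "spatlogit_control")
}

#' Bayesian (random-parameters) spatial logistic regression
#'
#' Fits one of three nested Bayesian models for a binary crash-fatality
#' outcome by adaptive Metropolis-within-Gibbs MCMC:
#'
#' * `"logistic"` -- plain logistic regression,
#'   `logit P(Y_i = 1) = beta0 + sum_j beta_j x_ij`;
#' * `"spatial"` -- adds a structured section effect `phi_m` with a Leroux
#'   CAR prior over the section network (hyper-parameters `rho`, `delta`);
#' * `"rp_spatial"` -- additionally lets selected coefficients vary across
#'   crashes, `beta_ij = beta_bar_j + mu_ij` with `mu_ij ~ N(0, sigma_j^2)`,
#'   capturing unobserved heterogeneity in those effects.
#'
#' Priors are diffuse ([prior_control()]); the section effects are updated
#' one at a time from their Leroux full conditionals combined with the
#' section's likelihood contribution, `rho` on the logit scale and scale
#' parameters on the log scale (with an additional joint rescaling move for
#' each `(sigma_j, mu_.j)` block to decouple the mixing-scale update from the
#' crash-level deviations).
#'
#' @param formula Model formula, e.g. `fatal ~ ems_time + truck + grade`.
#' @param data Crash-level data frame (validated with
#'   [validate_crash_data()]).
#' @param network A [build_adjacency()] `section_network`; required for the
#'   spatial families.
#' @param section Name of the column in `data` holding section ids.
#' @param family Model family; one of `"logistic"`, `"spatial"`,
#'   `"rp_spatial"`.
#' @param random Character vector of covariate names (model-matrix column
#'   names) given crash-level random coefficients; required for
#'   `"rp_spatial"`.
#' @param priors A [prior_control()] list.
#' @param control An [mcmc_control()] list.
#' @param seed Integer seed; recorded in the fit.
#' @param verbose Print progress every 10,000 iterations.
#' @return An object of class `spatlogit` with posterior draws (`$draws`),
#'   deviance draws, DIC decomposition (`$dic`), acceptance rates, posterior
#'   means of the section effects and crash-level deviations, and the data
#'   needed by the reporting methods. See [summary.spatlogit()],
#'   [compare_models()], [average_marginal_effect()].
#' @examples
#' sim <- simulate_crash_data(n = 300, m = 20, seed = 1)
#' fit <- spatlogit(fatal ~ ems_time + truck, data = sim$data,
#'                  network = sim$network, family = "spatial",
#'                  control = mcmc_control(n_iter = 2000, n_burnin = 1000),
#'                  seed = 1)
#' summary(fit)
#' @export
spatlogit <- function(formula, data, network = NULL, section = "section_id",
                      family = c("logistic", "spatial", "rp_spatial"),
                      random = NULL, priors = prior_control(),
                      control = mcmc_control(), seed = NULL,
                      verbose = FALSE) {
  family <- match.arg(family)
  cl <- match.call()
  spatial <- family != "logistic"

  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  X <- model.matrix(formula, mf)
  n <- nrow(X)

  if (spatial) {
    if (is.null(network)) stop("a section network is required for family '",
                               family, "'")
    if (!section %in% names(data))
      stop("missing section column '", section, "'")
    sec_id <- as.character(data[[section]])
    sec <- match(sec_id, network$section_ids)
    if (anyNA(sec))
      stop("unknown section id '", sec_id[which(is.na(sec))[1L]], "'")
    M <- network$M
    W <- network$adjacency
    eig <- eigen(diag(network$neighbor_counts, M) - W, symmetric = TRUE,
                 only.values = TRUE)$values
    sec_obs <- lapply(seq_len(M), function(m) which(sec == m) - 1L)
    nbrs <- lapply(seq_len(M), function(m) which(W[m, ] == 1L) - 1L)
  } else {
    sec <- rep(1L, n); M <- 0L
    eig <- numeric(); sec_obs <- list(); nbrs <- list()
  }

  if (family == "rp_spatial") {
    if (is.null(random) || !length(random))
      stop("family 'rp_spatial' needs at least one covariate in 'random'")
    random_idx <- match(random, colnames(X))
    if (anyNA(random_idx))
      stop("random coefficient(s) not in the model matrix: ",
           paste(random[is.na(random_idx)], collapse = ", "))
  } else {
    if (!is.null(random) && length(random))
      stop("'random' is only allowed for family 'rp_spatial'")
    random_idx <- integer()
  }

  init <- control$init
  beta_init <- numeric(ncol(X))
  if (is.null(init$beta) && !control$prior_only) {
    # start the chain at the maximum-likelihood logistic estimates so the
    # burn-in does not have to traverse the flat tail of the likelihood
    ml <- suppressWarnings(try(stats::glm.fit(X, y,
                                              family = stats::binomial()),
                               silent = TRUE))
    if (!inherits(ml, "try-error") && all(is.finite(ml$coefficients)))
      beta_init <- pmax(pmin(ml$coefficients, 10), -10)
  }
  init_full <- list(
    beta = if (!is.null(init$beta)) rep_len(init$beta, ncol(X)) else
      beta_init,
    phi = if (!is.null(init$phi)) rep_len(init$phi, max(M, 1L)) else
      numeric(max(M, 1L)),
    rho = if (!is.null(init$rho)) init$rho else 0.5,
    delta = if (!is.null(init$delta)) init$delta else 1,
    sigma = if (!is.null(init$sigma))
      rep_len(init$sigma, max(length(random_idx), 1L)) else
      rep(1, max(length(random_idx), 1L)))

  if (!is.null(seed)) set.seed(seed)
  res <- run_sampler(
    as.numeric(y), X, as.integer(sec - 1L),
    sec_obs, nbrs,
    as.numeric(if (spatial) network$neighbor_counts else numeric()),
    as.numeric(eig),
    match(family, c("logistic", "spatial", "rp_spatial")) - 1L,
    as.integer(random_idx - 1L),
    priors$beta_var, priors$scale_lower, priors$scale_upper,
    control$n_iter, control$n_burnin, control$thin,
    control$adapt_interval, control$target_accept,
    control$prior_only, init_full,
    if (is.null(control$fix_rho)) NA_real_ else control$fix_rho,
    if (is.null(control$fix_delta)) NA_real_ else control$fix_delta,
    control$phi_keep_max, verbose)

  par_names <- colnames(X)
  if (length(random_idx))
    par_names <- c(par_names, paste0("sd_", colnames(X)[random_idx]))
  if (spatial) par_names <- c(par_names, "rho", "delta")
  colnames(res$draws) <- par_names

  acc <- res$accept
  scalar_acc <- c(acc$beta, acc$mu, acc$sigma, acc$sigma_rescale,
                  acc$phi, acc$rho, acc$delta)
  if (!control$prior_only && all(is.na(scalar_acc) | scalar_acc == 0))
    stop("sampler failed: zero acceptance for every block after adaptation")

  dev <- res$deviance
  dbar <- mean(dev)
  dhat <- -2 * log_likelihood(as.numeric(y), res$eta_mean)
  pd <- dbar - dhat
  dic <- dic_report(dbar, pd)

  fit <- structure(list(
    call = cl, formula = formula, family = family, random = random,
    n_obs = n, y = as.numeric(y), X = X,
    section = if (spatial) sec_id else NULL,
    network = if (spatial) network else NULL,
    draws = res$draws, deviance = dev,
    eta_mean = res$eta_mean,
    phi_mean = if (spatial) stats::setNames(res$phi_mean,
                                            network$section_ids) else NULL,
    phi_sd = if (spatial) res$phi_sd else NULL,
    phi_draws = if (spatial) res$phi_draws else NULL,
    mu_mean = if (length(random_idx)) res$mu_mean else NULL,
    acceptance = acc, dic = dic,
    priors = unclass(priors),
    control = unclass(control)[c("n_iter", "n_burnin", "thin",
                                 "adapt_interval", "target_accept",
                                 "prior_only")],
    seed = seed), class = "spatlogit")
  fit
}
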