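#' Batch-means Monte Carlo standard error
#'
#' Estimates the Monte Carlo error of a posterior-mean estimate from a single
#' chain by the batch-means method.
#'
#' @param x Numeric vector of post-burn-in draws.
#' @param n_batches Number of batches (default 50).
#' @return The Monte Carlo standard error.
#' @export
mc_error <- function(x, n_batches = 50) {
  n <- length(x)
  if (n < 2 * n_batches)
    stop("need at least ", 2 * n_batches, " draws for ", n_batches, " batches")
  b <- n %/% n_batches
  means <- colMeans(matrix(x[seq_len(b * n_batches)], nrow = b))
  sd(means) / sqrt(n_batches)
}

#' Posterior summary table
#'
#' Posterior mean, SD, equal-tailed credible intervals, significance flags
#' (a parameter is "significant at level L" when its L-interval excludes 0)
#' and batch-means Monte Carlo error per monitored parameter.
#'
#' @param draws Matrix of post-burn-in draws (one column per parameter) or a
#'   numeric vector for a single parameter.
#' @param levels Credibility levels for the intervals.
#' @param n_batches Batches for [mc_error()].
#' @return A data frame with one row per parameter.
#' @export
summarize_posterior <- function(draws, levels = c(0.90, 0.95),
                                n_batches = 50) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "parameter"))
  if (nrow(draws) == 0L) stop("no posterior draws to summarize")
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    sd = apply(draws, 2L, sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (L in levels) {
    a <- (1 - L) / 2
    q <- apply(draws, 2L, quantile, probs = c(a, 1 - a), names = FALSE)
    tag <- sprintf("%g", 100 * L)
    out[[paste0("lower", tag)]] <- q[1L, ]
    out[[paste0("upper", tag)]] <- q[2L, ]
    out[[paste0("sig", tag)]] <- q[1L, ] > 0 | q[2L, ] < 0
  }
  out$mc_error <- apply(draws, 2L, function(x) {
    if (length(x) >= 2 * n_batches) mc_error(x, n_batches) else NA_real_
  })
  out$mc_ratio <- ifelse(out$sd > 0, out$mc_error / out$sd, NA_real_)
  out
}

#' Convergence check by the Monte-Carlo-error rule
#'
#' A parameter's chain is flagged as converged when its Monte Carlo error is
#' less than 5% of its posterior standard deviation (strict inequality).
#' Degenerate (constant) chains give a 0/0 ratio and are flagged
#' indeterminate (`NA`), not passed.
#'
#' @param object A fitted [spatlogit()] model or a draws matrix.
#' @param threshold Ratio threshold (default 0.05).
#' @param n_batches Batches for [mc_error()].
#' @return Data frame with columns `parameter`, `mc_error`, `sd`, `ratio`,
#'   `pass`.
#' @export
convergence_check <- function(object, threshold = 0.05, n_batches = 50) {
  draws <- if (inherits(object, "spatlogit")) object$draws else object
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "parameter"))
  if (nrow(draws) < 2 * n_batches)
    stop("need at least ", 2 * n_batches, " post-burn-in draws")
  s <- apply(draws, 2L, sd)
  e <- apply(draws, 2L, mc_error, n_batches = n_batches)
  ratio <- ifelse(s > 0, e / s, NA_real_)
  data.frame(parameter = colnames(draws), mc_error = e, sd = s,
             ratio = ratio,
             pass = ifelse(is.na(ratio), NA, ratio < threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Share of crashes with a positive random coefficient
#'
#' Under normal mixing `beta_i ~ N(beta_bar, sigma^2)`, the share of crashes
#' whose coefficient is positive is `Phi(beta_bar / sigma)`; e.g. a mean of
#' 0.51 with SD 1.23 implies about 66% of truck-involved crashes carry an
#' elevated fatality risk while the rest carry a reduced one.
#'
#' @param beta_bar Coefficient mean.
#' @param sigma Coefficient standard deviation (> 0).
#' @return Percent of crashes with a positive coefficient.
#' @export
heterogeneity_share <- function(beta_bar, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  100 * pnorm(beta_bar / sigma)
}

#' Average marginal effect of a continuous covariate
#'
#' Mean change in fatality probability when a covariate is increased by
#' `delta` for every crash, other covariates held at their observed values:
#' `AME = mean_i [p1(x_ij + delta) - p1(x_ij)]`. For a fitted model the
#' effect is averaged over posterior coefficient draws by default
#' (`method = "posterior"`; section effects and crash-level deviations enter
#' at their posterior means), or evaluated at posterior means
#' (`method = "plugin"`).
#'
#' Indicator covariates are rejected: their effect is a category contrast,
#' reported as an odds ratio instead.
#'
#' @param object A fitted [spatlogit()] model.
#' @param covariate Model-matrix column name of a continuous covariate.
#' @param delta Increase applied to the covariate (same units).
#' @param method `"posterior"` or `"plugin"`.
#' @return The average marginal effect (a scalar probability change).
#' @seealso [ame_profile()] for the same quantity at fixed coefficients.
#' @export
average_marginal_effect <- function(object, covariate, delta = 1,
                                    method = c("posterior", "plugin")) {
  stopifnot(inherits(object, "spatlogit"))
  method <- match.arg(method)
  X <- object$X
  if (!covariate %in% colnames(X)) stop("unknown covariate '", covariate, "'")
  xj <- X[, covariate]
  if (all(xj %in% c(0, 1)))
    stop("'", covariate, "' is an indicator; report its odds ratio instead")
  bnames <- colnames(X)
  offset <- object$eta_mean - drop(X %*% colMeans(object$draws[, bnames,
                                                               drop = FALSE]))
  if (method == "plugin") {
    beta_hat <- colMeans(object$draws[, bnames, drop = FALSE])
    return(ame_profile(X, beta_hat, covariate, delta, offset = offset))
  }
  draws <- object$draws[, bnames, drop = FALSE]
  if (nrow(draws) > 2000) {
    keep <- unique(round(seq(1L, nrow(draws), length.out = 2000)))
    draws <- draws[keep, , drop = FALSE]
  }
  eta <- tcrossprod(X, draws) + offset          # n x S
  shift <- delta * draws[, covariate]
  mean(plogis(sweep(eta, 2L, shift, "+")) - plogis(eta))
}

#' Marginal effect at fixed coefficients
#'
#' Brute-force finite-difference average marginal effect of increasing one
#' covariate by `delta`, at a single fixed coefficient vector. Useful for
#' evaluating effects at known (e.g. generative) parameter values.
#'
#' @param X Covariate matrix (including any intercept column).
#' @param beta Coefficient vector matching `colnames(X)`.
#' @param covariate Column name of the covariate to perturb.
#' @param delta Increase applied to the covariate.
#' @param offset Optional additive term (e.g. section effects) per crash.
#' @return The average marginal effect.
#' @export
ame_profile <- function(X, beta, covariate, delta = 1, offset = 0) {
  if (!covariate %in% colnames(X)) stop("unknown covariate '", covariate, "'")
  eta <- drop(X %*% beta) + offset
  mean(plogis(eta + delta * beta[[covariate]]) - plogis(eta))
}

#' DIC bookkeeping
#'
#' The deviance information criterion decomposes as `DIC = Dbar + pD`, where
#' `Dbar` is the posterior mean deviance (model fit) and `pD = Dbar - D(theta
#' hat)` the effective number of parameters (model complexity).
#'
#' @param dbar Posterior mean deviance.
#' @param pd Effective number of parameters.
#' @return An object of class `dic_report`: list with `dbar`, `pd`, `dic`.
#' @export
dic_report <- function(dbar, pd) {
  if (!is.finite(dbar) || !is.finite(pd))
    stop("DIC components must be finite")
  structure(list(dbar = dbar, pd = pd, dic = dbar + pd),
            class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("Dbar = %.1f, pD = %.1f, DIC = %.1f\n", x$dbar, x$pd, x$dic))
  invisible(x)
}

#' Compare models by DIC
#'
#' Ranks fitted models (or bare [dic_report()]s) by DIC. A model is flagged
#' "considerably superior" to another when its DIC is lower by strictly more
#' than 10; a difference of exactly 10 or less is not decisive.
#'
#' @param ... Fitted [spatlogit()] models and/or `dic_report` objects; names
#'   are used as model labels.
#' @param decisive_delta Decision threshold on the DIC difference.
#' @return A data frame sorted by DIC with columns `model`, `dbar`, `pd`,
#'   `dic`, `delta_dic` (difference to the best model) and
#'   `considerably_superior_to_next`. A pairwise logical matrix
#'   (`[i, j]` = model i considerably superior to model j) is attached as
#'   attribute `"superior"`.
#' @export
compare_models <- function(..., decisive_delta = 10) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], c("spatlogit", "dic_report")))
    fits <- fits[[1L]]
  if (length(fits) < 2L) stop("need at least two models to compare")
  labs <- names(fits)
  if (is.null(labs)) labs <- rep("", length(fits))
  reps <- vector("list", length(fits))
  nobs <- rep(NA_integer_, length(fits))
  ysum <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (inherits(f, "spatlogit")) {
      reps[[i]] <- f$dic
      nobs[i] <- f$n_obs
      ysum[i] <- sum(f$y)
      if (labs[i] == "") labs[i] <- f$family
    } else if (inherits(f, "dic_report")) {
      reps[[i]] <- f
      if (labs[i] == "") labs[i] <- paste0("model", i)
    } else stop("arguments must be 'spatlogit' fits or 'dic_report' objects")
  }
  known <- !is.na(nobs)
  if (sum(known) > 1L &&
      (length(unique(nobs[known])) > 1L || length(unique(ysum[known])) > 1L))
    stop("models were fitted to different datasets; DIC is not comparable")
  out <- data.frame(model = labs,
                    dbar = vapply(reps, `[[`, 0, "dbar"),
                    pd = vapply(reps, `[[`, 0, "pd"),
                    dic = vapply(reps, `[[`, 0, "dic"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$dic), , drop = FALSE]
  rownames(out) <- NULL
  out$delta_dic <- out$dic - out$dic[1L]
  sup <- outer(out$dic, out$dic, function(a, b) b - a > decisive_delta)
  dimnames(sup) <- list(out$model, out$model)
  out$considerably_superior_to_next <-
    c(diff(out$dic) > decisive_delta, NA)
  attr(out, "superior") <- sup
  out
}

#' Retain-or-collapse decision for a random parameter
#'
#' The posterior SD of a random coefficient can never bracket zero, so "the
#' posterior variance is not statistically significant" is operationalized
#' as: the lower `(1 - level)/2` posterior quantile of `sigma` lies below
#' `threshold` (default twice the lower prior bound, 0.02). When it does, the
#' heterogeneity is judged undetectable and the coefficient should be refit
#' as fixed.
#'
#' @param sigma_draws Posterior draws of a random-coefficient SD, or a fitted
#'   `rp_spatial` model (then `covariate` selects the coefficient).
#' @param level Credibility level of the decision (default 0.95).
#' @param threshold Collapse threshold on the lower quantile.
#' @param covariate Covariate name when `sigma_draws` is a fitted model.
#' @return `"random"` or `"collapse_to_fixed"`.
#' @export
classify_random_parameter <- function(sigma_draws, level = 0.95,
                                      threshold = 0.02, covariate = NULL) {
  if (inherits(sigma_draws, "spatlogit")) {
    if (is.null(covariate)) stop("'covariate' is required for a fitted model")
    col <- paste0("sd_", covariate)
    if (!col %in% colnames(sigma_draws$draws))
      stop("no random coefficient for '", covariate, "' in this fit")
    sigma_draws <- sigma_draws$draws[, col]
  }
  if (!length(sigma_draws)) stop("empty sample array")
  lo <- quantile(sigma_draws, probs = (1 - level) / 2, names = FALSE)
  if (lo < threshold) "collapse_to_fixed" else "random"
}
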