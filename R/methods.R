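#' @export
print.spatlogit <- function(x, ...) {
  cat("Bayesian", switch(x$family,
                         logistic = "logistic",
                         spatial = "spatial logistic",
                         rp_spatial = "random-parameters spatial logistic"),
      "model\n")
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("%d crashes (%d fatal)", x$n_obs, sum(x$y)))
  if (!is.null(x$network)) cat(sprintf(", %d sections", x$network$M))
  cat("\n")
  cat(sprintf("MCMC: %d iterations, %d burn-in, %d retained draws\n",
              x$control$n_iter, x$control$n_burnin, nrow(x$draws)))
  cat(sprintf("DIC: %.1f (Dbar %.1f, pD %.1f)\n",
              x$dic$dic, x$dic$dbar, x$dic$pd))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Posterior means, SDs, 90/95% equal-tailed credible intervals with
#' significance flags, Monte Carlo error ratios, and odds ratios for the
#' coefficient rows; printed in the conventional "mean (SD)" table layout
#' with significance stars and a Dbar/pD/DIC footer.
#'
#' @param object A fitted [spatlogit()] model.
#' @param levels Credibility levels.
#' @param ... Unused.
#' @return An object of class `summary.spatlogit`.
#' @export
summary.spatlogit <- function(object, levels = c(0.90, 0.95), ...) {
  tab <- summarize_posterior(object$draws, levels = levels)
  coef_rows <- colnames(object$X)
  is_coef <- tab$parameter %in% coef_rows
  tab$odds_ratio <- ifelse(is_coef, exp(tab$mean), NA_real_)
  tab$percent_change <- ifelse(is_coef, 100 * (exp(tab$mean) - 1), NA_real_)
  structure(list(call = object$call, family = object$family,
                 coefficients = tab, dic = object$dic,
                 n_obs = object$n_obs, n_fatal = sum(object$y),
                 levels = levels,
                 heterogeneity = summary_heterogeneity(object)),
            class = "summary.spatlogit")
}

summary_heterogeneity <- function(object) {
  if (is.null(object$random) || !length(object$random)) return(NULL)
  out <- lapply(object$random, function(v) {
    bb <- mean(object$draws[, v])
    sg <- mean(object$draws[, paste0("sd_", v)])
    c(mean = bb, sd = sg, share_positive = heterogeneity_share(bb, sg))
  })
  names(out) <- object$random
  do.call(rbind, out)
}

#' @export
print.summary.spatlogit <- function(x, digits = 3, ...) {
  cat("Bayesian", switch(x$family,
                         logistic = "logistic",
                         spatial = "spatial logistic",
                         rp_spatial = "random-parameters spatial logistic"),
      "model\n")
  cat(sprintf("%d crashes (%d fatal)\n\n", x$n_obs, x$n_fatal))
  tab <- x$coefficients
  stars <- ifelse(tab$sig95, "**", ifelse(tab$sig90, "*", ""))
  disp <- data.frame(
    parameter = tab$parameter,
    `mean (SD)` = sprintf("%s (%s)%s",
                          signif(tab$mean, digits), signif(tab$sd, digits),
                          stars),
    `95% CI` = sprintf("[%s, %s]", signif(tab$lower95, digits),
                       signif(tab$upper95, digits)),
    `MC ratio` = sprintf("%.3f", tab$mc_ratio),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(disp, row.names = FALSE, right = FALSE)
  cat("---\n* significant at 90%, ** at 95% credibility ",
      "(interval excludes 0)\n", sep = "")
  if (!is.null(x$heterogeneity)) {
    cat("\nRandom coefficients:\n")
    h <- x$heterogeneity
    for (v in rownames(h))
      cat(sprintf("  %s: mean %.3g, SD %.3g -> %.1f%% of crashes with a positive effect\n",
                  v, h[v, "mean"], h[v, "sd"], h[v, "share_positive"]))
  }
  cat(sprintf("\nDbar = %.1f, pD = %.1f, DIC = %.1f\n",
              x$dic$dbar, x$dic$pd, x$dic$dic))
  invisible(x)
}

#' @export
coef.spatlogit <- function(object, ...) {
  colMeans(object$draws[, colnames(object$X), drop = FALSE])
}

#' Fitted fatality probabilities
#'
#' Posterior-mean linear predictor mapped through the logistic link.
#'
#' @param object A fitted [spatlogit()] model.
#' @param ... Unused.
#' @export
fitted.spatlogit <- function(object, ...) plogis(object$eta_mean)

#' Predict fatality risk for new crashes
#'
#' Plug-in prediction at posterior means. Random coefficients enter at their
#' population mean (new crashes have no estimated deviation); section effects
#' at their posterior means, and 0 for sections absent from the fit's
#' network.
#'
#' @param object A fitted [spatlogit()] model.
#' @param newdata Optional data frame; defaults to the training data's design.
#' @param type `"response"` for fatality probabilities, `"link"` for the
#'   linear predictor.
#' @param section Name of the section-id column in `newdata`.
#' @param ... Unused.
#' @export
predict.spatlogit <- function(object, newdata = NULL,
                              type = c("response", "link"),
                              section = "section_id", ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$eta_mean
  } else {
    Terms <- stats::delete.response(stats::terms(object$formula))
    X <- model.matrix(Terms, model.frame(Terms, newdata))
    beta <- colMeans(object$draws[, colnames(object$X), drop = FALSE])
    eta <- drop(X %*% beta[colnames(X)])
    if (!is.null(object$phi_mean) && section %in% names(newdata)) {
      ph <- object$phi_mean[as.character(newdata[[section]])]
      ph[is.na(ph)] <- 0
      eta <- eta + ph
    }
  }
  if (type == "link") eta else plogis(eta)
}

#' Response, Pearson or deviance residuals
#'
#' @param object A fitted [spatlogit()] model.
#' @param type Residual type.
#' @param ... Unused.
#' @export
residuals.spatlogit <- function(object,
                                type = c("response", "pearson", "deviance"),
                                ...) {
  type <- match.arg(type)
  p <- fitted(object)
  r <- object$y - p
  switch(type,
         response = r,
         pearson = r / sqrt(p * (1 - p)),
         deviance = sign(r) * sqrt(-2 * (object$y * log(p) +
                                           (1 - object$y) * log(1 - p))))
}

#' Posterior predictive simulation
#'
#' Draws outcome vectors from the posterior predictive distribution: for each
#' simulation a retained posterior draw supplies the coefficients and spatial
#' hyper-parameters, section effects come from the nearest stored joint draw,
#' and crash-level random deviations are redrawn from their mixing
#' distribution (new realizations of the unobserved heterogeneity).
#'
#' @param object A fitted [spatlogit()] model.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.spatlogit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$draws)
  idx <- sample.int(S, nsim, replace = TRUE)
  X <- object$X
  out <- matrix(0L, object$n_obs, nsim)
  for (s in seq_len(nsim)) {
    d <- object$draws[idx[s], ]
    eta <- drop(X %*% d[colnames(X)])
    if (!is.null(object$random)) {
      for (v in object$random) {
        mu <- rnorm(object$n_obs, 0, d[paste0("sd_", v)])
        eta <- eta + mu * X[, v]
      }
    }
    if (!is.null(object$phi_draws) && nrow(object$phi_draws) > 0) {
      prow <- pmin(nrow(object$phi_draws),
                   pmax(1L, round(idx[s] / S * nrow(object$phi_draws))))
      phi <- object$phi_draws[prow, ]
      eta <- eta + phi[match(object$section, object$network$section_ids)]
    }
    out[, s] <- rbinom(object$n_obs, 1L, plogis(eta))
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Trace ("history") plots of monitored parameters
#'
#' @param x A fitted [spatlogit()] model.
#' @param parameters Parameter names to plot (default: up to 6 monitored
#'   parameters).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spatlogit <- function(x, parameters = NULL, ...) {
  pars <- if (is.null(parameters))
    utils::head(colnames(x$draws), 6L) else parameters
  bad <- setdiff(pars, colnames(x$draws))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  old <- graphics::par(mfrow = c(length(pars), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::plot(x$draws[, p], type = "l", xlab = "", ylab = p,
                   main = paste("History of", p), cex.main = 0.9, ...)
  }
  invisible(x)
}
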