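#' @useDynLib spatlogit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats model.matrix model.frame model.response quantile sd
#'   rnorm runif rbinom plogis qlogis qnorm pnorm uniroot var median
#' @importFrom utils read.csv write.csv packageVersion
"_PACKAGE"

# stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x < -35
  mid <- !lo & x <= 35
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out
}

#' Linear predictor of the latent fatality propensity
#'
#' Computes `eta_i = beta0 + sum_j beta_{(i,)j} x_{i,j} + phi_{m(i)}`, the
#' systematic part of the latent utility whose sign determines the binary
#' outcome. `beta` may be a single coefficient vector (fixed parameters) or an
#' `N x J` matrix of crash-level coefficients (random parameters, typically
#' from [expand_random_coefficients()]).
#'
#' @param X Numeric `N x J` covariate matrix.
#' @param beta Coefficient vector of length `J`, or an `N x J` matrix of
#'   per-crash coefficients.
#' @param intercept Constant term `beta0` (scalar, or length-`N` for a random
#'   intercept).
#' @param phi Optional vector of section effects.
#' @param section Integer or character index of each crash's section into
#'   `phi` (required when `phi` is supplied).
#' @return Numeric vector `eta` of length `N`.
#' @export
linear_predictor <- function(X, beta, intercept = 0, phi = NULL,
                             section = NULL) {
  X <- as.matrix(X)
  if (is.matrix(beta)) {
    if (!all(dim(beta) == dim(X)))
      stop("per-crash coefficient matrix must match the dimensions of X")
    eta <- rowSums(X * beta)
  } else {
    if (length(beta) != ncol(X))
      stop("length of 'beta' (", length(beta),
           ") does not match ncol(X) (", ncol(X), ")")
    eta <- drop(X %*% beta)
  }
  eta <- eta + intercept
  if (!is.null(phi)) {
    if (is.null(section))
      stop("'section' is required when section effects are supplied")
    eta <- eta + phi[section]
  }
  unname(eta)
}

#' Fatality and non-fatality probabilities under the logistic link
#'
#' @param eta Linear predictor vector.
#' @return A list with components `p1` (fatality probability
#'   `exp(eta) / (1 + exp(eta))`, computed overflow-safely) and `p0 = 1 - p1`.
#' @export
fatality_probability <- function(eta) {
  p1 <- plogis(eta)
  list(p1 = p1, p0 = plogis(eta, lower.tail = FALSE))
}

#' Odds ratios and percent changes from logistic coefficients
#'
#' Under the logistic link the odds ratio for a one-unit increase in a
#' covariate is `exp(beta)`; the equivalent percent change in the fatality
#' odds is `100 * (exp(beta) - 1)`.
#'
#' @param beta Numeric vector of coefficients (names are kept).
#' @return A data frame with columns `estimate`, `odds_ratio` and
#'   `percent_change`.
#' @examples
#' odds_ratio(c(ems_time = 0.026, other_vehicle = 0.71))
#' @export
odds_ratio <- function(beta) {
  data.frame(estimate = as.numeric(beta),
             odds_ratio = exp(as.numeric(beta)),
             percent_change = 100 * (exp(as.numeric(beta)) - 1),
             row.names = names(beta))
}

#' Bernoulli-logistic log-likelihood
#'
#' `sum_i [y_i * log p_{i,1} + (1 - y_i) * log p_{i,0}]` evaluated stably for
#' large `|eta|` as `sum(y * eta - log(1 + exp(eta)))`.
#'
#' @param y Binary outcome vector (0/1).
#' @param eta Linear predictor vector of the same length.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(y, eta) {
  if (length(y) != length(eta)) stop("'y' and 'eta' lengths differ")
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  sum(y * eta - log1pexp(eta))
}

#' Expand random coefficients to crash level
#'
#' Reconstructs crash-level coefficients `beta_{i,j} = beta_bar_j + mu_{i,j}`
#' from the population mean and either supplied deviations or fresh normal
#' draws `mu_{i,j} ~ N(0, sigma_j^2)`.
#'
#' @param beta_bar Named numeric vector of coefficient means (length `K`).
#' @param sigma Positive standard deviations (length `K`).
#' @param n Number of crashes (ignored when `mu` is supplied).
#' @param mu Optional `n x K` matrix of deviations; when `NULL` they are drawn
#'   i.i.d. normal.
#' @return An `n x K` matrix of crash-level coefficients, with `beta_bar`'s
#'   names as column names.
#' @export
expand_random_coefficients <- function(beta_bar, sigma, n, mu = NULL) {
  K <- length(beta_bar)
  if (length(sigma) != K) stop("'beta_bar' and 'sigma' lengths differ")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  if (is.null(mu)) {
    mu <- matrix(rnorm(n * K, 0, rep(sigma, each = n)), n, K)
  } else {
    mu <- as.matrix(mu)
    if (ncol(mu) != K) stop("'mu' must have one column per random coefficient")
    n <- nrow(mu)
  }
  out <- sweep(mu, 2L, beta_bar, "+")
  colnames(out) <- names(beta_bar)
  out
}
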