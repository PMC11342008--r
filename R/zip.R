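#' Zero-inflated Poisson log probability mass
#'
#' The ZIP distribution mixes a structural zero (probability `pi`) with a
#' Poisson(`lambda`) count: P(0) = pi + (1 - pi) e^-lambda and
#' P(y) = (1 - pi) lambda^y e^-lambda / y! for y > 0. The zero branch is
#' evaluated with a log-sum-exp so that extreme `pi` or `lambda` stay
#' finite.
#'
#' @param y nonnegative integer counts.
#' @param lambda positive Poisson rates (recycled against `y`).
#' @param pi structural-zero probabilities in \[0, 1\] (recycled).
#' @return log-probabilities, same length as the recycled arguments.
#' @export
zip_logpmf <- function(y, lambda, pi) {
  if (any(y < 0) || any(y != floor(y))) {
    stop("y must contain nonnegative integers")
  }
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  n <- max(length(y), length(lambda), length(pi))
  y <- rep_len(y, n); lambda <- rep_len(lambda, n); pi <- rep_len(pi, n)
  out <- numeric(n)
  z <- y == 0
  if (any(z)) {
    # log(pi + (1 - pi) e^-lambda) via pairwise log-sum-exp
    a <- log(pi[z])
    b <- log1p(-pi[z]) - lambda[z]
    m <- pmax(a, b)
    m[!is.finite(m)] <- -Inf
    out[z] <- ifelse(is.infinite(m) & m < 0, -Inf,
                     m + log(exp(a - m) + exp(b - m)))
    # pi = 1 gives log(1) = 0; pi = 0 reduces to -lambda
    out[z][pi[z] == 1] <- 0
  }
  if (any(!z)) {
    out[!z] <- log1p(-pi[!z]) +
      stats::dpois(y[!z], lambda[!z], log = TRUE)
  }
  out
}

# raw polynomial design row for one time code: (1, t, t^2, ..., t^order)
poly_design <- function(time_codes, order) {
  outer(time_codes, 0:order, `^`)
}

# per-group lambda (T-vector) and pi (T-vector) from coefficients
group_rates <- function(beta, alpha, time_codes) {
  eta_c <- drop(poly_design(time_codes, length(beta) - 1) %*% beta)
  eta_i <- drop(poly_design(time_codes, length(alpha) - 1) %*% alpha)
  list(lambda = exp(eta_c), pi = stats::plogis(eta_i),
       eta_count = eta_c, eta_inflation = eta_i)
}

# n x G matrix of per-user component log-likelihoods
component_loglik <- function(y, params, time_codes) {
  n <- nrow(y); G <- length(params)
  L <- matrix(0, n, G)
  for (j in seq_len(G)) {
    r <- group_rates(params[[j]]$beta, params[[j]]$alpha, time_codes)
    for (t in seq_along(time_codes)) {
      L[, j] <- L[, j] + zip_logpmf(y[, t], r$lambda[t], r$pi[t])
    }
  }
  L
}

row_logsumexp <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

#' Mixture log-likelihood of a ZIP trajectory model
#'
#' Sum over users of log sum over groups of w_j * prod over periods of the
#' ZIP density, computed with per-user log-sum-exp.
#'
#' @param y integer matrix (users x periods).
#' @param params list of per-group parameter lists, each with elements
#'   `beta` (count-model coefficients, intercept first) and `alpha`
#'   (inflation-model coefficients).
#' @param weights group mixing probabilities (summing to 1); a single
#'   group may omit them.
#' @param time_codes numeric time covariate per period.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(y, params, weights = NULL,
                           time_codes = default_period_grid()$time_codes) {
  y <- as.matrix(y)
  if (nrow(y) == 0) stop("empty series collection")
  G <- length(params)
  if (is.null(weights)) weights <- rep(1 / G, G)
  stopifnot(length(weights) == G, abs(sum(weights) - 1) < 1e-8)
  L <- component_loglik(y, params, time_codes)
  sum(row_logsumexp(sweep(L, 2, log(weights), `+`)))
}
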