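#' Specification of a ZIP trajectory mixture
#'
#' @param n_groups number of latent trajectory groups (1-8).
#' @param count_order per-group polynomial degree of the count (log-rate)
#'   trend, 0-3; recycled across groups.
#' @param inflation_order per-group polynomial degree of the
#'   structural-zero (logit) trend, 0-3; recycled.
#' @return object of class `zip_traj_spec`.
#' @export
zip_traj_spec <- function(n_groups, count_order = 3, inflation_order = 3) {
  stopifnot(n_groups >= 1, n_groups <= 8)
  co <- rep_len(as.integer(count_order), n_groups)
  io <- rep_len(as.integer(inflation_order), n_groups)
  if (any(co < 0 | co > 3) || any(io < 0 | io > 3)) {
    stop("polynomial degrees must be between 0 and 3")
  }
  structure(list(n_groups = as.integer(n_groups),
                 count_order = co, inflation_order = io),
            class = "zip_traj_spec")
}

n_free_params <- function(spec) {
  sum(spec$count_order + 1L) + sum(spec$inflation_order + 1L) +
    (spec$n_groups - 1L)
}

# ---- weighted ZIP M-step -------------------------------------------------
# Sufficient statistics per period for a group with user weights w:
#   W0_t = sum of w over users with y_it = 0
#   W1_t = sum of w over users with y_it > 0
#   S1_t = sum of w * y over users with y_it > 0
# The weighted log-likelihood (up to a constant in the parameters) is
#   sum_t W0_t log A_t + W1_t (log(1-pi_t) - lambda_t) + S1_t eta_t
# with A_t = pi_t + (1-pi_t) exp(-lambda_t).
wzip_stats <- function(y, w) {
  Z <- y == 0
  list(W0 = colSums(w * Z), W1 = colSums(w * !Z), S1 = colSums(w * y * !Z))
}

wzip_fit <- function(stats, Xc, Xi, beta0, alpha0) {
  nc <- ncol(Xc); ni <- ncol(Xi)
  obj <- function(par) {
    eta_c <- drop(Xc %*% par[1:nc])
    eta_i <- drop(Xi %*% par[nc + 1:ni])
    lam <- exp(eta_c)
    logp <- stats::plogis(eta_i, log.p = TRUE)
    log1mp <- stats::plogis(-eta_i, log.p = TRUE)
    m <- pmax(logp, log1mp - lam)
    logA <- m + log(exp(logp - m) + exp(log1mp - lam - m))
    -sum(stats$W0 * logA + stats$W1 * (log1mp - lam) + stats$S1 * eta_c)
  }
  grad <- function(par) {
    eta_c <- drop(Xc %*% par[1:nc])
    eta_i <- drop(Xi %*% par[nc + 1:ni])
    lam <- exp(eta_c)
    pi <- stats::plogis(eta_i)
    logp <- stats::plogis(eta_i, log.p = TRUE)
    log1mp <- stats::plogis(-eta_i, log.p = TRUE)
    m <- pmax(logp, log1mp - lam)
    logA <- m + log(exp(logp - m) + exp(log1mp - lam - m))
    d_c <- stats$W0 * (-lam * exp(log1mp - lam - logA)) +
      (stats$S1 - stats$W1 * lam)
    d_i <- stats$W0 * exp(logp + log1mp - logA) * (-expm1(-lam)) -
      stats$W1 * pi
    -c(drop(crossprod(Xc, d_c)), drop(crossprod(Xi, d_i)))
  }
  fit <- stats::optim(c(beta0, alpha0), obj, grad, method = "L-BFGS-B",
                      lower = -50, upper = 50,
                      control = list(maxit = 200))
  list(beta = fit$par[1:nc], alpha = fit$par[nc + 1:ni])
}

# ---- EM ------------------------------------------------------------------
em_run <- function(y, spec, time_codes, P0, tol, max_iter) {
  n <- nrow(y); G <- spec$n_groups
  Xc <- lapply(seq_len(G), function(j) poly_design(time_codes, spec$count_order[j]))
  Xi <- lapply(seq_len(G), function(j) poly_design(time_codes, spec$inflation_order[j]))
  params <- vector("list", G)
  # initial M-step from the supplied responsibilities
  for (j in seq_len(G)) {
    w <- P0[, j]
    mu <- max(sum(w * rowMeans(y)) / max(sum(w), 1e-9), 0.05)
    params[[j]] <- wzip_fit(wzip_stats(y, w), Xc[[j]], Xi[[j]],
                            c(log(mu), rep(0, spec$count_order[j])),
                            rep(0, spec$inflation_order[j] + 1))
  }
  wts <- pmax(colMeans(P0), 1e-12); wts <- wts / sum(wts)
  ll <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    L <- component_loglik(y, params, time_codes)
    Lw <- sweep(L, 2, log(wts), `+`)
    ll_new <- sum(row_logsumexp(Lw))
    P <- exp(Lw - row_logsumexp(Lw))
    if (is.finite(ll) && abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
    wts <- pmax(colMeans(P), 1e-12); wts <- wts / sum(wts)
    for (j in seq_len(G)) {
      params[[j]] <- wzip_fit(wzip_stats(y, P[, j]), Xc[[j]], Xi[[j]],
                              params[[j]]$beta, params[[j]]$alpha)
    }
  }
  L <- component_loglik(y, params, time_codes)
  Lw <- sweep(L, 2, log(wts), `+`)
  P <- exp(Lw - row_logsumexp(Lw))
  list(loglik = ll, params = params, weights = wts, posterior = P,
       converged = converged, iterations = it)
}

start_responsibilities <- function(y, G, start_index) {
  n <- nrow(y)
  if (G == 1) return(matrix(1, n, 1))
  if (start_index == 1) {
    # deterministic: quantile split of per-user totals, high volume first
    ord <- order(rowSums(y), decreasing = TRUE)
    grp <- cut(seq_len(n), breaks = G, labels = FALSE)
    P <- matrix(0, n, G)
    P[cbind(ord, grp)] <- 1
    # soften so no group starts empty-handed
    0.9 * P + 0.1 / G
  } else {
    P <- matrix(stats::rexp(n * G), n, G)
    P / rowSums(P)
  }
}

#' Fit a zero-inflated Poisson group-based trajectory model
#'
#' Maximum-likelihood estimation by expectation-maximization: the E-step
#' computes posterior group memberships, the M-step refits each group's
#' weighted ZIP regression (count and inflation trends jointly, by
#' quasi-Newton on the weighted likelihood) and the mixing proportions.
#' Multiple starts are used; start 1 is a deterministic quantile split of
#' per-user total counts, the rest are random responsibilities.
#'
#' Groups are reported in canonical order: sorted by expected total post
#' volume, descending, so group 1 is always the high-volume (high-risk)
#' group.
#'
#' @param y integer matrix (users x periods), e.g. from
#'   [build_user_series] or [simulate_counts].
#' @param spec a [zip_traj_spec].
#' @param time_codes numeric time covariate per period; defaults to the
#'   grid attached to `y`, else the default grid's codes.
#' @param n_starts number of EM starts.
#' @param seed integer seed for the random starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param compute_se compute coefficient standard errors from the
#'   numerically differentiated observed information at the optimum.
#' @return object of class `zip_traj_fit` with elements `params`
#'   (per-group `beta`, `alpha`), `weights`, `theta` (mixing logits,
#'   last group as reference), `loglik`, `aic`, `bic`, `entropy`,
#'   `posterior`, `assignment`, `app`, `composition`, `coef_table`
#'   (estimates, SEs, Wald z and p), `converged`, `n_users`.
#' @export
fit_zip_trajectory <- function(y, spec, time_codes = NULL, n_starts = 10,
                               seed = NULL, tol = 1e-8, max_iter = 500,
                               compute_se = TRUE) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  stopifnot(inherits(spec, "zip_traj_spec"))
  if (is.null(time_codes)) {
    g <- attr(y, "grid")
    time_codes <- if (!is.null(g)) g$time_codes else
      default_period_grid()$time_codes
  }
  stopifnot(ncol(y) == length(time_codes))
  n <- nrow(y)
  if (n < 10 * n_free_params(spec)) {
    warning(sprintf("only %d users for %d free parameters; estimates may be unstable",
                    n, n_free_params(spec)))
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL; diagnostics <- list()
  for (s in seq_len(n_starts)) {
    P0 <- start_responsibilities(y, spec$n_groups, s)
    run <- tryCatch(em_run(y, spec, time_codes, P0, tol, max_iter),
                    error = function(e) e)
    if (inherits(run, "error")) {
      diagnostics[[s]] <- conditionMessage(run)
      next
    }
    diagnostics[[s]] <- sprintf("start %d: loglik %.4f (%s, %d iterations)",
                                s, run$loglik,
                                if (run$converged) "converged" else "max iterations",
                                run$iterations)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best)) {
    stop("no EM start produced a solution; per-start diagnostics:\n",
         paste(unlist(diagnostics), collapse = "\n"))
  }
  fit <- finalize_fit(y, spec, time_codes, best, diagnostics, compute_se)
  fit
}

finalize_fit <- function(y, spec, time_codes, run, diagnostics, compute_se) {
  n <- nrow(y); G <- spec$n_groups
  # canonical ordering: expected total volume descending
  ev <- vapply(seq_len(G), function(j) {
    r <- group_rates(run$params[[j]]$beta, run$params[[j]]$alpha, time_codes)
    sum((1 - r$pi) * r$lambda)
  }, 0)
  ord <- order(ev, decreasing = TRUE)
  params <- run$params[ord]
  wts <- run$weights[ord]
  spec <- zip_traj_spec(G, spec$count_order[ord], spec$inflation_order[ord])
  P <- run$posterior[, ord, drop = FALSE]
  assignment <- max.col(P, ties.method = "first")
  if (any(wts < 1 / n)) {
    warning("collapsed group(s) with mixing weight below 1/n: ",
            paste(which(wts < 1 / n), collapse = ", "))
  }
  composition <- as.numeric(table(factor(assignment, levels = seq_len(G))) / n)
  app <- vapply(seq_len(G), function(j) {
    idx <- assignment == j
    if (!any(idx)) return(NA_real_)
    mean(P[idx, j])
  }, 0)
  if (anyNA(app)) warning("group(s) with no assigned users; APP undefined")
  k <- n_free_params(spec)
  ll <- run$loglik
  ent <- normalized_entropy(P)
  theta <- log(wts) - log(wts[G])
  coef_table <- build_coef_table(y, spec, time_codes, params, theta, compute_se)
  structure(list(
    spec = spec, params = params, weights = wts, theta = theta,
    time_codes = time_codes, loglik = ll,
    aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
    entropy = ent, posterior = P, assignment = assignment,
    app = app, composition = composition, coef_table = coef_table,
    converged = run$converged, n_users = n, n_params = k,
    start_diagnostics = unlist(diagnostics)
  ), class = "zip_traj_fit")
}

#' Normalized classification entropy of a posterior matrix
#'
#' 1 - \[-sum_i sum_j p_ij ln p_ij\] / (N ln G), clipped to \[0, 1\]:
#' 1 means every user is assigned with certainty, 0 means posteriors are
#' uniform over groups. Defined as 1 for a single group.
#'
#' @param P posterior membership matrix (users x groups, rows sum to 1).
#' @return scalar in \[0, 1\].
#' @export
normalized_entropy <- function(P) {
  P <- as.matrix(P)
  G <- ncol(P); n <- nrow(P)
  if (G == 1) return(1)
  plogp <- P * log(P)
  plogp[P <= 0] <- 0
  e <- 1 - (-sum(plogp)) / (n * log(G))
  min(max(e, 0), 1)
}

term_names <- c("intercept", "linear", "quadratic", "cubic")

# stack free parameters, evaluate the full-likelihood hessian numerically,
# and lay out the Wald table
build_coef_table <- function(y, spec, time_codes, params, theta, compute_se) {
  G <- spec$n_groups
  rows <- list()
  est <- c()
  for (j in seq_len(G)) {
    co <- spec$count_order[j]; io <- spec$inflation_order[j]
    rows[[length(rows) + 1]] <- data.frame(
      group = j, submodel = "count", term = term_names[1:(co + 1)],
      estimate = params[[j]]$beta)
    rows[[length(rows) + 1]] <- data.frame(
      group = j, submodel = "inflation", term = paste0("alpha", 0:io),
      estimate = params[[j]]$alpha)
    est <- c(est, params[[j]]$beta, params[[j]]$alpha)
  }
  if (G > 1) {
    rows[[length(rows) + 1]] <- data.frame(
      group = seq_len(G - 1), submodel = "mixing",
      term = paste0("theta", seq_len(G - 1)),
      estimate = theta[seq_len(G - 1)])
    est <- c(est, theta[seq_len(G - 1)])
  }
  tab <- do.call(rbind, rows)
  tab$se <- NA_real_
  if (compute_se) {
    nll <- function(par) {
      p <- unstack_params(par, spec)
      -mixture_loglik(y, p$params, p$weights, time_codes)
    }
    H <- tryCatch(pracma::hessian(nll, est), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)) {
      warning("observed information is singular or indefinite; SEs reported as missing")
    } else {
      tab$se <- sqrt(diag(V))
    }
  }
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  rownames(tab) <- NULL
  tab
}

unstack_params <- function(par, spec) {
  G <- spec$n_groups
  params <- vector("list", G)
  pos <- 0
  for (j in seq_len(G)) {
    nc <- spec$count_order[j] + 1; ni <- spec$inflation_order[j] + 1
    params[[j]] <- list(beta = par[pos + 1:nc], alpha = par[pos + nc + 1:ni])
    pos <- pos + nc + ni
  }
  theta <- if (G > 1) c(par[pos + seq_len(G - 1)], 0) else 0
  w <- exp(theta - max(theta)); w <- w / sum(w)
  list(params = params, weights = w)
}

#' Fit statistics of a trajectory model
#'
#' AIC = 2k - 2 lnL and BIC = k ln N - 2 lnL (smaller is better), with k
#' the number of free parameters including the G - 1 mixing logits, and
#' the normalized classification entropy
#' 1 - \[-sum_i sum_j p_ij ln p_ij\] / (N ln G), clipped to \[0, 1\]
#' (defined as 1 for a single group).
#'
#' @param model a `zip_traj_fit`.
#' @return list with `aic`, `bic`, `entropy`.
#' @export
fit_statistics <- function(model) {
  stopifnot(inherits(model, "zip_traj_fit"))
  list(aic = model$aic, bic = model$bic, entropy = model$entropy)
}

#' Average posterior probability of assigned membership
#'
#' For each group, the mean posterior probability of that group among the
#' users assigned to it by maximum posterior; the conventional adequacy
#' threshold is 0.7 per group.
#'
#' @param model a `zip_traj_fit`, or a posterior membership matrix
#'   (users x groups), in which case users are assigned by maximum
#'   posterior first.
#' @return numeric vector of per-group APPs (NA for empty groups).
#' @export
average_posterior_probability <- function(model) {
  if (inherits(model, "zip_traj_fit")) return(model$app)
  P <- as.matrix(model)
  assignment <- max.col(P, ties.method = "first")
  app <- vapply(seq_len(ncol(P)), function(j) {
    idx <- assignment == j
    if (!any(idx)) return(NA_real_)
    mean(P[idx, j])
  }, 0)
  if (anyNA(app)) warning("group(s) with no assigned users; APP undefined")
  app
}

#' @export
print.zip_traj_fit <- function(x, ...) {
  G <- x$spec$n_groups
  cat(sprintf("ZIP trajectory model: %d group(s), %d users, loglik %.2f\n",
              G, x$n_users, x$loglik))
  cat(sprintf("AIC %.2f  BIC %.2f  entropy %.3f\n", x$aic, x$bic, x$entropy))
  cat("composition:", paste(sprintf("%.2f%%", 100 * x$composition),
                            collapse = " / "), "\n")
  cat("APP:        ", paste(sprintf("%.3f", x$app), collapse = " / "), "\n")
  invisible(x)
}
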