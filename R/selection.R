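#' Model-selection ladder over the number of trajectory groups
#'
#' Fits each candidate number of groups with the full cubic specification
#' (count and inflation trends), computes AIC, BIC, normalized entropy and
#' group composition, flags candidates with a group below the composition
#' floor (default 5% of the sample) or entropy below the adequacy level
#' (default 0.8), and selects the candidate minimizing BIC among those
#' free of composition violations. When BIC values tie within 2 units the
#' smaller number of groups is preferred (parsimony). AIC and entropy are
#' reported as corroborating evidence, not used for selection.
#'
#' @param y integer count matrix (users x periods).
#' @param G_range integer vector of candidate group counts (within 2-8).
#' @param time_codes numeric time covariate per period.
#' @param n_starts EM starts per candidate.
#' @param seed integer seed.
#' @param composition_floor minimum admissible share per group.
#' @param entropy_floor adequacy threshold for normalized entropy.
#' @param app_floor adequacy threshold for per-group APP.
#' @return object of class `traj_ladder`: `candidates` (per-G fits),
#'   `stats` (per-G table), `violations`, `selected_G`, `selected`
#'   (the chosen fit), `trace` (ordered decision log).
#' @export
run_ladder <- function(y, G_range = 2:5, time_codes = NULL, n_starts = 10,
                       seed = NULL, composition_floor = 0.05,
                       entropy_floor = 0.8, app_floor = 0.7) {
  G_range <- sort(unique(as.integer(G_range)))
  if (any(G_range < 2 | G_range > 8)) stop("G_range must lie within [2, 8]")
  if (!is.null(seed)) set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max, length(G_range))
  candidates <- list(); violations <- list(); trace <- character()
  for (i in seq_along(G_range)) {
    G <- G_range[i]
    fit <- fit_zip_trajectory(y, zip_traj_spec(G, 3, 3),
                              time_codes = time_codes, n_starts = n_starts,
                              seed = fit_seeds[i], compute_se = FALSE)
    v <- character()
    small <- which(fit$composition < composition_floor)
    if (length(small)) {
      v <- c(v, sprintf("composition below %.0f%% for group(s) %s (%s)",
                        100 * composition_floor,
                        paste(small, collapse = ","),
                        paste(sprintf("%.2f%%", 100 * fit$composition[small]),
                              collapse = ",")))
    }
    if (fit$entropy < entropy_floor) {
      v <- c(v, sprintf("entropy %.3f below %.2f", fit$entropy, entropy_floor))
    }
    low_app <- which(!is.na(fit$app) & fit$app < app_floor)
    if (length(low_app)) {
      v <- c(v, sprintf("APP below %.2f for group(s) %s", app_floor,
                        paste(low_app, collapse = ",")))
    }
    candidates[[as.character(G)]] <- fit
    violations[[as.character(G)]] <- v
    trace <- c(trace, sprintf(
      "G=%d: loglik %.2f, AIC %.2f, BIC %.2f, entropy %.3f, composition %s%s",
      G, fit$loglik, fit$aic, fit$bic, fit$entropy,
      paste(sprintf("%.2f%%", 100 * fit$composition), collapse = "/"),
      if (length(v)) paste0(" [", paste(v, collapse = "; "), "]") else ""))
  }
  stats <- data.frame(
    G = G_range,
    loglik = vapply(candidates, `[[`, 0, "loglik"),
    aic = vapply(candidates, `[[`, 0, "aic"),
    bic = vapply(candidates, `[[`, 0, "bic"),
    entropy = vapply(candidates, `[[`, 0, "entropy"),
    composition = vapply(candidates, function(f)
      paste(sprintf("%.2f%%", 100 * f$composition), collapse = "/"), ""),
    admissible = vapply(violations, function(v)
      !any(grepl("composition", v)), TRUE),
    row.names = NULL
  )
  ok <- stats$admissible
  if (!any(ok)) {
    stop("every candidate violates the composition rule:\n",
         paste(trace, collapse = "\n"))
  }
  bic_ok <- stats$bic[ok]; G_ok <- stats$G[ok]
  # BIC-primary with a 2-unit parsimony band
  in_band <- bic_ok <= min(bic_ok) + 2
  selected_G <- min(G_ok[in_band])
  trace <- c(trace, sprintf(
    "selected G=%d (minimum BIC among admissible candidates%s)",
    selected_G,
    if (sum(in_band) > 1) ", parsimony tie-break within 2 BIC units" else ""))
  structure(list(candidates = candidates, stats = stats,
                 violations = violations, selected_G = selected_G,
                 selected = candidates[[as.character(selected_G)]],
                 trace = trace),
            class = "traj_ladder")
}

#' @export
print.traj_ladder <- function(x, ...) {
  cat("trajectory model-selection ladder\n")
  print(x$stats, row.names = FALSE)
  cat("selected:", x$selected_G, "groups\n")
  invisible(x)
}

#' Prune nonsignificant polynomial terms
#'
#' Starting from a fitted specification, repeatedly refits the model and
#' removes, one per round, the highest-order trend term with Wald p > .05
#' (largest p first across groups and submodels). Only the current
#' highest-order term of a trend is removable. Count-model linear terms
#' are always retained regardless of significance; intercepts are never
#' removed. Stops when every remaining removable term is significant.
#'
#' @param y integer count matrix.
#' @param spec starting [zip_traj_spec].
#' @param time_codes numeric time covariate per period.
#' @param n_starts,seed,alpha EM starts, seed, and significance level.
#' @return list with `spec` (pruned specification), `fit` (final fit),
#'   `trace` (per-round log).
#' @export
prune_polynomials <- function(y, spec, time_codes = NULL, n_starts = 5,
                              seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 64)
  trace <- character()
  round <- 1
  last_fit <- NULL
  repeat {
    fit <- tryCatch(
      fit_zip_trajectory(y, spec, time_codes = time_codes,
                         n_starts = n_starts, seed = seeds[round]),
      error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      warning("refit failed to converge during pruning; keeping last stable specification")
      return(list(spec = spec, fit = last_fit, trace = trace))
    }
    last_fit <- fit
    spec <- fit$spec  # canonical group order may permute the degrees
    tab <- fit$coef_table
    cand <- NULL
    for (j in seq_len(spec$n_groups)) {
      co <- spec$count_order[j]; io <- spec$inflation_order[j]
      if (co >= 2) {  # count linear protected, intercept never removed
        r <- tab[tab$group == j & tab$submodel == "count" &
                   tab$term == term_names[co + 1], ]
        cand <- rbind(cand, data.frame(group = j, submodel = "count",
                                       order = co, p = r$p))
      }
      if (io >= 1) {
        r <- tab[tab$group == j & tab$submodel == "inflation" &
                   tab$term == paste0("alpha", io), ]
        cand <- rbind(cand, data.frame(group = j, submodel = "inflation",
                                       order = io, p = r$p))
      }
    }
    if (is.null(cand)) {
      trace <- c(trace, sprintf("round %d: only protected terms remain; stop",
                                round))
      break
    }
    drop <- cand[!is.na(cand$p) & cand$p > alpha, , drop = FALSE]
    if (nrow(drop) == 0) {
      trace <- c(trace, sprintf("round %d: all remaining removable terms significant; stop",
                                round))
      break
    }
    worst <- drop[which.max(drop$p), ]
    trace <- c(trace, sprintf(
      "round %d: drop %s order-%d term of group %d (p = %.3f)",
      round, worst$submodel, worst$order, worst$group, worst$p))
    if (worst$submodel == "count") {
      spec$count_order[worst$group] <- spec$count_order[worst$group] - 1L
    } else {
      spec$inflation_order[worst$group] <- spec$inflation_order[worst$group] - 1L
    }
    round <- round + 1
  }
  list(spec = spec, fit = last_fit, trace = trace)
}

#' Validate a fitted model by average posterior probability
#'
#' Passes when every group's APP reaches the adequacy floor (default 0.7).
#'
#' @param model a `zip_traj_fit`.
#' @param floor adequacy threshold.
#' @return list with `pass` (logical), `app` (per-group values),
#'   `failing_groups`.
#' @export
validate_app <- function(model, floor = 0.7) {
  app <- average_posterior_probability(model)
  failing <- which(!is.na(app) & app < floor)
  list(pass = length(failing) == 0 && !anyNA(app), app = app,
       failing_groups = failing)
}
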