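#' Between-group Poisson rate ratio for one category and period
#'
#' Fits a log-linear count model of category hits on a high-risk
#' indicator with log(total words) as exposure offset, restricted to
#' users who posted in the period (zero-post periods are structurally
#' missing, not zero usage). With a single binary covariate and offset
#' the fitted rate ratio equals the ratio of aggregate rates
#' (high-group hits per word over low-group hits per word).
#'
#' @param matrix a [feature_matrix].
#' @param assignment per-user group labels aligned with `matrix$users`
#'   (or named by user id); the value of `high_group` marks the
#'   high-risk group, every other label is the low-risk reference.
#' @param period period label or index.
#' @param category category name or index.
#' @param high_group label identifying the high-risk group.
#' @return object of class `rate_comparison`: `category`, `period`, `rr`
#'   (rate ratio, low-risk reference), `se` (delta-method SE on the RR
#'   scale), `p` (Wald), `n_high`, `n_low`.
#' @export
compare_rates <- function(matrix, assignment, period, category,
                          high_group = 1) {
  stopifnot(inherits(matrix, "feature_matrix"))
  assignment <- align_assignment(assignment, matrix$users)
  t <- resolve_index(period, matrix$periods, "period")
  k <- resolve_index(category, matrix$categories, "category")
  words <- matrix$total_words[, t]
  keep <- words > 0
  high <- assignment == high_group
  n_high <- sum(keep & high); n_low <- sum(keep & !high)
  if (n_high < 2 || n_low < 2) {
    stop(sprintf("period %s: need at least 2 posting users per group (high %d, low %d)",
                 matrix$periods[t], n_high, n_low))
  }
  hits <- matrix$hits[keep, t, k]
  if (sum(hits) == 0) {
    stop(sprintf("zero hits in both groups for %s at %s; rate ratio undefined",
                 matrix$categories[k], matrix$periods[t]))
  }
  df <- data.frame(hits = hits, high = as.integer(high[keep]),
                   words = words[keep])
  fit <- stats::glm(hits ~ high + offset(log(words)),
                    family = stats::poisson(), data = df)
  cf <- summary(fit)$coefficients["high", ]
  rr <- exp(cf["Estimate"])
  structure(list(
    category = matrix$categories[k], period = matrix$periods[t],
    rr = unname(rr),
    se = unname(rr * cf["Std. Error"]),  # delta method on the RR scale
    log_se = unname(cf["Std. Error"]),
    p = unname(cf["Pr(>|z|)"]),
    n_high = n_high, n_low = n_low
  ), class = "rate_comparison")
}

align_assignment <- function(assignment, users) {
  if (is.null(users)) return(assignment)
  if (!is.null(names(assignment))) {
    miss <- setdiff(users, names(assignment))
    if (length(miss)) stop("assignment missing for user(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    assignment <- assignment[users]
  }
  stopifnot(length(assignment) == length(users))
  assignment
}

resolve_index <- function(x, labels, what) {
  if (is.numeric(x)) {
    stopifnot(x >= 1, x <= length(labels))
    return(as.integer(x))
  }
  i <- match(x, labels)
  if (is.na(i)) stop(sprintf("unknown %s: %s", what, x))
  i
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("%s @ %s: RR %.3f (SE %.3f), p = %.4g  [n high %d, low %d]\n",
              x$category, x$period, x$rr, x$se, x$p, x$n_high, x$n_low))
  invisible(x)
}

#' Full category x period grid of rate comparisons
#'
#' Per-cell failures (too few posting users, all-zero hits) are recorded
#' in the `status` column rather than aborting the grid.
#'
#' @inheritParams compare_rates
#' @param categories,periods subsets to compare; default all.
#' @param adjust optional p-value adjustment method passed to
#'   [stats::p.adjust] (e.g. "BH"); default `"none"` reports raw p-values.
#' @return data frame with columns `category`, `period`, `rr`, `se`, `p`,
#'   `stars` (significance at .05/.01/.001), `n_high`, `n_low`, `status`.
#' @export
comparison_grid <- function(matrix, assignment, categories = NULL,
                            periods = NULL, high_group = 1,
                            adjust = "none") {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.null(categories)) categories <- matrix$categories
  if (is.null(periods)) periods <- matrix$periods
  rows <- list()
  for (cat in categories) {
    for (per in periods) {
      res <- tryCatch(
        compare_rates(matrix, assignment, per, cat, high_group),
        error = function(e) e)
      rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
        data.frame(category = cat, period = per, rr = NA_real_,
                   se = NA_real_, p = NA_real_, n_high = NA_integer_,
                   n_low = NA_integer_, status = conditionMessage(res))
      } else {
        data.frame(category = cat, period = per, rr = res$rr, se = res$se,
                   p = res$p, n_high = res$n_high, n_low = res$n_low,
                   status = "ok")
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!identical(adjust, "none")) {
    out$p <- stats::p.adjust(out$p, method = adjust)
  }
  out$stars <- significance_stars(out$p)
  out[c("category", "period", "rr", "se", "p", "stars",
        "n_high", "n_low", "status")]
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", ""))))
}
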