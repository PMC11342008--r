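#' Keep categories with a significant between-group contrast
#'
#' Retains every category whose rate comparison reaches p <= .05
#' (inclusive threshold) in at least one of the requested periods.
#'
#' @param comparisons data frame from [comparison_grid].
#' @param periods period labels to inspect (the marker window, e.g.
#'   T5-T7).
#' @param alpha significance level (inclusive).
#' @return object of class `marker_candidates`: `stage`, `categories`,
#'   `audit` (per-category kept/removed log).
#' @export
filter_significant <- function(comparisons, periods, alpha = 0.05) {
  stopifnot(all(c("category", "period", "p") %in% names(comparisons)))
  missing_periods <- setdiff(periods, comparisons$period)
  if (length(missing_periods)) {
    stop("comparisons do not cover period(s): ",
         paste(missing_periods, collapse = ", "))
  }
  sub <- comparisons[comparisons$period %in% periods & !is.na(comparisons$p), ]
  keep <- sort(unique(sub$category[sub$p <= alpha]))
  all_cats <- sort(unique(comparisons$category))
  if (!length(keep)) warning("no category passes the significance filter")
  audit <- data.frame(
    category = all_cats,
    stage = ifelse(all_cats %in% keep, "kept", "removed:not_significant"),
    stringsAsFactors = FALSE
  )
  structure(list(stage = "significant", categories = keep, audit = audit),
            class = "marker_candidates")
}

#' Remove hierarchical parents from a candidate set
#'
#' Drops any candidate that is an ancestor (in the lexicon's category
#' hierarchy) of another candidate, so only the most specific categories
#' survive.
#'
#' @param candidates a `marker_candidates` (or character vector).
#' @param lexicon a [parse_lexicon] result carrying the hierarchy.
#' @return updated `marker_candidates`.
#' @export
prune_hierarchy <- function(candidates, lexicon) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  cats <- if (inherits(candidates, "marker_candidates"))
    candidates$categories else as.character(candidates)
  idx <- match(cats, lexicon$categories)
  if (anyNA(idx)) stop("candidate(s) absent from the lexicon: ",
                       paste(cats[is.na(idx)], collapse = ", "))
  anc <- unique(unlist(lexicon$ancestors[idx]))
  is_parent <- idx %in% anc
  keep <- cats[!is_parent]
  audit <- if (inherits(candidates, "marker_candidates")) {
    a <- candidates$audit
    a$stage[a$category %in% cats[is_parent]] <- "removed:hierarchy_parent"
    a
  } else {
    data.frame(category = cats,
               stage = ifelse(is_parent, "removed:hierarchy_parent", "kept"))
  }
  structure(list(stage = "hierarchy_pruned", categories = keep,
                 audit = audit),
            class = "marker_candidates")
}

#' Dichotomize window-averaged normalized frequencies
#'
#' Per user and category, averages the normalized frequency over the
#' marker window and recodes: an average of 0 stays 0 (the word was never
#' used in the window), any positive average becomes 1 (used at least
#' once, regardless of how often). Structurally missing periods (no
#' posts) contribute 0 to the numerator and still count in the
#' denominator.
#'
#' @param matrix a [feature_matrix].
#' @param categories category names to dichotomize.
#' @param periods the marker window labels (e.g. `c("T5","T6","T7")`).
#' @return 0/1 integer matrix (users x categories); users with every
#'   window period missing are recorded in attribute `"all_missing"`.
#' @export
dichotomize <- function(matrix, categories, periods) {
  stopifnot(inherits(matrix, "feature_matrix"))
  ti <- vapply(periods, resolve_index, 0L, labels = matrix$periods,
               what = "period")
  ki <- vapply(categories, resolve_index, 0L, labels = matrix$categories,
               what = "category")
  nf <- normalized_frequency(matrix)
  avg <- apply(nf$frequency[, ti, ki, drop = FALSE], c(1, 3), mean)
  out <- (avg > 0) * 1L
  dimnames(out) <- list(matrix$users, matrix$categories[ki])
  all_missing <- matrix$users[rowSums(!nf$missing[, ti, drop = FALSE]) == 0]
  attr(out, "all_missing") <- all_missing
  out
}

#' Screen markers with L1-penalized logistic regression
#'
#' Fits a lasso logistic model of high-risk membership on the binary
#' markers; the penalty is chosen by cross-validated deviance (stratified
#' folds, seeded). Categories whose coefficient is shrunk to zero at the
#' selected penalty are dropped. The penalized fit is used solely for
#' selection; no penalized coefficients are reported.
#'
#' @param binary_table 0/1 matrix (users x candidate categories).
#' @param assignment per-user group labels; `high_group` marks high risk.
#' @param n_folds cross-validation folds.
#' @param seed integer seed for the fold split.
#' @param high_group label of the high-risk group.
#' @param audit optional audit data frame from an earlier stage to extend.
#' @return a `marker_candidates` with the surviving categories.
#' @export
lasso_screen <- function(binary_table, assignment, n_folds = 10,
                         seed = NULL, high_group = 1, audit = NULL) {
  stopifnot(ncol(binary_table) >= 2)
  assignment <- align_assignment(assignment, rownames(binary_table))
  y <- as.integer(assignment == high_group)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: all users in one group; cannot screen")
  }
  if (!is.null(seed)) set.seed(seed)
  foldid <- stratified_folds(y, n_folds)
  cv <- glmnet::cv.glmnet(binary_table, y, family = "binomial",
                          foldid = foldid, nlambda = 100,
                          type.measure = "deviance")
  beta <- as.vector(stats::coef(cv, s = "lambda.min"))[-1]
  # coefficients are interpolated between path points; clip numerical dust
  keep <- colnames(binary_table)[abs(beta) > 1e-8]
  dropped <- setdiff(colnames(binary_table), keep)
  if (is.null(audit)) {
    audit <- data.frame(category = colnames(binary_table), stage = "kept")
  }
  audit$stage[audit$category %in% dropped] <- "removed:lasso_zero"
  structure(list(stage = "lasso_kept", categories = keep, audit = audit,
                 lambda = cv$lambda.min),
            class = "marker_candidates")
}

stratified_folds <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' Multivariate logistic marker model
#'
#' Unpenalized logistic regression of high-risk membership (coded 1) on
#' the binary markers. Reports per-marker odds ratios, standard errors on
#' the log-odds scale, Wald statistics and p-values, and labels markers
#' with OR > 1 and p <= .05 as high-risk markers, OR < 1 and p <= .05 as
#' low-risk (protective) markers.
#'
#' @param binary_table 0/1 matrix (users x markers).
#' @param assignment per-user group labels; `high_group` marks high risk.
#' @param high_group label of the high-risk group.
#' @return object of class `marker_model`: `table` (marker, or, se, z, p,
#'   direction), `intercept_or`, `n`, `fit`.
#' @export
fit_marker_model <- function(binary_table, assignment, high_group = 1) {
  assignment <- align_assignment(assignment, rownames(binary_table))
  y <- as.integer(assignment == high_group)
  df <- data.frame(y = y, binary_table, check.names = FALSE)
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = df)
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    stop("perfect or quasi-perfect separation detected; an unpenalized fit is not identifiable (consider a penalized fallback, reported as such)")
  }
  sm <- summary(fit)$coefficients
  markers <- rownames(sm)[-1]
  markers <- gsub("^`|`$", "", markers)
  tab <- data.frame(
    marker = markers,
    or = exp(sm[-1, "Estimate"]),
    se = sm[-1, "Std. Error"],
    z = sm[-1, "z value"],
    p = sm[-1, "Pr(>|z|)"],
    row.names = NULL
  )
  tab$direction <- ifelse(tab$p > 0.05, "ns",
                          ifelse(tab$or > 1, "high_risk", "low_risk"))
  structure(list(table = tab, intercept_or = exp(sm[1, "Estimate"]),
                 n = length(y), fit = fit),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("marker model: %d users, %d markers (intercept odds %.3f)\n",
              x$n, nrow(x$table), x$intercept_or))
  print(transform(x$table, or = round(or, 3), se = round(se, 3),
                  z = round(z, 2), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Run the full marker-selection cascade
#'
#' Significance filter over the marker window, hierarchy pruning,
#' window-averaging and dichotomization, lasso screening, and the final
#' unpenalized multivariate logistic model. Every input category appears
#' exactly once in the audit, either kept through all stages or removed
#' at a named stage with a reason.
#'
#' @param comparisons data frame from [comparison_grid].
#' @param matrix a [feature_matrix].
#' @param assignment per-user group labels.
#' @param lexicon a [parse_lexicon] result.
#' @param window marker-window period labels.
#' @param n_folds,seed lasso cross-validation controls.
#' @param high_group label of the high-risk group.
#' @return list with `model` (a `marker_model`), `audit`, `stages`
#'   (category sets per stage), `binary_table`.
#' @export
marker_cascade <- function(comparisons, matrix, assignment, lexicon,
                           window = c("T5", "T6", "T7"), n_folds = 10,
                           seed = NULL, high_group = 1) {
  s1 <- filter_significant(comparisons, window)
  s2 <- prune_hierarchy(s1, lexicon)
  if (length(s2$categories) < 2) {
    stop("fewer than 2 candidates survive hierarchy pruning; cascade cannot continue")
  }
  bt <- dichotomize(matrix, s2$categories, window)
  s3 <- lasso_screen(bt, assignment, n_folds = n_folds, seed = seed,
                     high_group = high_group, audit = s2$audit)
  model <- fit_marker_model(bt[, s3$categories, drop = FALSE], assignment,
                            high_group = high_group)
  list(model = model, audit = s3$audit,
       stages = list(significant = s1$categories,
                     hierarchy_pruned = s2$categories,
                     lasso_kept = s3$categories),
       binary_table = bt)
}
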