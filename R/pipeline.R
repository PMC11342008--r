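#' Default end-to-end run configuration
#'
#' All thresholds the analysis relies on live here: the significance
#' level (.05), the group-composition floor (5%), the entropy adequacy
#' level (0.8) and the APP adequacy level (0.7), along with the candidate
#' group range, polynomial caps, the marker window and the seeds.
#'
#' @param out_dir output directory for the run artifacts.
#' @param seed master integer seed for the run.
#' @param n_users synthetic cohort size (used when no counts are given).
#' @return a named list; pass to [run_pipeline].
#' @export
default_run_config <- function(out_dir = tempfile("ziptraj_run_"),
                               seed = 1L, n_users = 2000) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    n_users = as.integer(n_users),
    counts_csv = NULL,          # optional pre-aggregated input
    posts_jsonl = NULL,         # optional raw-post input
    lexicon = toy_lexicon_path(),
    g_min = 2L, g_max = 5L,
    max_order = 3L,
    n_starts = 5L,
    marker_window = c("T5", "T6", "T7"),
    lasso_folds = 10L,
    significance = 0.05,
    composition_floor = 0.05,
    entropy_floor = 0.8,
    app_floor = 0.7
  )
}

#' Run the full trajectory-and-markers pipeline
#'
#' Aggregation (or synthetic generation) of per-period counts, the group
#' model-selection ladder with polynomial pruning, linguistic feature
#' construction, the period-by-category rate-ratio grid, and the marker
#' cascade. Writes counts.csv, truth.csv (synthetic runs), ladder.json,
#' model.json, posteriors.csv, features.csv, comparisons.csv,
#' markers.json, markers.csv and a manifest.json with the config echo,
#' seed and per-file checksums, so a re-run with the same seed is
#' byte-identical.
#'
#' @param config list as produced by [default_run_config] (or a path to
#'   a YAML file with the same fields).
#' @return the output directory, invisibly; stage results as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- default_period_grid()
  lexicon <- parse_lexicon(config$lexicon)
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max %/% 2, 6)

  # --- stage 1: counts ----------------------------------------------------
  truth <- NULL
  if (!is.null(config$counts_csv)) {
    counts <- read_counts_csv(config$counts_csv, grid)
    fm <- NULL
  } else if (!is.null(config$posts_jsonl)) {
    posts <- read_posts_jsonl(config$posts_jsonl)
    counts <- build_user_series(posts, grid)
    fm <- build_feature_matrix(posts[posts$user_id %in% rownames(counts), ],
                               grid, lexicon)
  } else {
    spec <- canonical_cohort_spec(n_users = config$n_users)
    cohort <- simulate_counts(spec, seed = stage_seeds[1],
                              ensure_eligible = TRUE)
    counts <- cohort$counts
    attr(counts, "grid") <- grid
    truth <- cohort$true_groups
    fm <- simulate_features(cohort, seed = stage_seeds[2])
    utils::write.csv(data.frame(user_id = rownames(counts), group = truth),
                     file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  write_counts_csv(counts, file.path(config$out_dir, "counts.csv"))

  # --- stage 2: ladder + pruning -----------------------------------------
  ladder <- run_ladder(counts, config$g_min:config$g_max,
                       time_codes = grid$time_codes,
                       n_starts = config$n_starts, seed = stage_seeds[3],
                       composition_floor = config$composition_floor,
                       entropy_floor = config$entropy_floor,
                       app_floor = config$app_floor)
  pruned <- prune_polynomials(counts, ladder$selected$spec,
                              time_codes = grid$time_codes,
                              n_starts = config$n_starts,
                              seed = stage_seeds[4],
                              alpha = config$significance)
  model <- pruned$fit
  app_check <- validate_app(model, config$app_floor)
  jsonlite::write_json(
    list(stats = ladder$stats, selected_G = ladder$selected_G,
         trace = ladder$trace, pruning_trace = pruned$trace,
         app = app_check),
    file.path(config$out_dir, "ladder.json"), auto_unbox = TRUE,
    digits = NA)
  write_model_json(model, file.path(config$out_dir, "model.json"))
  utils::write.csv(
    data.frame(user_id = rownames(counts),
               round(model$posterior, 8),
               assignment = model$assignment, check.names = FALSE),
    file.path(config$out_dir, "posteriors.csv"), row.names = FALSE,
    quote = FALSE)

  # --- stage 3: features + comparisons -----------------------------------
  results <- list(ladder = ladder, model = model, app = app_check)
  if (!is.null(fm)) {
    utils::write.csv(feature_matrix_long(fm),
                     file.path(config$out_dir, "features.csv"),
                     row.names = FALSE, quote = FALSE)
    assignment <- stats::setNames(model$assignment, rownames(counts))
    comparisons <- comparison_grid(fm, assignment)
    utils::write.csv(comparisons,
                     file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    # --- stage 4: markers -------------------------------------------------
    cascade <- tryCatch(
      marker_cascade(comparisons, fm, assignment, lexicon,
                     window = config$marker_window,
                     n_folds = config$lasso_folds, seed = stage_seeds[5]),
      error = function(e) e)
    if (inherits(cascade, "error")) {
      warning("marker stage failed: ", conditionMessage(cascade))
      writeLines(jsonlite::toJSON(list(error = conditionMessage(cascade)),
                                  auto_unbox = TRUE),
                 file.path(config$out_dir, "markers.json"))
    } else {
      jsonlite::write_json(
        list(stages = cascade$stages, audit = cascade$audit,
             markers = cascade$model$table,
             intercept_or = cascade$model$intercept_or),
        file.path(config$out_dir, "markers.json"), auto_unbox = TRUE,
        digits = NA)
      utils::write.csv(cascade$model$table,
                       file.path(config$out_dir, "markers.csv"),
                       row.names = FALSE)
      results$cascade <- cascade
    }
    results$comparisons <- comparisons
  }

  # --- manifest -----------------------------------------------------------
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    package_version = as.character(utils::packageVersion("ziptraj")),
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(invisible(config$out_dir), results = results)
}

write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    n_groups = model$spec$n_groups,
    count_order = model$spec$count_order,
    inflation_order = model$spec$inflation_order,
    params = lapply(model$params, function(p)
      list(beta = p$beta, alpha = p$alpha)),
    weights = model$weights,
    loglik = model$loglik, aic = model$aic, bic = model$bic,
    entropy = model$entropy, app = model$app,
    composition = model$composition,
    coef_table = model$coef_table,
    converged = model$converged, n_users = model$n_users
  ), path, auto_unbox = TRUE, digits = NA)
}

#' Summarize a completed pipeline run
#'
#' Read-only: renders a plain-markdown report with the model-selection
#' table, the parameter table of the selected model, the comparison grid
#' for the marker window and the marker table. Missing artifacts are
#' listed rather than failing.
#'
#' @param run_dir directory written by [run_pipeline].
#' @return character vector of report lines, invisibly; also written to
#'   `report.md` in the run directory.
#' @export
summarize_run <- function(run_dir) {
  need <- c("ladder.json", "model.json", "comparisons.csv", "markers.csv")
  have <- file.exists(file.path(run_dir, need))
  out <- c("# Trajectory-and-markers run summary", "")
  if (!all(have)) {
    out <- c(out, "Missing artifacts:", paste0("- ", need[!have]), "")
  }
  if (have[1]) {
    ladder <- jsonlite::read_json(file.path(run_dir, "ladder.json"),
                                  simplifyVector = TRUE)
    out <- c(out, "## Model selection", "",
             utils::capture.output(print(ladder$stats, row.names = FALSE)),
             "", sprintf("Selected number of groups: %d", ladder$selected_G),
             "")
  }
  if (have[2]) {
    model <- jsonlite::read_json(file.path(run_dir, "model.json"),
                                 simplifyVector = TRUE)
    out <- c(out, "## Selected model parameters", "",
             sprintf("Composition: %s (sums to %.0f%%)",
                     paste(sprintf("%.2f%%", 100 * model$composition),
                           collapse = " / "),
                     100 * sum(model$composition)),
             sprintf("Entropy: %.3f; APP: %s", model$entropy,
                     paste(sprintf("%.3f", model$app), collapse = " / ")),
             "",
             utils::capture.output(print(model$coef_table,
                                         row.names = FALSE)), "")
  }
  if (have[3]) {
    cmp <- utils::read.csv(file.path(run_dir, "comparisons.csv"))
    sub <- cmp[cmp$period %in% c("T5", "T6", "T7") & cmp$status == "ok", ]
    out <- c(out, "## Rate-ratio contrasts (marker window)", "",
             utils::capture.output(print(utils::head(
               sub[order(sub$p), ], 15), row.names = FALSE)), "")
  }
  if (have[4]) {
    mk <- utils::read.csv(file.path(run_dir, "markers.csv"))
    out <- c(out, "## Linguistic markers (multivariate logistic)", "",
             utils::capture.output(print(mk, row.names = FALSE)), "")
  } else {
    out <- c(out, "## Linguistic markers", "", "(section unavailable)", "")
  }
  writeLines(out, file.path(run_dir, "report.md"))
  invisible(out)
}
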