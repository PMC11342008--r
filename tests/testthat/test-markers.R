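mk_comparisons <- function(cats, p_by_period) {
  # p_by_period: named list period -> p values aligned with cats
  do.call(rbind, lapply(names(p_by_period), function(per) {
    data.frame(category = cats, period = per, rr = 1.5, se = 0.1,
               p = p_by_period[[per]])
  }))
}

test_that("significance filter is inclusive at the threshold", {
  cmp <- mk_comparisons(c("a", "b", "c"),
                        list(T5 = c(0.05, 0.2, NA),
                             T6 = c(0.8, 0.051, 0.9)))
  out <- filter_significant(cmp, c("T5", "T6"))
  expect_equal(out$categories, "a")       # p = .05 retained, .051 not
  expect_equal(sort(out$audit$category), c("a", "b", "c"))
  expect_equal(out$audit$stage[out$audit$category == "b"],
               "removed:not_significant")
  # all-null grid gives an empty set with a warning
  cmp2 <- mk_comparisons(c("a", "b"), list(T5 = c(0.5, 0.5)))
  expect_warning(out2 <- filter_significant(cmp2, "T5"), "no category")
  expect_length(out2$categories, 0)
  expect_error(filter_significant(cmp2, c("T5", "T9")), "T9")
})

test_that("hierarchy pruning removes ancestors of surviving candidates", {
  lex <- toy_lexicon()
  out <- prune_hierarchy(c("negemo", "anger"), lex)
  expect_equal(out$categories, "anger")
  # grandparent removal: affect is an ancestor of anger
  out2 <- prune_hierarchy(c("affect", "negemo", "anger", "death"), lex)
  expect_equal(sort(out2$categories), c("anger", "death"))
  # candidates with no ancestry links are untouched
  out3 <- prune_hierarchy(c("death", "work"), lex)
  expect_equal(sort(out3$categories), c("death", "work"))
})

test_that("dichotomization implements the zero-retained truth table", {
  # three users x three window periods, one category
  hits <- array(0L, c(3, 3, 1),
                dimnames = list(c("never", "once", "silent"),
                                c("T5", "T6", "T7"), "cat"))
  words <- matrix(0L, 3, 3, dimnames = dimnames(hits)[1:2])
  words["never", ] <- 100L                  # posted, no usage
  words["once", ] <- 100L
  hits["once", 2, 1] <- 1L                  # frequency (0, 0.01, 0)
  # "silent" has no posts at all in the window
  fm <- feature_matrix(hits, words)
  bt <- dichotomize(fm, "cat", c("T5", "T6", "T7"))
  expect_equal(unname(bt[, "cat"]), c(0L, 1L, 0L))
  expect_equal(attr(bt, "all_missing"), "silent")
})

test_that("lasso screening drops duplicated collinear candidates", {
  set.seed(71)
  n <- 600
  x1 <- rbinom(n, 1, 0.5)
  x3 <- rbinom(n, 1, 0.4)
  bt <- cbind(a = x1, a_copy = x1, b = x3)
  rownames(bt) <- paste0("u", 1:n)
  y <- rbinom(n, 1, plogis(-1 + 2 * x1))
  out <- lasso_screen(bt, ifelse(y == 1, 1, 2), n_folds = 5, seed = 72)
  expect_lte(sum(c("a", "a_copy") %in% out$categories), 1)
  expect_true(all(out$audit$category %in% colnames(bt)))
  # degenerate outcome errors
  expect_error(lasso_screen(bt, rep(1, n), n_folds = 5, seed = 1),
               "degenerate")
})

test_that("null effects are heavily shrunk by the screen", {
  set.seed(73)
  n <- 500
  survivors <- vapply(1:10, function(s) {
    bt <- sapply(1:6, function(k) rbinom(n, 1, 0.5))
    colnames(bt) <- letters[1:6]
    rownames(bt) <- paste0("u", 1:n)
    y <- rbinom(n, 1, 0.3)
    length(lasso_screen(bt, ifelse(y == 1, 1, 2), n_folds = 5,
                        seed = s)$categories)
  }, 0)
  expect_gte(mean(survivors <= 2), 0.7)
})

test_that("with one binary marker the logistic OR is the cross-product ratio", {
  # 2x2 table: high risk 40/60 exposed, low risk 10/90 exposed -> OR 6
  marker <- c(rep(1L, 40), rep(0L, 60), rep(1L, 10), rep(0L, 90))
  group <- rep(c(1, 2), c(100, 100))
  bt <- matrix(marker, ncol = 1, dimnames = list(paste0("u", 1:200), "m"))
  mm <- fit_marker_model(bt, group)
  expect_equal(mm$table$or, 6.0, tolerance = 1e-6)
  expect_equal(mm$table$direction, "high_risk")
  # null marker: OR ~ 1, large p
  set.seed(74)
  bt2 <- matrix(rbinom(400, 1, 0.5), ncol = 1,
                dimnames = list(paste0("u", 1:400), "m"))
  mm2 <- fit_marker_model(bt2, sample(rep(c(1, 2), 200)))
  expect_gt(mm2$table$p, 0.05)
  expect_equal(mm2$table$direction, "ns")
  expect_lt(abs(log(mm2$table$or)), 3 * mm2$table$se)
})

test_that("perfect separation is reported, not silently fitted", {
  bt <- matrix(rep(c(1L, 0L), c(50, 50)), ncol = 1,
               dimnames = list(paste0("u", 1:100), "m"))
  group <- rep(c(1, 2), c(50, 50))
  expect_error(suppressWarnings(fit_marker_model(bt, group)), "separation")
})

test_that("OR recovery: fitted log odds stay within 3 SE of the truth", {
  sim <- simulate_marker_table(
    4000, canonical_marker_log_odds(),
    prevalence = canonical_marker_prevalence(),
    base_rate = 0.1207, seed = 75)
  mm <- fit_marker_model(sim$markers, ifelse(sim$high_risk == 1, 1, 2))
  truth <- canonical_marker_log_odds()[mm$table$marker]
  expect_true(all(abs(log(mm$table$or) - truth) <= 3 * mm$table$se))
})

test_that("the cascade audit covers every category exactly once", {
  spec <- canonical_cohort_spec(n_users = 700)
  cohort <- simulate_counts(spec, seed = 76, ensure_eligible = TRUE)
  fm <- simulate_features(cohort, seed = 77)
  asg <- setNames(cohort$true_groups, rownames(cohort$counts))
  cmp <- comparison_grid(fm, asg)
  lex <- toy_lexicon()
  s1 <- filter_significant(cmp, c("T5", "T6", "T7"))
  s2 <- prune_hierarchy(s1, lex)
  bt <- dichotomize(fm, s2$categories, c("T5", "T6", "T7"))
  s3 <- lasso_screen(bt, asg, n_folds = 5, seed = 78, audit = s2$audit)
  # monotone stage cardinalities
  expect_lte(length(s2$categories), length(s1$categories))
  expect_lte(length(s3$categories), length(s2$categories))
  # audit: every category once, stages accounted for
  expect_equal(sort(s3$audit$category), sort(unique(cmp$category)))
  expect_false(any(duplicated(s3$audit$category)))
  kept <- s3$audit$category[s3$audit$stage == "kept"]
  expect_setequal(kept, s3$categories)
  expect_true(all(grepl("^kept$|^removed:", s3$audit$stage)))
})
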