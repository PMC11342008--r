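test_that("single-group Poisson data recovers the log rate", {
  spec <- one_group_spec(2000, beta = log(3))
  cohort <- simulate_counts(spec, seed = 21)
  fit <- fit_zip_trajectory(cohort$counts, zip_traj_spec(1, 0, 0),
                            n_starts = 2, seed = 22, compute_se = FALSE)
  est <- fit$params[[1]]$beta[1]
  # Poisson information for the log rate: n * lambda
  se <- sqrt(1 / (2000 * 3))
  expect_true(fit$converged)
  expect_lt(abs(est - log(3)), 3 * se)
  expect_equal(fit$composition, 1)
  expect_equal(fit$entropy, 1)
  expect_equal(fit$app, 1)
})

test_that("interior ZIP fit reports usable standard errors", {
  spec <- generative_spec(1500, 1,
                          list(list(beta = log(2.5), alpha = qlogis(0.3))))
  cohort <- simulate_counts(spec, seed = 31)
  fit <- fit_zip_trajectory(cohort$counts, zip_traj_spec(1, 0, 0),
                            n_starts = 1, seed = 32)
  tab <- fit$coef_table
  expect_true(all(is.finite(tab$se)))
  expect_lt(abs(tab$estimate[tab$submodel == "count"] - log(2.5)),
            3 * tab$se[tab$submodel == "count"])
  expect_lt(abs(tab$estimate[tab$submodel == "inflation"] - qlogis(0.3)),
            3 * tab$se[tab$submodel == "inflation"])
})

test_that("well-separated two-group data is classified almost perfectly", {
  cohort <- separable_cohort(n = 400, seed = 23)
  fit <- fit_zip_trajectory(cohort$counts, zip_traj_spec(2, 0, 0),
                            n_starts = 3, seed = 24, compute_se = FALSE)
  # canonical order: group 1 is high volume, matching the generator
  acc <- mean(fit$assignment == cohort$true_groups)
  expect_gte(acc, 0.99)
  expect_gt(fit$entropy, 0.95)
  expect_true(all(fit$app > 0.95))
})

test_that("posterior rows sum to one and diagnostics are coherent", {
  cohort <- separable_cohort(n = 200, seed = 25)
  fit <- fit_zip_trajectory(cohort$counts, zip_traj_spec(2, 1, 1),
                            n_starts = 2, seed = 26, compute_se = FALSE)
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-8))
  expect_equal(sum(fit$composition), 1)
  expect_true(all(fit$app >= 0 & fit$app <= 1))
  # AIC/BIC consistent with loglik and the stated parameter count
  k <- fit$n_params
  expect_equal(k, 2 * (2 + 2) + 1)
  expect_equal(fit$aic, 2 * k - 2 * fit$loglik)
  expect_equal(fit$bic, k * log(fit$n_users) - 2 * fit$loglik)
})

test_that("groups are reported in canonical high-to-low volume order", {
  cohort <- separable_cohort(n = 300, seed = 27)
  fit <- fit_zip_trajectory(cohort$counts, zip_traj_spec(2, 0, 0),
                            n_starts = 3, seed = 28, compute_se = FALSE)
  ev <- vapply(fit$params, function(p) exp(p$beta[1]), 0)
  expect_true(ev[1] > ev[2])
  expect_gt(exp(fit$params[[1]]$beta[1]), 4)   # ~8 by construction
  expect_lt(exp(fit$params[[2]]$beta[1]), 1)   # ~0.2 by construction
})

test_that("best-of-starts log-likelihood is nondecreasing in the start set", {
  cohort <- separable_cohort(n = 150, seed = 29)
  ll <- vapply(c(1, 2, 4), function(ns) {
    fit_zip_trajectory(cohort$counts, zip_traj_spec(2, 1, 0),
                       n_starts = ns, seed = 30, compute_se = FALSE)$loglik
  }, 0)
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("entropy endpoints: uniform posteriors 0, degenerate posteriors 1", {
  n <- 50
  expect_equal(normalized_entropy(matrix(1 / 3, n, 3)), 0)
  P <- matrix(0, n, 3)
  P[cbind(seq_len(n), sample(1:3, n, TRUE))] <- 1
  expect_equal(normalized_entropy(P), 1)
  expect_equal(normalized_entropy(matrix(1, n, 1)), 1)  # single group
})

test_that("APP is the mean posterior among assigned users", {
  P <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.3, 0.7))
  app <- average_posterior_probability(P)
  expect_equal(app, c((0.8 + 0.6) / 2, 0.7))
  # degenerate posteriors give APP 1 for every nonempty group
  P1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(average_posterior_probability(P1), c(1, 1))
  # an empty group is NA with a warning
  expect_warning(app2 <- average_posterior_probability(rbind(c(0.9, 0.1))),
                 "no assigned users")
  expect_true(is.na(app2[2]))
})

test_that("a sample far smaller than the parameter count warns", {
  y <- matrix(rpois(5 * 7, 1), 5, 7)
  expect_warning(
    fit_zip_trajectory(y, zip_traj_spec(1, 0, 0), n_starts = 1, seed = 1,
                       compute_se = FALSE),
    "unstable")
})
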