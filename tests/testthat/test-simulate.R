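test_that("pure Poisson limit: mean count matches the rate", {
  spec <- one_group_spec(10000, beta = log(2))
  cohort <- simulate_counts(spec, seed = 3)
  means <- colMeans(cohort$counts)
  se <- sqrt(2 / 10000)
  expect_true(all(abs(means - 2) < 3 * se))
})

test_that("degenerate inflation gives all-zero counts", {
  spec <- one_group_spec(200, beta = log(3), alpha = 20)  # pi ~ 1
  cohort <- simulate_counts(spec, seed = 4)
  expect_true(all(cohort$counts == 0))
})

test_that("canonical scenario: high-volume group dominates every period", {
  spec <- canonical_cohort_spec()
  # evaluate lambda(1 - pi) per group/period directly from the coefficients
  tc <- spec$time_codes
  ev <- lapply(spec$groups, function(g) {
    lam <- exp(vapply(tc, function(t) sum(g$beta * t^(0:(length(g$beta) - 1))), 0))
    pi <- plogis(vapply(tc, function(t) sum(g$alpha * t^(0:(length(g$alpha) - 1))), 0))
    (1 - pi) * lam
  })
  expect_true(max(ev[[1]]) > max(ev[[2]]))          # peak dominance
  expect_true(all(ev[[1]] > ev[[2]]))               # at every period
  # the high-volume peak falls in the second peri-pandemic year (T5)
  expect_equal(which.max(ev[[1]]), 5L)
})

test_that("simulation is byte-for-byte reproducible under a seed", {
  spec <- canonical_cohort_spec(n_users = 300)
  a <- simulate_counts(spec, seed = 99, ensure_eligible = TRUE)
  b <- simulate_counts(spec, seed = 99, ensure_eligible = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$true_groups, b$true_groups)
  fa <- simulate_features(a, seed = 100)
  fb <- simulate_features(b, seed = 100)
  expect_identical(fa$hits, fb$hits)
})

test_that("empirical moments match the ZIP mixture within 4 SE", {
  spec <- canonical_cohort_spec(n_users = 20000)
  cohort <- simulate_counts(spec, seed = 5)
  tc <- spec$time_codes
  for (j in 1:2) {
    g <- spec$groups[[j]]
    lam <- exp(vapply(tc, function(t) sum(g$beta * t^(0:(length(g$beta) - 1))), 0))
    pi <- plogis(vapply(tc, function(t) sum(g$alpha * t^(0:(length(g$alpha) - 1))), 0))
    idx <- cohort$true_groups == j
    nj <- sum(idx)
    mean_th <- (1 - pi) * lam
    var_th <- mean_th + lam^2 * pi * (1 - pi)   # ZIP variance
    p0_th <- pi + (1 - pi) * exp(-lam)
    mean_emp <- colMeans(cohort$counts[idx, ])
    p0_emp <- colMeans(cohort$counts[idx, ] == 0)
    expect_true(all(abs(mean_emp - mean_th) < 4 * sqrt(var_th / nj)))
    expect_true(all(abs(p0_emp - p0_th) < 4 * sqrt(p0_th * (1 - p0_th) / nj)))
  }
  # group shares near the mixing weights
  share <- mean(cohort$true_groups == 1)
  expect_lt(abs(share - 0.1207), 3 * sqrt(0.1207 * 0.8793 / 20000))
})

test_that("eligibility resampling removes all-zero users only", {
  spec <- canonical_cohort_spec(n_users = 500)
  cohort <- simulate_counts(spec, seed = 6, ensure_eligible = TRUE)
  expect_true(all(rowSums(cohort$counts) >= 1))
  expect_equal(nrow(cohort$counts), 500)
})

test_that("non-finite rates from extreme coefficients are caught", {
  spec <- one_group_spec(100, beta = c(800, 200))
  expect_error(simulate_counts(spec, seed = 1), "non-finite.*group 1")
})

test_that("feature simulation: zero-post periods yield zero words and hits", {
  spec <- canonical_cohort_spec(n_users = 150)
  cohort <- simulate_counts(spec, seed = 8, ensure_eligible = TRUE)
  fm <- simulate_features(cohort, seed = 9)
  zero <- cohort$counts == 0
  expect_true(all(fm$total_words[zero] == 0))
  expect_true(all(apply(fm$hits, 3, function(h) all(h[zero] == 0))))
  expect_true(all(fm$total_words[!zero] >= cohort$counts[!zero]))
  # hits never exceed total words for a single category
  expect_true(all(apply(fm$hits, 3, function(h) all(h <= fm$total_words))))
})

test_that("feature simulation hit rates track the generating rates", {
  # one group, flat rates, many users: empirical rate ~ binomial mean
  rates <- matrix(0.1, 7, 2, dimnames = list(paste0("T", 1:7), c("a", "b")))
  rates[, 2] <- 0.02
  spec <- generative_spec(3000, 1, list(list(beta = log(3), alpha = -20)),
                          words_per_post = 30, category_rates = list(rates))
  cohort <- simulate_counts(spec, seed = 10)
  fm <- simulate_features(cohort, seed = 11)
  for (k in 1:2) {
    est <- sum(fm$hits[, , k]) / sum(fm$total_words)
    expect_equal(est, rates[1, k], tolerance = 0.02)
  }
})

test_that("feature simulation requires rates for every group present", {
  spec <- canonical_cohort_spec(n_users = 100)
  cohort <- simulate_counts(spec, seed = 12, ensure_eligible = TRUE)
  cohort$spec$category_rates <- cohort$spec$category_rates[1]
  expect_error(simulate_features(cohort, seed = 1), "missing for group")
})

test_that("marker table: null model hits the target base rate", {
  sim <- simulate_marker_table(5000, c(a = 0, b = 0), base_rate = 0.5,
                               seed = 13)
  expect_equal(mean(sim$high_risk), 0.5, tolerance = 3 * sqrt(0.25 / 5000) + 0.01)
  expect_equal(dim(sim$markers), c(5000, 2))
})

test_that("marker table: a single strong marker reproduces its odds ratio", {
  sim <- simulate_marker_table(60000, c(m = log(6)),
                               prevalence = c(m = 0.5),
                               base_rate = 0.3, seed = 14)
  tab <- table(sim$markers[, 1], sim$high_risk)
  or_hat <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_equal(or_hat, 6, tolerance = 0.4)
})

test_that("marker table rejects unattainable base rates", {
  expect_error(simulate_marker_table(200, c(a = 0), base_rate = 1),
               "unattainable")
})

test_that("generative spec validates its inputs", {
  expect_error(generative_spec(10, c(0.6, 0.6),
                               list(list(beta = 1, alpha = 1),
                                    list(beta = 1, alpha = 1))),
               "sum to 1")
  expect_error(generative_spec(10, 1, list(list(beta = 1, alpha = 1)),
                               words_per_post = 0.5),
               "words_per_post")
  bad <- matrix(2, 7, 1)
  expect_error(generative_spec(10, 1, list(list(beta = 1, alpha = 1)),
                               category_rates = list(bad)),
               "\\[0, 1\\]")
})
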