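#' Canonical two-group cohort scenario
#'
#' The package's built-in reference scenario: 6163 forum users in two
#' latent trajectory groups (12.07% high-volume / 87.93% low-volume)
#' observed over seven half-year windows spanning the COVID-19 pandemic.
#' The high-volume ("high risk") group follows a cubic count trend that
#' accelerates after the pandemic onset, peaks about one year in, and
#' falls back; the low-volume group stays low throughout. Both groups have
#' strongly time-varying structural-zero probabilities (most users joined
#' the forum only after the pandemic began, so early periods are mostly
#' zeros).
#'
#' @param n_users cohort size.
#' @param mixing group membership probabilities (high-volume first).
#' @param words_per_post mean words per post used when simulating
#'   linguistic features.
#' @param time_codes numeric time covariate per period.
#' @return A `generative_spec` list with per-group `beta` (count trend)
#'   and `alpha` (inflation trend) coefficients, mixing weights, time
#'   codes, words-per-post rate and per-group/period/category hit rates.
#' @export
canonical_cohort_spec <- function(n_users = 6163,
                                  mixing = c(0.1207, 0.8793),
                                  words_per_post = 120,
                                  time_codes = default_period_grid()$time_codes) {
  generative_spec(
    n_users = n_users,
    mixing = mixing,
    groups = list(
      list(beta = c(2.62, 0.10, -0.44, -0.22),
           alpha = c(-0.19, -1.85, 1.49, 0.75)),
      list(beta = c(0.59, -0.14, -0.12),
           alpha = c(-0.34, -2.31, 2.63, 1.49))
    ),
    time_codes = time_codes,
    words_per_post = words_per_post,
    category_rates = canonical_category_rates()
  )
}

#' Construct a generative cohort specification
#'
#' @param n_users positive integer cohort size.
#' @param mixing probability vector over groups (sums to 1).
#' @param groups list of per-group lists with `beta` (count-trend
#'   coefficients, intercept first) and `alpha` (inflation-trend
#'   coefficients).
#' @param time_codes numeric time covariate per period.
#' @param words_per_post mean words per post (> 1).
#' @param category_rates optional list of per-group matrices
#'   (periods x categories) of per-word hit probabilities.
#' @return object of class `generative_spec`.
#' @export
generative_spec <- function(n_users, mixing, groups,
                            time_codes = default_period_grid()$time_codes,
                            words_per_post = 120, category_rates = NULL) {
  stopifnot(n_users >= 1, length(mixing) == length(groups))
  if (abs(sum(mixing) - 1) > 1e-12) stop("mixing must sum to 1")
  if (words_per_post <= 1) stop("words_per_post must exceed 1")
  if (!is.null(category_rates)) {
    stopifnot(length(category_rates) == length(groups))
    for (m in category_rates) {
      if (any(m < 0 | m > 1)) stop("category rates must lie in [0, 1]")
    }
  }
  structure(list(n_users = as.integer(n_users), mixing = mixing,
                 groups = groups, time_codes = time_codes,
                 words_per_post = words_per_post,
                 category_rates = category_rates),
            class = "generative_spec")
}

spec_rates <- function(spec) {
  lapply(seq_along(spec$groups), function(j) {
    g <- spec$groups[[j]]
    r <- group_rates(g$beta, g$alpha, spec$time_codes)
    if (any(!is.finite(r$lambda)) || any(!is.finite(r$pi))) {
      bad <- which(!is.finite(r$lambda) | !is.finite(r$pi))[1]
      stop(sprintf("non-finite rate for group %d, period %d; check the coefficients",
                   j, bad))
    }
    r
  })
}

#' Simulate per-user per-period post counts from a ZIP trajectory mixture
#'
#' Each user draws a group from the mixing distribution; each period's
#' count is a structural zero with probability pi_jt, else
#' Poisson(lambda_jt), with lambda_jt = exp(beta_j . poly(t)) and
#' pi_jt = logistic(alpha_j . poly(t)).
#'
#' @param spec a [generative_spec].
#' @param seed integer seed (reproducible byte-for-byte).
#' @param ensure_eligible if `TRUE`, users whose whole series is zero are
#'   redrawn within their group until at least one post appears. This
#'   emulates a cohort defined by the eligibility rule "posted at least
#'   once over the observation range" while keeping the group mixing
#'   exactly at `spec$mixing`. If `FALSE` (default), all-zero series are
#'   kept and left to downstream filtering.
#' @return object of class `traj_cohort`: `counts` (integer matrix with
#'   user ids), `true_groups`, `spec`.
#' @export
simulate_counts <- function(spec, seed = NULL, ensure_eligible = FALSE) {
  stopifnot(inherits(spec, "generative_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_users; P <- length(spec$time_codes)
  rates <- spec_rates(spec)
  grp <- sample.int(length(spec$mixing), n, replace = TRUE,
                    prob = spec$mixing)
  Y <- matrix(0L, n, P)
  for (j in seq_along(spec$groups)) {
    idx <- which(grp == j)
    if (!length(idx)) next
    Y[idx, ] <- draw_zip_block(length(idx), rates[[j]])
    if (ensure_eligible) {
      for (rep in seq_len(1000)) {
        zero <- idx[rowSums(Y[idx, , drop = FALSE]) == 0]
        if (!length(zero)) break
        Y[zero, ] <- draw_zip_block(length(zero), rates[[j]])
      }
      if (length(idx[rowSums(Y[idx, , drop = FALSE]) == 0])) {
        stop(sprintf("could not draw eligible series for group %d", j))
      }
    }
  }
  rownames(Y) <- sprintf("u%05d", seq_len(n))
  colnames(Y) <- paste0("T", seq_len(P))
  structure(list(counts = Y, true_groups = grp, spec = spec),
            class = "traj_cohort")
}

draw_zip_block <- function(n, r) {
  P <- length(r$lambda)
  z <- matrix(stats::runif(n * P), n, P) <
    matrix(r$pi, n, P, byrow = TRUE)
  y <- matrix(stats::rpois(n * P, rep(r$lambda, each = n)), n, P)
  y[z] <- 0L
  storage.mode(y) <- "integer"
  y
}

#' @export
print.traj_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d users x %d periods, %d groups (shares %s)\n",
              nrow(x$counts), ncol(x$counts), length(x$spec$mixing),
              paste(sprintf("%.1f%%", 100 * tabulate(x$true_groups,
                                                     length(x$spec$mixing)) /
                              nrow(x$counts)), collapse = "/")))
  invisible(x)
}

#' Simulate per-user per-period category word counts
#'
#' For each user-period with at least one post, the total word count is
#' the sum over posts of per-post lengths drawn as
#' 1 + Poisson(words_per_post - 1) (so every post has at least one word),
#' and each category's hit count is Binomial(total words, rate) at the
#' group- and period-specific per-word rate. Zero-post periods get zero
#' words and zero hits.
#'
#' @param cohort a `traj_cohort` from [simulate_counts].
#' @param seed integer seed.
#' @return a `feature_matrix` (see [build_feature_matrix]).
#' @export
simulate_features <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "traj_cohort"))
  spec <- cohort$spec
  if (is.null(spec$category_rates)) {
    stop("the generative spec carries no category_rates")
  }
  if (length(spec$category_rates) < max(cohort$true_groups)) {
    stop("category_rates missing for group(s) present in the cohort")
  }
  if (!is.null(seed)) set.seed(seed)
  Y <- cohort$counts
  n <- nrow(Y); P <- ncol(Y)
  cats <- colnames(spec$category_rates[[1]])
  K <- length(cats)
  words <- matrix(0L, n, P, dimnames = dimnames(Y))
  pos <- Y > 0
  # total words = y + Poisson(y * (wpp - 1)): sum of y shifted-Poisson lengths
  words[pos] <- Y[pos] +
    stats::rpois(sum(pos), Y[pos] * (spec$words_per_post - 1))
  hits <- array(0L, dim = c(n, P, K),
                dimnames = list(rownames(Y), colnames(Y), cats))
  for (j in seq_along(spec$category_rates)) {
    rj <- spec$category_rates[[j]]
    for (t in seq_len(P)) {
      idx <- which(cohort$true_groups == j & pos[, t])
      if (!length(idx)) next
      for (k in seq_len(K)) {
        hits[idx, t, k] <- stats::rbinom(length(idx), words[idx, t], rj[t, k])
      }
    }
  }
  feature_matrix(hits, words)
}

#' Simulate a binary marker table with a logistic group model
#'
#' Draws independent binary marker indicators at the given prevalences and
#' assigns a high-risk label from a logistic model with the supplied
#' per-marker log-odds coefficients; the intercept is calibrated by
#' bisection so the marginal high-risk share equals `base_rate`.
#'
#' @param n number of users (at least 100).
#' @param coefficients named numeric vector of per-marker log-odds.
#' @param prevalence named numeric vector of marker prevalences in (0, 1);
#'   recycled from 0.5 when omitted.
#' @param base_rate target marginal probability of the high-risk label.
#' @param seed integer seed.
#' @return list with `markers` (0/1 matrix), `high_risk` (0/1 vector),
#'   `intercept` (calibrated log-odds intercept).
#' @export
simulate_marker_table <- function(n, coefficients, prevalence = NULL,
                                  base_rate = 0.1207, seed = NULL) {
  stopifnot(n >= 100, length(coefficients) >= 1)
  if (base_rate <= 0 || base_rate >= 1) {
    stop("base_rate unattainable: must lie strictly inside (0, 1)")
  }
  if (is.null(names(coefficients))) {
    names(coefficients) <- paste0("m", seq_along(coefficients))
  }
  if (is.null(prevalence)) {
    prevalence <- stats::setNames(rep(0.5, length(coefficients)),
                                  names(coefficients))
  }
  prevalence <- prevalence[names(coefficients)]
  stopifnot(all(prevalence > 0 & prevalence < 1))
  if (!is.null(seed)) set.seed(seed)
  X <- vapply(prevalence, function(p) stats::rbinom(n, 1L, p),
              integer(n))
  dimnames(X) <- list(sprintf("u%05d", seq_len(n)), names(coefficients))
  eta0 <- drop(X %*% coefficients)
  share <- function(c0) mean(stats::plogis(c0 + eta0))
  lo <- -40; hi <- 40
  if (share(lo) > base_rate || share(hi) < base_rate) {
    stop("base_rate unattainable given the coefficients and prevalences")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (share(mid) < base_rate) lo <- mid else hi <- mid
  }
  c0 <- (lo + hi) / 2
  y <- stats::rbinom(n, 1L, stats::plogis(c0 + eta0))
  list(markers = X, high_risk = y, intercept = c0)
}

#' Reference log-odds for the twelve-marker logistic scenario
#'
#' Named log odds ratios of high-risk membership for twelve dichotomized
#' usage markers (positive emotions through death words), used as the
#' default generating coefficients of the marker-recovery simulation.
#'
#' @return named numeric vector of log odds ratios.
#' @export
canonical_marker_log_odds <- function() {
  log(c(posemo = 1.79, anger = 3.23, sad = 3.23, social = 0.56,
        cogproc = 0.06, health = 2.56, achieve = 1.67, motion = 4.17,
        focuspast = 1.82, focuspresent = 0.03, focusfuture = 2.86,
        death = 4.35))
}

#' @rdname canonical_marker_log_odds
#' @export
canonical_marker_prevalence <- function() {
  c(posemo = 0.85, anger = 0.45, sad = 0.50, social = 0.90,
    cogproc = 0.92, health = 0.40, achieve = 0.55, motion = 0.60,
    focuspast = 0.80, focuspresent = 0.93, focusfuture = 0.50,
    death = 0.35)
}

#' Canonical per-group category hit rates
#'
#' Per-word hit probabilities (periods x categories) for the two canonical
#' groups over the toy lexicon's categories. Baseline rates follow typical
#' psycholinguistic word-category norms; both groups share a common
#' period activity profile (rates rise after the pandemic onset and fall
#' back), and the high-volume group carries category- and period-specific
#' rate multipliers so that between-group rate ratios in the later windows
#' match the magnitudes the pipeline is designed to detect (e.g. a
#' personal-pronoun rate ratio of 2.09 in the first peri-pandemic window).
#'
#' @return list of two matrices (high-volume group first).
#' @export
canonical_category_rates <- function() {
  base <- c(
    ppron = 0.100, i = 0.055, we = 0.007, you = 0.017, shehe = 0.010,
    they = 0.007, affect = 0.055, posemo = 0.025, negemo = 0.021,
    anx = 0.003, anger = 0.0045, sad = 0.0045, social = 0.095,
    family = 0.004, friend = 0.003, cogproc = 0.105, insight = 0.022,
    cause = 0.014, percept = 0.025, see = 0.010, hear = 0.007,
    feel = 0.006, bio = 0.020, body = 0.007, health = 0.006,
    ingest = 0.004, drives = 0.070, affiliation = 0.020, achieve = 0.013,
    power = 0.023, relativ = 0.140, motion = 0.020, space = 0.068,
    time = 0.050, focuspast = 0.040, focuspresent = 0.090,
    focusfuture = 0.014, work = 0.025, money = 0.006, death = 0.010)
  period_mult <- c(0.6, 0.7, 1.3, 1.5, 1.4, 1.1, 0.8)
  K <- length(base); P <- 7
  low <- outer(period_mult, base)
  dimnames(low) <- list(paste0("T", 1:P), names(base))
  # high-volume group multipliers (rate ratios vs the low-volume group)
  rr <- matrix(1, P, K, dimnames = dimnames(low))
  late_shift <- c("ppron", "i", "affect", "posemo", "negemo", "anger",
                  "sad", "social", "cogproc", "bio", "health", "drives",
                  "achieve", "relativ", "motion", "space", "time",
                  "focuspast", "focuspresent", "focusfuture", "death")
  rr[1:2, ] <- 1.2
  rr[3, ] <- 1.8
  rr[3, c("ppron", "affect", "relativ", "focuspresent")] <-
    c(2.09, 2.11, 2.02, 2.00)
  rr[4, ] <- 0.9
  rr[5, ] <- 1.1
  rr[5, late_shift] <- 1.5
  rr[5, c("ppron", "i", "affect", "negemo", "relativ", "focuspresent")] <-
    c(1.51, 1.54, 1.60, 1.66, 1.48, 1.53)
  rr[6, ] <- 1.05
  rr[6, late_shift] <- 1.6
  rr[7, ] <- 1.2
  rr[7, late_shift] <- 2.0
  rr[7, c("ppron", "i", "affect", "negemo", "drives", "relativ",
          "space", "time", "focuspresent")] <-
    c(3.61, 3.75, 3.98, 4.30, 3.78, 4.01, 3.88, 4.33, 4.19)
  high <- pmin(low * rr, 1)
  list(high, low)
}
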