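---
title: "Trajectory groups and linguistic markers: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory groups and linguistic markers: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The trajectory model

Per-user posting volume on a support forum is observed over seven
contiguous half-year calendar windows, T1 (2019-03-01–2019-08-31) through
T7 (2022-03-01–2022-08-31). Counts are zero-inflated: most users are
silent in most windows, both because posting is bursty and because many
users joined the forum mid-observation (their earlier windows are
structural zeros by construction of the series).

The package models the cohort as a finite mixture of `G` latent
trajectory groups. Within group `j`, window `t` contributes a
zero-inflated Poisson likelihood whose two linear predictors are raw
polynomials in a numeric time code `x_t`:

* count trend: `log lambda_jt = beta_j' (1, x_t, x_t^2, x_t^3)`
* inflation trend: `logit pi_jt = alpha_j' (1, x_t, x_t^2, x_t^3)`

with per-window independence given group membership (the standard GBTM
conditional-independence assumption). Group weights are estimated as
mixing logits. Marginally a user's likelihood is the weighted sum over
groups of the product over windows.

**Time coding.** The windows are coded symmetrically as `(-3:3)/3`, i.e.
centred on T4 and scaled to about [-1, 1]. Raw (not orthogonal)
polynomials on a bounded, centred covariate keep all four powers well
conditioned, keep coefficients interpretable as intercept/linear/
quadratic/cubic effects, and make the canonical two-group coefficient
set (below) reproduce the qualitative shape it is meant to have: the
high-volume group's expected volume peaks at T5, one year after the
pandemic-onset window, and falls back toward its starting level by T7.
The coding is configurable via `period_grid(time_codes = ...)`.

## Estimation

`fit_zip_trajectory()` maximizes the mixture likelihood by EM:

* **E-step**: posterior group memberships from the current parameters,
  computed with per-user log-sum-exp.
* **M-step**: group weights in closed form; each group's `(beta, alpha)`
  jointly by L-BFGS-B on the weighted ZIP log-likelihood. The weighted
  problem collapses to per-window sufficient statistics (weighted counts
  of zero cells, of positive cells, and weighted sums of positive
  counts), so each objective/gradient evaluation costs O(windows) after
  one O(users x windows) pass; analytic gradients are supplied.

Convergence is declared when the relative change in the observed-data
log-likelihood falls below 1e-8 (at most 500 EM iterations). Ten starts
are used by default: start 1 is a deterministic quantile split of
per-user totals (high-volume users seeded into group 1), the rest are
random responsibilities; the best converged log-likelihood wins.
Coefficient bounds of +-50 on the linear-predictor scale act as a
safeguard against divergence in degenerate weighted subproblems; in
practice estimates sit far inside the box. A group whose mixing weight
falls below 1/n is flagged as collapsed, not silently dropped.

Groups are reported in a canonical order — by expected total volume
`sum_t (1 - pi_jt) lambda_jt`, descending — so "group 1" is always the
high-volume group and label switching cannot confuse downstream stages.

**Uncertainty.** Standard errors come from inverting the numerically
differentiated observed information of the full mixture likelihood at
the optimum (all coefficients plus the `G - 1` mixing logits). Wald
z-statistics and two-sided p-values follow. A singular or indefinite
information matrix yields missing SEs with a warning rather than an
error. The t-versus-z distinction is immaterial at thousands of users;
z is used throughout.

## Model selection

`run_ladder()` fits `G = 2..5` (configurable within 2–8) with full cubic
specifications and collects four statistics: AIC `2k - 2 lnL`, BIC
`k ln N - 2 lnL` (`k` counts all trend coefficients plus `G - 1` mixing
logits; for both, smaller is better), normalized entropy
`1 - [-sum_ij p_ij ln p_ij] / (N ln G)`, and group composition.
Candidates with any group below the 5% composition floor are
inadmissible; among admissible candidates the minimum-BIC model wins,
with ties within 2 BIC units resolved toward fewer groups. Entropy
below 0.8 and APP below 0.7 are recorded as adequacy violations and
reported, but only composition excludes a candidate — they corroborate
rather than drive the choice. Some GBTM software reports AIC/BIC under
a different sign/scale convention; the textbook forms above are used
here, so only comparisons within a ladder are meaningful, not the
absolute magnitudes.

`prune_polynomials()` then refines the selected model's shape: in each
round it refits, finds the highest-order term of every trend whose Wald
p exceeds .05, and removes the single worst offender (largest p), so
each deletion is re-evaluated before the next — batch deletion could
discard a term that becomes significant once a collinear higher-order
term is gone. Count-model linear terms are protected regardless of
significance; inflation-model linear terms are not (the protection rule
is applied exactly as stated for count trends, and only there).
Intercepts are never candidates. The procedure terminates in at most
(total removable orders) rounds because each round removes exactly one
term and never adds any.

`validate_app()` applies the 0.7 adequacy floor to per-group average
posterior probabilities (mean posterior of a group among the users
assigned to it by maximum posterior).

## The synthetic cohort

`canonical_cohort_spec()` is the package's reference scenario: 6163
users, two groups with mixing 12.07%/87.93%, count trends
`(2.62, 0.10, -0.44, -0.22)` (cubic) and `(0.59, -0.14, -0.12)`
(quadratic), inflation trends `(-0.19, -1.85, 1.49, 0.75)` and
`(-0.34, -2.31, 2.63, 1.49)` (both cubic) on the default time codes.
Under this scenario the high-volume group's expected volume rises from
under one post per window pre-pandemic to a peak near nine posts at T5;
the low-volume group stays near or below one post throughout; early
windows are mostly structural zeros in both groups, mirroring a cohort
dominated by users who joined after the crisis began.

Two generation modes exist. Plain draws from the mixture are what the
parameter-recovery checks use: refitting then recovers every generating
coefficient to within sampling error, because the data really come from
the fitted family. `ensure_eligible = TRUE` additionally redraws any
all-zero series within its group, emulating a cohort defined by a
"posted at least once" inclusion rule while keeping the mixing exact.
That truncation is deliberately *not* undone by the estimator (real
analyses of such cohorts don't model the inclusion rule either), so
refits of truncated cohorts show a small upward bias in the low-volume
group's nonzero-probability — visible mainly in its inflation
intercept. Recovery checks therefore use plain draws; pipeline
demonstrations, where a cohort of partly all-zero users would be
artificial, use the truncated mode.

Word-level features are generated per user-window with at least one
post: total words are a sum of per-post lengths drawn as
`1 + Poisson(words_per_post - 1)` (default mean 120 words per post), so
no post has zero length and frequency normalization never divides by
zero for posting users; category hits are Binomial(total words,
group-and-window-specific rate). The canonical rate table uses baseline
per-word rates in the range of typical psycholinguistic norms (e.g.
personal pronouns 0.10, cognitive-process words 0.105, death words
0.01), one shared window-activity profile, and high-group rate
multipliers concentrated in the late windows (e.g. a personal-pronoun
rate ratio of 2.09 in T3 and multipliers of 1.5–2 across the
"late-shift" categories in T5–T7). Categories are drawn independently
of each other, so a parent category's simulated hits are not the sum of
its children's — the simulator emulates the marginal rate structure the
comparison stages consume, not lexical co-occurrence. No real text is
generated; the tokenizer/matcher path is exercised by its own unit
tests on constructed posts instead.

`simulate_marker_table()` generates the marker-recovery scenario
directly at the binary level: independent marker indicators at given
prevalences, a logistic group model with given log-odds, and an
intercept calibrated by bisection so the marginal high-risk share hits
a target (default 12.07%). The default coefficient set
(`canonical_marker_log_odds()`) spans strong risk markers (death odds
ratio 4.35, motion 4.17), moderate ones, and strong protective markers
(present focus 0.03); prevalences are set between 0.35 and 0.93, higher
for near-universal categories.

## Dictionary features

`parse_lexicon()` reads the classic two-section dic dialect: a header of
numeric category ids and names, then word patterns with their category
ids. Patterns are exact words or prefix wildcards (trailing `*`), the
only wildcard the dialect defines. The category hierarchy is not part
of the file format; it is supplied separately
(`default_category_hierarchy()` for the standard names) and validated
acyclic. The bundled `toy_lexicon_synthetic.dic` (~120 patterns, 40
categories) is a synthetic stand-in written for this package — it
mirrors the format and naming conventions of standard psycholinguistic
dictionaries but is not a licensed lexicon, and the pipeline's
arithmetic is lexicon-agnostic.

Tokenization lowercases and splits on runs of non-alphanumeric
characters, keeping apostrophes inside words. Each token increments
every category it matches; the matched set is expanded with hierarchy
ancestors *as a set union* before counting, so a dictionary that
already tags ancestors explicitly (as the classic files do) and one
that tags only leaves produce identical counts, and no token is counted
twice in the same category.

Normalized frequency is hits over total words per user-window. Windows
with no posts are structurally missing, not zero usage: the frequency
slot holds 0 but a parallel mask records missingness, and rate
contrasts exclude those users rather than treating silence as absence
of a word category.

## Group contrasts and the marker cascade

`compare_rates()` fits, per category and window, a Poisson regression
of hit counts on a high-risk indicator with log total words as exposure
offset, restricted to users who posted in that window. With one binary
covariate and an offset the MLE rate ratio equals the ratio of
aggregate rates exactly — a closed form the tests verify — and
reciprocating the group labels inverts it. Normalized frequencies are
never fed to the count model directly (they are not integers); the
offset formulation is the standard rate model that yields the same
estimand. Raw p-values with .05/.01/.001 stars are reported to mirror
common practice in this literature; a Benjamini–Hochberg toggle exists
(`comparison_grid(adjust = "BH")`) but defaults off.

The cascade then proceeds: keep categories significant (p ≤ .05,
inclusive) in at least one late window (default T5–T7); drop any
candidate that is a hierarchy ancestor of another candidate; average
each survivor's normalized frequency over the window — missing windows
contribute zero to the numerator and still count in the denominator —
and dichotomize (exactly zero stays 0, any positive average becomes 1);
screen with lasso logistic regression, penalty chosen at minimum
cross-validated deviance over glmnet's default path (10 stratified,
seeded folds; the 1-SE rule is deliberately not used — the screen's job
is removing redundancy, not maximal sparsity); and fit the surviving
binaries in an unpenalized multivariate logistic model, reporting odds
ratios with log-scale SEs and Wald tests. Interpolated lasso
coefficients below 1e-8 in magnitude count as zero, so exactly
collinear duplicates are reliably dropped. Every input category appears
exactly once in the cascade's audit trail, either kept or removed at a
named stage.

**Separation.** Dichotomized usage of a near-universal category over a
three-window span is nearly the indicator "posted at all in the
window"; when the latent classes differ sharply in posting activity,
such markers can separate the groups perfectly and the unpenalized
logistic MLE does not exist. The package detects this (non-convergence
or runaway coefficients) and raises an error recommending a penalized
fallback rather than silently reporting meaningless odds ratios; the
analysis scripts demonstrate the honest failure path. The
marker-recovery scenario avoids the issue by construction because its
markers are generated independently of posting volume.

## Numerical choices, in one place

* ZIP zero branch via pairwise log-sum-exp; finite for `pi` of 0 or 1
  and rates up to overflow.
* EM tolerance 1e-8 relative, 500 iterations; M-step L-BFGS-B with
  analytic gradients, coefficient box +-50.
* Entropy clipped to [0, 1]; defined as 1 for `G = 1`; `0 log 0 = 0`.
* BIC ties within 2 units break toward fewer groups.
* Posterior ties in assignment break toward the lower group index
  (first maximum).
* Lasso path: glmnet defaults (100 lambdas), `lambda.min`, coefficient
  zero-threshold 1e-8.
* Bisection for the marker-table intercept over [-40, 40], 200 halvings.
* Problem sizes in the shipped checks: the recovery surfaces run at the
  canonical 6163 users; the selection-ladder check runs at 2000 users,
  which keeps every fit in the 2–5 group range well identified while
  completing in minutes; unit tests use a few hundred users.

## Limitations

* The generator draws from the model family the estimator fits;
  passing recovery checks therefore demonstrates correctness of the
  machinery, not robustness to real-data misfit (overdispersion beyond
  ZIP, within-user serial dependence, covariate-driven membership).
  On real cohorts, classification diagnostics should be expected to be
  less flattering than on model-generated data: separation statistics
  computed on draws from the fitted family are upper bounds of sorts.
* Conditional independence across windows given group is assumed, as in
  standard GBTM.
* The marker stage inherits all caveats of post-selection inference;
  no correction is applied, matching common practice.
* Group-membership covariates, other GBTM families (censored normal,
  beta, Bernoulli), and bootstrap likelihood-ratio tests for `G` are out
  of scope.
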