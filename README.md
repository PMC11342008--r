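# ziptraj

Trajectory-based risk stratification for online support-forum cohorts:
group-based trajectory modelling (GBTM) of per-period posting volume with
a zero-inflated Poisson (ZIP) mixture likelihood, followed by
dictionary-based psycholinguistic feature extraction and a
marker-selection cascade that ends in multivariate logistic odds ratios.

## The problem

Users of suicide-support forums differ widely in how their activity — a
proxy for user-level risk — evolves over a crisis such as the COVID-19
pandemic. Given per-user post counts over seven half-year windows
(T1 = 2019-03-01…2019-08-31 through T7 = 2022-03-01…2022-08-31, two
pre-pandemic and five peri-pandemic), the package answers three
questions:

1. **How many latent activity trajectories are there, and what shape do
   they have?** Counts within each window are modelled as a finite
   mixture of ZIP distributions. For user *i* in latent group *j* at
   window *t* with time code *x_t*:

   - count trend: log λ_jt = β_j0 + β_j1 x_t + β_j2 x_t² + β_j3 x_t³
   - structural-zero trend: logit π_jt = α_j0 + α_j1 x_t + α_j2 x_t² + α_j3 x_t³
   - P(Y_it = y) = π_jt 1{y=0} + (1 − π_jt) Pois(y; λ_jt)

   Estimation is maximum likelihood by multi-start EM; the number of
   groups is chosen by a selection ladder (BIC primary, with AIC,
   normalized entropy, a 5% group-composition floor, and per-group
   average posterior probability ≥ 0.7 as adequacy checks), and
   polynomial orders are pruned stepwise (Wald p > .05, count-model
   linear terms always retained).

2. **How does word use differ between the groups?** Category hit counts
   from a dic-style lexicon (prefix wildcards, category hierarchy) are
   compared per window via Poisson rate ratios with a log total-words
   exposure offset, low-risk group as reference.

3. **Which word categories mark the high-risk group?** Candidates that
   are significant in the late window (T5–T7) are pruned of hierarchy
   parents, dichotomized to used/not-used over the window, screened with
   cross-validated lasso logistic regression, and the survivors enter an
   unpenalized multivariate logistic model whose exponentiated
   coefficients are the marker odds ratios.

A synthetic-cohort generator reproduces the statistical structure this
pipeline assumes — two latent groups (12.07% high-volume / 87.93%
low-volume) over 6163 users, with group- and period-dependent category
word rates — so the whole analysis is testable without any data
download. The bundled dictionary (`toy_lexicon_path()`) is a small
synthetic stand-in in the classic dic format; any user-supplied dic file
works.

## Worked example

```r
library(ziptraj)

cohort <- simulate_counts(canonical_cohort_spec(n_users = 2000),
                          seed = 20190301, ensure_eligible = TRUE)
ladder <- run_ladder(cohort$counts, G_range = 2:5, n_starts = 5,
                     seed = 20200301)
ladder$selected_G
#> [1] 2
pruned <- prune_polynomials(cohort$counts, ladder$selected$spec,
                            n_starts = 5, seed = 20200302)
print(pruned$fit)
#> ZIP trajectory model: 2 group(s), 2000 users, loglik -15587.15
#> AIC 31206.30  BIC 31295.91  entropy 0.991
#> composition: 12.30% / 87.70%
#> APP:         0.995 / 0.998
```

The high-volume ("high-risk") group holds 12.3% of users, matching the
generating 12.07% share; entropy near 1 and APPs above 0.99 say the two
trajectories are cleanly separated. Pruning drops the low-volume group's
cubic count term (its generating value is zero) and keeps everything
else, giving count orders 3/2 and inflation orders 3/3.

The numbered scripts under `analysis/` run the full sequence
(simulation → trajectory fit → rate-ratio grid → marker cascade) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_fit_trajectories.R
Rscript analysis/03_compare_language.R
Rscript analysis/04_select_markers.R
```

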