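# shared fixtures built in code

toy_lexicon <- function() parse_lexicon(toy_lexicon_path())

# a tiny dic file written to a tempfile; returns its path
write_mini_dic <- function(lines = c(
  "%",
  "1\taffect",
  "2\tanger",
  "3\tsad",
  "%",
  "hate\t2",
  "angr*\t2",
  "cry*\t3",
  "upset\t1\t2"
)) {
  path <- tempfile(fileext = ".dic")
  writeLines(lines, path)
  path
}

# well-separated two-group cohort for quick estimator checks
separable_cohort <- function(n = 400, seed = 1) {
  spec <- generative_spec(
    n_users = n, mixing = c(0.5, 0.5),
    groups = list(
      list(beta = c(log(8)), alpha = c(-20)),
      list(beta = c(log(0.2)), alpha = c(-20))
    )
  )
  simulate_counts(spec, seed = seed)
}

# single-group spec with the given count coefficients and near-zero
# inflation
one_group_spec <- function(n, beta, alpha = c(-20)) {
  generative_spec(n_users = n, mixing = 1,
                  groups = list(list(beta = beta, alpha = alpha)))
}
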