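test_that("toy lexicon parses with the expected shape", {
  lex <- toy_lexicon()
  expect_s3_class(lex, "category_lexicon")
  expect_equal(length(lex$categories), 40)
  expect_true(all(c("ppron", "anger", "death", "focuspresent") %in%
                    lex$categories))
  expect_gt(lex$n_patterns, 100)
  expect_gt(length(lex$prefixes), 10)
})

test_that("mini dic round-trips and rejects unknown category ids", {
  lex <- parse_lexicon(write_mini_dic())
  expect_equal(lex$categories, c("affect", "anger", "sad"))
  expect_equal(sort(lex$prefixes), c("angr", "cry"))
  # unknown id on a word line errors with its line number
  bad <- write_mini_dic(c("%", "1\taffect", "%", "hate\t99"))
  expect_error(parse_lexicon(bad), "line 4.*unknown category id 99")
})

test_that("duplicate word-category pairs are deduplicated", {
  lex <- parse_lexicon(write_mini_dic(c(
    "%", "1\taffect", "2\tanger", "%",
    "hate\t2", "hate\t2\t1")))
  h <- count_hits("hate", lex)
  expect_equal(unname(h[c("affect", "anger")]), c(1L, 1L))
})

test_that("hierarchy cycles are rejected", {
  h <- data.frame(parent = c("affect", "anger"), child = c("anger", "affect"))
  expect_error(parse_lexicon(write_mini_dic(), hierarchy = h), "cycle")
})

test_that("tokenizer lowercases, splits and keeps in-word apostrophes", {
  expect_equal(tokenize("I hate this!")[[1]], c("i", "hate", "this"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("don't-stop")[[1]], c("don't", "stop"))
  expect_equal(tokenize("'quoted' words")[[1]], c("quoted", "words"))
  expect_equal(tokenize(c("a b", "c"))[[2]], "c")
})

test_that("prefix wildcards match continuations, exact patterns do not", {
  lex <- toy_lexicon()
  for (w in c("angry", "angrier", "angr")) {
    expect_equal(unname(count_hits(w, lex)["anger"]), 1L, label = w)
  }
  expect_equal(unname(count_hits("mads", lex)["anger"]), 0L)  # exact "mad"
  expect_equal(unname(count_hits("mad", lex)["anger"]), 1L)
})

test_that("hits propagate to hierarchy ancestors and allow multi-membership", {
  lex <- toy_lexicon()
  h <- count_hits(c("i", "hate", "this"), lex)
  expect_equal(unname(h["i"]), 1L)
  expect_equal(unname(h["ppron"]), 1L)       # parent of i
  expect_equal(unname(h["anger"]), 1L)
  expect_equal(unname(h["negemo"]), 1L)      # parent of anger
  expect_equal(unname(h["affect"]), 1L)      # grandparent
  expect_equal(unname(h["posemo"]), 0L)
  # "alone" is tagged sad and social: both increment, plus sad's ancestors
  h2 <- count_hits("alone", lex)
  expect_equal(unname(h2[c("sad", "social", "negemo", "affect")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(count_hits(character(0), lex)), 0L)
})

test_that("matcher agrees with a naive brute-force matcher", {
  lex <- toy_lexicon()
  # independent oracle: scan every pattern against every token
  dic <- readLines(toy_lexicon_path())
  seps <- which(trimws(dic) == "%")
  header <- strsplit(trimws(dic[(seps[1] + 1):(seps[2] - 1)]), "\\s+")
  id2name <- setNames(vapply(header, `[`, "", 2),
                      vapply(header, `[`, "", 1))
  entries <- strsplit(trimws(dic[(seps[2] + 1):length(dic)]), "\\s+")
  entries <- entries[lengths(entries) > 1]
  parents <- default_category_hierarchy()
  ancestors_of <- function(cat) {
    out <- character(0); frontier <- cat
    while (length(frontier)) {
      p <- setdiff(parents$parent[parents$child %in% frontier], out)
      out <- c(out, p); frontier <- p
    }
    out
  }
  brute <- function(tokens) {
    counts <- setNames(integer(length(lex$categories)), lex$categories)
    for (tok in tokens) {
      cats <- character(0)
      for (e in entries) {
        pat <- e[1]
        hit <- if (endsWith(pat, "*"))
          startsWith(tok, sub("\\*$", "", pat)) else tok == pat
        if (hit) cats <- c(cats, id2name[e[-1]])
      }
      cats <- unique(cats)
      cats <- unique(c(cats, unlist(lapply(cats, ancestors_of))))
      counts[cats] <- counts[cats] + 1L
    }
    counts
  }
  set.seed(77)
  vocab <- c("i", "me", "hate", "angry", "crying", "happy", "walk",
             "walked", "zzz", "school", "die", "died", "alone", "was",
             "will", "pay", "payment", "x")
  for (rep in 1:5) {
    toks <- sample(vocab, 30, replace = TRUE)
    expect_equal(count_hits(toks, lex), brute(toks))
  }
})

test_that("feature matrix aggregates posts by user and period", {
  lex <- toy_lexicon()
  g <- default_period_grid()
  recs <- data.frame(
    user_id = c("u1", "u1", "u2"),
    timestamp = c("2020-05-01", "2020-10-01", "2020-05-02"),
    text = c("i hate this i hate everything",
             "we were happy",
             "sleep sleep sleep")
  )
  fm <- build_feature_matrix(recs, g, lex)
  expect_equal(unname(fm$total_words["u1", "T3"]), 6L)
  expect_equal(unname(fm$total_words["u1", "T4"]), 3L)
  expect_equal(unname(fm$hits["u1", "T3", "anger"]), 2L)
  expect_equal(unname(fm$hits["u1", "T3", "i"]), 2L)
  expect_equal(unname(fm$hits["u1", "T4", "posemo"]), 1L)
  expect_equal(unname(fm$hits["u1", "T4", "focuspast"]), 1L)  # "were"
  expect_equal(unname(fm$hits["u2", "T3", "body"]), 3L)       # sleep*
  # silent periods are all-zero with zero words
  expect_true(all(fm$hits["u2", "T1", ] == 0))
  expect_equal(unname(fm$total_words["u2", "T1"]), 0L)
})

test_that("normalized frequencies divide hits by words and mask silence", {
  hits <- array(0L, c(2, 2, 1), dimnames = list(c("a", "b"), c("T1", "T2"), "cat"))
  hits[1, 1, 1] <- 5L
  tw <- matrix(c(100L, 0L, 40L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("T1", "T2")))
  fm <- feature_matrix(hits, tw)
  nf <- normalized_frequency(fm)
  expect_equal(nf$frequency[1, 1, 1], 0.05)
  expect_equal(nf$frequency[1, 2, 1], 0)      # posted, zero hits
  expect_equal(nf$frequency[2, 1, 1], 0)      # silent: value 0 ...
  expect_true(nf$missing[2, 1])               # ... but masked missing
  expect_false(nf$missing[1, 2])
})

test_that("simulated frequencies equal hits over words elementwise", {
  spec <- canonical_cohort_spec(n_users = 120)
  cohort <- simulate_counts(spec, seed = 55, ensure_eligible = TRUE)
  fm <- simulate_features(cohort, seed = 56)
  nf <- normalized_frequency(fm)
  k <- sample(seq_along(fm$categories), 3)
  for (kk in k) {
    manual <- fm$hits[, , kk] / pmax(fm$total_words, 1)
    expect_equal(nf$frequency[, , kk], manual, ignore_attr = TRUE)
  }
  expect_true(all(nf$frequency >= 0 & nf$frequency <= 1))
})
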