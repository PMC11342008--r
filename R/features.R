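#' Tokenize post text
#'
#' Lowercases and splits on runs of non-alphanumeric characters, keeping
#' apostrophes inside words ("don't" is one token). Empty text yields an
#' empty token list.
#'
#' @param text character vector.
#' @return list of character vectors, one per input element.
#' @export
tokenize <- function(text) {
  lapply(text, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    toks <- strsplit(tolower(s), "[^[:alnum:]']+")[[1]]
    toks <- gsub("^'+|'+$", "", toks)
    toks[nzchar(toks)]
  })
}

# matched category indices for one token (exact + prefix), before
# hierarchy expansion
match_token <- function(token, lexicon) {
  cats <- lexicon$exact[[token]]
  if (is.null(cats)) cats <- integer(0)
  if (length(lexicon$prefixes)) {
    hit <- startsWith(token, lexicon$prefixes)
    if (any(hit)) cats <- c(cats, unlist(lexicon$prefix_cats[hit]))
  }
  unique(cats)
}

#' Count category hits in a token list
#'
#' Each token increments every category whose pattern set matches it
#' (exact or prefix); a token may hit several categories at once. A
#' token's matched category set is expanded with all hierarchy ancestors
#' before counting, so parent categories accumulate their children's hits
#' (and a word tagged with both a child and its parent counts once for
#' each).
#'
#' @param tokens character vector of tokens.
#' @param lexicon a [parse_lexicon] result.
#' @return named integer vector over the lexicon's categories.
#' @export
count_hits <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  K <- length(lexicon$categories)
  out <- integer(K)
  if (length(tokens)) {
    ut <- unique(tokens)
    per <- lapply(ut, function(w) {
      cats <- match_token(w, lexicon)
      if (!length(cats)) return(integer(0))
      unique(c(cats, unlist(lexicon$ancestors[cats])))
    })
    freq <- tabulate(match(tokens, ut), length(ut))
    for (i in seq_along(ut)) {
      if (length(per[[i]])) out[per[[i]]] <- out[per[[i]]] + freq[i]
    }
  }
  stats::setNames(out, lexicon$categories)
}

#' Construct a user x period x category feature matrix
#'
#' @param hits integer array (users x periods x categories) of category
#'   hit counts.
#' @param total_words integer matrix (users x periods) of total word
#'   counts; zero wherever the user posted nothing.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(hits, total_words) {
  stopifnot(length(dim(hits)) == 3,
            all(dim(hits)[1:2] == dim(total_words)))
  if (any(hits < 0) || any(total_words < 0)) {
    stop("hits and total_words must be nonnegative")
  }
  structure(list(
    hits = hits, total_words = total_words,
    users = dimnames(hits)[[1]], periods = dimnames(hits)[[2]],
    categories = dimnames(hits)[[3]]
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d users x %d periods x %d categories\n",
              dim(x$hits)[1], dim(x$hits)[2], dim(x$hits)[3]))
  invisible(x)
}

#' Build a feature matrix from raw post records
#'
#' Per user-period, sums category hits and token counts over all posts in
#' the window.
#'
#' @param records data frame with `user_id`, `timestamp`, `text`.
#' @param grid a [period_grid].
#' @param lexicon a [parse_lexicon] result.
#' @return a [feature_matrix].
#' @export
build_feature_matrix <- function(records, grid, lexicon) {
  stopifnot(is.data.frame(records), inherits(grid, "period_grid"),
            inherits(lexicon, "category_lexicon"))
  users <- sort(unique(as.character(records$user_id)))
  P <- length(grid$labels); K <- length(lexicon$categories)
  hits <- array(0L, dim = c(length(users), P, K),
                dimnames = list(users, grid$labels, lexicon$categories))
  words <- matrix(0L, length(users), P,
                  dimnames = list(users, grid$labels))
  if (nrow(records)) {
    idx <- assign_period(records$timestamp, grid)
    toks <- tokenize(records$text)
    ui <- match(as.character(records$user_id), users)
    for (r in seq_len(nrow(records))) {
      h <- count_hits(toks[[r]], lexicon)
      hits[ui[r], idx[r], ] <- hits[ui[r], idx[r], ] + h
      words[ui[r], idx[r]] <- words[ui[r], idx[r]] + length(toks[[r]])
    }
  }
  feature_matrix(hits, words)
}

#' Normalized word frequencies with a missingness mask
#'
#' Frequency is hits / total words per user-period-category. Periods in
#' which a user posted nothing are structurally missing, not zero usage:
#' the frequency slot is 0 there and the parallel `missing` mask is TRUE,
#' so downstream stages can distinguish "silent user" from "posted but
#' never used the category".
#'
#' @param matrix a [feature_matrix].
#' @return list with `frequency` (array) and `missing` (users x periods
#'   logical matrix).
#' @export
normalized_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  tw <- matrix$total_words
  freq <- matrix$hits
  denom <- array(rep(pmax(tw, 1L), times = dim(freq)[3]), dim = dim(freq))
  freq <- freq / denom
  freq[array(rep(tw == 0L, times = dim(freq)[3]), dim = dim(freq))] <- 0
  list(frequency = freq, missing = tw == 0L)
}

#' Rebuild a feature matrix from its long-format export
#'
#' Inverse of [feature_matrix_long]: accepts a data frame (or CSV path)
#' with columns `user_id`, `period`, `category`, `hits`, `total_words`.
#'
#' @param long data frame or CSV file path.
#' @param periods period labels in display order.
#' @return a [feature_matrix].
#' @export
feature_matrix_from_long <- function(long, periods = paste0("T", 1:7)) {
  if (is.character(long)) long <- utils::read.csv(long)
  stopifnot(all(c("user_id", "period", "category", "hits",
                  "total_words") %in% names(long)))
  users <- sort(unique(as.character(long$user_id)))
  cats <- sort(unique(as.character(long$category)))
  hits <- array(0L, c(length(users), length(periods), length(cats)),
                dimnames = list(users, periods, cats))
  words <- matrix(0L, length(users), length(periods),
                  dimnames = list(users, periods))
  ui <- match(as.character(long$user_id), users)
  ti <- match(as.character(long$period), periods)
  if (anyNA(ti)) stop("period label(s) outside the supplied grid")
  hits[cbind(ui, ti, match(as.character(long$category), cats))] <-
    as.integer(long$hits)
  words[cbind(ui, ti)] <- as.integer(long$total_words)
  feature_matrix(hits, words)
}

#' Export a feature matrix as a long-format data frame
#'
#' @param matrix a [feature_matrix].
#' @return data frame with columns `user_id`, `period`, `category`,
#'   `hits`, `total_words`.
#' @export
feature_matrix_long <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  d <- dim(matrix$hits)
  grid <- expand.grid(user = seq_len(d[1]), period = seq_len(d[2]),
                      category = seq_len(d[3]))
  data.frame(
    user_id = matrix$users[grid$user],
    period = matrix$periods[grid$period],
    category = matrix$categories[grid$category],
    hits = as.vector(matrix$hits),
    total_words = as.vector(matrix$total_words[cbind(grid$user, grid$period)])
  )
}
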