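#' Parse a category lexicon in the classic dic dialect
#'
#' The dic dialect has two sections delimited by lines containing only
#' `%`: a header mapping numeric category ids to names, then one line per
#' word pattern followed by the ids of the categories it belongs to.
#' Patterns are lowercase words, either exact or prefix wildcards (a
#' trailing `*` matches any continuation). Duplicate word-category pairs
#' are deduplicated.
#'
#' Category hierarchy (e.g. anger within negative emotions within
#' affective processes) is not part of the dic format; it is supplied
#' separately and defaults to the conventional psycholinguistic category
#' tree for the standard category names ([default_category_hierarchy]).
#'
#' @param path path to a dic file.
#' @param hierarchy data frame with columns `parent`, `child`; rows whose
#'   categories are absent from the file are ignored.
#' @return object of class `category_lexicon`.
#' @export
parse_lexicon <- function(path, hierarchy = default_category_hierarchy()) {
  lines <- readLines(path, warn = FALSE)
  seps <- which(trimws(lines) == "%")
  if (length(seps) < 2) stop("not a dic file: expected two % delimiter lines")
  header <- lines[(seps[1] + 1):(seps[2] - 1)]
  header <- header[nzchar(trimws(header))]
  hp <- strsplit(trimws(header), "\\s+")
  ids <- vapply(hp, function(x) as.integer(x[1]), 0L)
  nms <- vapply(hp, function(x) x[2], "")
  if (anyNA(ids) || any(duplicated(ids)) || any(!nzchar(nms))) {
    stop("malformed category header in dic file")
  }
  body <- lines[(seps[2] + 1):length(lines)]
  keep <- nzchar(trimws(body))
  body_lines <- which(keep) + seps[2]
  body <- body[keep]
  id2idx <- match(seq_len(max(ids)), ids)
  entries <- new.env(parent = emptyenv())
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    w <- tolower(parts[1])
    cids <- suppressWarnings(as.integer(parts[-1]))
    if (anyNA(cids)) {
      stop(sprintf("line %d: malformed category ids for pattern '%s'",
                   body_lines[i], w))
    }
    unknown <- cids[!(cids %in% ids)]
    if (length(unknown)) {
      stop(sprintf("line %d: pattern '%s' references unknown category id %d",
                   body_lines[i], w, unknown[1]))
    }
    prev <- if (!is.null(entries[[w]])) entries[[w]] else integer(0)
    entries[[w]] <- sort(unique(c(prev, match(cids, ids))))
  }
  words <- ls(entries)
  if (!length(words)) stop("dic file defines no word patterns")
  is_prefix <- endsWith(words, "*")
  hierarchy <- hierarchy[hierarchy$parent %in% nms &
                           hierarchy$child %in% nms, , drop = FALSE]
  if (has_cycle(hierarchy)) stop("category hierarchy contains a cycle")
  structure(list(
    categories = nms,
    exact = mirror_env(entries, words[!is_prefix]),
    prefixes = sub("\\*$", "", words[is_prefix]),
    prefix_cats = lapply(words[is_prefix], function(w) entries[[w]]),
    hierarchy = hierarchy,
    ancestors = ancestor_closure(nms, hierarchy),
    n_patterns = length(words)
  ), class = "category_lexicon")
}

mirror_env <- function(src, keys) {
  e <- new.env(parent = emptyenv())
  for (k in keys) e[[k]] <- src[[k]]
  e
}

has_cycle <- function(h) {
  if (nrow(h) == 0) return(FALSE)
  nodes <- unique(c(h$parent, h$child))
  indeg <- stats::setNames(tabulate(match(h$child, nodes), length(nodes)),
                           nodes)
  queue <- nodes[indeg == 0]
  seen <- 0
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1
    ch <- h$child[h$parent == v]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1
      if (indeg[c] == 0) queue <- c(queue, c)
    }
  }
  seen < length(nodes)
}

# per-category vector of all ancestor indices (transitive)
ancestor_closure <- function(categories, hierarchy) {
  parent_of <- split(match(hierarchy$parent, categories),
                     factor(hierarchy$child, levels = categories))
  lapply(seq_along(categories), function(i) {
    out <- integer(0); frontier <- i
    while (length(frontier)) {
      ps <- unique(unlist(parent_of[frontier]))
      ps <- setdiff(ps[!is.na(ps)], out)
      out <- c(out, ps)
      frontier <- ps
    }
    sort(out)
  })
}

#' Conventional psycholinguistic category hierarchy
#'
#' Parent-child links for the standard category names: personal pronouns
#' over the individual pronoun classes, affective processes over positive
#' and negative emotions (the latter over anxiety, anger, sadness),
#' social, cognitive, perceptual and biological processes over their
#' subcategories, drives over its motives, and relativity over motion,
#' space and time.
#'
#' @return data frame with columns `parent`, `child`.
#' @export
default_category_hierarchy <- function() {
  links <- list(
    ppron = c("i", "we", "you", "shehe", "they"),
    affect = c("posemo", "negemo"),
    negemo = c("anx", "anger", "sad"),
    social = c("family", "friend"),
    cogproc = c("insight", "cause"),
    percept = c("see", "hear", "feel"),
    bio = c("body", "health", "ingest"),
    drives = c("affiliation", "achieve", "power"),
    relativ = c("motion", "space", "time")
  )
  data.frame(
    parent = rep(names(links), lengths(links)),
    child = unlist(links, use.names = FALSE)
  )
}

#' Path to the bundled synthetic toy lexicon
#'
#' A small dictionary (~120 word patterns over 40 categories) written for
#' this package. It mirrors the *format* and category naming conventions
#' of standard psycholinguistic dictionaries but is a synthetic stand-in:
#' its word lists are illustrative, not a licensed lexicon.
#'
#' @return file path of the dic file.
#' @export
toy_lexicon_path <- function() {
  system.file("extdata", "toy_lexicon_synthetic.dic", package = "ziptraj",
              mustWork = TRUE)
}

#' @export
print.category_lexicon <- function(x, ...) {
  cat(sprintf("category lexicon: %d categories, %d patterns (%d prefix wildcards), %d hierarchy links\n",
              length(x$categories), x$n_patterns, length(x$prefixes),
              nrow(x$hierarchy)))
  invisible(x)
}
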