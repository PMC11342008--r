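#' Half-year observation windows for a posting cohort
#'
#' A period grid is an ordered set of contiguous, date-inclusive calendar
#' windows together with the numeric time codes used as the covariate in
#' polynomial trajectory trends. The default grid covers seven half-year
#' windows, two pre-pandemic and five peri-pandemic: T1 starts 2019-03-01
#' and T7 ends 2022-08-31.
#'
#' @param starts,ends `Date` vectors of inclusive window bounds.
#' @param labels character labels, one per window.
#' @param time_codes numeric covariate value per window, strictly
#'   increasing. The default centres the seven windows symmetrically and
#'   scales them to approximately \[-1, 1\] (`(-3:3)/3`), which keeps raw
#'   polynomial terms well conditioned during optimization.
#' @return An object of class `period_grid`.
#' @export
period_grid <- function(starts, ends, labels = paste0("T", seq_along(starts)),
                        time_codes = NULL) {
  starts <- as.Date(starts)
  ends <- as.Date(ends)
  n <- length(starts)
  stopifnot(length(ends) == n, length(labels) == n, n >= 1)
  if (any(ends < starts)) stop("each window must end on or after its start")
  if (n > 1 && any(starts[-1] != ends[-n] + 1L)) {
    stop("windows must be contiguous and non-overlapping")
  }
  if (is.null(time_codes)) {
    k <- (n - 1) / 2
    time_codes <- (seq_len(n) - 1 - k) / max(k, 1)
  }
  if (length(time_codes) != n || any(diff(time_codes) <= 0)) {
    stop("time_codes must be strictly increasing, one per window")
  }
  structure(
    list(labels = as.character(labels), starts = starts, ends = ends,
         time_codes = as.numeric(time_codes)),
    class = "period_grid"
  )
}

#' @rdname period_grid
#' @export
default_period_grid <- function(time_codes = NULL) {
  period_grid(
    starts = as.Date(c("2019-03-01", "2019-09-01", "2020-03-01",
                       "2020-09-01", "2021-03-01", "2021-09-01",
                       "2022-03-01")),
    ends = as.Date(c("2019-08-31", "2020-02-29", "2020-08-31",
                     "2021-02-28", "2021-08-31", "2022-02-28",
                     "2022-08-31")),
    labels = paste0("T", 1:7),
    time_codes = time_codes
  )
}

#' @export
print.period_grid <- function(x, ...) {
  cat(sprintf("period grid: %d windows, %s .. %s\n", length(x$labels),
              format(x$starts[1]), format(x$ends[length(x$ends)])))
  print(data.frame(label = x$labels, start = x$starts, end = x$ends,
                   time_code = round(x$time_codes, 4)), row.names = FALSE)
  invisible(x)
}

#' Map timestamps to observation windows
#'
#' Timestamps are compared at date granularity in UTC; a boundary date
#' belongs to the window whose inclusive range contains it.
#'
#' @param timestamps date-times (`Date`, `POSIXt`, or parseable strings).
#' @param grid a [period_grid].
#' @return Integer vector of 1-based window indices.
#' @export
assign_period <- function(timestamps, grid) {
  stopifnot(inherits(grid, "period_grid"))
  d <- as_utc_date(timestamps)
  idx <- findInterval(as.integer(d), as.integer(grid$starts))
  bad <- idx == 0L | d > grid$ends[pmax(idx, 1L)]
  if (any(bad)) {
    stop(sprintf("timestamp(s) outside the period grid range %s..%s: %s",
                 format(grid$starts[1]), format(grid$ends[length(grid$ends)]),
                 paste(format(d[bad])[seq_len(min(5, sum(bad)))],
                       collapse = ", ")))
  }
  idx
}

as_utc_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXt")) return(as.Date(x, tz = "UTC"))
  if (is.character(x)) {
    # accept ISO-8601 date-times and plain dates
    d <- as.Date(substr(x, 1, 10), format = "%Y-%m-%d")
    if (anyNA(d)) stop("unparseable timestamp(s): ",
                       paste(utils::head(x[is.na(d)], 5), collapse = ", "))
    return(d)
  }
  stop("unsupported timestamp type: ", paste(class(x), collapse = "/"))
}

#' Aggregate post records into per-user per-period count series
#'
#' Every period in which a user made no post is recorded as 0, including
#' all periods before a late joiner's first post. Users whose series is
#' zero everywhere are dropped (the cohort eligibility rule: every included
#' user posted at least once across the whole observation range).
#'
#' @param records a data frame with columns `user_id` and `timestamp`
#'   (a `text` column, if present, is ignored here).
#' @param grid a [period_grid].
#' @return Integer matrix (users x periods) with user ids as row names and
#'   period labels as column names; the grid is attached as attribute
#'   `"grid"`.
#' @export
build_user_series <- function(records, grid) {
  stopifnot(is.data.frame(records), inherits(grid, "period_grid"))
  P <- length(grid$labels)
  if (nrow(records) == 0) {
    warning("empty record collection; returning an empty count table")
    m <- matrix(integer(0), nrow = 0, ncol = P,
                dimnames = list(NULL, grid$labels))
    attr(m, "grid") <- grid
    return(m)
  }
  idx <- assign_period(records$timestamp, grid)
  users <- sort(unique(as.character(records$user_id)))
  m <- matrix(0L, nrow = length(users), ncol = P,
              dimnames = list(users, grid$labels))
  tab <- table(factor(as.character(records$user_id), levels = users),
               factor(idx, levels = seq_len(P)))
  m[] <- as.integer(tab)
  keep <- rowSums(m) >= 1L
  m <- m[keep, , drop = FALSE]
  attr(m, "grid") <- grid
  m
}

#' Read or write a per-user count table as CSV
#'
#' The CSV layout is one row per user: a `user_id` column followed by one
#' integer column per period label.
#'
#' @param counts integer matrix as returned by [build_user_series].
#' @param path file path.
#' @param grid optional [period_grid] to attach when reading.
#' @export
write_counts_csv <- function(counts, path) {
  df <- data.frame(user_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path, grid = default_period_grid()) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("user_id" %in% names(df))
  m <- as.matrix(df[setdiff(names(df), "user_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$user_id)
  if (!is.null(grid)) {
    stopifnot(identical(colnames(m), grid$labels))
    attr(m, "grid") <- grid
  }
  m
}

#' Read post records from a JSONL file
#'
#' One JSON object per line with fields `user_id`, `timestamp`
#' (ISO-8601) and optionally `text`.
#'
#' @param path file path.
#' @return data frame with columns `user_id`, `timestamp`, `text`.
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    user_id = vapply(recs, function(r) as.character(r$user_id), ""),
    timestamp = vapply(recs, function(r) as.character(r$timestamp), ""),
    text = vapply(recs, function(r) {
      if (is.null(r$text)) "" else as.character(r$text)
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Percentage helper used for screening arithmetic
#'
#' Expresses a count out of a total as a percentage rounded to a fixed
#' number of decimal places (e.g. 18 off-topic posts out of 3372 sampled
#' posts is 0.53%).
#'
#' @param x,n count and total.
#' @param digits decimal places to round to.
#' @export
pct <- function(x, n, digits = 2) round(100 * x / n, digits)
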