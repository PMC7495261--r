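#' Study window in Japan Standard Time
#'
#' The analysis window runs from midnight JST on the day of the
#' Tohoku earthquake for exactly one year: the half-open interval
#' \[2011-03-11 00:00:00, 2012-03-11 00:00:00) JST, i.e. every second up to
#' and including 2012-03-10 23:59:59. All bucketing in the package is
#' performed in JST; timestamps carrying other offsets are converted on read.
#'
#' @param start Window start (a POSIXct, interpreted in JST).
#' @param days Window length in days; the default `NULL` means one calendar
#'   year (so the leap day of February 2012 is included and the window ends
#'   2012-03-10 23:59:59 as stated).
#' @return An object of class `study_window` with elements `start` and `end`
#'   (both POSIXct in `Asia/Tokyo`); `end` is the last included second.
#' @export
#' @examples
#' w <- study_window()
#' format(w$start); format(w$end)
study_window <- function(start = as.POSIXct("2011-03-11 00:00:00", tz = "Asia/Tokyo"),
                         days = NULL) {
  start <- lubridate::with_tz(start, RADSENT_TZ)
  start <- trunc_seconds(start)
  end <- if (is.null(days)) {
    lubridate::add_with_rollback(start, lubridate::years(1)) - 1
  } else {
    start + days * 86400 - 1
  }
  stopifnot(start < end)
  structure(list(start = start, end = end), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("<study_window> ", format(x$start, "%Y-%m-%d %H:%M:%S %Z"), " -- ",
      format(x$end, "%Y-%m-%d %H:%M:%S %Z"), "\n", sep = "")
  invisible(x)
}

# Drop sub-second precision; window membership is decided at 1 s granularity.
trunc_seconds <- function(x) {
  as.POSIXct(floor(as.numeric(x)), origin = "1970-01-01", tz = RADSENT_TZ)
}

#' Test window membership
#'
#' @param timestamp POSIXct vector.
#' @param window A [study_window()].
#' @return Logical vector; `TRUE` for timestamps inside the window.
#' @export
in_window <- function(timestamp, window = study_window()) {
  t <- trunc_seconds(timestamp)
  t >= window$start & t <= window$end
}

parse_timestamps <- function(x) {
  if (is.numeric(x)) {
    # epoch seconds, assumed UTC, converted to JST
    return(as.POSIXct(x, origin = "1970-01-01", tz = RADSENT_TZ))
  }
  x <- as.character(x)
  numeric_like <- !is.na(x) & stringi::stri_detect_regex(x, "^\\d+(\\.\\d+)?$")
  out <- rep(as.POSIXct(NA, tz = RADSENT_TZ), length(x))
  if (any(numeric_like)) {
    out[numeric_like] <- as.POSIXct(as.numeric(x[numeric_like]),
                                    origin = "1970-01-01", tz = RADSENT_TZ)
  }
  iso <- !numeric_like & !is.na(x)
  if (any(iso)) {
    parsed <- lubridate::ymd_hms(x[iso], tz = "UTC", quiet = TRUE)
    # ymd_hms honours an explicit offset and returns UTC; strings without an
    # offset are taken as already being JST wall-clock time.
    has_offset <- stringi::stri_detect_regex(x[iso], "(Z|[+-]\\d{2}:?\\d{2})$")
    naive <- lubridate::ymd_hms(x[iso], tz = RADSENT_TZ, quiet = TRUE)
    res <- lubridate::with_tz(parsed, RADSENT_TZ)
    res[!has_offset] <- naive[!has_offset]
    out[iso] <- res
  }
  out
}

#' Read a line-delimited tweet corpus
#'
#' Reads a JSON-lines corpus (one object per line with keys `tweet_id`,
#' `timestamp`, `user_id`, `text`) or a 4-column delimited text file with
#' those names in a header. Timestamps may be ISO-8601 (an explicit offset is
#' honoured; otherwise JST wall-clock is assumed) or epoch seconds (UTC).
#' Records outside `window` are dropped and counted, malformed lines and
#' unparseable timestamps are skipped with a warning, and for duplicated
#' `tweet_id`s the first occurrence is kept.
#'
#' @param path Path to the corpus file. Missing file is an error.
#' @param window A [study_window()]; only tweets inside it are returned.
#' @param format `"jsonl"`, `"tsv"`/`"csv"`, or `"auto"` (sniff first line).
#' @return A tibble with columns `tweet_id`, `timestamp` (POSIXct, JST),
#'   `user_id`, `text`, sorted by timestamp, with attribute `corpus_log`
#'   (counts of bad lines, out-of-window records and duplicate ids).
#' @export
read_corpus <- function(path, window = study_window(), format = c("auto", "jsonl", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    df <- tibble::tibble(tweet_id = character(0),
                         timestamp = as.POSIXct(character(0), tz = RADSENT_TZ),
                         user_id = character(0), text = character(0))
    attr(df, "corpus_log") <- list(n_bad_lines = 0L, n_outside_window = 0L,
                                   n_duplicates = 0L, n_kept = 0L)
    return(df)
  }
  if (format == "auto") {
    format <- if (length(lines) && startsWith(trimws(lines[[1]]), "{")) "jsonl" else "tsv"
  }

  n_bad <- 0L
  if (format == "jsonl") {
    recs <- lapply(lines, function(l) {
      tryCatch({
        r <- jsonlite::fromJSON(l)
        if (!all(c("tweet_id", "timestamp", "user_id", "text") %in% names(r))) NULL else r
      }, error = function(e) NULL)
    })
    n_bad <- sum(vapply(recs, is.null, logical(1)))
    recs <- recs[!vapply(recs, is.null, logical(1))]
    df <- tibble::tibble(
      tweet_id = vapply(recs, function(r) as.character(r$tweet_id), character(1)),
      timestamp_raw = vapply(recs, function(r) as.character(r$timestamp), character(1)),
      user_id = vapply(recs, function(r) as.character(r$user_id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1))
    )
  } else {
    delim <- if (format == "csv") "," else "\t"
    df <- readr::read_delim(I(lines), delim = delim, col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
    miss <- setdiff(c("tweet_id", "timestamp", "user_id", "text"), names(df))
    if (length(miss)) stop("corpus is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
    df <- tibble::tibble(tweet_id = df$tweet_id, timestamp_raw = df$timestamp,
                         user_id = df$user_id, text = df$text)
  }

  df$timestamp <- parse_timestamps(df$timestamp_raw)
  bad_ts <- is.na(df$timestamp)
  n_bad <- n_bad + sum(bad_ts)
  df <- df[!bad_ts, ]

  outside <- !in_window(df$timestamp, window)
  n_outside <- sum(outside)
  df <- df[!outside, ]

  dup <- duplicated(df$tweet_id)
  n_dup <- sum(dup)
  df <- df[!dup, ]

  df <- df[order(df$timestamp, df$tweet_id), c("tweet_id", "timestamp", "user_id", "text")]
  df$text[is.na(df$text)] <- ""
  if (n_bad > 0) warning(n_bad, " corpus line(s) skipped (unparseable)", call. = FALSE)
  if (n_dup > 0) warning(n_dup, " duplicate tweet id(s) dropped (first kept)", call. = FALSE)
  attr(df, "corpus_log") <- list(n_bad_lines = n_bad, n_outside_window = n_outside,
                                 n_duplicates = n_dup, n_kept = nrow(df))
  df
}

#' Write a tweet corpus as JSON lines
#'
#' Timestamps are serialised as ISO-8601 with the `+09:00` offset so that a
#' write/read cycle reproduces the corpus exactly.
#'
#' @param tweets Tibble with `tweet_id`, `timestamp`, `user_id`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(tweets, path) {
  stopifnot(all(c("tweet_id", "timestamp", "user_id", "text") %in% names(tweets)))
  ts <- format(lubridate::with_tz(tweets$timestamp, RADSENT_TZ), "%Y-%m-%dT%H:%M:%S+09:00")
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    jsonlite::toJSON(list(tweet_id = tweets$tweet_id[i], timestamp = ts[i],
                          user_id = tweets$user_id[i], text = tweets$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a table of results as CSV
#'
#' All tabular outputs of the pipeline go through this function: UTF-8 CSV
#' with a header row and RFC-4180 quoting, round-trippable via
#' [readr::read_csv()]. List columns (e.g. prefecture sets) are flattened to
#' `;`-separated strings.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  for (j in seq_along(rows)) {
    if (is.list(rows[[j]])) {
      rows[[j]] <- vapply(rows[[j]], function(x) paste(x, collapse = ";"), character(1))
    }
  }
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
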