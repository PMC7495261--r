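#' The 47 prefectures plus Other
#'
#' Canonical ordering of Japan's 47 prefectures (north to south) plus the
#' `Other` bucket that holds foreign place names (e.g. Chernobyl, Three Mile
#' Island) and identifiers too generic to resolve (e.g. "1-chome",
#' "1-banchi" address words).
#'
#' @return Character vector of length 48.
#' @export
prefecture_levels <- function() {
  c("Hokkaido", "Aomori", "Iwate", "Miyagi", "Akita", "Yamagata", "Fukushima",
    "Ibaraki", "Tochigi", "Gunma", "Saitama", "Chiba", "Tokyo", "Kanagawa",
    "Niigata", "Toyama", "Ishikawa", "Fukui", "Yamanashi", "Nagano", "Gifu",
    "Shizuoka", "Aichi", "Mie", "Shiga", "Kyoto", "Osaka", "Hyogo", "Nara",
    "Wakayama", "Tottori", "Shimane", "Okayama", "Hiroshima", "Yamaguchi",
    "Tokushima", "Kagawa", "Ehime", "Kochi", "Fukuoka", "Saga", "Nagasaki",
    "Kumamoto", "Oita", "Miyazaki", "Kagoshima", "Okinawa", "Other")
}

#' Load the offline gazetteer
#'
#' A two-column TSV (`word`, `prefecture`) mapping region words to
#' prefectures; rows whose prefecture is `Other` form the set of foreign or
#' unresolvable names. The packaged
#' `radsent_extdata("gazetteer_fixture.tsv")` covers all 47 prefecture
#' names, major cities, and the historically salient foreign sites; it is a
#' small offline stand-in for a full geocoding service.
#'
#' @param path TSV path.
#' @return An object of class `radsent_gazetteer`: list with `place_names`
#'   (named character: word -> prefecture), `other_names` (character), and
#'   `words` (all region words).
#' @export
load_gazetteer <- function(path = radsent_extdata("gazetteer_fixture.tsv")) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  stopifnot(all(c("word", "prefecture") %in% names(df)))
  bad <- !df$prefecture %in% prefecture_levels()
  if (any(bad)) stop("unknown prefecture in gazetteer: ",
                     paste(unique(df$prefecture[bad]), collapse = ", "), call. = FALSE)
  other <- df$word[df$prefecture == "Other"]
  conc <- df[df$prefecture != "Other", ]
  structure(list(place_names = setNames(conc$prefecture, conc$word),
                 other_names = other,
                 words = df$word),
            class = "radsent_gazetteer")
}

#' Load a prefix lookup table (postal or telephone)
#'
#' @param path TSV with columns `prefix`, `prefecture`.
#' @return Named character vector prefix -> prefecture.
#' @export
load_prefix_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  stopifnot(all(c("prefix", "prefecture") %in% names(df)))
  setNames(df$prefecture, df$prefix)
}

#' Load the prefecture population table
#'
#' Populations are persons as of the 2011-10-01 reference date (census-based
#' reference values are packaged in
#' `radsent_extdata("population_2011.tsv")`). `Other` has no population and
#' no per-capita rate.
#'
#' @param path TSV with columns `prefecture`, `population`.
#' @return Named numeric vector prefecture -> persons.
#' @export
load_population_table <- function(path = radsent_extdata("population_2011.tsv")) {
  df <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  stopifnot(all(c("prefecture", "population") %in% names(df)))
  if (any(df$population <= 0)) stop("populations must be positive", call. = FALSE)
  setNames(df$population, df$prefecture)
}

#' Extract region-word tokens
#'
#' Keeps the surfaces of tokens tagged noun / proper noun / region — the
#' part-of-speech triple used to nominate place-name candidates. With the
#' builtin tokenizer exactly the gazetteer vocabulary carries this triple.
#'
#' @param tokens A tokenizer-contract tibble (`surface`, `base`, `pos`,
#'   `pos1`, `pos2`).
#' @return Character vector of region words, in order of appearance.
#' @export
extract_region_tokens <- function(tokens) {
  tokens$surface[tokens$pos == "noun" & tokens$pos1 == "proper" & tokens$pos2 == "region"]
}

#' Extract 7-digit postal codes from text
#'
#' Matches `〒?ddd-dddd` (hyphen optional, full-width digits and hyphens
#' tolerated via NFKC) and returns digit-only strings.
#'
#' @param text Character vector.
#' @return For a single input, a character vector of 7-digit codes; for a
#'   vector input, a list of such vectors.
#' @export
#' @examples
#' extract_postal_codes("〒960-8001 です")
extract_postal_codes <- function(text) {
  text <- stringi::stri_trans_nfkc(text)
  # NFKC maps full-width digits/hyphens; the minus sign and long dash remain
  m <- stringi::stri_extract_all_regex(
    text, "(?<!\\d)\\u3012?\\d{3}[-\\u30FC\\u2212\\u2010-\\u2015]?\\d{4}(?!\\d)")
  out <- lapply(m, function(x) {
    if (length(x) == 1 && is.na(x)) character(0)
    else stringi::stri_replace_all_regex(x, "\\D", "")
  })
  if (length(text) == 1L) out[[1]] else out
}

#' Extract candidate telephone numbers from text
#'
#' Japanese numbering-plan heuristic: a leading 0, nine or more digits in
#' total, hyphens tolerated. Returns digit-only strings.
#'
#' @param text Character vector.
#' @return For a single input, a character vector; otherwise a list.
#' @export
extract_phone_numbers <- function(text) {
  text <- stringi::stri_trans_nfkc(text)
  m <- stringi::stri_extract_all_regex(
    text, "(?<!\\d)0\\d{1,4}[-\\u30FC\\u2212\\u2010-\\u2015]?\\d{1,4}[-\\u30FC\\u2212\\u2010-\\u2015]?\\d{3,4}(?!\\d)")
  out <- lapply(m, function(x) {
    if (length(x) == 1 && is.na(x)) return(character(0))
    d <- stringi::stri_replace_all_regex(x, "\\D", "")
    d[stringi::stri_length(d) >= 9]
  })
  if (length(text) == 1L) out[[1]] else out
}

match_prefix <- function(codes, table, n_min = 1L) {
  if (!length(codes)) return(character(0))
  prefixes <- names(table)
  out <- character(0)
  for (code in codes) {
    # longest prefix wins
    cand <- prefixes[startsWith(code, prefixes)]
    if (length(cand)) {
      out <- c(out, unname(table[cand[which.max(nchar(cand))]]))
    }
  }
  out
}

#' Resolve the prefectures a tweet refers to
#'
#' Takes the union of three lookup paths: gazetteer place-name tokens,
#' 3-digit postal-code prefixes, and telephone area-code prefixes (longest
#' prefix wins). Foreign or generic region words resolve to `Other`, but
#' `Other` is reported only when no concrete prefecture matched; a tweet
#' with no regional identifier gets an empty set. Multi-region tweets keep
#' all matched prefectures (multi-label); set `first_only = TRUE` for
#' single-label (first match) behaviour.
#'
#' @param text Tweet text (length 1).
#' @param tokens Tokenizer output for the text; if `NULL`, `tokenizer` is
#'   applied.
#' @param gazetteer A [load_gazetteer()] object.
#' @param postal,phone Prefix tables from [load_prefix_table()] (or `NULL`
#'   to skip that path).
#' @param tokenizer Used when `tokens` is `NULL`.
#' @param first_only Keep only the first matched prefecture.
#' @return Character vector (possibly empty) of prefecture names; sorted,
#'   deduplicated.
#' @export
resolve_prefectures <- function(text, tokens = NULL, gazetteer,
                                postal = NULL, phone = NULL,
                                tokenizer = NULL, first_only = FALSE) {
  if (is.null(tokens)) {
    if (is.null(tokenizer)) stop("supply either tokens or a tokenizer", call. = FALSE)
    tokens <- tokenizer(text)
  }
  words <- extract_region_tokens(tokens)
  hits <- character(0)
  other <- FALSE
  if (length(words)) {
    conc <- unname(gazetteer$place_names[words])
    hits <- c(hits, conc[!is.na(conc)])
    other <- other || any(words %in% gazetteer$other_names)
  }
  if (!is.null(postal)) {
    codes <- extract_postal_codes(text)
    hits <- c(hits, match_prefix(substr(codes, 1L, 3L), postal))
  }
  if (!is.null(phone)) {
    nums <- extract_phone_numbers(text)
    hits <- c(hits, match_prefix(nums, phone))
  }
  if (first_only && length(hits)) hits <- hits[1]
  hits <- sort(unique(hits))
  if (!length(hits) && other) hits <- "Other"
  hits
}

#' Geoparse a scored corpus
#'
#' Adds a `prefectures` list-column to a corpus table by running
#' [resolve_prefectures()] on each tweet's `clean_text`. With the builtin
#' tokenizer, region tokens are extracted through the same cached
#' chunk tokenization used by [score_corpus()], so large corpora parse
#' quickly.
#'
#' @param scored Tibble with `clean_text`.
#' @param gazetteer,postal,phone Lookup tables.
#' @param tokenizer Tokenizer function (builtin recommended).
#' @param first_only Single-label mode, see [resolve_prefectures()].
#' @return `scored` with a `prefectures` list-column.
#' @export
geoparse_corpus <- function(scored, gazetteer, postal = NULL, phone = NULL,
                            tokenizer, first_only = FALSE) {
  texts <- clean_tweet_text(scored$clean_text)
  n <- length(texts)
  chunk_fn <- attr(tokenizer, "chunk_fn", exact = TRUE)
  prefs <- vector("list", n)
  if (!is.null(chunk_fn) && n > 0) {
    pieces <- stringi::stri_split_regex(texts, "[\\s\\u3000]+", omit_empty = TRUE)
    flat <- unlist(pieces, use.names = FALSE)
    row <- rep.int(seq_len(n), lengths(pieces))
    uc <- unique(flat)
    region_of <- lapply(uc, function(ch) {
      tk <- chunk_fn(ch)
      tk$surface[tk$pos == "noun" & tk$pos1 == "proper" & tk$pos2 == "region"]
    })
    words_by_row <- split(region_of[match(flat, uc)], factor(row, levels = seq_len(n)))
    has_digits <- stringi::stri_detect_regex(texts, "\\d")
    for (i in seq_len(n)) {
      words <- unlist(words_by_row[[i]], use.names = FALSE)
      hits <- character(0); other <- FALSE
      if (length(words)) {
        conc <- unname(gazetteer$place_names[words])
        hits <- conc[!is.na(conc)]
        other <- any(words %in% gazetteer$other_names)
      }
      if (has_digits[i]) {
        if (!is.null(postal)) {
          codes <- extract_postal_codes(texts[i])
          hits <- c(hits, match_prefix(substr(codes, 1L, 3L), postal))
        }
        if (!is.null(phone)) {
          nums <- extract_phone_numbers(texts[i])
          hits <- c(hits, match_prefix(nums, phone))
        }
      }
      if (first_only && length(hits)) hits <- hits[1]
      hits <- sort(unique(hits))
      if (!length(hits) && other) hits <- "Other"
      prefs[[i]] <- hits
    }
  } else {
    for (i in seq_len(n)) {
      prefs[[i]] <- resolve_prefectures(texts[i], tokens = NULL, gazetteer,
                                        postal = postal, phone = phone,
                                        tokenizer = tokenizer, first_only = first_only)
    }
  }
  scored$prefectures <- prefs
  scored
}

#' Tweets per 1000 residents
#'
#' @param count Number of tweets attributed to the prefecture.
#' @param population Residents (persons); must be positive.
#' @return `round(count / population * 1000)` to the nearest integer.
#' @export
#' @examples
#' per_capita_rate(1000, 1e6)
per_capita_rate <- function(count, population) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  round(count / population * 1000)
}

#' Prefecture breakdown table
#'
#' Counts tweets attributed to each prefecture (a multi-label tweet counts
#' once per matched prefecture) and computes per-capita rates; `Other` gets
#' `NA` because its population is unknown.
#'
#' @param geo A [geoparse_corpus()] table.
#' @param population A [load_population_table()] vector.
#' @return Tibble with `prefecture`, `n_tweets`, `per_1000`.
#' @export
prefecture_breakdown <- function(geo, population = load_population_table()) {
  flat <- unlist(geo$prefectures, use.names = FALSE)
  counts <- table(factor(flat, levels = prefecture_levels()))
  out <- tibble::tibble(prefecture = names(counts), n_tweets = as.integer(counts))
  pop <- unname(population[out$prefecture])
  out$per_1000 <- ifelse(is.na(pop), NA_real_, round(out$n_tweets / pop * 1000))
  out
}
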