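#' Default masked words
#'
#' The corpus-defining radiation terms carry strongly negative dictionary
#' polarities (radioactivity -0.598318, radiation -0.560393, radioactive
#' -0.178744), yet every tweet in the corpus contains one by construction.
#' To keep the selection keywords from dragging every score down they are
#' forced to 0 points. 放射性 ("radioactive") is included because
#' 放射性物質 segments as 放射性 + 物質 under standard
#' morphological analysis. Masked words still count toward the word count:
#' they are scored 0, not deleted.
#'
#' @return Character vector of masked words.
#' @export
default_masked_words <- function() c("放射線", "放射能", "放射性", "放射性物質")

POS_JA_MAP <- c("名詞" = "noun",       # 名詞
                "動詞" = "verb",       # 動詞
                "形容詞" = "adjective",  # 形容詞
                "副詞" = "adverb")     # 副詞

#' Load a semantic-orientation lexicon
#'
#' Supports two file dialects: the four-field colon format
#' `surface:reading:pos:value` of the published Japanese
#' semantic-orientation dictionary, and a two-column TSV (`word`, `value`,
#' with or without a header). Values are real numbers in \[-1, 1\]
#' (negative = negative impression); values outside are clipped with a
#' warning. Malformed lines and unparseable values are skipped with a
#' warning; on duplicate words the first value is kept. An empty lexicon is
#' an error.
#'
#' @param path Lexicon file path.
#' @param masked Words forced to 0 regardless of their dictionary value;
#'   see [default_masked_words()].
#' @return An object of class `radsent_lexicon`: a list with `entries`
#'   (named numeric vector), `pos` (named character vector of parts of
#'   speech) and `masked`.
#' @export
load_lexicon <- function(path, masked = default_masked_words()) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  colon <- stringi::stri_count_fixed(lines, ":") >= 3 &
    !stringi::stri_detect_fixed(lines, "\t")
  words <- character(0); values <- numeric(0); pos <- character(0)
  n_bad <- 0L
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (colon[i]) {
      parts <- stringi::stri_split_fixed(l, ":")[[1]]
      if (length(parts) < 4) { n_bad <- n_bad + 1L; next }
      w <- parts[1]
      p <- unname(POS_JA_MAP[parts[3]])
      v <- suppressWarnings(as.numeric(parts[length(parts)]))
    } else {
      parts <- stringi::stri_split_regex(l, "\t")[[1]]
      if (length(parts) < 2) { n_bad <- n_bad + 1L; next }
      w <- parts[1]
      p <- NA_character_
      v <- suppressWarnings(as.numeric(parts[2]))
      if (w == "word" && is.na(v)) next  # header row
    }
    if (is.na(v) || !nzchar(w)) { n_bad <- n_bad + 1L; next }
    words <- c(words, w); values <- c(values, v)
    pos <- c(pos, if (is.na(p)) "noun" else p)
  }
  if (n_bad > 0) warning(n_bad, " malformed lexicon line(s) skipped", call. = FALSE)
  keep <- !duplicated(words)
  if (any(!keep)) warning(sum(!keep), " duplicate lexicon word(s); first value kept", call. = FALSE)
  words <- words[keep]; values <- values[keep]; pos <- pos[keep]
  if (!length(words)) stop("lexicon is empty", call. = FALSE)
  if (any(values < -1 | values > 1)) {
    warning("lexicon values outside [-1, 1] clipped", call. = FALSE)
    values <- pmin(1, pmax(-1, values))
  }
  structure(list(entries = setNames(values, words),
                 pos = setNames(pos, words),
                 masked = unique(masked)),
            class = "radsent_lexicon")
}

#' @export
print.radsent_lexicon <- function(x, ...) {
  cat("<radsent_lexicon> ", length(x$entries), " entries, ",
      length(x$masked), " masked words\n", sep = "")
  invisible(x)
}

#' Semantic-orientation value of a word
#'
#' Masked words score 0; words absent from the lexicon (out of vocabulary)
#' score 0; otherwise the dictionary value. Lookup is by base (dictionary)
#' form.
#'
#' @param lexicon A [load_lexicon()] object.
#' @param word Character vector of base forms.
#' @return Numeric vector of values in \[-1, 1\].
#' @export
word_value <- function(lexicon, word) {
  v <- unname(lexicon$entries[word])
  v[is.na(v)] <- 0
  v[word %in% lexicon$masked] <- 0
  v
}

# Noise stripped before tokenization: URLs, @mentions, repost markers and
# hashtag signs are not dictionary words and would otherwise inflate the
# word count.
clean_tweet_text <- function(text) {
  text <- stringi::stri_trans_nfkc(text)
  text <- stringi::stri_replace_all_regex(text, "https?://\\S+", " ")
  text <- stringi::stri_replace_all_regex(text, "\\b(RT|QT)\\b\\s*:?", " ",
                                          case_insensitive = TRUE)
  text <- stringi::stri_replace_all_regex(text, "@[A-Za-z0-9_]+\\s*:?", " ")
  stringi::stri_replace_all_fixed(text, "#", " ")
}

#' Score one tweet's semantic orientation
#'
#' Computes the tweet semantic-orientation value: the sum of the words'
#' semantic-orientation values divided by the number of words,
#' `t_pn = sum(w_pn) / w_c`. The text is cleaned (URLs, mentions, repost
#' markers, hashtag signs removed), tokenized, and scored on base forms.
#' By default `w_c` counts content tokens only (symbol/punctuation tokens
#' are excluded); set `count_all = TRUE` to count every token. An empty
#' tweet (`w_c == 0`) scores `(0, 0)`.
#'
#' @param clean_text One tweet text (already truncated at any inline repost
#'   marker for target-group tweets).
#' @param tokenizer A tokenizer function, e.g. [builtin_tokenizer()].
#' @param lexicon A [load_lexicon()] object.
#' @param count_all Count symbol tokens in `w_c` as well.
#' @return A list with elements `t_pn` (in \[-1, 1\]) and `w_c`.
#' @export
score_tweet <- function(clean_text, tokenizer, lexicon, count_all = FALSE) {
  toks <- tokenizer(clean_tweet_text(clean_text))
  content <- if (count_all) rep(TRUE, nrow(toks)) else toks$pos != "symbol"
  w_c <- sum(content)
  if (w_c == 0L) return(list(t_pn = 0, w_c = 0L))
  list(t_pn = sum(word_value(lexicon, toks$base[content])) / w_c, w_c = w_c)
}

#' Score a whole grouped corpus
#'
#' Adds `t_pn` and `w_c` columns to a [group_corpus()] table. With the
#' builtin tokenizer, scoring is vectorised over unique whitespace-separated
#' spans and is exactly equivalent to calling [score_tweet()] row by row.
#'
#' @param grouped Tibble with a `clean_text` column.
#' @param lexicon A [load_lexicon()] object.
#' @param tokenizer A tokenizer function.
#' @param count_all Count symbol tokens in `w_c`.
#' @return `grouped` with `t_pn` and `w_c` columns.
#' @export
score_corpus <- function(grouped, lexicon, tokenizer, count_all = FALSE) {
  texts <- clean_tweet_text(grouped$clean_text)
  chunk_fn <- attr(tokenizer, "chunk_fn", exact = TRUE)
  n <- length(texts)
  t_pn <- numeric(n); w_c <- integer(n)
  if (!is.null(chunk_fn) && n > 0) {
    pieces <- stringi::stri_split_regex(texts, "[\\s\\u3000]+", omit_empty = TRUE)
    lens <- lengths(pieces)
    flat <- unlist(pieces, use.names = FALSE)
    row <- rep.int(seq_len(n), lens)
    uc <- unique(flat)
    stats <- vapply(uc, function(ch) {
      tk <- chunk_fn(ch)
      keep <- if (count_all) rep(TRUE, length(tk$pos)) else tk$pos != "symbol"
      c(sum(keep), sum(word_value(lexicon, tk$base[keep])))
    }, numeric(2))
    idx <- match(flat, uc)
    cnt <- stats[1L, idx]
    val <- stats[2L, idx]
    if (length(flat)) {
      w_c_all <- rowsum(cnt, row, reorder = FALSE)
      sum_all <- rowsum(val, row, reorder = FALSE)
      rows_present <- as.integer(rownames(w_c_all))
      w_c[rows_present] <- as.integer(w_c_all[, 1L])
      t_sum <- numeric(n)
      t_sum[rows_present] <- sum_all[, 1L]
      t_pn <- ifelse(w_c > 0L, t_sum / pmax(w_c, 1L), 0)
    }
  } else {
    for (i in seq_len(n)) {
      s <- score_tweet(texts[i], tokenizer, lexicon, count_all = count_all)
      t_pn[i] <- s$t_pn; w_c[i] <- s$w_c
    }
  }
  grouped$t_pn <- t_pn
  grouped$w_c <- as.integer(w_c)
  grouped
}
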