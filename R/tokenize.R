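#' Default filler vocabulary for the builtin tokenizer
#'
#' Neutral topic words that are deliberately absent from the fixture lexicon
#' (so they score 0 as out-of-vocabulary) but are known to the builtin
#' tokenizer and count toward the word count.
#'
#' @return Character vector of words.
#' @export
default_filler_words <- function() {
  c("ニュース", "今日", "明日", "情報",
    "話題", "記事", "測定", "数値",
    "様子", "現場")
}

#' Build the vocabulary table for the builtin tokenizer
#'
#' The builtin tokenizer is dictionary-driven: it knows exactly the words in
#' this table. The vocabulary is the union of the lexicon entries (with the
#' part of speech recorded in the lexicon, or noun when unknown), the masked
#' keyword set, gazetteer place names (tagged noun / proper noun / region),
#' and any extra words.
#'
#' @param lexicon A [load_lexicon()] object, or `NULL`.
#' @param gazetteer A [load_gazetteer()] object, or `NULL`.
#' @param extra_words Additional plain-noun words, e.g.
#'   [default_filler_words()].
#' @return A tibble with columns `word`, `pos`, `pos1`, `pos2`.
#' @export
tokenizer_vocabulary <- function(lexicon = NULL, gazetteer = NULL,
                                 extra_words = default_filler_words()) {
  rows <- list()
  if (!is.null(lexicon)) {
    w <- names(lexicon$entries)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      word = w,
      pos = unname(lexicon$pos[w]),
      pos1 = "general", pos2 = ""
    )
    if (length(lexicon$masked)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        word = lexicon$masked, pos = "noun", pos1 = "general", pos2 = "")
    }
  }
  if (!is.null(gazetteer)) {
    w <- c(names(gazetteer$place_names), gazetteer$other_names)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      word = w, pos = "noun", pos1 = "proper", pos2 = "region")
  }
  if (length(extra_words)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      word = extra_words, pos = "noun", pos1 = "general", pos2 = "")
  }
  vocab <- dplyr::bind_rows(rows)
  vocab$pos[is.na(vocab$pos)] <- "noun"
  vocab <- vocab[!duplicated(vocab$word), , drop = FALSE]
  vocab
}

# Tokenize one whitespace-free chunk by greedy longest match against the
# vocabulary; unmatched ASCII alphanumeric runs become single unknown tokens,
# punctuation/symbol characters become symbol tokens, any other character a
# single-character unknown noun.
chunk_tokens <- function(chunk, vocab_env, max_len) {
  n <- stringi::stri_length(chunk)
  surfaces <- character(0)
  poss <- character(0); pos1s <- character(0); pos2s <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      cand <- stringi::stri_sub(chunk, i, i + len - 1L)
      hit <- vocab_env[[cand]]
      if (!is.null(hit)) {
        surfaces <- c(surfaces, cand)
        poss <- c(poss, hit[[1L]]); pos1s <- c(pos1s, hit[[2L]]); pos2s <- c(pos2s, hit[[3L]])
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (matched) next
    ch <- stringi::stri_sub(chunk, i, i)
    if (stringi::stri_detect_regex(ch, "[A-Za-z0-9]")) {
      j <- i
      while (j < n && stringi::stri_detect_regex(stringi::stri_sub(chunk, j + 1L, j + 1L), "[A-Za-z0-9]")) {
        j <- j + 1L
      }
      surfaces <- c(surfaces, stringi::stri_sub(chunk, i, j))
      poss <- c(poss, "noun"); pos1s <- c(pos1s, "unknown"); pos2s <- c(pos2s, "")
      i <- j + 1L
    } else if (stringi::stri_detect_regex(ch, "[\\p{P}\\p{S}\\p{Z}\\p{C}]")) {
      surfaces <- c(surfaces, ch)
      poss <- c(poss, "symbol"); pos1s <- c(pos1s, "general"); pos2s <- c(pos2s, "")
      i <- i + 1L
    } else {
      surfaces <- c(surfaces, ch)
      poss <- c(poss, "noun"); pos1s <- c(pos1s, "unknown"); pos2s <- c(pos2s, "")
      i <- i + 1L
    }
  }
  list(surface = surfaces, base = surfaces, pos = poss, pos1 = pos1s, pos2 = pos2s)
}

#' Construct the builtin dictionary-driven tokenizer
#'
#' Returns a tokenizer function satisfying the package's tokenizer contract:
#' `function(text)` returning a tibble with columns `surface`, `base`,
#' `pos`, `pos1`, `pos2` (one row per token, in order). Any morphological
#' analyzer can be adapted to the same contract; the builtin implementation
#' applies Unicode NFKC normalisation, drops whitespace, and segments each
#' remaining span by greedy longest match against `vocab`. The
#' concatenation of surfaces reproduces the input text minus whitespace.
#' Base forms equal surfaces (the builtin vocabulary stores dictionary
#' forms).
#'
#' @param vocab A vocabulary table from [tokenizer_vocabulary()].
#' @return A tokenizer function with attribute `"chunk_fn"` used internally
#'   for fast whole-corpus scoring.
#' @export
#' @examples
#' lex <- load_lexicon(radsent_extdata("lexicon_fixture.tsv"))
#' tok <- builtin_tokenizer(tokenizer_vocabulary(lex))
#' tok("良いニュース")
builtin_tokenizer <- function(vocab) {
  stopifnot(is.data.frame(vocab), all(c("word", "pos", "pos1", "pos2") %in% names(vocab)))
  env <- new.env(parent = emptyenv(), size = max(64L, 2L * nrow(vocab)))
  for (k in seq_len(nrow(vocab))) {
    env[[vocab$word[k]]] <- c(vocab$pos[k], vocab$pos1[k], vocab$pos2[k])
  }
  max_len <- if (nrow(vocab)) max(stringi::stri_length(vocab$word)) else 1L
  cache <- new.env(parent = emptyenv())

  chunk_fn <- function(chunk) {
    hit <- cache[[chunk]]
    if (is.null(hit)) {
      hit <- chunk_tokens(chunk, env, max_len)
      cache[[chunk]] <- hit
    }
    hit
  }

  f <- function(text) {
    stopifnot(length(text) == 1L)
    text <- stringi::stri_trans_nfkc(text)
    chunks <- stringi::stri_split_regex(text, "[\\s\\u3000]+", omit_empty = TRUE)[[1]]
    parts <- lapply(chunks, chunk_fn)
    tibble::tibble(
      surface = unlist(lapply(parts, `[[`, "surface"), use.names = FALSE) %||% character(0),
      base = unlist(lapply(parts, `[[`, "base"), use.names = FALSE) %||% character(0),
      pos = unlist(lapply(parts, `[[`, "pos"), use.names = FALSE) %||% character(0),
      pos1 = unlist(lapply(parts, `[[`, "pos1"), use.names = FALSE) %||% character(0),
      pos2 = unlist(lapply(parts, `[[`, "pos2"), use.names = FALSE) %||% character(0)
    )
  }
  attr(f, "chunk_fn") <- chunk_fn
  class(f) <- c("radsent_tokenizer", class(f))
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
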