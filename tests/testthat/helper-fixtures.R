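# Shared fixtures, built once per test run from the packaged tables.

fixture_lexicon <- function() {
  load_lexicon(radsent_extdata("lexicon_fixture.tsv"))
}

fixture_gazetteer <- function() load_gazetteer()

fixture_postal <- function() load_prefix_table(radsent_extdata("postal_prefixes.tsv"))

fixture_phone <- function() load_prefix_table(radsent_extdata("phone_prefixes.tsv"))

fixture_tokenizer <- function(lex = fixture_lexicon(), gaz = fixture_gazetteer()) {
  builtin_tokenizer(tokenizer_vocabulary(lex, gaz))
}

# Minimal tweet tibble with JST timestamps.
make_tweets <- function(text, user_id = "alice",
                        timestamp = "2011-04-01 12:00:00") {
  n <- length(text)
  tibble::tibble(
    tweet_id = sprintf("x%03d", seq_len(n)),
    timestamp = as.POSIXct(rep_len(timestamp, n), tz = "Asia/Tokyo"),
    user_id = rep_len(user_id, n),
    text = text
  )
}

# A small lexicon written to a temp file, for tests that need exact values
# not present in the packaged fixture.
temp_lexicon <- function(words, values, masked = default_masked_words()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(paste(words, values, sep = "\t"), path, useBytes = TRUE)
  load_lexicon(path, masked = masked)
}

# Brute-force scoring oracle: plain loop over token base forms.
oracle_score <- function(bases, lexicon) {
  if (!length(bases)) return(0)
  total <- 0
  for (b in bases) {
    v <- if (b %in% lexicon$masked) 0
    else if (b %in% names(lexicon$entries)) unname(lexicon$entries[[b]])
    else 0
    total <- total + v
  }
  total / length(bases)
}
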