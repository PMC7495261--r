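test_that("lexicon loads both the colon dialect and 2-column TSV", {
  path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("優れる:すぐれる:動詞:1",
               "良い:よい:形容詞:0.995827",
               "ばか:ばか:名詞:-0.923837"), path, useBytes = TRUE)
  lex <- load_lexicon(path)
  expect_equal(unname(lex$entries["優れる"]), 1)
  expect_equal(unname(lex$pos["優れる"]), "verb")
  expect_equal(unname(lex$entries["良い"]), 0.995827)

  lex2 <- temp_lexicon(c("良い", "悪い"), c(0.8, -0.3))
  expect_equal(word_value(lex2, "良い"), 0.8)
  expect_equal(word_value(lex2, "悪い"), -0.3)
})

test_that("masked and out-of-vocabulary words score 0; masking beats the dictionary", {
  lex <- fixture_lexicon()
  # the dictionary itself carries the published negative values...
  expect_equal(unname(lex$entries["放射能"]), -0.598318)
  expect_equal(unname(lex$entries["放射線"]), -0.560393)
  expect_equal(unname(lex$entries["放射性"]), -0.178744)
  # ...but lookups through word_value are masked to 0
  expect_equal(word_value(lex, c("放射能", "放射線", "放射性", "放射性物質")),
               c(0, 0, 0, 0))
  expect_equal(word_value(lex, "グーグル"), 0)  # OOV
  expect_equal(word_value(lex, "美味しい"), 0.89)
})

test_that("malformed lines, duplicates and out-of-range values are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("良い\t0.5", "良い\t0.9", "broken line", "大きい\t1.7"), path,
             useBytes = TRUE)
  expect_warning(expect_warning(expect_warning(
    lex <- load_lexicon(path), "malformed"), "duplicate"), "clipped")
  expect_equal(unname(lex$entries["良い"]), 0.5)   # first value kept
  expect_equal(unname(lex$entries["大きい"]), 1)   # clipped

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(load_lexicon(empty), "empty")
})

test_that("builtin tokenizer reconstructs input and resolves longest matches", {
  tok <- fixture_tokenizer()
  txts <- c("良いニュース", "放射性物質が検出", "福島市の様子",
            "今日は良い天気123 abc!")
  for (tx in txts) {
    tk <- tok(tx)
    expect_equal(paste(tk$surface, collapse = ""),
                 stringi::stri_replace_all_regex(stringi::stri_trans_nfkc(tx), "\\s", ""))
  }
  # longest match: 放射性物質 is one (masked) token, not 放射性 + 物質
  expect_true("放射性物質" %in% tok("放射性物質が検出")$surface)
  # 福島市 beats 福島
  expect_true("福島市" %in% tok("福島市の様子")$surface)
  # full-width input hits the same vocabulary keys after NFKC
  expect_equal(tok("ＡＢＣ１２３")$surface, "ABC123")
})

test_that("tweet scoring implements sum(word values) / word count", {
  lex <- temp_lexicon(c("良い", "悪い"), c(0.6, -0.2))
  tok <- builtin_tokenizer(tokenizer_vocabulary(lex, extra_words = c("謎", "何か")))
  # {0.6, -0.2, OOV} over w_c = 3
  s <- score_tweet("良い 悪い 謎", tok, lex)
  expect_equal(s$w_c, 3L)
  expect_equal(s$t_pn, 0.4 / 3, tolerance = 1e-12)
  # single token
  expect_equal(score_tweet("良い", tok, lex)$t_pn, 0.6)
  # all OOV -> zero numerator, not zero w_c
  s2 <- score_tweet("謎 何か 謎", tok, lex)
  expect_equal(s2, list(t_pn = 0, w_c = 3L))
  # empty text
  expect_equal(score_tweet("", tok, lex), list(t_pn = 0, w_c = 0L))
})

test_that("a tweet consisting only of a masked keyword scores exactly 0", {
  lex <- fixture_lexicon()
  tok <- fixture_tokenizer(lex)
  for (kw in default_keywords()) {
    s <- score_tweet(kw, tok, lex)
    expect_identical(s$t_pn, 0)
    expect_gte(s$w_c, 1L)
  }
})

test_that("punctuation is excluded from the word count by default, included on request", {
  lex <- temp_lexicon("良い", 0.5)
  tok <- builtin_tokenizer(tokenizer_vocabulary(lex))
  s <- score_tweet("良い。", tok, lex)
  expect_equal(s$w_c, 1L)
  expect_equal(s$t_pn, 0.5)
  s_all <- score_tweet("良い。", tok, lex, count_all = TRUE)
  expect_equal(s_all$w_c, 2L)
  expect_equal(s_all$t_pn, 0.25)
})

test_that("URLs, mentions, repost markers and hashtags do not affect the score", {
  lex <- temp_lexicon("良い", 0.5)
  tok <- builtin_tokenizer(tokenizer_vocabulary(lex))
  plain <- score_tweet("良い", tok, lex)
  expect_equal(score_tweet("RT @user123: 良い", tok, lex), plain)
  expect_equal(score_tweet("良い http://example.com/x?y=1", tok, lex), plain)
  expect_equal(score_tweet("#良い", tok, lex), plain)
})

test_that("scores match a brute-force oracle on random token lists and stay in [-1, 1]", {
  lex <- fixture_lexicon()
  gaz <- fixture_gazetteer()
  tok <- fixture_tokenizer(lex, gaz)
  vocab_words <- c(names(lex$entries), lex$masked, default_filler_words(),
                   gaz$words)
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:20, 1)
    words <- sample(vocab_words, n, replace = TRUE)
    s <- score_tweet(paste(words, collapse = " "), tok, lex)
    expect_equal(s$w_c, n)
    expect_equal(s$t_pn, oracle_score(words, lex), tolerance = 1e-12)
    expect_lte(abs(s$t_pn), 1)
    # permutation invariance
    s2 <- score_tweet(paste(sample(words), collapse = " "), tok, lex)
    expect_equal(s2$t_pn, s$t_pn, tolerance = 1e-12)
  }
})

test_that("adding a masked word leaves the numerator unchanged but grows w_c", {
  lex <- fixture_lexicon()
  tok <- fixture_tokenizer(lex)
  base <- score_tweet("良い 悪い", tok, lex)
  with_mask <- score_tweet("良い 悪い 放射能", tok, lex)
  expect_equal(with_mask$w_c, base$w_c + 1L)
  expect_equal(with_mask$t_pn * with_mask$w_c, base$t_pn * base$w_c, tolerance = 1e-12)
})

test_that("vectorised corpus scoring equals row-wise score_tweet", {
  lex <- fixture_lexicon()
  gaz <- fixture_gazetteer()
  tok <- fixture_tokenizer(lex, gaz)
  set.seed(7)
  words <- c(names(lex$entries), default_filler_words(), gaz$words)
  texts <- replicate(60, paste(sample(words, sample(0:12, 1), replace = TRUE),
                               collapse = " "))
  texts <- c(texts, "RT @x: 良い 未知語テスト xyz 123", "", "。。。")
  df <- make_tweets(texts)
  df$clean_text <- df$text
  out <- score_corpus(df, lex, tok)
  for (i in seq_along(texts)) {
    s <- score_tweet(texts[i], tok, lex)
    expect_equal(out$t_pn[i], s$t_pn, tolerance = 1e-12)
    expect_equal(out$w_c[i], s$w_c)
  }
})
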