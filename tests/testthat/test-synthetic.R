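small_config <- function(seed = 101, ...) {
  synthetic_config(base_volume = 25,
                   events = data.frame(day = 1, magnitude = 150, half_life = 3),
                   seed = seed, ...)
}

test_that("the same seed yields a byte-identical corpus", {
  g1 <- generate_corpus(small_config())
  g2 <- generate_corpus(small_config())
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$truth, g2$truth)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_corpus(g1$corpus, p1); write_corpus(g2$corpus, p2)
  expect_identical(readLines(p1, encoding = "UTF-8"), readLines(p2, encoding = "UTF-8"))
  # a different seed yields a different stream
  g3 <- generate_corpus(small_config(seed = 102))
  expect_false(identical(g1$corpus$text, g3$corpus$text))
})

test_that("every generated tweet passes the keyword filter and sits in the window", {
  g <- generate_corpus(small_config())
  expect_true(all(keyword_filter(g$corpus$text)))
  expect_true(all(in_window(g$corpus$timestamp)))
  expect_true(all(g$corpus$timestamp == sort(g$corpus$timestamp)))
})

test_that("grouping rules recover the intended labels exactly", {
  g <- generate_corpus(small_config())
  grp <- group_corpus(g$corpus)
  expect_equal(nrow(grp), nrow(g$corpus))
  expect_identical(grp$group, g$truth$group)
  expect_identical(grp$rt_reason, g$truth$rt_reason)
})

test_that("with no bots or reposts every tweet is target", {
  g <- generate_corpus(small_config(bot_fraction = 0, rt_fraction = 0))
  grp <- group_corpus(g$corpus)
  expect_true(all(grp$group == "TARGET"))
})

test_that("realised scores equal the recorded achievable scores through the real scorer", {
  g <- generate_corpus(small_config())
  lex <- fixture_lexicon()
  tok <- fixture_tokenizer(lex)
  sc <- score_corpus(group_corpus(g$corpus), lex, tok)
  expect_lt(max(abs(sc$t_pn - g$truth$achieved_score)), 1e-12)
  expect_identical(sc$w_c, g$truth$w_c)
  # achieved scores track the drawn targets up to the token grid
  expect_lt(max(abs(g$truth$achieved_score - g$truth$target_score)), 0.05)
})

test_that("a degenerate generator (no noise, no drift) pins every target tweet at the base score", {
  g <- generate_corpus(small_config(noise_sd = 0, sentiment_slope = 0,
                                    bot_fraction = 0, rt_fraction = 0,
                                    sentiment_base = -0.55))
  lex <- fixture_lexicon()
  sc <- score_corpus(group_corpus(g$corpus), lex, fixture_tokenizer(lex))
  expect_lt(max(abs(sc$t_pn + 0.55)), 1e-9)
})

test_that("geoparsing recovers the intended prefectures", {
  g <- generate_corpus(small_config())
  geo <- geoparse_corpus(g$corpus |> dplyr::mutate(clean_text = text),
                         fixture_gazetteer(), tokenizer = fixture_tokenizer())
  got <- vapply(geo$prefectures, function(p) if (length(p)) p[1] else NA_character_,
                character(1))
  expect_identical(got, g$truth$prefecture)
})

test_that("daily counts follow the configured intensity on average", {
  cfg <- small_config()
  totals <- vapply(1:5, function(s) {
    nrow(generate_corpus(synthetic_config(base_volume = 25,
                                          events = data.frame(day = 1, magnitude = 150, half_life = 3),
                                          seed = s))$corpus)
  }, numeric(1))
  expected <- sum(radsent:::intensity_curve(cfg)$lambda)
  # Poisson totals over 5 seeds: allow 4 sd of the mean estimate
  expect_lt(abs(mean(totals) - expected), 4 * sqrt(expected / 5))
})

test_that("recovery report flags the generating parameters as recovered", {
  cfg <- synthetic_config(base_volume = 120, events = NULL, seed = 77)
  g <- generate_corpus(cfg)
  lex <- fixture_lexicon()
  gaz <- fixture_gazetteer()
  tok <- builtin_tokenizer(tokenizer_vocabulary(lex, gaz))
  sc <- score_corpus(group_corpus(g$corpus), lex, tok)
  geo <- geoparse_corpus(sc, gaz, tokenizer = tok)
  rep <- recovery_report(geo, g$truth)
  expect_setequal(rep$parameter, c("weekly_sentiment_slope", "bot_sentiment_offset",
                                   "fukushima_share_trend_sign"))
  expect_true(all(rep$within_tolerance))
})

test_that("null generator slope is recovered as statistically zero", {
  cfg <- synthetic_config(base_volume = 100, events = NULL,
                          sentiment_slope = 0, seed = 55)
  g <- generate_corpus(cfg)
  lex <- fixture_lexicon()
  sc <- score_corpus(group_corpus(g$corpus), lex, fixture_tokenizer(lex))
  tgt <- sc[sc$group == "TARGET", ]
  wk <- bucketize(tgt, "week")
  f <- fit_trend(as.numeric(wk$bucket), wk$mean_tpn)
  expect_lt(abs(f$slope), 3 * f$stderr_slope)
})
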