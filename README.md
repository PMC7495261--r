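# radsent

Sentiment surveillance of radiation-related microblog streams.

`radsent` is an R package for infoveillance analyses of the kind applied
to Japanese Twitter after the March 2011 Fukushima Daiichi accident: it
tracks how public feeling about radiation — overall, in the bot/retweet
amplification channel, and toward specific regions — evolves in a
year-long tweet stream. It is aimed at digital-epidemiology and
risk-communication researchers who need the whole chain, from raw
timestamped posts to weekly statistics, as tested, reproducible code.

## What it computes

Every post containing 放射線 (radiation), 放射能 (radioactivity) or
放射性物質 (radioactive substances) inside the study window
(2011-03-11 00:00 – 2012-03-10 23:59 JST) is

1. **partitioned**: handles beginning/ending in `bot`, and texts starting
   with `RT`/`QT` repost markers, form the *RT group*; everything else is
   the *target group*, with inline `RT @…` tails truncated so only the
   original poster's words are scored;
2. **scored** with a semantic-orientation lexicon (word polarities
   W<sub>pn</sub> ∈ [−1, 1]):

   T<sub>pn</sub> = Σ W<sub>pn</sub> / W<sub>c</sub>,

   the mean polarity over the tweet's W<sub>c</sub> words, where the
   corpus keywords are masked to 0 and out-of-vocabulary words score 0;
3. **geoparsed** to the 47 prefectures via an offline gazetteer, postal
   codes and telephone area codes (foreign/unresolvable names go to
   *Other*);
4. **aggregated**: daily/weekly/minute counts and sentiment means,
   cumulative sentiment, weekly target-vs-RT F tests (α = .05),
   Fukushima-versus-other-prefecture count and (+1-shifted) mean-sentiment
   ratios, OLS trend lines, and per-1000-residents rates by prefecture.

Tokenization is a pluggable contract (any MeCab-style analyzer can be
wrapped); a deterministic dictionary-driven longest-match tokenizer is
built in. Because the original 19-million-tweet corpus is not
redistributable, the package includes a seeded synthetic stream generator
(`generate_corpus()`) with per-tweet ground truth — event-driven volume
spikes, drifting group sentiment, a negatively offset bot/RT
subpopulation, and a rising Fukushima share — so the full pipeline is
testable end to end. See the vignette
(`vignettes/radiation-sentiment.Rmd`) for the model, conventions and
design decisions.

## Worked example

```r
library(radsent)

g <- generate_corpus(synthetic_config(base_volume = 60, seed = 42))
lex <- load_lexicon(radsent_extdata("lexicon_fixture.tsv"))
gaz <- load_gazetteer()
tok <- builtin_tokenizer(tokenizer_vocabulary(lex, gaz))

scored <- score_corpus(group_corpus(g$corpus), lex, tok)
geo    <- geoparse_corpus(scored, gaz, tokenizer = tok)

dplyr::count(scored, group)
#>   group        n
#> 1 RT_GROUP 38799
#> 2 TARGET   35541

wk <- bucketize(geo[geo$group == "TARGET", ], "week")
head(wk, 3)
#>   bucket     n sum_tpn mean_tpn
#> 1      0 12926  -7098.   -0.549
#> 2      1  9002  -4905.   -0.545
#> 3      2  5304  -2873.   -0.542

fit_trend(as.numeric(wk$bucket), wk$mean_tpn)
#> <trend_fit> slope 0.00337141 (se 0.000124), intercept -0.548957, n = 53

recovery_report(geo, g$truth)
#>   parameter                     true estimated tolerance within_tolerance
#> 1 weekly_sentiment_slope      0.0035   0.00337  0.000371 TRUE
#> 2 bot_sentiment_offset       -0.1    -0.0982    0.00275  TRUE
#> 3 fukushima_share_trend_sign  1       1        NA        TRUE
```

Reading this: the 74,340-tweet synthetic year starts around a weekly mean
sentiment of −0.55 in the target group and drifts positive by ≈ +0.0034
per week (the generator's true drift was +0.0005/day = +0.0035/week); the
RT group sits ≈ 0.10 below the target group; the Fukushima share of
region mentions trends upward. All three generating parameters are
recovered within tolerance.

`run_pipeline(pipeline_config(corpus, out_dir = "run1"))` executes the
same chain in one call and writes every intermediate and final table
(CSV) plus a JSON run manifest; reruns are byte-identical.

One exact worked example from the corpus-scale statistics: on
2011-11-22, 1797 of 34,173 tweets were Geiger-counter advertisements —
`share_of_total(1797, 34173)` returns `5.26` (percent).

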