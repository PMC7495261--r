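Package: radsent
Title: Sentiment Surveillance of Radiation-Related Microblog Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for infoveillance of public sentiment toward radiation on
    2011-era Japanese microblog streams. Implements keyword-based corpus
    selection, heuristic bot and retweet partitioning, lexicon-based semantic
    orientation scoring of individual posts (mean word polarity over a
    semantic-orientation dictionary), offline toponym resolution of posts to
    Japanese prefectures via place names, postal codes and telephone area
    codes, and the temporal and regional statistics used in disaster
    risk-communication analysis: daily and weekly counts and sentiment means,
    cumulative sentiment, Fukushima-versus-other-prefecture ratios, ordinary
    least squares trend lines, weekly F tests, and per-capita tweet rates.
    A seeded synthetic tweet-stream generator with recorded ground truth
    supports end-to-end testing and parameter-recovery studies without access
    to any platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
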