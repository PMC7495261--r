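#' Configuration for the synthetic tweet-stream generator
#'
#' Defaults emulate, at desk scale, the qualitative regimes of the 2011
#' radiation tweet stream: an event-driven volume spike followed by
#' exponential decay with a few secondary spikes, an overall negative
#' sentiment level drifting slowly positive, a bot/RT subpopulation with a
#' negative sentiment offset, and a Fukushima share among region-mentioning
#' tweets that rises over the year on the logistic scale.
#'
#' @param window Study window, see [study_window()].
#' @param base_volume Expected baseline tweets/day at day 0.
#' @param volume_decay Exponential decay rate of the baseline (per day).
#' @param events Data frame with columns `day` (0-based offset from window
#'   start), `magnitude` (added expected tweets/day at the event) and
#'   `half_life` (days) for each news-event spike.
#' @param sentiment_base Mean tweet score of the target group at day 0.
#' @param sentiment_slope Drift of the mean score, per day.
#' @param bot_fraction,rt_fraction Probability a tweet is bot-authored /
#'   an RT or QT repost; together they form the RT group.
#' @param bot_sentiment_offset Additive shift of the mean score for RT-group
#'   tweets (negative: bots/reposts skew negative).
#' @param geo_fraction Probability a tweet mentions a region.
#' @param fukushima_share_intercept,fukushima_share_slope Logistic-scale
#'   intercept and per-day slope of the probability that a region mention
#'   is about Fukushima Prefecture.
#' @param noise_sd Standard deviation of per-tweet scores around the group
#'   mean (scores are truncated to \[-1, 1\]).
#' @param wc_range Range of content-word counts per tweet.
#' @param seed Integer seed; the same seed yields a byte-identical corpus.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(window = study_window(),
                             base_volume = 500,
                             volume_decay = 0.006,
                             events = data.frame(
                               day = c(1, 4, 12, 217, 257),
                               magnitude = c(4000, 5000, 2500, 1200, 600),
                               half_life = c(3, 3, 4, 2, 2)),
                             sentiment_base = -0.55,
                             sentiment_slope = 0.0005,
                             bot_fraction = 0.12,
                             rt_fraction = 0.40,
                             bot_sentiment_offset = -0.1,
                             geo_fraction = 0.33,
                             fukushima_share_intercept = -1.4,
                             fukushima_share_slope = 0.007,
                             noise_sd = 0.12,
                             wc_range = c(12L, 18L),
                             seed = 1L) {
  stopifnot(bot_fraction >= 0, rt_fraction >= 0, bot_fraction + rt_fraction <= 1,
            geo_fraction >= 0, geo_fraction <= 1, noise_sd >= 0,
            wc_range[1] >= 4, wc_range[2] >= wc_range[1])
  structure(list(window = window, base_volume = base_volume,
                 volume_decay = volume_decay, events = events,
                 sentiment_base = sentiment_base, sentiment_slope = sentiment_slope,
                 bot_fraction = bot_fraction, rt_fraction = rt_fraction,
                 bot_sentiment_offset = bot_sentiment_offset,
                 geo_fraction = geo_fraction,
                 fukushima_share_intercept = fukushima_share_intercept,
                 fukushima_share_slope = fukushima_share_slope,
                 noise_sd = noise_sd, wc_range = as.integer(wc_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Expected tweets/day over the window.
intensity_curve <- function(config) {
  n_days <- as.integer(ceiling(as.numeric(difftime(config$window$end, config$window$start,
                                                   units = "days"))))
  t <- seq_len(n_days) - 1L
  lambda <- config$base_volume * exp(-config$volume_decay * t)
  ev <- config$events
  if (!is.null(ev) && nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      on <- t >= ev$day[k]
      lambda[on] <- lambda[on] + ev$magnitude[k] * 2^(-(t[on] - ev$day[k]) / ev$half_life[k])
    }
  }
  tibble::tibble(day = t, lambda = lambda)
}

# Truncated-normal draw on [-1, 1] via inverse CDF (deterministic given the
# RNG stream).
rtrunc_norm <- function(n, mean, sd) {
  if (sd == 0) return(pmin(1, pmax(-1, mean)))
  lo <- stats::pnorm((-1 - mean) / sd)
  hi <- stats::pnorm((1 - mean) / sd)
  u <- runif(n, lo, hi)
  mean + sd * stats::qnorm(u)
}

# Denomination words of the fixture lexicon used to realise exact scores:
# a +/-1 unit word plus one word per tenth and per hundredth, so any score
# sum on the 0.01 grid needs at most ceil(|sum|) unit words and two
# precision words.
COIN_ONE_POS <- "素晴らしい"
COIN_ONE_NEG <- "最悪"
COIN_TENTH_POS <- c("安心", "便利", "楽しい", "嬉しい", "良い",
                    "素敵", "健康", "幸せ", "感動")
COIN_TENTH_NEG <- c("不安", "心配", "悪い", "怖い", "危険",
                    "汚染", "恐怖", "絶望", "悲惨")
COIN_HUNDREDTH_POS <- c("元気", "静か", "明るい", "温かい", "丁寧",
                        "親切", "清潔", "爽やか", "豊か")
COIN_HUNDREDTH_NEG <- c("眠い", "退屈", "曇り", "騒音", "疲れる",
                        "残念", "迷惑", "苦情", "違反")

#' Generate a synthetic tweet corpus with ground truth
#'
#' Daily tweet counts are Poisson with an event-spike intensity; each tweet
#' is assembled from fixture-lexicon tokens chosen so that its exact score
#' under the builtin tokenizer equals a per-tweet target score drawn from a
#' truncated normal around the group mean (drifting linearly in time, with
#' an additive offset for the bot/RT subpopulation). Every tweet contains
#' one of the corpus keywords (masked, so it does not move the score);
#' region-mentioning tweets carry a gazetteer place word whose Fukushima
#' probability follows the configured logistic trend; bots get handles
#' ending or beginning with "bot"; reposts get an `RT @user:` (or
#' `QT @user:`) prefix. Scores not exactly representable by the token
#' denominations (or infeasible within the tweet's word budget) are
#' replaced by the nearest achievable value, which is what `truth` records
#' in `achieved_score`.
#'
#' @param config A [synthetic_config()].
#' @param gazetteer Gazetteer used for region words (defaults to the
#'   packaged fixture).
#' @return A list with `corpus` (tibble: `tweet_id`, `timestamp`,
#'   `user_id`, `text`) and `truth` (tibble: per-tweet intended group,
#'   reason, target and achieved scores, word count and prefecture, plus
#'   the generating config as attribute `config`).
#' @export
generate_corpus <- function(config = synthetic_config(),
                            gazetteer = load_gazetteer()) {
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  window <- config$window
  ic <- intensity_curve(config)
  n_day <- rpois(nrow(ic), ic$lambda)
  n <- sum(n_day)
  if (n == 0L) stop("configuration generates an empty corpus", call. = FALSE)
  day <- rep.int(ic$day, n_day)

  sec <- floor(runif(n, 0, 86400))
  timestamp <- window$start + day * 86400 + sec

  # group assignment
  u <- runif(n)
  is_bot <- u < config$bot_fraction
  is_rt <- !is_bot & u < config$bot_fraction + config$rt_fraction
  is_qt <- is_rt & runif(n) < 0.1
  group <- ifelse(is_bot | is_rt, "RT_GROUP", "TARGET")
  reason <- rep(NA_character_, n)
  reason[is_bot] <- "BOT_ACCOUNT"
  reason[is_rt & !is_qt] <- "STARTS_WITH_RT"
  reason[is_qt] <- "STARTS_WITH_QT"

  # per-tweet target score
  mu <- config$sentiment_base + config$sentiment_slope * day +
    ifelse(group == "RT_GROUP", config$bot_sentiment_offset, 0)
  target <- rtrunc_norm(n, mu, config$noise_sd)

  # region mention
  has_geo <- runif(n) < config$geo_fraction
  p_fuk <- stats::plogis(config$fukushima_share_intercept +
                           config$fukushima_share_slope * day)
  is_fuk <- has_geo & runif(n) < p_fuk
  conc <- gazetteer$place_names
  fuk_words <- names(conc)[conc == "Fukushima"]
  other_words <- names(conc)[conc != "Fukushima"]
  region_word <- rep(NA_character_, n)
  region_word[is_fuk] <- fuk_words[sample.int(length(fuk_words), sum(is_fuk), replace = TRUE)]
  oth <- has_geo & !is_fuk
  region_word[oth] <- other_words[sample.int(length(other_words), sum(oth), replace = TRUE)]
  region_pref <- rep(NA_character_, n)
  region_pref[has_geo] <- unname(conc[region_word[has_geo]])

  # word budget: 1 keyword + optional region word are structural zeros; the
  # rest of the w_c slots carry denomination words and neutral fillers.
  # Realising sum S needs ceil(|S|) unit words plus at most 2 precision
  # words, so w_c is bumped where needed to keep |t| feasible.
  zeros <- 1L + as.integer(has_geo)
  w_c <- sample.int(config$wc_range[2] - config$wc_range[1] + 1L, n, replace = TRUE) +
    config$wc_range[1] - 1L
  need <- ceiling((zeros + 2L) / pmax(1e-9, 1 - abs(target)))
  w_c <- pmin(60L, pmax(w_c, need))
  budget <- w_c - zeros
  s_hund <- round(abs(target) * w_c * 100)           # |score sum| in hundredths
  s_hund <- pmin(s_hund, (budget - 2L) * 100L + 99L) # keep the word count feasible
  a <- s_hund %/% 100L
  r <- s_hund %% 100L
  d10 <- r %/% 10L                                   # tenth-valued word index
  d1 <- r %% 10L                                     # hundredth-valued word index
  achieved <- sign(target) * s_hund / 100 / w_c
  n_fill <- budget - a - (d10 > 0L) - (d1 > 0L)

  neg <- target < 0
  one_w <- ifelse(neg, COIN_ONE_NEG, COIN_ONE_POS)
  tenth_w <- ifelse(d10 > 0L,
                    ifelse(neg, COIN_TENTH_NEG[pmax(d10, 1L)],
                           COIN_TENTH_POS[pmax(d10, 1L)]), "")
  hund_w <- ifelse(d1 > 0L,
                   ifelse(neg, COIN_HUNDREDTH_NEG[pmax(d1, 1L)],
                          COIN_HUNDREDTH_POS[pmax(d1, 1L)]), "")
  keywords <- default_keywords()
  kw <- keywords[sample.int(length(keywords), n, replace = TRUE)]
  fillers <- default_filler_words()
  fill_word <- fillers[sample.int(length(fillers), n, replace = TRUE)]

  body <- paste0(
    kw, " ",
    ifelse(has_geo, paste0(region_word, " "), ""),
    strrep(paste0(one_w, " "), a),
    ifelse(nzchar(tenth_w), paste0(tenth_w, " "), ""),
    ifelse(nzchar(hund_w), paste0(hund_w, " "), ""),
    strrep(paste0(fill_word, " "), n_fill)
  )
  body <- sub(" $", "", body)

  # handles and repost prefixes
  uid <- sample.int(50000L, n, replace = TRUE)
  user_id <- paste0("u", uid)
  bot_suffix <- runif(n) < 0.5
  user_id[is_bot] <- ifelse(bot_suffix[is_bot],
                            paste0("u", uid[is_bot], "bot"),
                            paste0("bot_u", uid[is_bot]))
  text <- body
  src <- paste0("u", sample.int(50000L, n, replace = TRUE))
  text[is_rt & !is_qt] <- paste0("RT @", src[is_rt & !is_qt], ": ", body[is_rt & !is_qt])
  text[is_qt] <- paste0("QT @", src[is_qt], ": ", body[is_qt])

  ord <- order(timestamp, day, sec, seq_len(n))
  tweet_id <- sprintf("t%08d", seq_len(n))
  corpus <- tibble::tibble(
    tweet_id = tweet_id,
    timestamp = timestamp[ord],
    user_id = user_id[ord],
    text = text[ord]
  )
  truth <- tibble::tibble(
    tweet_id = tweet_id,
    day = day[ord],
    group = group[ord],
    rt_reason = reason[ord],
    mu = mu[ord],
    target_score = target[ord],
    achieved_score = achieved[ord],
    w_c = as.integer(w_c[ord]),
    prefecture = region_pref[ord]
  )
  attr(truth, "config") <- config
  list(corpus = corpus, truth = truth)
}

#' Parameter-recovery report for a synthetic corpus
#'
#' Runs the comparison between what the generator intended and what the
#' analysis pipeline estimates: the weekly-mean sentiment trend of the
#' target group against `7 * sentiment_slope`, the RT-versus-target mean
#' score gap against `bot_sentiment_offset`, and the sign of the weekly
#' Fukushima-to-others count-ratio trend against the sign of
#' `fukushima_share_slope`. Tolerances are 3 standard errors of the
#' respective estimates.
#'
#' @param scored A scored (and, for the share trend, geoparsed) corpus with
#'   `timestamp`, `group`, `t_pn` and optionally `prefectures`.
#' @param truth The truth table from [generate_corpus()] (supplies the
#'   generating config).
#' @param config Generating config; defaults to the one attached to
#'   `truth`.
#' @return Tibble with columns `parameter`, `true`, `estimated`,
#'   `tolerance`, `within_tolerance`.
#' @export
recovery_report <- function(scored, truth, config = attr(truth, "config")) {
  stopifnot(!is.null(config))
  window <- config$window
  rows <- list()

  tgt <- scored[scored$group == "TARGET", ]
  wk <- bucketize(tgt, "week", window = window)
  ft <- fit_trend(as.numeric(wk$bucket), wk$mean_tpn)
  rows[[1]] <- tibble::tibble(parameter = "weekly_sentiment_slope",
                              true = 7 * config$sentiment_slope,
                              estimated = ft$slope,
                              tolerance = 3 * ft$stderr_slope,
                              within_tolerance = abs(ft$slope - 7 * config$sentiment_slope) <=
                                3 * ft$stderr_slope)

  a <- scored$t_pn[scored$group == "RT_GROUP"]
  b <- scored$t_pn[scored$group == "TARGET"]
  gap <- mean(a) - mean(b)
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  rows[[2]] <- tibble::tibble(parameter = "bot_sentiment_offset",
                              true = config$bot_sentiment_offset,
                              estimated = gap,
                              tolerance = 3 * se,
                              within_tolerance = abs(gap - config$bot_sentiment_offset) <= 3 * se)

  if (!is.null(scored$prefectures)) {
    rs <- weekly_ratio_series(scored, window = window)
    ok <- !is.na(rs$count_ratio)
    ftr <- fit_trend(as.numeric(rs$week[ok]), rs$count_ratio[ok])
    rows[[3]] <- tibble::tibble(parameter = "fukushima_share_trend_sign",
                                true = sign(config$fukushima_share_slope),
                                estimated = sign(ftr$slope),
                                tolerance = NA_real_,
                                within_tolerance = sign(ftr$slope) ==
                                  sign(config$fukushima_share_slope))
  }
  dplyr::bind_rows(rows)
}
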