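#' Pipeline configuration
#'
#' Collects every input and tunable of a full analysis run. `corpus` may be
#' a path to a JSON-lines corpus or an in-memory tweet tibble; lookup
#' tables default to the packaged fixtures.
#'
#' @param corpus Corpus path or tibble (`tweet_id`, `timestamp`, `user_id`,
#'   `text`).
#' @param lexicon_path Semantic-orientation lexicon file.
#' @param gazetteer_path,postal_path,phone_path,population_path Lookup
#'   tables (TSV).
#' @param keywords Corpus keyword set.
#' @param masked Masked word set.
#' @param alpha Significance level for weekly F tests.
#' @param ftest_mode `"anova"` or `"var_ratio"`.
#' @param count_all Count symbol tokens in word counts.
#' @param window Study window.
#' @param out_dir Output directory for tables and the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus,
                            lexicon_path = radsent_extdata("lexicon_fixture.tsv"),
                            gazetteer_path = radsent_extdata("gazetteer_fixture.tsv"),
                            postal_path = radsent_extdata("postal_prefixes.tsv"),
                            phone_path = radsent_extdata("phone_prefixes.tsv"),
                            population_path = radsent_extdata("population_2011.tsv"),
                            keywords = default_keywords(),
                            masked = default_masked_words(),
                            alpha = 0.05,
                            ftest_mode = "anova",
                            count_all = FALSE,
                            window = study_window(),
                            out_dir = tempfile("radsent_run_")) {
  structure(list(corpus = corpus, lexicon_path = lexicon_path,
                 gazetteer_path = gazetteer_path, postal_path = postal_path,
                 phone_path = phone_path, population_path = population_path,
                 keywords = keywords, masked = masked, alpha = alpha,
                 ftest_mode = ftest_mode, count_all = count_all,
                 window = window, out_dir = out_dir),
            class = "pipeline_config")
}

stage_fail <- function(stage, msg) {
  stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates read -> group -> score -> geoparse -> aggregate and writes
#' every output table plus a run manifest to `config$out_dir`. Outputs are
#' deterministic: re-running with the same configuration and inputs
#' reproduces identical bytes (the manifest records no wall-clock time for
#' this reason). On a stage failure the error names the failing stage.
#'
#' Output files: `grouped.csv` row counts per group; `daily_stats.csv`,
#' `daily_group_stats.csv`, `cumulative.csv`, `weekly_group_stats.csv`,
#' `weekly_region_group_stats.csv`, `weekly_ftest.csv`,
#' `weekly_ratios.csv`, `prefecture_table.csv`, `trends.csv`,
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory tables (`scored`, `geo`,
#'   plus each aggregate) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = list(
    lexicon_path = config$lexicon_path, gazetteer_path = config$gazetteer_path,
    postal_path = config$postal_path, phone_path = config$phone_path,
    population_path = config$population_path, keywords = config$keywords,
    masked = config$masked, alpha = config$alpha, ftest_mode = config$ftest_mode,
    count_all = config$count_all,
    window = c(format(config$window$start, "%Y-%m-%dT%H:%M:%S+09:00"),
               format(config$window$end, "%Y-%m-%dT%H:%M:%S+09:00"))
  ), stages = list(), warnings = list())

  # --- read ---------------------------------------------------------------
  tweets <- tryCatch({
    if (is.character(config$corpus)) read_corpus(config$corpus, config$window)
    else {
      tw <- config$corpus
      tw[in_window(tw$timestamp, config$window), , drop = FALSE]
    }
  }, error = function(e) stage_fail("read", conditionMessage(e)))
  log <- attr(tweets, "corpus_log")
  manifest$stages$read <- list(n = nrow(tweets))
  if (!is.null(log)) manifest$warnings$read <- log[c("n_bad_lines", "n_outside_window", "n_duplicates")]

  # --- group --------------------------------------------------------------
  grouped <- tryCatch(group_corpus(tweets, config$keywords),
                      error = function(e) stage_fail("group", conditionMessage(e)))
  manifest$stages$group <- list(
    n = nrow(grouped),
    n_target = sum(grouped$group == "TARGET"),
    n_rt_group = sum(grouped$group == "RT_GROUP"))

  # --- score --------------------------------------------------------------
  scored <- tryCatch({
    lex <- load_lexicon(config$lexicon_path, masked = config$masked)
    gaz <- load_gazetteer(config$gazetteer_path)
    tok <- builtin_tokenizer(tokenizer_vocabulary(lex, gaz))
    score_corpus(grouped, lex, tok, count_all = config$count_all)
  }, error = function(e) stage_fail("sentiment", conditionMessage(e)))
  manifest$stages$score <- list(n = nrow(scored),
                                n_zero_wc = sum(scored$w_c == 0))

  # --- geoparse -----------------------------------------------------------
  geo <- tryCatch({
    gaz <- load_gazetteer(config$gazetteer_path)
    lex <- load_lexicon(config$lexicon_path, masked = config$masked)
    tok <- builtin_tokenizer(tokenizer_vocabulary(lex, gaz))
    postal <- load_prefix_table(config$postal_path)
    phone <- load_prefix_table(config$phone_path)
    geoparse_corpus(scored, gaz, postal, phone, tok)
  }, error = function(e) stage_fail("geoparse", conditionMessage(e)))
  n_geo <- sum(lengths(geo$prefectures) > 0)
  manifest$stages$geoparse <- list(n = nrow(geo), n_geolocated = n_geo)

  # --- aggregate ----------------------------------------------------------
  out <- tryCatch({
    daily <- bucketize(geo, "day", window = config$window)
    daily_group <- bucketize(geo, "day", by_group = TRUE, window = config$window)
    cum <- cumulative_series(daily)
    weekly_group <- bucketize(geo, "week", by_group = TRUE, window = config$window)
    weekly_region_group <- bucketize(geo, "week", by_group = TRUE,
                                     region = "fukushima", window = config$window)
    ftests <- ftest_by_week(geo, alpha = config$alpha, mode = config$ftest_mode,
                            window = config$window)
    ratios <- weekly_ratio_series(geo, window = config$window)
    pop <- load_population_table(config$population_path)
    pref_table <- prefecture_breakdown(geo, pop)

    trend_rows <- list()
    add_trend <- function(name, t, v) {
      ok <- !is.na(v)
      if (sum(ok) >= 2 && length(unique(t[ok])) >= 2) {
        f <- fit_trend(t[ok], v[ok])
        tibble::tibble(series = name, slope = f$slope, intercept = f$intercept,
                       stderr_slope = f$stderr_slope, n_points = f$n_points)
      } else NULL
    }
    trend_rows[[1]] <- add_trend("daily_count", as.numeric(daily$bucket), daily$n)
    trend_rows[[2]] <- add_trend("daily_mean_tpn", as.numeric(daily$bucket), daily$mean_tpn)
    wt <- weekly_group[weekly_group$group == "TARGET", ]
    trend_rows[[3]] <- add_trend("weekly_mean_tpn_target", as.numeric(wt$bucket), wt$mean_tpn)
    wr <- weekly_group[weekly_group$group == "RT_GROUP", ]
    trend_rows[[4]] <- add_trend("weekly_mean_tpn_rt", as.numeric(wr$bucket), wr$mean_tpn)
    trend_rows[[5]] <- add_trend("weekly_count_ratio", as.numeric(ratios$week), ratios$count_ratio)
    trend_rows[[6]] <- add_trend("weekly_shifted_mean_ratio", as.numeric(ratios$week),
                                 ratios$shifted_mean_ratio)
    for (g in c("TARGET", "RT_GROUP")) {
      for (r in c("Fukushima", "Others")) {
        s <- weekly_region_group[weekly_region_group$group == g &
                                   weekly_region_group$region == r, ]
        trend_rows[[length(trend_rows) + 1]] <-
          add_trend(paste0("weekly_mean_tpn_", tolower(g), "_", tolower(r)),
                    as.numeric(s$bucket), s$mean_tpn)
      }
    }
    trends <- dplyr::bind_rows(trend_rows)
    list(daily = daily, daily_group = daily_group, cumulative = cum,
         weekly_group = weekly_group, weekly_region_group = weekly_region_group,
         ftests = ftests, ratios = ratios, prefecture_table = pref_table,
         trends = trends)
  }, error = function(e) stage_fail("aggregate", conditionMessage(e)))
  manifest$stages$aggregate <- list(
    n_daily_cells = nrow(out$daily), n_weekly_cells = nrow(out$weekly_group),
    n_ftest_weeks = nrow(out$ftests))

  # --- write --------------------------------------------------------------
  grouped_counts <- dplyr::count(grouped, .data$group, .data$rt_reason, name = "n")
  write_table(grouped_counts, file.path(config$out_dir, "grouped.csv"))
  write_table(out$daily, file.path(config$out_dir, "daily_stats.csv"))
  write_table(out$daily_group, file.path(config$out_dir, "daily_group_stats.csv"))
  write_table(out$cumulative, file.path(config$out_dir, "cumulative.csv"))
  write_table(out$weekly_group, file.path(config$out_dir, "weekly_group_stats.csv"))
  write_table(out$weekly_region_group, file.path(config$out_dir, "weekly_region_group_stats.csv"))
  write_table(out$ftests, file.path(config$out_dir, "weekly_ftest.csv"))
  write_table(out$ratios, file.path(config$out_dir, "weekly_ratios.csv"))
  write_table(out$prefecture_table, file.path(config$out_dir, "prefecture_table.csv"))
  write_table(out$trends, file.path(config$out_dir, "trends.csv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(c(list(tweets = tweets, grouped = grouped, scored = scored, geo = geo,
                   manifest = manifest), out))
}
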