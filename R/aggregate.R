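#' Assign time buckets in JST
#'
#' `day` and `minute` buckets are calendar-aligned in JST; `week` buckets
#' are 7-day half-open intervals anchored at the study-window start (not
#' ISO calendar weeks), so week 0 starts at the event.
#'
#' @param timestamp POSIXct vector.
#' @param granularity `"day"`, `"week"` or `"minute"`.
#' @param window A [study_window()] (anchors weekly buckets).
#' @return For `day`, a `Date`; for `minute`, a POSIXct floored to the
#'   minute; for `week`, an integer week index (0-based from the window
#'   start).
#' @export
time_bucket <- function(timestamp, granularity = c("day", "week", "minute"),
                        window = study_window()) {
  granularity <- match.arg(granularity)
  t <- lubridate::with_tz(timestamp, RADSENT_TZ)
  switch(granularity,
    day = lubridate::as_date(t, tz = RADSENT_TZ),
    minute = lubridate::floor_date(t, "minute"),
    week = as.integer(floor(as.numeric(difftime(t, window$start, units = "days")) / 7))
  )
}

week_start_date <- function(week, window = study_window()) {
  lubridate::as_date(window$start, tz = RADSENT_TZ) + 7L * week
}

#' Bucketed counts and sentiment statistics
#'
#' Produces one row per occupied (bucket x group x region) cell with the
#' tweet count, the sum of semantic-orientation values and their mean.
#' Empty cells are omitted — a missing mean is reported as missing, never
#' as 0, since 0 is a meaningful sentiment value.
#'
#' @param scored Tibble with `timestamp`, `t_pn`, and (as needed) `group`
#'   and `prefectures`.
#' @param granularity `"day"`, `"week"` or `"minute"`.
#' @param by_group Stratify by target/RT group.
#' @param region `"none"` (ignore geography), `"prefecture"` (explode the
#'   multi-label prefecture sets; a tweet contributes to each matched
#'   prefecture), or `"fukushima"` (two sides: `Fukushima` vs `Others` =
#'   any concrete non-Fukushima prefecture; `Other`-only tweets are not a
#'   prefecture and are excluded; a tweet matching both sides contributes
#'   to both).
#' @param window Study window anchoring weekly buckets.
#' @return Tibble with `bucket`, optional `group`/`region`, `n`, `sum_tpn`,
#'   `mean_tpn`.
#' @export
bucketize <- function(scored, granularity = c("day", "week", "minute"),
                      by_group = FALSE, region = c("none", "prefecture", "fukushima"),
                      window = study_window()) {
  granularity <- match.arg(granularity)
  region <- match.arg(region)
  df <- tibble::tibble(bucket = time_bucket(scored$timestamp, granularity, window),
                       t_pn = scored$t_pn)
  if (by_group) df$group <- scored$group
  if (region != "none") {
    stopifnot(!is.null(scored$prefectures))
    prefs <- scored$prefectures
    lens <- lengths(prefs)
    df$.tweet <- seq_len(nrow(df))
    idx <- rep.int(seq_len(nrow(df)), lens)
    df <- df[idx, , drop = FALSE]
    df$region <- unlist(prefs, use.names = FALSE)
    if (region == "fukushima") {
      df <- df[df$region != "Other", , drop = FALSE]
      df$region <- ifelse(df$region == "Fukushima", "Fukushima", "Others")
      # a tweet naming several non-Fukushima prefectures counts once on the
      # Others side
      df <- df[!duplicated(df[c(".tweet", "region")]), , drop = FALSE]
    }
    df$.tweet <- NULL
  }
  keys <- intersect(c("bucket", "group", "region"), names(df))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(), sum_tpn = sum(.data$t_pn),
                     mean_tpn = mean(.data$t_pn), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  out
}

#' Cumulative (integrated) daily sentiment
#'
#' Running prefix sum of the per-bucket `sum_tpn`, the "daily integration"
#' view of sentiment drift.
#'
#' @param daily A [bucketize()] table (single stratum), sorted by bucket.
#' @return Tibble with `bucket` and `cum_sum_tpn`.
#' @export
cumulative_series <- function(daily) {
  daily <- dplyr::arrange(daily, .data$bucket)
  tibble::tibble(bucket = daily$bucket, cum_sum_tpn = cumsum(daily$sum_tpn))
}

#' Fukushima-to-others tweet count ratio
#'
#' @param n_fukushima,n_others Tweet counts for the two sides.
#' @return `n_fukushima / n_others`; `NA` (with a message) when
#'   `n_others == 0`.
#' @export
count_ratio <- function(n_fukushima, n_others) {
  out <- ifelse(n_others > 0, n_fukushima / n_others, NA_real_)
  if (any(n_others == 0)) message("count_ratio: undefined for ", sum(n_others == 0),
                                  " bucket(s) with zero 'others' count")
  out
}

#' +1-shifted mean sentiment ratio
#'
#' Semantic-orientation means lie in \[-1, 1\], so both means are shifted by
#' +1 before taking the ratio: `(mean_f + 1) / (mean_o + 1)`. Note the
#' ratio is unbounded above as `mean_o` approaches -1 (it is not confined
#' to \[0, 2\], despite the intuition that shifted means lie in \[0, 2\]);
#' the true ratio is returned undamped. Undefined when `mean_o == -1`.
#'
#' @param mean_f,mean_o Mean semantic-orientation values of the two sides.
#' @return The shifted ratio, `NA` where undefined.
#' @export
shifted_mean_ratio <- function(mean_f, mean_o) {
  ifelse(mean_o == -1, NA_real_, (mean_f + 1) / (mean_o + 1))
}

#' Ordinary least squares trend line
#'
#' The dashed "linear approximation" drawn through a bucketed series.
#'
#' @param t Numeric time index (e.g. week number); at least two distinct
#'   values.
#' @param value Series values; missing pairs are dropped.
#' @return A list of class `trend_fit`: `slope`, `intercept`,
#'   `stderr_slope`, `n_points`.
#' @export
fit_trend <- function(t, value) {
  keep <- !is.na(t) & !is.na(value)
  t <- t[keep]; value <- value[keep]
  if (length(t) < 2) stop("need at least 2 points", call. = FALSE)
  if (length(unique(t)) < 2) stop("need at least 2 distinct time points", call. = FALSE)
  fit <- lm(value ~ t)
  # an exactly collinear series triggers lm's perfect-fit warning; a zero
  # standard error is the correct report for it
  co <- suppressWarnings(summary(fit)$coefficients)
  structure(list(slope = unname(co["t", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 stderr_slope = unname(co["t", "Std. Error"]),
                 n_points = length(t)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.6g (se %.3g), intercept %.6g, n = %d\n",
              x$slope, x$stderr_slope, x$intercept, x$n_points))
  invisible(x)
}

#' Weekly F test between two groups of tweet scores
#'
#' Default mode is a one-way between-groups ANOVA on the two samples
#' (`df1 = 1`, `df2 = n_a + n_b - 2`), testing divergence of the group
#' means; `"var_ratio"` mode instead tests equality of variances with
#' `F = s_a^2 / s_b^2` on (`n_a - 1`, `n_b - 1`) degrees of freedom
#' (two-sided p). A group with fewer than 2 observations yields a missing
#' result.
#'
#' @param scores_a,scores_b Numeric vectors of tweet-level scores.
#' @param alpha Significance level (default 0.05).
#' @param mode `"anova"` or `"var_ratio"`.
#' @return A list: `f_stat`, `df1`, `df2`, `p_value`, `significant`; all
#'   `NA` when a group is too small.
#' @export
#' @examples
#' weekly_f_test(c(0, 0.2), c(1.0, 1.2))
weekly_f_test <- function(scores_a, scores_b, alpha = 0.05,
                          mode = c("anova", "var_ratio")) {
  mode <- match.arg(mode)
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  na <- length(scores_a); nb <- length(scores_b)
  if (na < 2 || nb < 2) {
    return(list(f_stat = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p_value = NA_real_, significant = NA))
  }
  if (mode == "anova") {
    grand <- (sum(scores_a) + sum(scores_b)) / (na + nb)
    ssb <- na * (mean(scores_a) - grand)^2 + nb * (mean(scores_b) - grand)^2
    ssw <- sum((scores_a - mean(scores_a))^2) + sum((scores_b - mean(scores_b))^2)
    df1 <- 1L; df2 <- na + nb - 2L
    f <- if (ssw == 0) {
      if (ssb == 0) 0 else Inf
    } else (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
    if (ssb == 0 && ssw == 0) p <- 1
  } else {
    df1 <- na - 1L; df2 <- nb - 1L
    va <- var(scores_a); vb <- var(scores_b)
    f <- if (vb == 0) ifelse(va == 0, 1, Inf) else va / vb
    p_one <- pf(f, df1, df2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_one, 1 - p_one))
  }
  list(f_stat = f, df1 = df1, df2 = df2, p_value = p, significant = p < alpha)
}

#' Weekly F tests across a grouped, scored corpus
#'
#' Runs [weekly_f_test()] per week between the target group and the RT
#' group.
#'
#' @param scored A scored corpus with `timestamp`, `group`, `t_pn`.
#' @param alpha Significance level.
#' @param mode See [weekly_f_test()].
#' @param window Study window anchoring weeks.
#' @return Tibble with one row per week: `week`, `week_start`, `n_target`,
#'   `n_rt`, `f_stat`, `df1`, `df2`, `p_value`, `significant`.
#' @export
ftest_by_week <- function(scored, alpha = 0.05, mode = c("anova", "var_ratio"),
                          window = study_window()) {
  mode <- match.arg(mode)
  wk <- time_bucket(scored$timestamp, "week", window)
  weeks <- sort(unique(wk))
  rows <- lapply(weeks, function(w) {
    a <- scored$t_pn[wk == w & scored$group == "TARGET"]
    b <- scored$t_pn[wk == w & scored$group == "RT_GROUP"]
    r <- weekly_f_test(a, b, alpha = alpha, mode = mode)
    tibble::tibble(week = w, week_start = week_start_date(w, window),
                   n_target = length(a), n_rt = length(b),
                   f_stat = r$f_stat, df1 = r$df1, df2 = r$df2,
                   p_value = r$p_value, significant = r$significant)
  })
  dplyr::bind_rows(rows)
}

#' Weekly Fukushima-versus-others ratio series
#'
#' For each week: the count ratio and the +1-shifted mean-sentiment ratio
#' between tweets about Fukushima Prefecture and tweets about other
#' prefectures (see [bucketize()] for side definitions).
#'
#' @param geo A geoparsed, scored corpus (needs `timestamp`, `t_pn`,
#'   `prefectures`).
#' @param window Study window anchoring weeks.
#' @return Tibble: `week`, `week_start`, `n_fukushima`, `n_others`,
#'   `count_ratio`, `mean_fukushima`, `mean_others`, `shifted_mean_ratio`.
#' @export
weekly_ratio_series <- function(geo, window = study_window()) {
  wk <- bucketize(geo, "week", by_group = FALSE, region = "fukushima", window = window)
  wide <- tidyr::pivot_wider(wk, id_cols = "bucket", names_from = "region",
                             values_from = c("n", "mean_tpn"))
  for (col in c("n_Fukushima", "n_Others", "mean_tpn_Fukushima", "mean_tpn_Others")) {
    if (!col %in% names(wide)) wide[[col]] <- if (startsWith(col, "n_")) 0L else NA_real_
  }
  wide$n_Fukushima[is.na(wide$n_Fukushima)] <- 0L
  wide$n_Others[is.na(wide$n_Others)] <- 0L
  tibble::tibble(
    week = wide$bucket,
    week_start = week_start_date(wide$bucket, window),
    n_fukushima = wide$n_Fukushima,
    n_others = wide$n_Others,
    count_ratio = suppressMessages(count_ratio(wide$n_Fukushima, wide$n_Others)),
    mean_fukushima = wide$mean_tpn_Fukushima,
    mean_others = wide$mean_tpn_Others,
    shifted_mean_ratio = shifted_mean_ratio(wide$mean_tpn_Fukushima, wide$mean_tpn_Others)
  )
}

#' Percentage share of a subcount
#'
#' @param subcount,total Counts with `0 <= subcount <= total`, `total > 0`.
#' @return `100 * subcount / total`, rounded to 2 decimals.
#' @export
#' @examples
#' share_of_total(1797, 34173)
share_of_total <- function(subcount, total) {
  stopifnot(all(total > 0), all(subcount <= total), all(subcount >= 0))
  round(100 * subcount / total, 2)
}
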