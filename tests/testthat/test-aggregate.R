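scored_fixture <- function(n = 200, seed = 3) {
  set.seed(seed)
  w <- study_window()
  tibble::tibble(
    timestamp = w$start + floor(runif(n, 0, 20 * 86400)),
    group = sample(c("TARGET", "RT_GROUP"), n, replace = TRUE),
    t_pn = round(runif(n, -1, 1), 3),
    prefectures = lapply(seq_len(n), function(i) {
      k <- sample(0:2, 1, prob = c(0.4, 0.45, 0.15))
      sample(c("Fukushima", "Tokyo", "Osaka", "Other"), k)
    })
  )
}

test_that("bucketize aggregates counts, sums and means per cell", {
  w <- study_window()
  df <- tibble::tibble(
    timestamp = w$start + c(3600, 7200, 10000, 90000),
    group = "TARGET",
    t_pn = c(0, 0.3, -0.3, 0.5))
  day <- bucketize(df, "day")
  expect_equal(day$n, c(3L, 1L))
  expect_equal(day$mean_tpn, c(0, 0.5))
  expect_equal(day$sum_tpn, c(0, 0.5))
  # single tweet cell keeps its own score as the mean
  expect_equal(day$mean_tpn[2], df$t_pn[4])
})

test_that("bucket conservation: weekly cell counts sum to the corpus size", {
  df <- scored_fixture(500)
  wk <- bucketize(df, "week")
  expect_equal(sum(wk$n), 500L)
  byg <- bucketize(df, "week", by_group = TRUE)
  expect_equal(sum(byg$n), 500L)
  day <- bucketize(df, "day")
  expect_equal(sum(day$n), 500L)
})

test_that("weekly mean equals the n-weighted mean of daily means", {
  df <- scored_fixture(800, seed = 9)
  day <- bucketize(df, "day")
  wk <- bucketize(df, "week")
  w <- study_window()
  day$week <- as.integer(floor(as.numeric(difftime(
    as.POSIXct(paste(day$bucket, "12:00:00"), tz = "Asia/Tokyo"), w$start,
    units = "days")) / 7))
  for (wx in unique(day$week)) {
    d <- day[day$week == wx, ]
    expect_equal(wk$mean_tpn[wk$bucket == wx],
                 sum(d$mean_tpn * d$n) / sum(d$n), tolerance = 1e-12)
  }
})

test_that("minute buckets floor to the JST minute", {
  w <- study_window()
  df <- tibble::tibble(timestamp = w$start + c(59, 60, 61), t_pn = c(1, 0, -1))
  mn <- bucketize(df, "minute")
  expect_equal(mn$n, c(1L, 2L))
})

test_that("fukushima split excludes Other and deduplicates sides per tweet", {
  w <- study_window()
  df <- tibble::tibble(
    timestamp = rep(w$start + 3600, 4),
    t_pn = c(0.1, -0.2, 0.4, 0.8),
    prefectures = list(c("Fukushima", "Tokyo"), c("Tokyo", "Osaka"),
                       "Other", character(0)))
  wk <- bucketize(df, "week", region = "fukushima")
  f <- wk[wk$region == "Fukushima", ]
  o <- wk[wk$region == "Others", ]
  expect_equal(f$n, 1L)
  expect_equal(o$n, 2L)  # tweet 2 counts once despite two non-Fukushima matches
  expect_equal(o$mean_tpn, mean(c(0.1, -0.2)))
})

test_that("cumulative series is the prefix sum and ends at the total", {
  daily <- tibble::tibble(bucket = as.Date("2011-03-11") + 0:2,
                          sum_tpn = c(-1, -2, 0.5))
  cs <- cumulative_series(daily)
  expect_equal(cs$cum_sum_tpn, c(-1, -3, -2.5))
  zeros <- tibble::tibble(bucket = as.Date("2011-03-11") + 0:4, sum_tpn = rep(0, 5))
  expect_equal(cumulative_series(zeros)$cum_sum_tpn, rep(0, 5))
  set.seed(5)
  rnd <- tibble::tibble(bucket = as.Date("2011-03-11") + 0:49, sum_tpn = rnorm(50))
  expect_equal(dplyr::last(cumulative_series(rnd)$cum_sum_tpn), sum(rnd$sum_tpn),
               tolerance = 1e-12)
})

test_that("count ratio and shifted mean ratio follow their definitions", {
  expect_equal(count_ratio(50, 100), 0.5)
  expect_equal(count_ratio(0, 100), 0)
  expect_equal(count_ratio(77, 77), 1)
  expect_message(expect_true(is.na(count_ratio(5, 0))), "undefined")

  expect_equal(shifted_mean_ratio(-0.3, -0.3), 1)
  expect_equal(shifted_mean_ratio(-1, 0.2), 0)
  expect_equal(shifted_mean_ratio(0, -0.5), 2)
  expect_true(is.na(shifted_mean_ratio(0, -1)))
  # monotone increasing in mean_f, decreasing in mean_o
  mf <- seq(-0.9, 0.9, by = 0.3)
  expect_true(all(diff(shifted_mean_ratio(mf, -0.2)) > 0))
  expect_true(all(diff(shifted_mean_ratio(0.1, mf)) < 0))
  # the ratio exceeds 2 as mean_o approaches -1: it is not confined to [0, 2]
  expect_gt(shifted_mean_ratio(0, -0.9), 2)
})

test_that("trend fit reproduces OLS exactly and flags degenerate input", {
  t <- 0:10
  f <- fit_trend(t, 2 * t + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  f0 <- fit_trend(t, rep(4, 11))
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_error(fit_trend(rep(1, 5), 1:5), "distinct")
  expect_error(fit_trend(1, 1), "2 points")

  # closed-form normal equations as an independent check
  set.seed(21)
  y <- 3 * t + rnorm(11, sd = 0.5)
  f2 <- fit_trend(t, y)
  slope_hat <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(f2$slope, slope_hat, tolerance = 1e-12)

  # recovery: simulated slope 3 within 3 standard errors
  set.seed(22)
  t3 <- 0:99
  f3 <- fit_trend(t3, 3 * t3 + rnorm(100, sd = 0.1))
  expect_lt(abs(f3$slope - 3), 3 * f3$stderr_slope)
})

test_that("two-group ANOVA F matches hand computation and the pooled t^2", {
  r <- weekly_f_test(c(0, 0.2), c(1.0, 1.2))
  expect_equal(r$f_stat, 50, tolerance = 1e-12)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 2L)
  expect_equal(r$p_value, 0.019419, tolerance = 1e-4)
  expect_true(r$significant)

  ident <- weekly_f_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(ident$f_stat, 0)
  expect_equal(ident$p_value, 1)

  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = 0.3)
    r <- weekly_f_test(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$f_stat, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("variance-ratio mode matches var.test", {
  set.seed(32)
  a <- rnorm(20); b <- rnorm(25, sd = 2)
  r <- weekly_f_test(a, b, mode = "var_ratio")
  vt <- var.test(a, b)
  expect_equal(r$f_stat, unname(vt$statistic), tolerance = 1e-12)
  expect_equal(r$df1, 19L)
  expect_equal(r$df2, 24L)
  # upper-tail pf vs 1 - pf differ in the last float digits
  expect_equal(r$p_value, vt$p.value, tolerance = 1e-8)
})

test_that("undersized groups yield missing F results", {
  r <- weekly_f_test(c(0.1), c(0.2, 0.3))
  expect_true(is.na(r$f_stat) && is.na(r$p_value) && is.na(r$significant))
})

test_that("weekly ratio series combines counts and shifted means per week", {
  df <- scored_fixture(600, seed = 13)
  rs <- weekly_ratio_series(df)
  wk <- bucketize(df, "week", region = "fukushima")
  for (i in seq_len(nrow(rs))) {
    nf <- wk$n[wk$bucket == rs$week[i] & wk$region == "Fukushima"]
    no <- wk$n[wk$bucket == rs$week[i] & wk$region == "Others"]
    expect_equal(rs$n_fukushima[i], if (length(nf)) nf else 0L)
    expect_equal(rs$n_others[i], if (length(no)) no else 0L)
    if (length(nf) && length(no)) {
      expect_equal(rs$count_ratio[i], nf / no)
    }
  }
})

test_that("share_of_total reproduces printed percentages to 2 decimals", {
  expect_identical(share_of_total(1797, 34173), 5.26)
  expect_identical(share_of_total(0, 10), 0)
  expect_identical(share_of_total(10, 10), 100)
  expect_error(share_of_total(11, 10))
})
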