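#' Default radiation keyword set
#'
#' The three Japanese terms that define corpus membership: radiation
#' (放射線), radioactivity (放射能) and radioactive
#' substances (放射性物質).
#'
#' @return Character vector of keywords.
#' @export
default_keywords <- function() c("放射線", "放射能", "放射性物質")

#' Keyword filter for corpus membership
#'
#' A tweet belongs to the corpus if its text contains any keyword as a
#' substring. Japanese text has no word boundaries, so substring matching is
#' the appropriate reading; matching is done on the full, untruncated text.
#'
#' @param text Character vector of tweet texts.
#' @param keywords Non-empty character vector of keywords.
#' @return Logical vector.
#' @export
#' @examples
#' keyword_filter(c("今日の放射能ニュース", "地震と津波"))
keyword_filter <- function(text, keywords = default_keywords()) {
  stopifnot(length(keywords) > 0)
  hit <- rep(FALSE, length(text))
  for (kw in keywords) hit <- hit | stringi::stri_detect_fixed(text, kw)
  hit & !is.na(text)
}

# "RT @..."/"QT @..." prefix of 2011-era clients; tolerates leading
# whitespace and the full-width colon.
RT_PREFIX_RE <- "^[\\s\\u3000]*(RT|QT)[\\s@:\\uFF1A]"

#' Classify a tweet into the target group or the RT group
#'
#' The RT group pools (a) bot accounts, detected by the handle beginning or
#' ending with "bot" (case-insensitive, literal prefix/suffix — so
#' "botanist" counts but "robotics_fan" does not; a documented
#' false-positive source of the heuristic), and (b) tweets whose text starts
#' with an RT or QT repost marker. The bot rule is checked first. Everything
#' else is the target group, taken to express the poster's own feeling.
#'
#' @param user_id Character vector of account handles.
#' @param text Character vector of tweet texts.
#' @return A tibble with columns `group` (`"TARGET"` or `"RT_GROUP"`) and
#'   `rt_reason` (`NA`, `"BOT_ACCOUNT"`, `"STARTS_WITH_RT"` or
#'   `"STARTS_WITH_QT"`).
#' @export
#' @examples
#' classify_group("news_bot", "放射線...")
#' classify_group("alice", "RT @bob: 放射線...")
classify_group <- function(user_id, text) {
  n <- max(length(user_id), length(text))
  user_id <- rep_len(as.character(user_id), n)
  text <- rep_len(as.character(text), n)
  lc <- stringi::stri_trans_tolower(user_id)
  is_bot <- startsWith(lc, "bot") | endsWith(lc, "bot")
  m <- stringi::stri_match_first_regex(text, RT_PREFIX_RE, case_insensitive = TRUE)
  marker <- stringi::stri_trans_toupper(m[, 2])
  is_rt <- !is_bot & !is.na(marker) & marker == "RT"
  is_qt <- !is_bot & !is.na(marker) & marker == "QT"
  group <- ifelse(is_bot | is_rt | is_qt, "RT_GROUP", "TARGET")
  reason <- rep(NA_character_, n)
  reason[is_bot] <- "BOT_ACCOUNT"
  reason[is_rt] <- "STARTS_WITH_RT"
  reason[is_qt] <- "STARTS_WITH_QT"
  tibble::tibble(group = group, rt_reason = reason)
}

#' Truncate an inline repost from a target-group tweet
#'
#' A target-group tweet of the form "comment RT @user: original" quotes
#' someone else's words after the marker; everything from the first inline
#' `RT @`/`QT @` marker onwards is removed so that scoring reflects only the
#' original poster's comment. Texts without a marker are returned unchanged;
#' the operation is idempotent.
#'
#' @param text Character vector (texts of target-group tweets).
#' @return Character vector of truncated texts.
#' @export
#' @examples
#' truncate_inline_rt("同意です RT @x: 放射能が...")
truncate_inline_rt <- function(text) {
  pos <- stringi::stri_locate_first_regex(text, "(RT|QT)\\s*@", case_insensitive = TRUE)[, 1]
  out <- text
  hit <- !is.na(pos)
  out[hit] <- substr(text[hit], 1L, pos[hit] - 1L)
  out
}

#' Apply the corpus-definition rules to a tweet table
#'
#' Filters to keyword-matching tweets, classifies each into the target or RT
#' group, and adds `clean_text`: target tweets are truncated at the first
#' inline repost marker; RT-group texts are kept whole (their leading marker
#' is stripped later, at scoring time). The keyword filter is applied to the
#' full text before truncation, so a tweet whose only keyword sits in the
#' quoted tail is retained; this choice is deliberate and documented.
#'
#' @param tweets Tibble with at least `user_id` and `text`.
#' @param keywords Keyword set, see [default_keywords()].
#' @return The keyword-matching rows with added columns `group`, `rt_reason`
#'   and `clean_text`.
#' @export
group_corpus <- function(tweets, keywords = default_keywords()) {
  keep <- keyword_filter(tweets$text, keywords)
  out <- tweets[keep, , drop = FALSE]
  cls <- classify_group(out$user_id, out$text)
  out$group <- cls$group
  out$rt_reason <- cls$rt_reason
  out$clean_text <- out$text
  tgt <- out$group == "TARGET"
  out$clean_text[tgt] <- truncate_inline_rt(out$text[tgt])
  out
}
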