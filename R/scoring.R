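#' Construct a comment stream
#'
#' A time-stamped comment stream for one video. Timestamps are seconds from
#' video onset and must satisfy `0 <= timestamp_s < duration_s`.
#'
#' @param video_id Identifier (coerced to character).
#' @param duration_s Positive integer video duration in seconds.
#' @param comments Data frame with columns `timestamp_s` (numeric) and
#'   `text` (character). May have zero rows.
#' @return Object of class `comment_stream`.
#' @export
comment_stream <- function(video_id, duration_s, comments) {
  duration_s <- as.integer(duration_s)
  if (is.na(duration_s) || duration_s < 1L)
    stop("duration_s must be a positive integer number of seconds")
  if (!is.data.frame(comments) ||
      !all(c("timestamp_s", "text") %in% names(comments)))
    stop("comments needs columns 'timestamp_s' and 'text'")
  ts <- comments$timestamp_s
  if (length(ts) && (any(!is.finite(ts)) || any(ts < 0) || any(ts >= duration_s)))
    stop("comment timestamps must satisfy 0 <= t < duration_s")
  structure(list(video_id = as.character(video_id),
                 duration_s = duration_s,
                 comments = data.frame(timestamp_s = as.numeric(ts),
                                       text = as.character(comments$text),
                                       stringsAsFactors = FALSE)),
            class = "comment_stream")
}

#' @export
print.comment_stream <- function(x, ...) {
  cat(sprintf("<comment_stream> video '%s': %d s, %d comments\n",
              x$video_id, x$duration_s, nrow(x$comments)))
  invisible(x)
}

# Greedy longest-match of lexicon terms in a vector of texts.
# Returns a list (one element per text) of matched terms in order.
# Implemented as a PCRE alternation with alternatives sorted by decreasing
# length: the regex engine tries alternatives in order at the leftmost
# matching position and gregexpr returns successive non-overlapping
# matches, which is exactly the left-to-right greedy longest-match scan.
match_lexicon <- function(texts, dict) {
  terms <- c(names(dict$entries), dict$negators, names(dict$degree_words))
  if (!length(terms)) return(rep(list(character(0)), length(texts)))
  terms <- terms[order(-nchar(terms))]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", terms)
  pat <- paste0("(?:", paste(esc, collapse = "|"), ")")
  m <- gregexpr(pat, texts, perl = TRUE)
  Map(function(txt, mm) {
    if (mm[1] == -1L) return(character(0))
    substring(txt, mm, mm + attr(mm, "match.length") - 1L)
  }, texts, m, USE.NAMES = FALSE)
}

# Turn an ordered term sequence into scored tokens. Modifiers (negators and
# degree words) matched since the last entry term compose multiplicatively
# and attach to the next entry term; trailing modifiers contribute nothing.
tokens_from_terms <- function(terms, dict) {
  out_term <- character(0); out_score <- integer(0); out_w <- numeric(0)
  pend <- 1
  for (tm in terms) {
    if (tm %in% dict$negators) {
      pend <- pend * -1
    } else if (tm %in% names(dict$degree_words)) {
      pend <- pend * dict$degree_words[[tm]]
    } else {
      out_term <- c(out_term, tm)
      out_score <- c(out_score, dict$entries[[tm]])
      out_w <- c(out_w, pend)
      pend <- 1
    }
  }
  data.frame(term = out_term, dict_score = out_score, weight = out_w,
             stringsAsFactors = FALSE)
}

#' Tokenize one comment against the dictionary
#'
#' Scans the text left to right with greedy longest-match against the union
#' of all lexicon terms (entries, negators, degree words); unmatched spans
#' are skipped. Each matched entry term becomes a scored token whose weight
#' is the product of the effects of the modifier terms matched before it
#' (since the last entry term): a negator multiplies the weight by -1, a
#' degree word by its multiplier. Modifiers not followed by an entry term
#' contribute nothing.
#'
#' @param text Character scalar.
#' @param dict An `emotion_dictionary`.
#' @return Data frame with columns `term`, `dict_score`, `weight` (zero rows
#'   when nothing matches).
#' @examples
#' d <- build_dictionary(c(touching = 2L), negators = "not")
#' tokenize_comment("not very touching", d)
#' @export
tokenize_comment <- function(text, dict) {
  validate_dictionary(dict)
  stopifnot(is.character(text), length(text) == 1L)
  tokens_from_terms(match_lexicon(text, dict)[[1]], dict)
}

#' Score a comment stream second by second
#'
#' Comments are binned into non-overlapping 1-s windows `[i, i+1)` by
#' timestamp. The raw score of second `i` is the sum over all scored tokens
#' of all comments in that window of `weight * dict_score`, divided by `N`,
#' the total number of comments in the whole video. Seconds with no
#' comments score 0; a video with no comments at all yields an all-zero
#' series.
#'
#' @param stream A `comment_stream`.
#' @param dict An `emotion_dictionary`.
#' @return A `score_series` (raw) with one value per second of the video.
#' @export
score_seconds <- function(stream, dict) {
  stopifnot(inherits(stream, "comment_stream"))
  validate_dictionary(dict)
  n_sec <- stream$duration_s
  score <- numeric(n_sec)
  N <- nrow(stream$comments)
  if (N > 0L) {
    sec <- floor(stream$comments$timestamp_s) + 1L  # 1-based window index
    toks <- match_lexicon(stream$comments$text, dict)
    flat <- unlist(toks, use.names = FALSE)
    cid <- rep.int(seq_len(N), lengths(toks))
    contrib <- numeric(N)
    if (length(flat)) {
      tok_score <- dict$entries[flat]          # NA for modifier terms
      is_entry <- !is.na(tok_score)
      # segment = (comment, run of modifiers up to and including the next
      # entry term); the entry term's weight is the product of the
      # modifier effects in its segment
      eb <- cumsum(is_entry) - is_entry        # entries before each token
      key <- eb * (N + 1) + cid
      mval <- rep(1, length(flat))
      is_neg <- !is_entry & flat %in% dict$negators
      mval[is_neg] <- -1
      is_deg <- !is_entry & !is_neg
      if (any(is_deg)) mval[is_deg] <- dict$degree_words[flat[is_deg]]
      logs <- rowsum(log(abs(mval)), key)
      negs <- rowsum(as.numeric(mval < 0), key)
      wseg <- exp(logs[, 1L]) * (-1)^negs[, 1L]
      w <- wseg[match(key[is_entry], as.numeric(rownames(logs)))]
      sums <- rowsum(w * as.numeric(tok_score[is_entry]), cid[is_entry])
      contrib[as.integer(rownames(sums))] <- sums[, 1L]
    }
    sums <- rowsum(contrib, sec)
    score[as.integer(rownames(sums))] <- sums[, 1L]
    score <- score / N
  }
  score_series(score, data.frame(video_id = stream$video_id,
                                 start = 1L, length = n_sec),
               normalized = "raw")
}

#' Per-second score series
#'
#' Container for a per-second emotion score vector, possibly concatenated
#' over several videos.
#'
#' @param score Numeric vector, one value per second.
#' @param videos Data frame with columns `video_id`, `start` (1-based index
#'   into `score`), `length`.
#' @param normalized One of `"raw"` or `"z"`.
#' @return Object of class `score_series`.
#' @export
score_series <- function(score, videos, normalized = "raw") {
  stopifnot(is.numeric(score), all(is.finite(score)))
  if (!is.data.frame(videos) ||
      !all(c("video_id", "start", "length") %in% names(videos)))
    stop("videos needs columns video_id, start, length")
  if (sum(videos$length) != length(score))
    stop("sum of video lengths must equal length(score)")
  normalized <- match.arg(normalized, c("raw", "z"))
  structure(list(score = as.numeric(score), videos = videos,
                 normalized = normalized),
            class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("<score_series> %d s over %d video(s), %s\n",
              length(x$score), nrow(x$videos), x$normalized))
  invisible(x)
}

#' Concatenate raw score series and z-score across videos
#'
#' Inter-video normalization: the per-second raw scores of all videos are
#' concatenated and z-scored jointly over all 1-s segments, so different
#' videos live on a unified scale. The population SD convention (divide by
#' n) is used, so the output has mean exactly 0 and SD exactly 1.
#'
#' @param series_list A single raw `score_series` or a list of them.
#' @return A z-scored `score_series` carrying attributes `center` and
#'   `scale` (the affine map back to the raw concatenation).
#' @export
zscore_across_videos <- function(series_list) {
  if (inherits(series_list, "score_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, logical(1), "score_series")))
  if (any(vapply(series_list, function(s) s$normalized, character(1)) != "raw"))
    stop("inputs must be raw score series")
  x <- unlist(lapply(series_list, `[[`, "score"), use.names = FALSE)
  if (length(x) < 2L) stop("need at least 2 segments to z-score")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) stop("zero variance: degenerate tagging, cannot z-score")
  vids <- do.call(rbind, lapply(series_list, `[[`, "videos"))
  vids$start <- cumsum(c(1L, head(vids$length, -1L)))
  out <- score_series((x - mu) / sdev, vids, normalized = "z")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdev
  out
}

#' Optional moving-average smoothing of a score series
#'
#' Centered moving average of odd width; no smoothing is applied anywhere
#' by default.
#'
#' @param series A `score_series`.
#' @param width_s Odd positive integer window width in seconds (1 = no-op).
#' @return A `score_series` of the same length and normalization flag.
#' @export
smooth_score_series <- function(series, width_s = 1L) {
  stopifnot(inherits(series, "score_series"))
  width_s <- as.integer(width_s)
  if (width_s < 1L || width_s %% 2L == 0L)
    stop("width_s must be an odd positive integer")
  if (width_s == 1L) return(series)
  k <- (width_s - 1L) %/% 2L
  x <- series$score
  n <- length(x)
  sm <- vapply(seq_len(n), function(i)
    mean(x[max(1L, i - k):min(n, i + k)]), numeric(1))
  out <- series
  out$score <- sm
  out
}

#' Compare a danmaku score series with a continuous self-report trace
#'
#' Pearson correlation (with two-sided p-value) between the per-second
#' danmaku-derived scores and a per-second self-report trace (the mean of
#' the raters' sliding-bar traces, already resampled to 1 value/s).
#'
#' @param danmaku A `score_series` or numeric vector.
#' @param selfreport Numeric vector of equal length.
#' @return List with elements `r`, `p`, `n`.
#' @export
compare_with_selfreport <- function(danmaku, selfreport) {
  x <- if (inherits(danmaku, "score_series")) danmaku$score else danmaku
  y <- as.numeric(selfreport)
  if (length(x) != length(y)) stop("length mismatch between series")
  if (length(x) < 3L) stop("need at least 3 paired seconds")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one of the series")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
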