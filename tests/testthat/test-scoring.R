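test_that("tokenizer applies greedy longest match and modifier composition", {
  d <- tiny_dictionary()
  tk <- tokenize_comment("very touching", d)
  expect_identical(tk$term, "touching")
  expect_identical(tk$dict_score, 2L)
  expect_equal(tk$weight, 1.5)

  expect_identical(nrow(tokenize_comment("zzz qqq", d)), 0L)

  tk <- tokenize_comment("not touching", d)
  expect_equal(tk$weight, -1)

  tk <- tokenize_comment("not very touching", d)
  expect_equal(tk$weight, -1.5)

  # exactly one entry term -> one token with weight 1
  tk <- tokenize_comment("touching", d)
  expect_identical(nrow(tk), 1L)
  expect_equal(tk$weight, 1)

  # multi-word modifier and trailing modifier contributing nothing
  tk <- tokenize_comment("a little nice but very", d)
  expect_equal(tk$weight, 0.75)
  expect_identical(tk$term, "nice")

  # longest match wins over embedded shorter terms
  d2 <- build_dictionary(c(warm = 1L, heartwarming = 2L))
  tk <- tokenize_comment("heartwarming", d2)
  expect_identical(tk$term, "heartwarming")
})

test_that("per-second scores follow the weighted sum over the video total N", {
  d <- tiny_dictionary()
  # second 0 holds (score 2, w 1) and (score 1, w 1.5); 98 inert fillers
  filler <- data.frame(timestamp_s = seq(2, 97.9, length.out = 98),
                       text = "zzz")
  cm <- rbind(data.frame(timestamp_s = c(0.1, 0.9),
                         text = c("touching", "very nice")),
              filler)
  s <- score_seconds(comment_stream("v", 100L, cm), d)
  expect_equal(s$score[1], (2 * 1 + 1 * 1.5) / 100)
  expect_equal(s$score[2], 0)          # no comments that second
  expect_length(s$score, 100L)

  # all comments scoring 0 -> all-zero series
  s0 <- score_seconds(comment_stream("v", 4L,
          data.frame(timestamp_s = c(0.5, 2.2), text = "meh")), d)
  expect_identical(s0$score, rep(0, 4))
})

test_that("scores are invariant to doubling all comments and to order", {
  d <- tiny_dictionary()
  cm <- data.frame(timestamp_s = c(0.2, 0.7, 1.5, 3.1),
                   text = c("touching", "not nice", "very touching", "meh"))
  s1 <- score_seconds(comment_stream("v", 5L, cm), d)
  s2 <- score_seconds(comment_stream("v", 5L, rbind(cm, cm)), d)
  expect_equal(s2$score, s1$score)
  s3 <- score_seconds(comment_stream("v", 5L, cm[sample(4), ]), d)
  expect_equal(s3$score, s1$score)
})

test_that("timestamps at integer boundaries fall into the later window", {
  d <- tiny_dictionary()
  s <- score_seconds(comment_stream("v", 3L,
         data.frame(timestamp_s = 1.0, text = "touching")), d)
  expect_equal(s$score, c(0, 2, 0))
})

test_that("inter-video z-scoring is the z-score of the concatenation", {
  mk <- function(x, id) score_series(x, data.frame(video_id = id, start = 1L,
                                                   length = length(x)))
  z <- zscore_across_videos(mk(c(0, 0.02, 0.04), "a"))
  expect_equal(mean(z$score), 0)
  expect_equal(sqrt(mean(z$score^2)), 1)   # population SD convention

  a <- c(0.1, 0.4, 0.2); b <- c(0.9, 0.3)
  z2 <- zscore_across_videos(list(mk(a, "a"), mk(b, "b")))
  cat_ref <- (c(a, b) - mean(c(a, b))) /
    sqrt(mean((c(a, b) - mean(c(a, b)))^2))
  expect_equal(z2$score, cat_ref)
  expect_identical(z2$videos$start, c(1L, 4L))

  # inverse affine map recovers the raw concatenation exactly
  raw_back <- z2$score * attr(z2, "scale") + attr(z2, "center")
  expect_equal(raw_back, c(a, b))

  expect_error(zscore_across_videos(mk(rep(0.5, 4), "a")), "zero variance")
})

test_that("self-report comparison returns exact correlations and errors", {
  x <- c(1, 2, 3, 5, 4)
  expect_equal(compare_with_selfreport(x, x)$r, 1)
  expect_equal(compare_with_selfreport(x, -x)$r, -1)
  expect_error(compare_with_selfreport(x, x[-1]), "length mismatch")
  expect_error(compare_with_selfreport(x, rep(1, 5)), "zero variance")
  expect_error(compare_with_selfreport(x[1:2], x[1:2]), "at least 3")
})

test_that("danmaku series correlates with a planted latent via self-report", {
  cfg <- tiny_sim_config(comment_rate = 40)
  lat <- gen_latent(cfg)
  dict <- synthetic_dictionary()
  z <- zscore_across_videos(lapply(gen_comments(lat, dict, cfg),
                                   score_seconds, dict = dict))
  sr <- gen_selfreport(lat, cfg, noise_sd = 0.3)
  cmp <- compare_with_selfreport(z, sr$mean_trace)
  expect_gt(cmp$r, 0.3)
  expect_lt(cmp$p, 0.05)
})

test_that("smoothing validates width and preserves length", {
  s <- score_series(rnorm(10), data.frame(video_id = "v", start = 1L,
                                          length = 10L))
  expect_identical(smooth_score_series(s, 1L)$score, s$score)
  expect_length(smooth_score_series(s, 3L)$score, 10L)
  expect_error(smooth_score_series(s, 2L), "odd")
})
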