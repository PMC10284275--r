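test_that("the latent trajectory is smooth, standardized and deterministic", {
  cfg <- sim_config(seed = 31)
  l1 <- gen_latent(cfg)
  l2 <- gen_latent(cfg)
  expect_identical(l1, l2)
  expect_length(l1$values, 300L)
  expect_equal(mean(l1$values), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(l1$values^2)), 1, tolerance = 1e-12)
  expect_gt(acf(l1$values, plot = FALSE)$acf[2], 0.8)
})

test_that("comment generation tracks the latent monotonically", {
  dict <- synthetic_dictionary()
  cfg <- sim_config(video_durations_s = 2L, comment_rate = 800, seed = 32)
  lat <- list(values = c(2, -2), durations = 2L)
  streams <- gen_comments(lat, dict, cfg, seed = 1)
  s <- streams[[1]]
  sec <- floor(s$comments$timestamp_s)
  mean_tok_score <- function(texts) {
    toks <- do.call(rbind, lapply(texts, tokenize_comment, dict = dict))
    mean(toks$dict_score)
  }
  hi <- mean_tok_score(s$comments$text[sec == 0])
  lo <- mean_tok_score(s$comments$text[sec == 1])
  expect_gt(hi, lo)

  # zero rate -> empty streams and an all-zero raw series
  cfg0 <- sim_config(video_durations_s = c(5L, 4L), comment_rate = 0, seed = 33)
  lat0 <- gen_latent(cfg0)
  st0 <- gen_comments(lat0, dict, cfg0)
  expect_identical(vapply(st0, function(s) nrow(s$comments), integer(1)),
                   c(0L, 0L))
  expect_identical(score_seconds(st0[[1]], dict)$score, rep(0, 5))

  expect_error(gen_comments(lat0, build_dictionary(c(x = 2L)), cfg0),
               "every score level")
})

test_that("the danmaku series recovers the latent at the default comment rate", {
  cfg <- sim_config(seed = 34)          # rate 60/s, 300 s
  lat <- gen_latent(cfg)
  dict <- synthetic_dictionary()
  z <- zscore_across_videos(lapply(gen_comments(lat, dict, cfg),
                                   score_seconds, dict = dict))
  expect_gt(cor(z$score, lat$values), 0.5)
})

test_that("EEG generation is deterministic and rejects oversized couplings", {
  cfg <- tiny_sim_config()
  lat <- gen_latent(cfg)
  r1 <- gen_eeg(lat, cfg, participants = 1)
  r2 <- gen_eeg(lat, cfg, participants = 1)
  expect_identical(r1[[1]]$data, r2[[1]]$data)
  expect_identical(length(r1), length(cfg$video_durations_s))

  cfg_big <- tiny_sim_config(
    n_participants = 1L,
    couplings = data.frame(channel = "F4", band = "beta", sign = -1,
                           effect_r = 0.999))
  expect_error(gen_eeg(gen_latent(cfg_big), cfg_big, participants = 1),
               "negative envelope")
})

test_that("preprocessing strips the generated 50-Hz line interference", {
  cfg <- tiny_sim_config(video_durations_s = 6L)
  lat <- gen_latent(cfg)
  rec <- gen_eeg(lat, cfg, participants = 1)[[1]]
  power50 <- function(x) {
    n <- length(x)
    f <- exp(-2i * pi * 50 * (seq_len(n) - 1) / cfg$fs)
    Mod(sum(x * f))^2 / n
  }
  before <- power50(rec$data[1, ])
  after <- power50(preprocess(rec)$data[1, ])
  expect_lt(after / before, 10^(-20 / 10))   # >= 20 dB in power
})

test_that("group features are deterministic and sized by the configuration", {
  cfg <- tiny_sim_config()
  lat <- gen_latent(cfg)
  f1 <- simulate_group_features(lat, cfg)
  f2 <- simulate_group_features(lat, cfg)
  expect_identical(unclass(f1), unclass(f2))
  expect_identical(dim(unclass(f1)), c(22L, 128L))
  expect_true(all(f1 >= 0))
})

test_that("less coupling gain is needed as more participants are averaged", {
  # the calibrated modulation depth shrinks like 1/sqrt(n): averaging
  # reduces noise, so a weaker planted effect achieves the same r
  g23 <- elevdec:::coupling_gains(sim_config(n_participants = 23))
  g46 <- elevdec:::coupling_gains(sim_config(n_participants = 46))
  expect_true(all(g46 < g23))
  expect_equal(g46 / g23, rep(1 / sqrt(2), length(g23)), tolerance = 1e-10)
})

test_that("self-report traces are lagged, clipped copies of the latent", {
  cfg <- tiny_sim_config()
  lat <- gen_latent(cfg)
  sr0 <- gen_selfreport(lat, cfg, noise_sd = 0, lag_s = 1L, gain = 0.5)
  expect_equal(cor(sr0$mean_trace, lat$values), 1)     # affine, no clipping
  sr1 <- gen_selfreport(lat, cfg)
  sr2 <- gen_selfreport(lat, cfg)
  expect_identical(sr1$traces, sr2$traces)
  expect_identical(dim(sr1$traces), c(22L, 5L))
  expect_true(all(sr1$traces >= 0 & sr1$traces <= 10))
})
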