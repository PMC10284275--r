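#' Synthetic emotion dictionary
#'
#' A small English-vocabulary dictionary shipped for simulation and tests:
#' 20 terms at each score level (0, 1, 2), three negators and the four
#' default degree words. Purely synthetic — it stands in for a rated
#' lexicon so simulated comment streams can be scored.
#'
#' @return An `emotion_dictionary`.
#' @export
synthetic_dictionary <- function() {
  score2 <- c("touching", "moving", "inspiring", "heartwarming", "uplifting",
              "admirable", "noble", "salute", "respect", "tears",
              "moved", "greatness", "heroic", "selfless", "kindness",
              "virtue", "gratitude", "warmth", "touched", "awe")
  score1 <- c("nice", "good", "sweet", "warm", "caring",
              "gentle", "friendly", "helpful", "thoughtful", "decent",
              "pleasant", "positive", "hopeful", "support", "cheer",
              "comfort", "sincere", "honest", "humble", "brave")
  score0 <- c("first", "lol", "haha", "wow", "hmm",
              "what", "when", "where", "video", "music",
              "camera", "editing", "random", "boring", "meh",
              "okay", "test", "hello", "nope", "nothing")
  entries <- c(stats::setNames(rep(2L, 20), score2),
               stats::setNames(rep(1L, 20), score1),
               stats::setNames(rep(0L, 20), score0))
  build_dictionary(entries, negators = c("not", "never", "hardly"),
                   degree_words = default_degree_words())
}

#' Default planted channel-band couplings
#'
#' Seven negative couplings in the beta and gamma bands at frontal and
#' bilateral temporo-parietal electrodes (T5/T6 are the temporo-parietal
#' sites, equivalent to modern P7/P8), with univariate group-level effect
#' sizes between 0.22 and 0.28.
#'
#' @return Data frame with columns `channel`, `band`, `sign`, `effect_r`.
#' @export
default_couplings <- function() {
  data.frame(
    channel = c("F4", "T5", "Fz", "F4", "FC2", "T5", "T6"),
    band = c("beta", "beta", "gamma", "gamma", "gamma", "gamma", "gamma"),
    sign = rep(-1, 7),
    effect_r = c(0.23, 0.22, 0.27, 0.26, 0.24, 0.24, 0.28),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults reproduce the study dimensions: 23 participants, the 32-channel
#' montage, 250 Hz sampling, three videos of 136, 84 and 80 s (300 s
#' total), a mean comment rate of 60 comments/s, and the seven default
#' negative beta/gamma couplings.
#'
#' @param n_participants Number of simulated participants.
#' @param montage Channel names (default [default_montage()]).
#' @param fs Sampling rate, Hz.
#' @param video_durations_s Integer vector of per-video durations, seconds.
#' @param comment_rate Mean comments per second (Poisson rate).
#' @param comment_beta Strength of the multinomial-logit link between the
#'   latent value and the sampled term-score category.
#' @param p_negator,p_degree Per-token probabilities of inserting a negator
#'   / degree word before an entry term in a generated comment.
#' @param couplings Data frame of planted (channel, band, sign, effect_r)
#'   couplings (default [default_couplings()]).
#' @param bands Band definitions (default [eeg_bands()]).
#' @param band_sd Amplitude SD of each band-limited EEG component.
#' @param broadband_sd SD of the additive broadband sensor noise.
#' @param line_hz,line_amplitude Powerline interference frequency and
#'   amplitude.
#' @param latent_smooth_s Gaussian smoothing SD (s) of the latent
#'   trajectory.
#' @param n_raters,selfreport_noise_sd,selfreport_lag_s Sliding-bar
#'   self-report parameters.
#' @param seed Master seed; every generated quantity derives its own seed
#'   from it deterministically.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 23L,
                       montage = default_montage(),
                       fs = 250,
                       video_durations_s = c(136L, 84L, 80L),
                       comment_rate = 60,
                       comment_beta = 0.8,
                       p_negator = 0.05,
                       p_degree = 0.10,
                       couplings = default_couplings(),
                       bands = eeg_bands(),
                       band_sd = 1,
                       broadband_sd = 0.5,
                       line_hz = 50,
                       line_amplitude = 2,
                       latent_smooth_s = 4,
                       n_raters = 5L,
                       selfreport_noise_sd = 1,
                       selfreport_lag_s = 2L,
                       seed = 1L) {
  stopifnot(n_participants >= 1L, fs > 0, all(video_durations_s >= 1))
  if (!is.null(couplings) && nrow(couplings)) {
    if (!all(couplings$channel %in% montage))
      stop("coupling channel(s) not in montage: ",
           paste(setdiff(couplings$channel, montage), collapse = ", "))
    if (!all(couplings$band %in% names(bands)))
      stop("coupling band(s) not defined")
    stopifnot(all(couplings$sign %in% c(-1, 1)),
              all(couplings$effect_r > 0 & couplings$effect_r < 1))
  }
  structure(list(n_participants = as.integer(n_participants),
                 montage = montage, fs = fs,
                 video_durations_s = as.integer(video_durations_s),
                 comment_rate = comment_rate, comment_beta = comment_beta,
                 p_negator = p_negator, p_degree = p_degree,
                 couplings = couplings, bands = eeg_bands(bands),
                 band_sd = band_sd, broadband_sd = broadband_sd,
                 line_hz = line_hz, line_amplitude = line_amplitude,
                 latent_smooth_s = latent_smooth_s,
                 n_raters = as.integer(n_raters),
                 selfreport_noise_sd = selfreport_noise_sd,
                 selfreport_lag_s = as.integer(selfreport_lag_s),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic sub-seeds for each generated quantity (kept below 2^31).
sim_seeds <- function(cfg) {
  set.seed(cfg$seed)
  list(latent = sample.int(2147483646L, 1L),
       comments = sample.int(2147483646L, 1L),
       eeg = sample.int(2147483646L, cfg$n_participants),
       selfreport = sample.int(2147483646L, 1L))
}

#' Generate a smooth latent elevation trajectory
#'
#' Per video: Gaussian-kernel-smoothed white noise (smoothing SD
#' `latent_smooth_s` seconds, giving a lag-1 autocorrelation well above
#' 0.8) plus 2-4 positive bumps of 5-10 s width; the concatenation over
#' videos is standardized to mean 0 and population SD 1.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed override (defaults to the master-derived one).
#' @return List with `values` (numeric, one per second) and `durations`.
#' @export
gen_latent <- function(cfg, seed = NULL) {
  if (is.null(seed)) seed <- sim_seeds(cfg)$latent
  set.seed(seed)
  vals <- lapply(cfg$video_durations_s, function(d) {
    sig <- cfg$latent_smooth_s
    half <- ceiling(3 * sig)
    kern <- exp(-((-half):half)^2 / (2 * sig^2))
    kern <- kern / sum(kern)
    z <- rnorm(d + 2L * half)
    base <- as.numeric(stats::filter(z, kern, sides = 2L))
    base <- base[(half + 1L):(half + d)]
    base <- base / max(sd(base), 1e-12)
    nb <- sample(2:4, 1L)
    tt <- seq_len(d)
    for (b in seq_len(nb)) {
      ctr <- runif(1L, 1, d)
      wid <- runif(1L, 5, 10)
      amp <- runif(1L, 1, 2)
      base <- base + amp * exp(-(tt - ctr)^2 / (2 * wid^2))
    }
    base
  })
  x <- unlist(vals, use.names = FALSE)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  list(values = x, durations = cfg$video_durations_s)
}

#' Generate comment streams that track a latent trajectory
#'
#' Per second, the comment count is Poisson with mean `comment_rate`; each
#' comment holds 1-3 dictionary entry terms whose score category (0/1/2) is
#' drawn from a multinomial-logit link in the latent value, so score-2
#' terms become monotonically more likely as the latent rises. Negators
#' and degree words are inserted before entry terms with small fixed
#' probabilities.
#'
#' @param latent Output of [gen_latent()].
#' @param dict An `emotion_dictionary` with entries at every score level.
#' @param cfg A [sim_config()].
#' @param seed Optional seed override.
#' @return List of `comment_stream`, one per video.
#' @export
gen_comments <- function(latent, dict, cfg, seed = NULL) {
  validate_dictionary(dict)
  by_score <- split(names(dict$entries), dict$entries)
  if (!all(c("0", "1", "2") %in% names(by_score)))
    stop("dictionary needs entry terms at every score level 0, 1, 2")
  if (is.null(seed)) seed <- sim_seeds(cfg)$comments
  set.seed(seed)
  offs <- cumsum(c(0L, head(latent$durations, -1L)))
  streams <- vector("list", length(latent$durations))
  for (v in seq_along(latent$durations)) {
    d <- latent$durations[v]
    lv <- latent$values[offs[v] + seq_len(d)]
    counts <- rpois(d, cfg$comment_rate)
    total <- sum(counts)
    if (total == 0L) {
      streams[[v]] <- comment_stream(paste0("video", v), d,
                                     data.frame(timestamp_s = numeric(0),
                                                text = character(0)))
      next
    }
    sec <- rep.int(seq_len(d), counts)            # 1-based second index
    ts <- (sec - 1L) + runif(total)
    nt <- sample(1:3, total, replace = TRUE)
    tok_comment <- rep.int(seq_len(total), nt)
    tok_l <- lv[sec][tok_comment]
    u0 <- exp(-cfg$comment_beta * tok_l)
    u2 <- exp(cfg$comment_beta * tok_l)
    u1 <- rep(1.5, length(tok_l))
    tot <- u0 + u1 + u2
    rnd <- runif(length(tok_l)) * tot
    cat_id <- ifelse(rnd < u0, 0L, ifelse(rnd < u0 + u1, 1L, 2L))
    words <- character(length(cat_id))
    for (s in 0:2) {
      pick <- cat_id == s
      pool <- by_score[[as.character(s)]]
      words[pick] <- pool[sample.int(length(pool), sum(pick), replace = TRUE)]
    }
    deg <- runif(length(words)) < cfg$p_degree & length(dict$degree_words) > 0
    neg <- runif(length(words)) < cfg$p_negator & length(dict$negators) > 0
    if (any(deg)) {
      dw <- names(dict$degree_words)
      words[deg] <- paste(dw[sample.int(length(dw), sum(deg), replace = TRUE)],
                          words[deg])
    }
    if (any(neg)) {
      nw <- dict$negators
      words[neg] <- paste(nw[sample.int(length(nw), sum(neg), replace = TRUE)],
                          words[neg])
    }
    texts <- vapply(split(words, tok_comment), paste, character(1),
                    collapse = " ")
    streams[[v]] <- comment_stream(paste0("video", v), d,
                                   data.frame(timestamp_s = ts,
                                              text = unname(texts)))
  }
  streams
}

# --- EEG generation -------------------------------------------------------

# Spectral quantities for the coupling calibration: power gains of the
# generation filter (single pass) and the full zero-phase feature chain
# (notch, wide band-pass, band filter; each applied forward-backward, so
# the chain's power gain is the product of the |H|^4 terms).
band_spectra <- function(cfg) {
  f <- seq(0, cfg$fs / 2, by = 0.05)
  gn <- filter_power_gain(design_notch(cfg$fs, cfg$line_hz), f, cfg$fs)
  gbp <- filter_power_gain(design_butter(cfg$fs, c(0.05, 47), "pass"), f, cfg$fs)
  lapply(cfg$bands, function(e) {
    g1 <- filter_power_gain(design_butter(cfg$fs, e, "pass"), f, cfg$fs)
    list(f = f, gen_gain = g1, feat_gain = (gn * gbp * g1)^2)
  })
}

# Coupling gain g for a target group-level univariate effect size r.
# Derivation (documented in the methods vignette): with the coupled
# component's spectral density S_c and total in-feature density S_tot, the
# per-second feature power has mean-shift derivative 2 g fs v_c per unit
# latent (v_c = integral of S_c x feature gain) and group-level noise SD
# fs * sqrt(integral of S_tot^2 / n), so
#   g = r / sqrt(1 - r^2) * sqrt(integral(S_tot^2) / n) / (2 v_c).
coupling_gains <- function(cfg, spectra = band_spectra(cfg)) {
  cp <- cfg$couplings
  if (is.null(cp) || !nrow(cp)) return(numeric(0))
  half <- cfg$fs / 2
  vapply(seq_len(nrow(cp)), function(i) {
    b <- cp$band[i]
    sp <- spectra[[b]]
    df <- sp$f[2] - sp$f[1]
    # densities over [0, fs/2], each component normalized to its variance
    dens_band <- function(bb) {
      g1 <- spectra[[bb]]$gen_gain
      cfg$band_sd^2 * g1 / (sum(g1) * df)
    }
    S_tot <- Reduce(`+`, lapply(names(cfg$bands), dens_band)) +
      cfg$broadband_sd^2 / half
    S_tot <- S_tot * sp$feat_gain
    S_c <- dens_band(b) * sp$feat_gain
    v_c <- sum(S_c) * df
    r <- cp$effect_r[i]
    r / sqrt(1 - r^2) * sqrt(sum(S_tot^2) * df / cfg$n_participants) /
      (2 * v_c)
  }, numeric(1))
}

# One participant-video's raw signal as a samples x channels matrix.
# latent_v: per-second latent values of that video. The band filters warm
# up on 2 s of prepended noise that is then discarded.
gen_eeg_mat <- function(latent_v, cfg, seed, gains = NULL, spectra = NULL) {
  set.seed(seed)
  if (is.null(spectra)) spectra <- band_spectra(cfg)
  if (is.null(gains)) gains <- coupling_gains(cfg, spectra)
  nch <- length(cfg$montage)
  d <- length(latent_v)
  nsamp <- d * cfg$fs
  warm <- 2L * as.integer(cfg$fs)
  x <- matrix(0, nsamp, nch)
  cp <- cfg$couplings
  for (b in names(cfg$bands)) {
    filt <- design_butter(cfg$fs, cfg$bands[[b]], "pass")
    z <- matrix(rnorm((nsamp + warm) * nch), nsamp + warm, nch)
    z <- iir_filter_mat(filt$b, filt$a, z)[(warm + 1L):(warm + nsamp), ,
                                           drop = FALSE]
    z <- z / sqrt(mean(spectra[[b]]$gen_gain))   # unit variance
    if (!is.null(cp) && nrow(cp)) {
      sel <- which(cp$band == b)
      for (i in sel) {
        ch <- match(cp$channel[i], cfg$montage)
        amp <- 1 + gains[i] * cp$sign[i] * latent_v
        if (any(amp <= 0))
          stop("coupling gain too large: negative envelope amplitude")
        z[, ch] <- z[, ch] * rep(amp, each = cfg$fs)
      }
    }
    x <- x + cfg$band_sd * z
  }
  x <- x + cfg$broadband_sd * matrix(rnorm(nsamp * nch), nsamp, nch)
  if (cfg$line_amplitude > 0) {
    # per-channel random phase via sin(a + phi) = sin(a)cos(phi) + cos(a)sin(phi)
    phases <- runif(nch, 0, 2 * pi)
    arg <- 2 * pi * cfg$line_hz * seq_len(nsamp) / cfg$fs
    x <- x + cfg$line_amplitude *
      (sin(arg) %o% cos(phases) + cos(arg) %o% sin(phases))
  }
  x
}

gen_eeg_video <- function(latent_v, cfg, participant, video, seed,
                          gains = NULL, spectra = NULL) {
  x <- gen_eeg_mat(latent_v, cfg, seed, gains, spectra)
  eeg_recording(participant, video, t(x), cfg$montage, cfg$fs)
}

#' Generate multi-participant EEG with planted couplings
#'
#' Each channel is a sum of band-limited Gaussian noise components, one per
#' band. For a planted coupling (channel, band, sign, effect_r) the
#' component's per-second envelope amplitude is `1 + g * sign * latent_i`,
#' with `g` calibrated in closed form from the filter responses so the
#' group-level univariate feature-latent correlation is approximately
#' `effect_r` at the configured participant count. Broadband sensor noise
#' and powerline interference are added.
#'
#' @param latent Output of [gen_latent()].
#' @param cfg A [sim_config()].
#' @param participants Integer vector of participant indices (default all).
#' @param seed Optional vector of per-participant seed overrides.
#' @return List of `eeg_recording` (participants x videos, participant-major).
#' @export
gen_eeg <- function(latent, cfg, participants = seq_len(cfg$n_participants),
                    seed = NULL) {
  if (is.null(seed)) seed <- sim_seeds(cfg)$eeg[participants]
  stopifnot(length(seed) == length(participants))
  spectra <- band_spectra(cfg)
  gains <- coupling_gains(cfg, spectra)
  offs <- cumsum(c(0L, head(latent$durations, -1L)))
  out <- list()
  for (pi in seq_along(participants)) {
    p <- participants[pi]
    set.seed(seed[pi])
    video_seeds <- sample.int(2147483646L, length(latent$durations))
    for (v in seq_along(latent$durations)) {
      lv <- latent$values[offs[v] + seq_len(latent$durations[v])]
      out[[length(out) + 1L]] <-
        gen_eeg_video(lv, cfg, paste0("sub", p), paste0("video", v),
                      video_seeds[v], gains, spectra)
    }
  }
  out
}

#' Simulate group-level EEG features without retaining raw recordings
#'
#' Streams participant by participant: generates each participant's EEG,
#' extracts band-power features, accumulates the group mean, and discards
#' the raw signal — so the memory footprint stays at a single participant.
#'
#' @inheritParams gen_eeg
#' @param log10_power Passed to [segment_power()].
#' @return The group-level `feature_matrix` (seconds x features).
#' @export
simulate_group_features <- function(latent, cfg, log10_power = FALSE) {
  seeds <- sim_seeds(cfg)$eeg
  spectra <- band_spectra(cfg)
  gains <- coupling_gains(cfg, spectra)
  offs <- cumsum(c(0L, head(latent$durations, -1L)))
  acc <- NULL
  for (p in seq_len(cfg$n_participants)) {
    set.seed(seeds[p])
    video_seeds <- sample.int(2147483646L, length(latent$durations))
    fms <- lapply(seq_along(latent$durations), function(v) {
      lv <- latent$values[offs[v] + seq_len(latent$durations[v])]
      x <- gen_eeg_mat(lv, cfg, video_seeds[v], gains, spectra)
      features_from_samples(x, cfg$fs, cfg$montage, cfg$bands,
                            log10_power = log10_power)
    })
    fm <- do.call(rbind, lapply(fms, unclass))
    acc <- if (is.null(acc)) fm else acc + fm
    if (p == 1L) labels <- feature_labels(fms[[1]])
  }
  out <- acc / cfg$n_participants
  structure(out, feature_labels = labels,
            class = c("feature_matrix", "matrix"))
}

#' Generate sliding-bar self-report traces
#'
#' Each rater's trace is the latent trajectory passed through a causal
#' boxcar lag kernel (`selfreport_lag_s` seconds), scaled onto the bar
#' range, plus white noise, clipped to the bar limits (0-10).
#'
#' @param latent Output of [gen_latent()].
#' @param cfg A [sim_config()].
#' @param n_raters,noise_sd,lag_s Overrides of the config values.
#' @param gain,baseline Affine map from latent units onto the bar.
#' @param seed Optional seed override.
#' @return List with `traces` (seconds x raters matrix) and `mean_trace`.
#' @export
gen_selfreport <- function(latent, cfg, n_raters = cfg$n_raters,
                           noise_sd = cfg$selfreport_noise_sd,
                           lag_s = cfg$selfreport_lag_s,
                           gain = 1.5, baseline = 5, seed = NULL) {
  if (is.null(seed)) seed <- sim_seeds(cfg)$selfreport
  set.seed(seed)
  stopifnot(n_raters >= 1L)
  x <- latent$values
  n <- length(x)
  if (lag_s > 1L) {
    lagged <- as.numeric(stats::filter(x, rep(1 / lag_s, lag_s), sides = 1L))
    for (i in seq_len(min(lag_s - 1L, n)))
      lagged[i] <- mean(x[seq_len(i)])       # warm-up: partial means
  } else {
    lagged <- x
  }
  traces <- vapply(seq_len(n_raters), function(r) {
    tr <- baseline + gain * lagged + rnorm(n, sd = noise_sd)
    pmin(pmax(tr, 0), 10)
  }, numeric(n))
  list(traces = traces, mean_trace = rowMeans(traces))
}
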