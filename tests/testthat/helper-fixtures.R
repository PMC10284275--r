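# Shared fixtures, built in code.

tiny_dictionary <- function() {
  build_dictionary(c(touching = 2L, nice = 1L, meh = 0L),
                   negators = "not",
                   degree_words = c("very" = 1.5, "a little" = 0.75))
}

# A deliberately small simulation: few participants, short videos.
tiny_sim_config <- function(...) {
  defaults <- list(n_participants = 2L, video_durations_s = c(12L, 10L),
                   comment_rate = 20, seed = 42L)
  do.call(sim_config, modifyList(defaults, list(...)))
}

# A single-channel-pair recording holding given per-channel signals
# (samples x channels matrix in, channels x samples recording out).
signal_recording <- function(x, fs = 250, names = NULL) {
  x <- as.matrix(x)
  if (is.null(names)) names <- paste0("ch", seq_len(ncol(x)))
  eeg_recording("sub1", "video1", t(x), names, fs)
}

rms <- function(x) sqrt(mean(x^2))
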