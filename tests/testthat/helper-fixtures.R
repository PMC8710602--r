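# Shared fixture builders; everything is generated in code at test time.

# Three well-separated keyword pairs inside a `duration_s`-second trial.
fixture_keywords <- function(duration_s = 12) {
  third <- duration_s / 3
  tk <- list(
    keyword_interval(0.5 * third, 0.5 * third + 0.5, "target"),
    keyword_interval(1.5 * third, 1.5 * third + 0.5, "target"),
    keyword_interval(2.5 * third, 2.5 * third + 0.4, "target"))
  mk <- list(
    keyword_interval(0.5 * third + 0.2, 0.5 * third + 0.8, "masker"),
    keyword_interval(1.5 * third + 0.1, 1.5 * third + 0.6, "masker"),
    keyword_interval(2.5 * third, 2.5 * third + 0.4, "masker"))
  list(target = tk, masker = mk)
}

fixture_windows <- function(responses = c("target", "target", "target"),
                            duration_s = 12) {
  kw <- fixture_keywords(duration_s)
  make_windows(kw$target, kw$masker, responses)
}

# Random (but seeded) window layout for property tests: three ordered,
# disjoint windows anywhere in the trial.
random_windows <- function(seed, duration_s = 12) {
  withr::with_seed(seed, {
    starts <- sort(runif(3, 0.3, duration_s - 1.5))
    while (min(diff(starts)) < 1.2) {
      starts <- sort(runif(3, 0.3, duration_s - 1.5))
    }
    widths <- runif(3, 0.4, 1.0)
    tk <- mk <- vector("list", 3)
    for (i in 1:3) {
      tk[[i]] <- keyword_interval(starts[i], starts[i] + widths[i] * 0.7,
                                  "target")
      mk[[i]] <- keyword_interval(starts[i] + widths[i] * 0.3,
                                  starts[i] + widths[i], "masker")
    }
    resp <- sample(c("target", "masker", "extraneous"), 3, replace = TRUE)
    make_windows(tk, mk, resp)
  })
}

# Small set of trials with EEG generated by a known forward model.
fixture_trials <- function(n_trials = 6, n_channels = 4, duration_s = 12,
                           snr = Inf, seed = 1, kernel_seed = 5) {
  kern <- forward_trf(n_channels, seed = kernel_seed)
  lapply(seq_len(n_trials), function(i) {
    env_t <- gen_stream(duration_s, seed * 1000 + i)
    env_m <- gen_stream(duration_s, seed * 1000 + 500 + i)
    eeg <- gen_eeg(env_t, kern, snr, seed * 2000 + i)
    list(trial_id = sprintf("t%02d", i), env_target = env_t,
         env_masker = env_m, eeg = eeg, seed = seed * 1000 + i)
  })
}

# Modulated-noise waveform (speech-like broadband carrier) for DSP tests.
modulated_noise <- function(duration_s, fs, seed, mod_hz = 3) {
  withr::with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    mod <- 1 + 0.8 * sin(2 * pi * mod_hz * t + runif(1, 0, 2 * pi))
    waveform(mod * rnorm(n), fs)
  })
}
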