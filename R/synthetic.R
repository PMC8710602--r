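#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic cocktail-party
#' generator: per-condition switch hazards and lapse probabilities, trial
#' counts and durations, and the forward EEG model. The default three
#' conditions mirror an easy / intermediate / difficult voice-similarity
#' manipulation: attentional switches essentially absent when the voices are
#' clearly distinct, and increasingly likely (with more response lapses) as
#' the voices converge.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_trials_per_condition Trials per subject per condition (the full
#'   study used 48).
#' @param trial_duration_range_s Trial durations are drawn uniformly from
#'   this range (seconds).
#' @param rate_hz Model rate for envelopes and EEG.
#' @param conditions Data frame with columns `condition`,
#'   `switch_hazard_per_s` and `lapse_prob`.
#' @param n_channels Number of EEG channels (the recorded montage had 31).
#' @param kernel_latency_s,kernel_width_s Forward-TRF morphology: response
#'   peak latency and support length in seconds.
#' @param snr Ratio of per-channel signal power to noise power in the
#'   simulated EEG; `Inf` gives noiseless recordings.
#' @param master_seed Integer master seed; every artifact of the dataset is a
#'   pure function of `(cfg, master_seed)`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 20,
                       n_trials_per_condition = 48,
                       trial_duration_range_s = c(11, 18),
                       rate_hz = 64,
                       conditions = data.frame(
                         condition = c("easy", "intermediate", "difficult"),
                         switch_hazard_per_s = c(0.00, 0.02, 0.08),
                         lapse_prob = c(0.05, 0.10, 0.15)),
                       n_channels = 31,
                       kernel_latency_s = 0.15,
                       kernel_width_s = 0.4,
                       snr = 0.05,
                       master_seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "switch_hazard_per_s", "lapse_prob") %in%
                  names(conditions)))
  if (any(conditions$lapse_prob < 0 | conditions$lapse_prob > 1)) {
    stop("lapse probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(conditions$switch_hazard_per_s < 0)) {
    stop("switch hazards must be nonnegative", call. = FALSE)
  }
  if (length(trial_duration_range_s) != 2 ||
      any(trial_duration_range_s <= 0) ||
      trial_duration_range_s[1] > trial_duration_range_s[2]) {
    stop("`trial_duration_range_s` must be a positive increasing pair",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 trial_duration_range_s = trial_duration_range_s,
                 rate_hz = rate_hz,
                 conditions = conditions,
                 n_channels = as.integer(n_channels),
                 kernel_latency_s = kernel_latency_s,
                 kernel_width_s = kernel_width_s,
                 snr = snr,
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

#' Generate a speech-like stream
#'
#' Produces a nonnegative envelope with dominant syllabic-rate (2-8 Hz)
#' modulation: a sum of randomized modulation components with frequencies
#' drawn in the syllabic band, half-wave rectified, plus a small positive
#' floor. In waveform mode the envelope is multiplied onto a Gaussian noise
#' carrier at an audio rate.
#'
#' @param duration_s Stream duration in seconds (> 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param mode `"envelope"` (default) or `"waveform"`.
#' @param rate_hz Output rate: model rate for envelope mode (default 64),
#'   audio rate for waveform mode (default 16000).
#' @return An [envelope()] or [waveform()].
#' @export
gen_stream <- function(duration_s, seed, mode = c("envelope", "waveform"),
                       rate_hz = if (mode[1] == "waveform") 16000 else 64) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  with_local_seed(seed, {
    n_env <- round(duration_s * 64)
    t <- (seq_len(n_env) - 1) / 64
    n_comp <- 8L
    freqs <- stats::runif(n_comp, 2, 8)
    amps <- stats::rexp(n_comp)
    phases <- stats::runif(n_comp, 0, 2 * pi)
    raw <- rowSums(vapply(seq_len(n_comp), function(k) {
      amps[k] * cos(2 * pi * freqs[k] * t + phases[k])
    }, numeric(n_env)))
    env <- pmax(raw, 0) + 0.05 * mean(amps)
    if (mode == "envelope") {
      envelope(env, 64)
    } else {
      n_audio <- round(duration_s * rate_hz)
      ta <- (seq_len(n_audio) - 1) / rate_hz
      env_audio <- stats::approx(t, env, xout = ta, rule = 2)$y
      carrier <- stats::rnorm(n_audio)
      waveform(env_audio * carrier, rate_hz)
    }
  })
}

#' Generate keyword timing for a trial
#'
#' Places one target/masker keyword pair in each third of the trial
#' (beginning, middle, end), with keyword lengths of 0.3-0.8 s and
#' target-masker onset offsets of 0-1 s, such that the three response windows
#' are ordered and disjoint.
#'
#' @param duration_s Trial duration, at least 9 s.
#' @param seed Integer seed.
#' @return List with elements `target` and `masker`, each a list of three
#'   [keyword_interval()]s.
#' @export
gen_keyword_times <- function(duration_s, seed) {
  if (duration_s < 9) stop("trial must last at least 9 s", call. = FALSE)
  with_local_seed(seed, {
    third <- duration_s / 3
    tk <- vector("list", 3)
    mk <- vector("list", 3)
    for (i in 1:3) {
      lo <- (i - 1) * third
      len_t <- stats::runif(1, 0.3, 0.8)
      len_m <- stats::runif(1, 0.3, 0.8)
      offset <- stats::runif(1, 0, 1) * sample(c(-1, 1), 1)
      # the union window must fit inside the third with a 15% margin,
      # which also keeps windows across thirds disjoint
      lo_bound <- lo + 0.15 * third
      hi_bound <- lo + 0.85 * third
      w_start_rel <- min(0, offset)            # window start re target onset
      w_end_rel <- max(len_t, offset + len_m)  # window end re target onset
      if (hi_bound - w_end_rel < lo_bound - w_start_rel) {
        offset <- 0                            # fall back: overlapping pair
        w_start_rel <- 0
        w_end_rel <- max(len_t, len_m)
      }
      on_t <- stats::runif(1, lo_bound - w_start_rel,
                           hi_bound - w_end_rel)
      tk[[i]] <- keyword_interval(on_t, on_t + len_t, "target")
      mk[[i]] <- keyword_interval(on_t + offset, on_t + offset + len_m,
                                  "masker")
    }
    list(target = tk, masker = mk)
  })
}

#' Generate a latent attention trajectory
#'
#' The listener starts attending the target; attentional switches between the
#' streams occur at Poisson times with the given hazard, with a minimum dwell
#' of 1 s between switches (candidate switches arriving sooner are dropped).
#'
#' @param duration_s Trial duration in seconds.
#' @param hazard_per_s Switch hazard (events per second, >= 0).
#' @param seed Integer seed.
#' @return A list of class `"attention_trajectory"`: `switch_times_s`
#'   (possibly empty) and `labels`, the attended source on each inter-switch
#'   interval, starting with `"target"`.
#' @export
gen_attention_trajectory <- function(duration_s, hazard_per_s, seed) {
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  if (hazard_per_s < 0) stop("hazard must be nonnegative", call. = FALSE)
  switches <- numeric(0)
  if (hazard_per_s > 0) {
    switches <- with_local_seed(seed, {
      t_now <- 0
      last <- -Inf
      out <- numeric(0)
      repeat {
        t_now <- t_now + stats::rexp(1, hazard_per_s)
        if (t_now >= duration_s) break
        if (t_now - last >= 1) { # minimum dwell 1 s
          out <- c(out, t_now)
          last <- t_now
        }
      }
      out
    })
  }
  labels <- rep(c("target", "masker"), length.out = length(switches) + 1)
  structure(list(duration_s = duration_s, switch_times_s = switches,
                 labels = labels),
            class = "attention_trajectory")
}

# Attended-source indicator of a trajectory sampled on the model grid:
# 1 where the target is attended, 0 where the masker is.
trajectory_indicator <- function(traj, rate_hz, n) {
  t <- (seq_len(n) - 1) / rate_hz
  piece <- findInterval(t, traj$switch_times_s) + 1L
  as.numeric(traj$labels[piece] == "target")
}

# Fraction of a time interval during which the target is attended.
attended_fraction <- function(traj, from_s, to_s, rate_hz = 256) {
  n <- max(2L, round((to_s - from_s) * rate_hz))
  t <- seq(from_s, to_s, length.out = n)
  piece <- findInterval(t, traj$switch_times_s) + 1L
  mean(traj$labels[piece] == "target")
}

#' Generate behavioral responses from a latent trajectory
#'
#' The response for window i is the source attended for the majority of that
#' window, replaced by `"extraneous"` with probability `lapse_prob`
#' (a response-level lapse: the latent attention signal itself is unchanged).
#'
#' @param traj An [gen_attention_trajectory()] result.
#' @param windows A [make_windows()] result (its `response` column is
#'   ignored; only the window extents are used).
#' @param lapse_prob Probability in `[0, 1]` of an extraneous response.
#' @param seed Integer seed for the lapse draws.
#' @return Character vector of three responses.
#' @export
gen_responses <- function(traj, windows, lapse_prob, seed) {
  if (lapse_prob < 0 || lapse_prob > 1) {
    stop("`lapse_prob` must lie in [0, 1]", call. = FALSE)
  }
  majority <- vapply(seq_len(nrow(windows)), function(i) {
    frac <- attended_fraction(traj, windows$start_s[i], windows$end_s[i])
    if (frac >= 0.5) "target" else "masker"
  }, character(1))
  lapses <- with_local_seed(seed,
                            stats::runif(nrow(windows)) < lapse_prob)
  ifelse(lapses, "extraneous", majority)
}

#' Forward TRF kernel bank
#'
#' Per-channel forward kernels mapping the attended envelope to EEG: a
#' gamma-windowed sinusoid peaking near `latency_s` with compact support
#' `width_s` — typical speech-TRF morphology. Channels differ in gain,
#' latency (20% jitter around the nominal peak) and oscillation phase, as
#' TRFs do across a scalp montage; without that variation every channel
#' would be a scalar multiple of one filtered signal and the montage would
#' carry no more information than a single electrode.
#'
#' @param n_channels Number of channels.
#' @param rate_hz Model rate.
#' @param latency_s Nominal kernel peak latency in seconds.
#' @param width_s Kernel support in seconds.
#' @param seed Integer seed for the per-channel parameters.
#' @return Numeric matrix, channels x kernel samples.
#' @export
forward_trf <- function(n_channels = 31, rate_hz = 64, latency_s = 0.15,
                        width_s = 0.4, seed = 1L) {
  n_k <- round(width_s * rate_hz)
  t <- (seq_len(n_k) - 1) / rate_hz
  shape <- 3
  with_local_seed(seed, {
    gains <- stats::rnorm(n_channels, mean = 1, sd = 0.3)
    lats <- latency_s * stats::runif(n_channels, 0.8, 1.2)
    phases <- stats::runif(n_channels, -pi / 4, pi / 4)
    kb <- vapply(seq_len(n_channels), function(ch) {
      win <- stats::dgamma(t, shape = shape,
                           scale = lats[ch] / (shape - 1)) # mode at latency
      win <- win / max(win)
      gains[ch] * win * sin(2 * pi * t / (2 * lats[ch]) + phases[ch])
    }, numeric(n_k))
    t(kb)
  })
}

#' Generate simulated EEG from an attended signal
#'
#' Each channel is the convolution of its forward kernel with the attended
#' signal plus Gaussian noise scaled per channel so that
#' signal power / noise power equals `snr`. The attended signal is
#' `w_T * env_T + w_M * env_M`, where the weights follow the true latent
#' trajectory with raised-cosine crossfades of 250 ms at each switch.
#'
#' @param attended Numeric vector (or [envelope()]): the attended signal at
#'   the model rate.
#' @param kernels Matrix from [forward_trf()].
#' @param snr Signal-to-noise power ratio (> 0; `Inf` = noiseless).
#' @param seed Integer seed for the noise.
#' @param rate_hz Model rate.
#' @return An [eeg_record()] at `rate_hz` with `nrow(kernels)` channels.
#' @export
gen_eeg <- function(attended, kernels, snr, seed, rate_hz = 64) {
  x <- as_samples(attended)
  if (!(snr > 0)) stop("`snr` must be positive", call. = FALSE)
  n <- length(x)
  n_ch <- nrow(kernels)
  clean <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    # causal convolution truncated to the trial length
    full <- stats::convolve(x, rev(kernels[ch, ]), type = "open")
    clean[ch, ] <- full[seq_len(n)]
  }
  if (is.infinite(snr)) return(eeg_record(clean, rate_hz))
  noise <- with_local_seed(seed, matrix(stats::rnorm(n_ch * n), n_ch, n))
  for (ch in seq_len(n_ch)) {
    sp <- mean(clean[ch, ]^2)
    np <- mean(noise[ch, ]^2)
    # a silent channel (zero kernel) stays pure unit-variance noise: the
    # power ratio is undefined there
    if (sp > 0) noise[ch, ] <- noise[ch, ] * sqrt(sp / (snr * np))
  }
  eeg_record(clean + noise, rate_hz)
}

# Attended mixture of the two stream envelopes under the true trajectory,
# with raised-cosine crossfades of `switch_s` seconds at each switch.
attended_mixture <- function(env_T, env_M, traj, rate_hz = 64,
                             switch_s = 0.25) {
  xt <- as_samples(env_T)
  xm <- as_samples(env_M)
  n <- length(xt)
  t <- (seq_len(n) - 1) / rate_hz
  w_t <- rep(as.numeric(traj$labels[1] == "target"), n)
  for (j in seq_along(traj$switch_times_s)) {
    b <- traj$switch_times_s[j]
    h <- switch_s / 2
    theta <- pmin(pmax((t - (b - h)) / (2 * h), 0), 1)
    u <- 0.5 * (1 - cos(pi * theta))
    to_target <- traj$labels[j + 1] == "target"
    # switches are at least 1 s apart and ramps last 250 ms, so consecutive
    # ramps never overlap and min/max composition is exact
    w_t <- if (to_target) pmax(w_t, u) else pmin(w_t, 1 - u)
  }
  w_t * xt + (1 - w_t) * xm
}

#' Generate one simulated trial
#'
#' @param condition Row of the condition table (list or one-row data frame).
#' @param duration_s Trial duration in seconds.
#' @param kernels Forward kernel bank for this subject.
#' @param snr Signal-to-noise ratio for the EEG.
#' @param seed Integer seed; sub-seeds for streams, keywords, trajectory,
#'   responses and noise are derived from it.
#' @param trial_id Identifier.
#' @param rate_hz Model rate.
#' @return A list of class `"sim_trial"` with the source envelopes, keyword
#'   windows (with generated responses), the latent trajectory, the EEG
#'   record, and seed provenance.
#' @export
gen_trial <- function(condition, duration_s, kernels, snr, seed,
                      trial_id = "t01", rate_hz = 64) {
  seeds <- list(target = child_seed(seed, 1),
                masker = child_seed(seed, 2),
                keywords = child_seed(seed, 3),
                trajectory = child_seed(seed, 4),
                responses = child_seed(seed, 5),
                noise = child_seed(seed, 6))
  env_T <- gen_stream(duration_s, seeds$target)
  env_M <- gen_stream(duration_s, seeds$masker)
  env_T$trial_id <- env_M$trial_id <- trial_id
  kws <- gen_keyword_times(duration_s, seeds$keywords)
  traj <- gen_attention_trajectory(duration_s,
                                   condition$switch_hazard_per_s,
                                   seeds$trajectory)
  # window extents are needed before responses exist; build with placeholder
  # responses, then fill in the generated ones
  win <- make_windows(kws$target, kws$masker, rep("target", 3))
  responses <- gen_responses(traj, win, condition$lapse_prob,
                             seeds$responses)
  win$response <- responses
  attended <- attended_mixture(env_T, env_M, traj, rate_hz)
  eeg <- gen_eeg(attended, kernels, snr, seeds$noise, rate_hz)
  structure(list(trial_id = trial_id,
                 condition = as.character(condition$condition),
                 duration_s = duration_s,
                 env_target = env_T,
                 env_masker = env_M,
                 windows = win,
                 responses = responses,
                 trajectory = traj,
                 eeg = eeg,
                 seed = seed,
                 seeds = seeds),
            class = "sim_trial")
}

#' Generate a full synthetic dataset
#'
#' Full factorial subjects x conditions x trials with hierarchical seeding:
#' the master seed determines per-subject seeds, which determine per-trial
#' seeds, so any slice of the dataset can be regenerated independently and
#' the whole dataset is a pure function of `(cfg, master_seed)`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"sim_dataset"`: `cfg` plus `subjects`, each with
#'   `subject_id`, the forward `kernels`, and a list of [gen_trial()]s.
#' @export
gen_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    s_seed <- child_seed(cfg$master_seed, s)
    kernels <- forward_trf(cfg$n_channels, cfg$rate_hz,
                           cfg$kernel_latency_s, cfg$kernel_width_s,
                           seed = child_seed(s_seed, 0))
    trials <- list()
    for (ci in seq_len(nrow(cfg$conditions))) {
      cond <- cfg$conditions[ci, ]
      for (k in seq_len(cfg$n_trials_per_condition)) {
        t_seed <- child_seed(s_seed, ci, k)
        dur <- with_local_seed(child_seed(t_seed, 99),
                               stats::runif(1, cfg$trial_duration_range_s[1],
                                            cfg$trial_duration_range_s[2]))
        tid <- sprintf("s%02d_%s_t%02d", s, cond$condition, k)
        trials[[length(trials) + 1L]] <-
          gen_trial(cond, dur, kernels, cfg$snr, t_seed, tid, cfg$rate_hz)
      }
    }
    subjects[[s]] <- list(subject_id = sprintf("s%02d", s),
                          seed = s_seed, kernels = kernels, trials = trials)
  }
  structure(list(cfg = cfg, subjects = subjects), class = "sim_dataset")
}

# Convenience: split one subject's trials by condition.
trials_by_condition <- function(subject, condition) {
  Filter(function(tr) tr$condition == condition, subject$trials)
}
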