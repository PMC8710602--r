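#' Filterbank specification for envelope extraction
#'
#' Defaults follow the standard configuration for speech-tracking analyses:
#' 28 gammatone bands with center frequencies from 50 to 5000 Hz, equally
#' spaced on the ERB_N scale, with power-law amplitude compression with
#' exponent 0.6.
#'
#' @param n_bands Number of gammatone bands (>= 2).
#' @param f_min_hz,f_max_hz Lowest and highest center frequency in Hz.
#' @param compression_exponent Power-law exponent applied to the rectified
#'   band signals (Stevens-type loudness compression).
#' @return A list of class `"filterbank_spec"`.
#' @export
filterbank_spec <- function(n_bands = 28, f_min_hz = 50, f_max_hz = 5000,
                            compression_exponent = 0.6) {
  if (n_bands < 2) stop("`n_bands` must be at least 2", call. = FALSE)
  if (!(f_min_hz > 0 && f_max_hz > f_min_hz)) {
    stop("need 0 < f_min_hz < f_max_hz", call. = FALSE)
  }
  stopifnot_scalar_number(compression_exponent, "compression_exponent",
                          positive = TRUE)
  structure(list(n_bands = as.integer(n_bands), f_min_hz = f_min_hz,
                 f_max_hz = f_max_hz,
                 compression_exponent = compression_exponent),
            class = "filterbank_spec")
}

#' ERB_N-scale conversions and equally spaced center frequencies
#'
#' The ERB_N number scale (Glasberg & Moore) maps frequency in Hz to an
#' auditory-filter count: `E(f) = 21.4 * log10(0.00437 * f + 1)`.
#' `erb_center_frequencies()` returns `n` frequencies whose ERB numbers are
#' equally spaced between `E(f_min)` and `E(f_max)`, endpoints included.
#'
#' @param f_min,f_max Frequency range in Hz, `0 < f_min < f_max`.
#' @param n Number of center frequencies (>= 2).
#' @return Numeric vector of `n` center frequencies in Hz, increasing, with
#'   first element `f_min` and last element `f_max`.
#' @examples
#' erb_center_frequencies(50, 5000, 28)
#' @export
erb_center_frequencies <- function(f_min, f_max, n) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 ||
      f_max <= f_min) {
    stop("need 0 < f_min < f_max", call. = FALSE)
  }
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  e <- seq(hz_to_erb(f_min), hz_to_erb(f_max), length.out = n)
  f <- erb_to_hz(e)
  # pin the endpoints exactly (round-trip is accurate to ~1e-12 anyway)
  f[1] <- f_min
  f[n] <- f_max
  f
}

#' @rdname erb_center_frequencies
#' @param f Frequency in Hz.
#' @export
hz_to_erb <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_center_frequencies
#' @param e ERB number.
#' @export
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

# One biquad (second-order IIR) pass, direct form, via stats::filter so the
# recursion runs in C. b has length 3, a has length 3 with a[1] == 1.
biquad <- function(x, b, a) {
  v <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
  # one-sided convolution leaves the first length(b)-1 samples NA; fill them
  # assuming zero history
  for (i in seq_len(min(length(b) - 1, length(x)))) {
    v[i] <- sum(b[seq_len(i)] * x[i:1])
  }
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

# Slaney-style 4th-order all-pole gammatone filter: four cascaded biquads
# sharing one pole pair, with the overall gain normalized to unity at the
# center frequency. Returns the band-filtered signal.
gammatone_filter <- function(x, cf, fs) {
  T <- 1 / fs
  ear_q <- 9.26449
  min_bw <- 24.7
  erb <- cf / ear_q + min_bw
  B <- 1.019 * 2 * pi * erb
  arg <- 2 * cf * pi * T
  ebt <- exp(B * T)
  rt_pos <- sqrt(3 + 2^1.5)
  rt_neg <- sqrt(3 - 2^1.5)

  a0 <- T
  a2 <- 0
  b0 <- 1
  b1 <- -2 * cos(arg) / ebt
  b2 <- exp(-2 * B * T)

  a11 <- -(2 * T * cos(arg) / ebt + rt_pos * 2 * T * sin(arg) / ebt) / 2
  a12 <- -(2 * T * cos(arg) / ebt - rt_pos * 2 * T * sin(arg) / ebt) / 2
  a13 <- -(2 * T * cos(arg) / ebt + rt_neg * 2 * T * sin(arg) / ebt) / 2
  a14 <- -(2 * T * cos(arg) / ebt - rt_neg * 2 * T * sin(arg) / ebt) / 2

  z <- exp(4i * cf * pi * T)
  w <- 2 * exp(-(B * T) + 2i * cf * pi * T) * T
  gain <- abs(
    (-2 * z * T + w * (cos(arg) - rt_neg * sin(arg))) *
    (-2 * z * T + w * (cos(arg) + rt_neg * sin(arg))) *
    (-2 * z * T + w * (cos(arg) - rt_pos * sin(arg))) *
    (-2 * z * T + w * (cos(arg) + rt_pos * sin(arg))) /
    (-2 / exp(2 * B * T) - 2 * z + 2 * (1 + z) / ebt)^4
  )

  a <- c(b0, b1, b2)
  y <- biquad(x, c(a0 / gain, a11 / gain, a2 / gain), a)
  y <- biquad(y, c(a0, a12, a2), a)
  y <- biquad(y, c(a0, a13, a2), a)
  biquad(y, c(a0, a14, a2), a)
}

#' Apply the gammatone filterbank to a waveform
#'
#' Runs the waveform through every band of the filterbank and returns the raw
#' (uncompressed, unrectified) band signals. This stage is linear; the
#' nonlinearity of envelope extraction enters only in the subsequent
#' rectification and power-law compression inside [extract_envelope()].
#'
#' @param w A [waveform()].
#' @param spec A [filterbank_spec()].
#' @return Numeric matrix, one row per band, columns aligned with the input
#'   samples.
#' @export
apply_gammatone_filterbank <- function(w, spec = filterbank_spec()) {
  stopifnot(inherits(w, "waveform"), inherits(spec, "filterbank_spec"))
  if (w$rate_hz <= 2 * spec$f_max_hz) {
    stop("sampling rate must exceed twice the highest center frequency",
         call. = FALSE)
  }
  cfs <- erb_center_frequencies(spec$f_min_hz, spec$f_max_hz, spec$n_bands)
  out <- matrix(0, nrow = spec$n_bands, ncol = length(w$samples))
  for (b in seq_along(cfs)) {
    out[b, ] <- gammatone_filter(w$samples, cfs[b], w$rate_hz)
  }
  out
}

# Anti-aliased rate reduction by uniform bin averaging: integer decimation
# by k = floor(fs / target_hz), so the boxcar is time-invariant (uneven bins
# would modulate out-of-band energy into the retained band). Output samples
# are stamped at bin centers; the < k leftover samples at the end are
# dropped (< one bin, recovered by edge-rule interpolation downstream).
bin_average <- function(x, fs, target_hz) {
  k <- max(1L, floor(fs / target_hz))
  n_full <- floor(length(x) / k)
  m <- colMeans(matrix(x[seq_len(n_full * k)], nrow = k))
  list(samples = as.numeric(m),
       times = ((seq_len(n_full) - 1) * k + k / 2) / fs,
       rate = fs / k)
}

# Interpolate a (time, value) series onto the shared model-rate grid
# t_k = k / rate, k = 0 ... n_out - 1.
to_model_grid <- function(samples, times, rate, n_out) {
  grid <- (seq_len(n_out) - 1) / rate
  stats::approx(times, samples, xout = grid, rule = 2)$y
}

# Zero-phase Butterworth low-pass, order `order` each way.
zp_lowpass <- function(x, fs, cutoff_hz, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

# Zero-phase Butterworth high-pass.
zp_highpass <- function(x, fs, cutoff_hz, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  signal::filtfilt(bf, x)
}

#' Extract the model-rate speech envelope from a waveform
#'
#' The waveform is passed through an ERB-spaced gammatone filterbank; each
#' band is full-wave rectified and compressed with a power law (exponent 0.6
#' by default); the band envelopes are averaged into a single broadband
#' envelope, which is then brought to the 64 Hz model rate with anti-aliased
#' downsampling and low-pass filtered below 8 Hz (zero-phase Butterworth).
#'
#' Downsampling runs in two stages: bin averaging to an intermediate 256 Hz
#' grid (anti-aliasing far above the retained band), a zero-phase low-pass,
#' interpolation onto the 64 Hz trial grid, and the final sub-8 Hz low-pass at
#' the model rate. Values are not clipped at zero after filtering.
#'
#' @param w A [waveform()].
#' @param spec A [filterbank_spec()].
#' @param out_rate_hz Model rate of the returned envelope (default 64 Hz).
#' @param lowpass_hz Final low-pass cutoff (default 8 Hz).
#' @param trial_id Identifier attached to the result.
#' @return An [envelope()] at `out_rate_hz` whose length is
#'   `round(duration * out_rate_hz)`.
#' @export
extract_envelope <- function(w, spec = filterbank_spec(), out_rate_hz = 64,
                             lowpass_hz = 8, trial_id = NA_character_) {
  stopifnot(inherits(w, "waveform"))
  bands <- apply_gammatone_filterbank(w, spec)
  comp <- abs(bands)^spec$compression_exponent
  broad <- colMeans(comp)
  n_out <- round(length(w$samples) / w$rate_hz * out_rate_hz)
  if (n_out < 2) {
    stop("waveform too short for envelope extraction at this rate",
         call. = FALSE)
  }
  inter_hz <- 4 * out_rate_hz
  if (w$rate_hz > inter_hz) {
    ba <- bin_average(broad, w$rate_hz, inter_hz)
    sm <- zp_lowpass(ba$samples, ba$rate, min(lowpass_hz * 2.5,
                                              ba$rate / 2.5))
    env <- to_model_grid(sm, ba$times, out_rate_hz, n_out)
  } else {
    times <- (seq_along(broad) - 0.5) / w$rate_hz
    env <- to_model_grid(broad, times, out_rate_hz, n_out)
  }
  env <- zp_lowpass(env, out_rate_hz, lowpass_hz)
  envelope(env, out_rate_hz, trial_id)
}

#' Preprocess an EEG record for backward-TRF modelling
#'
#' Zero-phase band-pass between `band_hz[1]` and `band_hz[2]` (default 2-8 Hz,
#' implemented as cascaded Butterworth high-pass and low-pass, order 4 each,
#' applied forward and backward), followed by anti-aliased downsampling to the
#' 64 Hz model rate. For numerical robustness at high input rates the record
#' is first bin-averaged to an intermediate 256 Hz grid (the retained band is
#' untouched), band-passed there, and interpolated onto the model-rate grid.
#'
#' @param raw An [eeg_record()] at any rate >= 64 Hz.
#' @param out_rate_hz Output rate (default 64 Hz).
#' @param band_hz Length-2 numeric pass band in Hz.
#' @return An [eeg_record()] at `out_rate_hz` with the same channels.
#' @export
preprocess_eeg <- function(raw, out_rate_hz = 64, band_hz = c(2, 8)) {
  stopifnot(inherits(raw, "eeg_record"))
  if (raw$rate_hz < out_rate_hz) {
    stop("EEG rate must be at least the model rate", call. = FALSE)
  }
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1]) {
    stop("`band_hz` must be an increasing positive pair", call. = FALSE)
  }
  inter_hz <- min(4 * out_rate_hz, raw$rate_hz)
  n_out <- round(ncol(raw$data) / raw$rate_hz * out_rate_hz)
  out <- matrix(0, nrow = nrow(raw$data), ncol = n_out)
  for (ch in seq_len(nrow(raw$data))) {
    x <- raw$data[ch, ]
    if (raw$rate_hz > inter_hz) {
      ba <- bin_average(x, raw$rate_hz, inter_hz)
      y <- ba$samples
      times <- ba$times
      fs <- ba$rate
    } else {
      y <- x
      times <- (seq_along(x) - 0.5) / raw$rate_hz
      fs <- raw$rate_hz
    }
    y <- zp_highpass(y, fs, band_hz[1])
    y <- zp_lowpass(y, fs, band_hz[2])
    out[ch, ] <- to_model_grid(y, times, out_rate_hz, n_out)
  }
  eeg_record(out, out_rate_hz, raw$channel_labels)
}
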