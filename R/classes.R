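#' Construct a waveform object
#'
#' A waveform is an audio-rate signal: a numeric vector of samples together
#' with its sampling rate. Waveforms are the input to [extract_envelope()] and
#' the substrate on which inferred stimuli can be built at full audio
#' resolution.
#'
#' @param samples Numeric vector of finite sample values (arbitrary units).
#' @param rate_hz Positive sampling rate in Hz (e.g. 44100).
#' @return An object of class `"waveform"`: a list with elements `samples`
#'   and `rate_hz`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' @export
waveform <- function(samples, rate_hz) {
  samples <- as.numeric(samples)
  stopifnot_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  if (length(samples) == 0L) {
    stop("waveform must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite", call. = FALSE)
  }
  structure(list(samples = samples, rate_hz = rate_hz), class = "waveform")
}

#' Construct an envelope object
#'
#' An envelope is a one-dimensional representation of a stream's acoustic
#' energy over a trial, sampled on the shared model-rate grid (64 Hz by
#' default). Sample index 1 covers the half-open interval `[0, 1/rate)` s from
#' trial onset. Values may dip slightly below zero after zero-phase low-pass
#' filtering; they are not clipped because Pearson correlation, the evaluation
#' metric throughout, is shift and scale invariant.
#'
#' @param samples Numeric vector of envelope samples.
#' @param rate_hz Sampling rate in Hz; the model rate is 64.
#' @param trial_id Optional identifier carried through the pipeline.
#' @return An object of class `"envelope"`.
#' @export
envelope <- function(samples, rate_hz = 64, trial_id = NA_character_) {
  samples <- as.numeric(samples)
  stopifnot_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  if (!all(is.finite(samples))) {
    stop("envelope samples must all be finite", call. = FALSE)
  }
  structure(list(samples = samples, rate_hz = rate_hz,
                 trial_id = as.character(trial_id)),
            class = "envelope")
}

#' Construct an EEG record
#'
#' @param data Numeric matrix, channels in rows and samples in columns.
#' @param rate_hz Positive sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names; defaults
#'   to `"ch01"`, `"ch02"`, ...
#' @return An object of class `"eeg_record"`.
#' @export
eeg_record <- function(data, rate_hz, channel_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  if (any(!is.finite(data))) {
    stop("EEG data must contain no non-finite entries", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must have one entry per channel (row)",
         call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(list(data = data, rate_hz = rate_hz,
                 channel_labels = as.character(channel_labels)),
            class = "eeg_record")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz))
  invisible(x)
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> trial %s: %d samples @ %g Hz (%.3f s)\n",
              x$trial_id, length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz))
  invisible(x)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$rate_hz))
  invisible(x)
}

n_samples <- function(x) {
  if (inherits(x, "eeg_record")) ncol(x$data) else length(x$samples)
}

as_samples <- function(x) {
  if (inherits(x, c("waveform", "envelope"))) x$samples else as.numeric(x)
}

signal_rate <- function(x, default = NULL) {
  if (inherits(x, c("waveform", "envelope", "eeg_record"))) return(x$rate_hz)
  if (is.null(default)) stop("cannot infer sampling rate", call. = FALSE)
  default
}
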