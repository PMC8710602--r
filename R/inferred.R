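#' Keyword intervals and response windows
#'
#' A keyword interval marks when one keyword was spoken in one stream. A
#' response window is the union of the i-th target and i-th masker keyword
#' intervals — it starts at the onset of whichever keyword appears first and
#' ends at the offset of whichever ends last — and carries the participant's
#' ternary recall response for that row (`"target"`, `"masker"`, or
#' `"extraneous"`).
#'
#' @param onset_s,offset_s Interval bounds in seconds from trial onset,
#'   `0 <= onset_s < offset_s`.
#' @param stream `"target"` or `"masker"`.
#' @return `keyword_interval()` returns a list of class `"keyword_interval"`.
#' @export
keyword_interval <- function(onset_s, offset_s, stream = c("target", "masker")) {
  stream <- match.arg(stream)
  stopifnot_scalar_number(onset_s, "onset_s")
  stopifnot_scalar_number(offset_s, "offset_s")
  if (onset_s < 0 || offset_s <= onset_s) {
    stop("need 0 <= onset_s < offset_s", call. = FALSE)
  }
  structure(list(onset_s = onset_s, offset_s = offset_s, stream = stream),
            class = "keyword_interval")
}

#' Build the three response windows of a trial
#'
#' @param target_kws,masker_kws Lists of three [keyword_interval()]s each, in
#'   temporal order; pair i spans row i of the recall matrix.
#' @param responses Character vector of three responses, each one of
#'   `"target"`, `"masker"`, `"extraneous"`.
#' @return A data frame of class `"response_windows"` with columns `index`,
#'   `start_s`, `end_s`, `response`, plus the four keyword bounds.
#' @rdname keyword_interval
#' @export
make_windows <- function(target_kws, masker_kws, responses) {
  if (length(target_kws) != 3L || length(masker_kws) != 3L ||
      length(responses) != 3L) {
    stop("exactly three keyword pairs and three responses are required",
         call. = FALSE)
  }
  ok <- c("target", "masker", "extraneous")
  if (!all(responses %in% ok)) {
    stop("responses must be 'target', 'masker' or 'extraneous'",
         call. = FALSE)
  }
  rows <- lapply(1:3, function(i) {
    tk <- target_kws[[i]]
    mk <- masker_kws[[i]]
    stopifnot(inherits(tk, "keyword_interval"),
              inherits(mk, "keyword_interval"))
    data.frame(index = i,
               start_s = min(tk$onset_s, mk$onset_s),
               end_s = max(tk$offset_s, mk$offset_s),
               response = responses[i],
               target_onset_s = tk$onset_s, target_offset_s = tk$offset_s,
               masker_onset_s = mk$onset_s, masker_offset_s = mk$offset_s)
  })
  w <- do.call(rbind, rows)
  if (any(diff(w$start_s) <= 0) || any(w$end_s[-3] > w$start_s[-1])) {
    stop("response windows must be temporally ordered and non-overlapping",
         call. = FALSE)
  }
  class(w) <- c("response_windows", "data.frame")
  w
}

#' Inference configuration for the attended-stimulus model
#'
#' Selects one strategy for reconstructing the attended stimulus from the
#' three recall responses:
#'
#' * `scope` — how a window's attention label is extrapolated to un-probed
#'   time. `"segments"` divides the trial into three segments cut halfway
#'   between consecutive windows, each inheriting its window's source;
#'   `"target_windows"` keeps the label inside the window only and assumes the
#'   target stream everywhere in between.
#' * `filler` — what stands in for the attended signal in a window answered
#'   with an extraneous keyword: the target+masker `"mixture"`, the
#'   `"target"`, the `"masker"`, seeded Gaussian `"noise"`, or unrelated
#'   `"other_speech"`; the latter two are RMS-matched to the target.
#' * `switch_duration_s` — attentional switch duration: every change of
#'   source is a complementary raised-cosine crossfade of this length,
#'   centered on the boundary (0 = instantaneous switch).
#'
#' The configuration shown to give the best reconstruction — target-windows
#' scope, mixture filler, 2 s switch — is the default and is what
#' "behavioral decoder" refers to elsewhere in the package.
#'
#' @param scope `"segments"` or `"target_windows"`.
#' @param filler One of `"mixture"`, `"target"`, `"masker"`, `"noise"`,
#'   `"other_speech"`.
#' @param switch_duration_s Crossfade length in seconds (>= 0).
#' @return A list of class `"inference_config"`.
#' @export
inference_config <- function(scope = c("target_windows", "segments"),
                             filler = c("mixture", "target", "masker",
                                        "noise", "other_speech"),
                             switch_duration_s = 2) {
  scope <- match.arg(scope)
  filler <- match.arg(filler)
  stopifnot_scalar_number(switch_duration_s, "switch_duration_s")
  if (switch_duration_s < 0) {
    stop("`switch_duration_s` must be nonnegative", call. = FALSE)
  }
  structure(list(scope = scope, filler = filler,
                 switch_duration_s = switch_duration_s),
            class = "inference_config")
}

# Piecewise-constant source label track implied by (windows, scope):
# a list of breakpoints 0 = b_0 < b_1 < ... < b_K = duration and the label
# ("target" / "masker" / "filler") on each interval. Consecutive intervals
# with equal labels are merged, so every interior breakpoint is a genuine
# source change.
label_track <- function(windows, scope, duration_s) {
  stopifnot(inherits(windows, "response_windows"))
  if (any(windows$end_s > duration_s + 1e-9) || any(windows$start_s < 0)) {
    stop("windows must lie within [0, duration]", call. = FALSE)
  }
  in_label <- ifelse(windows$response == "target", "target",
                     ifelse(windows$response == "masker", "masker", "filler"))
  if (scope == "segments") {
    cuts <- (windows$end_s[-3] + windows$start_s[-1]) / 2
    breaks <- c(0, cuts, duration_s)
    labels <- in_label
  } else {
    breaks <- c(0, as.vector(rbind(windows$start_s, windows$end_s)),
                duration_s)
    labels <- c("target", in_label[1], "target", in_label[2], "target",
                in_label[3], "target")
    # drop zero-length edge pieces (window touching trial start or end)
    keep <- diff(breaks) > 1e-12
    breaks <- c(breaks[1], breaks[-1][keep])
    labels <- labels[keep]
  }
  # merge equal-label neighbours so boundaries are true source changes
  k <- 1
  while (k < length(labels)) {
    if (labels[k] == labels[k + 1]) {
      labels <- labels[-(k + 1)]
      breaks <- breaks[-(k + 1)]
    } else {
      k <- k + 1
    }
  }
  list(breaks = breaks, labels = labels)
}

#' Attention weights realizing the inferred-stimulus model
#'
#' Converts the three response windows plus an [inference_config()] into
#' per-sample mixing weights `w_T(t)`, `w_M(t)`, `w_F(t)` (target, masker,
#' filler) forming a partition of unity: each weight lies in `[0, 1]` and the
#' three sum to 1 at every sample. Inside window i the source dictated by the
#' response has weight 1 on its plateau; outside windows the scope rule
#' applies; every source change is a complementary raised-cosine crossfade of
#' `switch_duration_s` seconds centered on the boundary, with the weight
#' exactly 0.5 at the boundary instant. No ramp is placed at the trial edges.
#' If two boundaries are closer than the switch duration, each ramp is
#' shortened to the midpoint of the gap (and a warning is issued), which
#' keeps the weights complementary.
#'
#' @param windows A [make_windows()] result.
#' @param cfg An [inference_config()].
#' @param duration_s Trial duration in seconds.
#' @param rate_hz Sampling rate of the weight sequences.
#' @param warn_truncation Warn when ramps are shortened; batch callers
#'   (e.g. the evaluation grid) disable this after logging it once.
#' @return A list of class `"attention_weights"` with numeric vectors `w_T`,
#'   `w_M`, `w_F` of length `round(duration_s * rate_hz)` and the generating
#'   `cfg`.
#' @export
attention_weights <- function(windows, cfg, duration_s, rate_hz,
                              warn_truncation = TRUE) {
  stopifnot(inherits(cfg, "inference_config"))
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  trk <- label_track(windows, cfg$scope, duration_s)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  w <- list(target = numeric(n), masker = numeric(n), filler = numeric(n))

  breaks <- trk$breaks
  labels <- trk$labels
  K <- length(labels)
  if (K == 1L) {
    w[[labels]] <- rep(1, n)
  } else {
    s <- cfg$switch_duration_s
    inner <- breaks[2:K]                       # interior boundaries
    gaps_prev <- diff(breaks)[seq_len(K - 1)]  # piece lengths left of each
    gaps_next <- diff(breaks)[2:K]             # and right of each
    half <- pmin(s / 2, gaps_prev / 2, gaps_next / 2)
    if (warn_truncation && s > 0 && any(half < s / 2 - 1e-12)) {
      warning("switch ramps truncated at segment midpoints ",
              "(boundaries closer than the switch duration)", call. = FALSE)
    }
    # weight of the "new" source for boundary j, as a function of time
    ramp_up <- function(tt, b, h) {
      if (h <= 0) return(as.numeric(tt >= b))
      theta <- pmin(pmax((tt - (b - h)) / (2 * h), 0), 1)
      0.5 * (1 - cos(pi * theta))
    }
    # accumulate: start fully on labels[1], then add each transition
    w[[labels[1]]] <- rep(1, n)
    for (j in seq_len(K - 1)) {
      u <- ramp_up(t, inner[j], half[j])
      w[[labels[j]]] <- w[[labels[j]]] - u
      w[[labels[j + 1]]] <- w[[labels[j + 1]]] + u
    }
  }
  structure(list(w_T = w$target, w_M = w$masker, w_F = w$filler,
                 rate_hz = rate_hz, cfg = cfg),
            class = "attention_weights")
}

#' Build the filler signal for extraneous responses
#'
#' @param cfg An [inference_config()]; its `filler` field selects the signal.
#' @param x_T,x_M Target and masker signals ([waveform()] or [envelope()]),
#'   equal rate and length.
#' @param other_speech Unrelated speech signal, required iff
#'   `cfg$filler == "other_speech"`; looped or truncated to the trial length.
#' @param seed Integer seed for the noise filler.
#' @return Numeric vector, same length as `x_T`. Noise and other-speech
#'   fillers are scaled to match the root-mean-square level of the target.
#' @export
make_filler <- function(cfg, x_T, x_M, other_speech = NULL, seed = 1L) {
  xt <- as_samples(x_T)
  xm <- as_samples(x_M)
  if (length(xt) != length(xm)) {
    stop("target and masker must have equal length", call. = FALSE)
  }
  n <- length(xt)
  switch(cfg$filler,
    mixture = xt + xm,
    target = xt,
    masker = xm,
    noise = {
      z <- with_local_seed(seed, stats::rnorm(n))
      z * (rms(xt) / rms(z))
    },
    other_speech = {
      if (is.null(other_speech)) {
        stop("`other_speech` signal required for the other_speech filler",
             call. = FALSE)
      }
      os <- as_samples(other_speech)
      os <- rep_len(os, n)
      os * (rms(xt) / rms(os))
    }
  )
}

#' Build the inferred attended stimulus
#'
#' Assembles the behaviorally inferred attended signal: inside each response
#' window the source named by the response (target, masker, or — for
#' extraneous responses — the filler), extrapolated outside windows by the
#' scope rule, with raised-cosine attentional-switch crossfades. Operates on
#' waveforms or directly on envelopes (the envelope-domain fast path used in
#' simulation studies).
#'
#' When the weights select a single source everywhere (e.g. all three
#' responses are "target" under the target-windows scope), the input signal
#' is returned unchanged, so the inferred stimulus is bit-identical to the
#' target — the exact-identity property that makes behavioral and
#' assume-target decoders coincide when no errors occur.
#'
#' @param x_T,x_M Target and masker signals ([waveform()] or [envelope()] or
#'   bare numeric vectors), time-aligned, equal rate and length.
#' @param windows A [make_windows()] result.
#' @param cfg An [inference_config()].
#' @param rate_hz Sampling rate; inferred from `x_T` if it carries one.
#' @param other_speech Optional unrelated speech for the other-speech filler.
#' @param seed Seed for the noise filler.
#' @param warn_truncation Passed to [attention_weights()].
#' @return Numeric vector: the inferred signal at `rate_hz`.
#' @export
build_inferred_signal <- function(x_T, x_M, windows, cfg,
                                  rate_hz = signal_rate(x_T),
                                  other_speech = NULL, seed = 1L,
                                  warn_truncation = TRUE) {
  xt <- as_samples(x_T)
  xm <- as_samples(x_M)
  if (length(xt) != length(xm)) {
    stop("target and masker must have equal length", call. = FALSE)
  }
  duration_s <- length(xt) / rate_hz
  wts <- attention_weights(windows, cfg, duration_s, rate_hz,
                           warn_truncation = warn_truncation)
  n <- length(xt)
  stopifnot(length(wts$w_T) == n)
  out <- numeric(n)
  # add only active components so single-source regions stay bit-exact
  if (any(wts$w_T > 0)) out <- out + ifelse(wts$w_T == 1, xt, wts$w_T * xt)
  if (any(wts$w_M > 0)) out <- out + wts$w_M * xm
  if (any(wts$w_F > 0)) {
    f <- make_filler(cfg, xt, xm, other_speech = other_speech, seed = seed)
    out <- out + wts$w_F * f
  }
  out
}
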