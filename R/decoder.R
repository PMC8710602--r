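#' Lag specification for backward-TRF decoding
#'
#' Backward stimulus reconstruction estimates the envelope at time `t` from
#' the EEG between `t` and `t + 900` ms (the stimulus precedes the neural
#' response it evokes). At the 64 Hz model rate this is the integer lag grid
#' -57 ... 0 samples — 58 lags in steps of one EEG sample (15.625 ms).
#'
#' @param min_lag_ms,max_lag_ms Lag range in milliseconds, `min <= max <= 0`.
#' @param rate_hz Model rate in Hz.
#' @return A list of class `"lag_spec"` with the integer `lag_samples` grid
#'   and `step_ms`, the lag step in milliseconds.
#' @examples
#' lag_spec()                # 58 lags, -900 to 0 ms at 64 Hz
#' @export
lag_spec <- function(min_lag_ms = -900, max_lag_ms = 0, rate_hz = 64) {
  if (min_lag_ms > max_lag_ms) stop("need min_lag_ms <= max_lag_ms",
                                    call. = FALSE)
  stopifnot_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  lags <- seq(ceiling(min_lag_ms / 1000 * rate_hz),
              floor(max_lag_ms / 1000 * rate_hz))
  structure(list(min_lag_ms = min_lag_ms, max_lag_ms = max_lag_ms,
                 rate_hz = rate_hz, lag_samples = as.integer(lags),
                 step_ms = 1000 / rate_hz),
            class = "lag_spec")
}

#' Build the lagged EEG design matrix
#'
#' Stacks time-shifted copies of every channel into the `(N*L) x T` design
#' matrix `R` of the backward model: row `(n, tau)` at column `t` holds
#' channel `n` at time `t - tau` (zero where that index falls outside the
#' recording). `T` is the trial length plus `|min lag|` samples, so the
#' envelope must be zero-padded to the same length (see [pad_envelope()]).
#' Rows are grouped by channel, lags varying fastest.
#'
#' @param eeg An [eeg_record()] at the model rate.
#' @param spec A [lag_spec()].
#' @return Numeric matrix `(channels * lags) x T`.
#' @export
build_lag_matrix <- function(eeg, spec = lag_spec()) {
  stopifnot(inherits(eeg, "eeg_record"), inherits(spec, "lag_spec"))
  X <- eeg$data
  if (ncol(X) == 0L) stop("EEG record is empty", call. = FALSE)
  lags <- spec$lag_samples
  L <- length(lags)
  N <- nrow(X)
  Tn <- ncol(X)
  Tp <- Tn + max(0L, -min(lags))
  out <- matrix(0, nrow = N * L, ncol = Tp)
  for (li in seq_len(L)) {
    tau <- lags[li]
    src <- seq_len(Tn) - tau          # channel sample index for column t
    valid <- src >= 1L & src <= Tn
    cols <- seq_len(Tn)[valid]
    rows <- (seq_len(N) - 1L) * L + li
    out[rows, cols] <- X[, src[valid], drop = FALSE]
  }
  rn <- as.vector(t(outer(eeg$channel_labels, lags, paste, sep = "@")))
  rownames(out) <- rn
  out
}

#' Zero-pad an envelope to the lagged design length
#'
#' @param env An [envelope()] or numeric vector.
#' @param spec A [lag_spec()]; the envelope is padded with
#'   `|min(lag_samples)|` zeros at the end.
#' @return Numeric vector of padded samples.
#' @export
pad_envelope <- function(env, spec = lag_spec()) {
  s <- as_samples(env)
  c(s, numeric(max(0L, -min(spec$lag_samples))))
}

#' Fit a backward-TRF decoder by ridge regression
#'
#' Solves the regularized normal equations `d = (R R' + lambda I)^(-1) R S'`,
#' the exact ridge estimate of the decoder weights. With `lambda = 0` and a
#' singular Gram matrix, the minimum-norm least-squares solution is returned
#' (SVD pseudo-inverse) with a warning. The default regularization is
#' `lambda = 10^0.5`, appropriate for standardized EEG channels and centered
#' envelopes (see [loo_reconstruction_accuracy()]).
#'
#' When `T < N*L` the solution is computed through the dual identity
#' `(R R' + lambda I)^(-1) R = R (R' R + lambda I)^(-1)`, which is
#' algebraically exact and avoids factorizing the larger Gram matrix.
#'
#' @param R Lagged design matrix from [build_lag_matrix()], `(N*L) x T`.
#' @param S Envelope samples padded to `T` columns ([pad_envelope()]).
#' @param lambda Ridge parameter, `>= 0`; default `10^0.5`.
#' @param spec The [lag_spec()] used to build `R` (metadata only).
#' @return A list of class `"trf_decoder"` with fields `weights` (length
#'   `N*L`), `lambda`, and `lagspec`.
#' @export
fit_ridge_decoder <- function(R, S, lambda = 10^0.5, spec = lag_spec()) {
  S <- as_samples(S)
  if (ncol(R) != length(S)) {
    stop("design matrix and envelope lengths disagree", call. = FALSE)
  }
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  d <- ridge_solve(R, S, lambda)
  structure(list(weights = as.numeric(d), lambda = lambda, lagspec = spec),
            class = "trf_decoder")
}

ridge_solve <- function(R, S, lambda) {
  p <- nrow(R)
  Tn <- ncol(R)
  if (lambda == 0) {
    G <- tcrossprod(R)
    d <- tryCatch(solve(G, R %*% S), error = function(e) NULL)
    if (is.null(d)) {
      warning("singular system at lambda = 0; using the SVD pseudo-inverse",
              call. = FALSE)
      sv <- svd(R)
      tol <- max(dim(R)) * .Machine$double.eps * sv$d[1]
      pos <- sv$d > tol
      d <- sv$u[, pos, drop = FALSE] %*%
        ((crossprod(sv$v[, pos, drop = FALSE], S)) / sv$d[pos])
    }
    return(d)
  }
  if (Tn < p) {
    # dual form: d = R (R'R + lambda I)^(-1) S
    G <- crossprod(R)
    diag(G) <- diag(G) + lambda
    R %*% solve(G, S)
  } else {
    G <- tcrossprod(R)
    diag(G) <- diag(G) + lambda
    solve(G, R %*% S)
  }
}

#' Reconstruct an envelope from lagged EEG with a decoder
#'
#' Applies the backward model `S_hat(t) = sum_n sum_tau d[n, tau] *
#' R[(n, tau), t]`, i.e. `S_hat = d' R`, on the padded time grid, returned at
#' the model rate.
#'
#' @param d A `"trf_decoder"` from [fit_ridge_decoder()], or a bare numeric
#'   weight vector.
#' @param R Lagged design matrix with `N*L` rows.
#' @param rate_hz Rate of the returned envelope.
#' @return An [envelope()] of length `ncol(R)`.
#' @export
reconstruct_envelope <- function(d, R, rate_hz = 64) {
  w <- if (inherits(d, "trf_decoder")) d$weights else as.numeric(d)
  if (length(w) != nrow(R)) {
    stop("decoder weight length must equal nrow(R)", call. = FALSE)
  }
  envelope(as.numeric(crossprod(w, R)), rate_hz)
}

#' Pearson correlation between two signals
#'
#' Reconstruction accuracy metric: the product-moment correlation between a
#' reconstructed and a reference envelope, computed over their full (padded)
#' common support.
#'
#' @param a,b Equal-length numeric vectors (or envelope objects), length >= 3,
#'   each with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  a <- as_samples(a)
  b <- as_samples(b)
  if (length(a) != length(b)) stop("signals must have equal length",
                                   call. = FALSE)
  if (length(a) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for zero-variance signal", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Fisher z-transform of a correlation
#'
#' `atanh(r)`, variance-stabilizing for averaging and paired testing of
#' correlation coefficients.
#'
#' @param r Correlation value(s), `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}

# Standardize EEG channels (zero mean, unit variance) and center an envelope;
# makes a fixed lambda meaningful across signal scales.
standardize_eeg <- function(eeg) {
  X <- eeg$data
  mu <- rowMeans(X)
  X <- X - mu
  sdv <- sqrt(rowMeans(X^2))
  sdv[sdv == 0] <- 1
  eeg_record(X / sdv, eeg$rate_hz, eeg$channel_labels)
}

# Per-trial decoder precomputation shared by every training-envelope kind:
# the lagged design (on standardized EEG by default) and the Cholesky factor
# of its regularized Gram matrix, which does not depend on the envelope.
prepare_trial_design <- function(eeg, spec, lambda, standardize = TRUE) {
  if (standardize) eeg <- standardize_eeg(eeg)
  R <- build_lag_matrix(eeg, spec)
  p <- nrow(R)
  Tn <- ncol(R)
  dual <- Tn < p && lambda > 0
  G <- if (dual) crossprod(R) else tcrossprod(R)
  diag(G) <- diag(G) + lambda
  ch <- chol(G)
  list(R = R, chol = ch, dual = dual, T_padded = Tn)
}

# Ridge weights for one prepared trial and one (padded, centered) envelope.
decoder_weights_from_prep <- function(prep, s_padded) {
  if (prep$dual) {
    prep$R %*% backsolve(prep$chol, forwardsolve(t(prep$chol), s_padded))
  } else {
    rhs <- prep$R %*% s_padded
    backsolve(prep$chol, forwardsolve(t(prep$chol), rhs))
  }
}

#' Leave-one-trial-out stimulus-reconstruction accuracy
#'
#' Fits one decoder per trial on the chosen training envelope (the original
#' target envelope, or the behaviorally inferred envelope), then reconstructs
#' each held-out trial with the unweighted mean of the other trials' decoder
#' weights. Accuracy is always scored against the held-out trial's original
#' target envelope, whichever envelope was used in training, so the
#' assume-target and behavioral decoders are directly comparable.
#'
#' EEG channels are standardized and envelopes mean-centered per trial before
#' fitting (switchable), so the default `lambda = 10^0.5` is meaningful
#' across scales.
#'
#' @param trials List of trial records; each element needs `eeg` (an
#'   [eeg_record()] at the model rate), `env_target` ([envelope()]), an
#'   envelope matching `train_on` (`env_inferred` when
#'   `train_on = "inferred"`), and optionally `trial_id`.
#' @param train_on `"target"` or `"inferred"`: which envelope the decoders
#'   are trained on.
#' @param lambda Ridge parameter.
#' @param spec A [lag_spec()].
#' @param standardize Standardize EEG and center envelopes before fitting.
#' @return Data frame with one row per trial: `trial_id`, `decoder_kind`
#'   (`"target"` or `"behavioral"`), `r`, `z`.
#' @export
loo_reconstruction_accuracy <- function(trials,
                                        train_on = c("target", "inferred"),
                                        lambda = 10^0.5, spec = lag_spec(),
                                        standardize = TRUE) {
  train_on <- match.arg(train_on)
  bundle <- loo_prepare(trials, lambda, spec, standardize = standardize)
  envs <- lapply(trials, function(tr) {
    e <- if (train_on == "target") tr$env_target else tr$env_inferred
    if (is.null(e)) {
      stop(sprintf("trial lacks the '%s' training envelope", train_on),
           call. = FALSE)
    }
    as_samples(e)
  })
  r <- loo_scores(bundle, envs)
  data.frame(trial_id = bundle$ids,
             decoder_kind = if (train_on == "target") "target"
                            else "behavioral",
             r = r, z = atanh(r))
}

#' Precompute per-trial decoder designs for repeated LOO evaluation
#'
#' Factorizes each trial's regularized Gram matrix once so that many training
#' envelopes (e.g. every cell of an inference-strategy grid) can be evaluated
#' against the same EEG cheaply. Used together with [loo_scores()].
#'
#' @inheritParams loo_reconstruction_accuracy
#' @return An opaque bundle for [loo_scores()].
#' @export
loo_prepare <- function(trials, lambda = 10^0.5, spec = lag_spec(),
                        standardize = TRUE) {
  if (length(trials) < 2) stop("need at least 2 trials", call. = FALSE)
  preps <- lapply(trials, function(tr) {
    prepare_trial_design(tr$eeg, spec, lambda, standardize = standardize)
  })
  ref <- lapply(trials, function(tr) pad_envelope(tr$env_target, spec))
  ids <- vapply(seq_along(trials), function(i) {
    id <- trials[[i]]$trial_id
    if (is.null(id)) sprintf("trial%02d", i) else as.character(id)
  }, character(1))
  structure(list(preps = preps, ref = ref, ids = ids, spec = spec,
                 standardize = standardize, lambda = lambda,
                 n = length(trials)),
            class = "loo_bundle")
}

#' Held-out reconstruction accuracies for one set of training envelopes
#'
#' @param bundle A [loo_prepare()] result.
#' @param envelopes List (one per trial) of training envelopes ([envelope()]
#'   objects or numeric vectors at the model rate, unpadded).
#' @return Numeric vector of held-out Pearson r values, one per trial,
#'   scored against each trial's original target envelope.
#' @export
loo_scores <- function(bundle, envelopes) {
  stopifnot(inherits(bundle, "loo_bundle"))
  n <- bundle$n
  if (length(envelopes) != n) {
    stop("need one training envelope per trial", call. = FALSE)
  }
  train <- lapply(seq_len(n), function(i) {
    s <- pad_envelope(as_samples(envelopes[[i]]), bundle$spec)
    if (bundle$standardize) s - mean(s) else s
  })
  W <- vapply(seq_len(n), function(i) {
    as.numeric(decoder_weights_from_prep(bundle$preps[[i]], train[[i]]))
  }, numeric(nrow(bundle$preps[[1]]$R)))
  wsum <- rowSums(W)
  vapply(seq_len(n), function(i) {
    d_avg <- (wsum - W[, i]) / (n - 1)
    shat <- as.numeric(crossprod(d_avg, bundle$preps[[i]]$R))
    pearson_r(shat, bundle$ref[[i]])
  }, numeric(1))
}
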