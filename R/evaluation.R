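#' Voice distance in semitones
#'
#' Total target-masker voice distance: the Euclidean norm of the fundamental
#' frequency (F0) and vocal-tract length (VTL) shifts, both expressed in
#' semitones: `sqrt(dF0^2 + dVTL^2)`.
#'
#' @param delta_f0_st F0 shift in semitones.
#' @param delta_vtl_st VTL shift in semitones.
#' @return Distance in semitones (unrounded; round only for display).
#' @examples
#' round(semitone_distance(-3.2, 1.21), 2) # 3.42
#' round(semitone_distance(-4.8, 1.82), 2) # 5.13
#' @export
semitone_distance <- function(delta_f0_st, delta_vtl_st) {
  if (!all(is.finite(delta_f0_st)) || !all(is.finite(delta_vtl_st))) {
    stop("inputs must be finite", call. = FALSE)
  }
  sqrt(delta_f0_st^2 + delta_vtl_st^2)
}

#' Relative gain between two reconstruction accuracies
#'
#' `100 * (r_new - r_old) / r_old`, rounded to the nearest integer percent.
#'
#' @param r_old Baseline accuracy (nonzero).
#' @param r_new Improved accuracy.
#' @return Gain in percent, nearest integer.
#' @examples
#' relative_gain(0.09, 0.11) # 22
#' @export
relative_gain <- function(r_old, r_new) {
  if (any(r_old == 0)) stop("`r_old` must be nonzero", call. = FALSE)
  round(100 * (r_new - r_old) / r_old)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at 1),
#' delegated to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, never smaller than the input.
#' @export
adjust_pvalues_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Inferred envelopes for a list of simulated trials under one inference
# configuration (envelope-domain fast path). The other-speech filler borrows
# the target envelope of another trial, chosen with a seeded draw.
build_inferred_for_trials <- function(trials, cfg) {
  n <- length(trials)
  lapply(seq_len(n), function(i) {
    tr <- trials[[i]]
    other <- NULL
    if (cfg$filler == "other_speech" && n > 1) {
      j <- with_local_seed(child_seed(tr$seed, 7),
                           sample(setdiff(seq_len(n), i), 1))
      other <- trials[[j]]$env_target
    }
    build_inferred_signal(tr$env_target, tr$env_masker, tr$windows, cfg,
                          other_speech = other,
                          seed = child_seed(tr$seed, 8),
                          warn_truncation = FALSE)
  })
}

#' Reconstruction-accuracy grid over inference strategies
#'
#' Evaluates every combination of condition x scope x filler x switch
#' duration on a simulated dataset: builds the inferred envelopes for each
#' cell, trains leave-one-trial-out decoders on them, and summarizes
#' reconstruction accuracy (scored, as always, against the original target
#' envelope). Mean z is the mean of `atanh(r)` values, not `atanh` of the
#' mean r.
#'
#' @param dataset A [gen_dataset()] result.
#' @param scopes,fillers,speeds Character/numeric vectors spanning the grid.
#' @param lambda Ridge parameter.
#' @param spec A [lag_spec()].
#' @return Data frame with one row per cell: `condition`, `scope`, `filler`,
#'   `switch_duration_s`, `mean_r`, `mean_z`, `n_trials`, `n_subjects`.
#'   Per-subject means are in `attr(, "per_subject")`.
#' @export
run_grid <- function(dataset,
                     scopes = c("target_windows", "segments"),
                     fillers = c("mixture", "target", "masker", "noise",
                                 "other_speech"),
                     speeds = c(1, 2, 3),
                     lambda = 10^0.5, spec = lag_spec()) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (length(scopes) == 0 || length(fillers) == 0 || length(speeds) == 0) {
    stop("grid axes must be non-empty", call. = FALSE)
  }
  conditions <- dataset$cfg$conditions$condition
  cells <- expand.grid(condition = conditions, scope = scopes,
                       filler = fillers, switch_duration_s = speeds,
                       stringsAsFactors = FALSE)
  per_subject <- list()
  for (subj in dataset$subjects) {
    for (cond in conditions) {
      trials <- trials_by_condition(subj, cond)
      bundle <- loo_prepare(trials, lambda, spec)
      for (ci in which(cells$condition == cond)) {
        cfg <- inference_config(cells$scope[ci], cells$filler[ci],
                                cells$switch_duration_s[ci])
        envs <- build_inferred_for_trials(trials, cfg)
        r <- loo_scores(bundle, envs)
        per_subject[[length(per_subject) + 1L]] <- data.frame(
          subject_id = subj$subject_id,
          condition = cond,
          scope = cells$scope[ci],
          filler = cells$filler[ci],
          switch_duration_s = cells$switch_duration_s[ci],
          mean_r = mean(r),
          mean_z = mean(atanh(r)),
          n_trials = length(trials))
      }
    }
  }
  ps <- do.call(rbind, per_subject)
  agg <- stats::aggregate(
    cbind(mean_r, mean_z) ~ condition + scope + filler + switch_duration_s,
    data = ps, FUN = mean)
  agg$n_trials <- dataset$cfg$n_trials_per_condition
  agg$n_subjects <- length(dataset$subjects)
  attr(agg, "per_subject") <- ps
  agg
}

#' Contrast the behavioral decoder against the assume-target decoder
#'
#' For each condition, computes per-subject mean Fisher-z reconstruction
#' accuracy for decoders trained on the original target envelope and for
#' decoders trained on the behaviorally inferred envelope (by default the
#' best-performing configuration: target-windows scope, mixture filler, 2 s
#' switch), then runs a paired test across subjects with Benjamini-Hochberg
#' adjustment across conditions. If the two decoders are numerically
#' identical in a condition (no behavioral errors anywhere), the difference
#' is exactly zero and `p = 1` by convention.
#'
#' @param dataset A [gen_dataset()] result with at least 2 subjects.
#' @param lambda Ridge parameter.
#' @param behavioral_cfg The [inference_config()] defining the behavioral
#'   decoder.
#' @param spec A [lag_spec()].
#' @param alternative Passed to [stats::t.test()]; `"greater"` tests
#'   behavioral > target.
#' @return Data frame with one row per condition: subject-mean accuracies
#'   for both decoders, the paired t statistic, `p_value` and `adjusted_p`.
#'   Per-subject means are in `attr(, "per_subject")`.
#' @export
contrast_decoders <- function(dataset, lambda = 10^0.5,
                              behavioral_cfg = inference_config(),
                              spec = lag_spec(),
                              alternative = "two.sided") {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (length(dataset$subjects) < 2) {
    stop("need at least 2 subjects for a paired contrast", call. = FALSE)
  }
  conditions <- dataset$cfg$conditions$condition
  rows <- list()
  per_subject <- list()
  for (cond in conditions) {
    zt <- zr <- rt <- rb <- numeric(0)
    for (subj in dataset$subjects) {
      trials <- trials_by_condition(subj, cond)
      bundle <- loo_prepare(trials, lambda, spec)
      envs_b <- build_inferred_for_trials(trials, behavioral_cfg)
      envs_t <- lapply(trials, function(tr) as_samples(tr$env_target))
      r_t <- loo_scores(bundle, envs_t)
      r_b <- loo_scores(bundle, envs_b)
      rt <- c(rt, mean(r_t)); rb <- c(rb, mean(r_b))
      zt <- c(zt, mean(atanh(r_t))); zr <- c(zr, mean(atanh(r_b)))
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject_id = subj$subject_id, condition = cond,
        mean_r_target = mean(r_t), mean_r_behavioral = mean(r_b),
        mean_z_target = mean(atanh(r_t)), mean_z_behavioral = mean(atanh(r_b)))
    }
    d <- zr - zt
    if (all(d == 0)) {
      stat <- 0; p <- 1
    } else {
      tt <- stats::t.test(zr, zt, paired = TRUE, alternative = alternative)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond,
      mean_r_target_decoder = mean(rt),
      mean_r_behavioral_decoder = mean(rb),
      mean_z_target_decoder = mean(zt),
      mean_z_behavioral_decoder = mean(zr),
      statistic = stat, p_value = p,
      n_subjects = length(dataset$subjects))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- adjust_pvalues_bh(out$p_value)
  attr(out, "per_subject") <- do.call(rbind, per_subject)
  out
}
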