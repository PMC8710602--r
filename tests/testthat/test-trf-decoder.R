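test_that("lag grid covers -900 to 0 ms in single-sample steps", {
  sp <- lag_spec()
  expect_equal(sp$lag_samples, -57:0)
  expect_length(sp$lag_samples, 58)
  expect_equal(sp$step_ms, 1000 / 64)
  expect_equal(round(sp$step_ms, 1), 15.6)
})

test_that("lag matrix matches the hand-constructed shift oracle", {
  # identity at lag 0
  x <- c(0.5, -1, 2, 4)
  R0 <- build_lag_matrix(eeg_record(matrix(x, 1), 64), lag_spec(0, 0))
  expect_equal(unname(R0), matrix(x, 1))

  # lags {-1, 0}: row tau holds x[t - tau], zero-padded
  R <- build_lag_matrix(eeg_record(matrix(c(1, 2, 3), 1), 64),
                        lag_spec(-1000 / 64, 0))
  expect_equal(unname(R), rbind(c(2, 3, 0, 0),
                                c(1, 2, 3, 0)))

  # full-size dimensions: 31 channels x 58 lags, 12 s trial
  eeg <- eeg_record(matrix(rnorm(31 * 768), 31), 64)
  Rf <- build_lag_matrix(eeg, lag_spec())
  expect_equal(dim(Rf), c(31 * 58, 768 + 57))
})

test_that("ridge solution obeys closed forms and shrinks to zero", {
  withr::with_seed(1, {
    r <- rnorm(40)
    s <- 0.3 * r + rnorm(40, sd = 0.1)
  })
  R1 <- matrix(r, 1)
  # scalar closed form
  for (lam in c(0.1, 1, 10)) {
    d <- fit_ridge_decoder(R1, s, lam)
    expect_equal(d$weights, sum(r * s) / (sum(r * r) + lam),
                 tolerance = 1e-10)
  }
  # infinite shrinkage
  dbig <- fit_ridge_decoder(R1, s, 1e12 * sum(r^2))
  expect_lt(abs(dbig$weights), 1e-6)
})

test_that("ridge estimate attains the penalized least-squares optimum", {
  # brute-force quadratic minimizer as the independent oracle
  objective <- function(d, R, s, lam) {
    sum((s - as.numeric(crossprod(d, R)))^2) + lam * sum(d^2)
  }
  for (seed in 1:50) {
    withr::with_seed(seed, {
      p <- sample(3:8, 1)
      Tn <- 40
      R <- matrix(rnorm(p * Tn), p)
      s <- rnorm(Tn)
      lam <- 10^runif(1, -2, 2)
    })
    d_hat <- fit_ridge_decoder(R, s, lam)$weights
    opt <- stats::optim(rep(0, p), objective, R = R, s = s, lam = lam,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    expect_lte(objective(d_hat, R, s, lam), opt$value + 1e-8)
  }
})

test_that("decoder norm is monotone non-increasing in lambda", {
  withr::with_seed(7, {
    R <- matrix(rnorm(12 * 60), 12)
    s <- rnorm(60)
  })
  lambdas <- 10^seq(-3, 3, by = 1)
  norms <- vapply(lambdas, function(l) {
    sqrt(sum(fit_ridge_decoder(R, s, l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("lambda = 0 on a singular system falls back to the pseudo-inverse", {
  R <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8)) # rank 1
  s <- c(1, 2, 3, 4)
  expect_warning(d <- fit_ridge_decoder(R, s, 0), "pseudo-inverse")
  # prediction must still be the least-squares fit
  expect_equal(as.numeric(crossprod(d$weights, R)), s, tolerance = 1e-8)
})

test_that("reconstruction is the linear map d'R", {
  eeg <- eeg_record(matrix(rnorm(3 * 100), 3), 64)
  sp <- lag_spec(-3000 / 64, 0)
  R <- build_lag_matrix(eeg, sp)
  expect_equal(reconstruct_envelope(rep(0, nrow(R)), R)$samples,
               rep(0, ncol(R)))
  withr::with_seed(2, {
    d1 <- rnorm(nrow(R))
    d2 <- rnorm(nrow(R))
  })
  expect_equal(reconstruct_envelope(d1 + d2, R)$samples,
               reconstruct_envelope(d1, R)$samples +
                 reconstruct_envelope(d2, R)$samples,
               tolerance = 1e-10)

  # exact recovery: EEG that IS the envelope at lag 0
  env <- gen_stream(12, 3)
  sp0 <- lag_spec(0, 0)
  R0 <- build_lag_matrix(eeg_record(matrix(env$samples, 1), 64), sp0)
  d <- fit_ridge_decoder(R0, pad_envelope(env, sp0), 0, sp0)
  shat <- reconstruct_envelope(d, R0)
  expect_gt(pearson_r(shat, pad_envelope(env, sp0)), 0.999)
})

test_that("pearson_r matches the sum-of-products oracle and edge cases", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 4, 5, 9)
  n <- 4
  oracle <- (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  expect_equal(pearson_r(a, b), oracle, tolerance = 1e-12)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_error(pearson_r(a, rep(1, 4)), "zero-variance")
  expect_error(pearson_r(a, b[1:3]), "equal length")
  expect_error(pearson_r(a[1:2], b[1:2]), "3 samples")
})

test_that("fisher_z is atanh with odd symmetry and domain checks", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log((1 + 0.5) / (1 - 0.5)),
               tolerance = 1e-12)
  r <- c(0.1, 0.37, 0.92)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "< 1")
})

test_that("leave-one-out averaging uses the mean of the other decoders", {
  trials <- fixture_trials(n_trials = 4, n_channels = 2, snr = 2, seed = 3)
  sp <- lag_spec()
  bundle <- loo_prepare(trials, spec = sp)
  envs <- lapply(trials, function(tr) tr$env_target$samples)
  r <- loo_scores(bundle, envs)

  # independent recomputation for held-out trial 1: average the decoders of
  # trials 2..4 fit individually, reconstruct, correlate
  others <- 2:4
  W <- vapply(others, function(i) {
    eeg_std <- inferTRF:::standardize_eeg(trials[[i]]$eeg)
    R <- build_lag_matrix(eeg_std, sp)
    s <- pad_envelope(trials[[i]]$env_target, sp)
    fit_ridge_decoder(R, s - mean(s), 10^0.5, sp)$weights
  }, numeric(2 * 58))
  d_avg <- rowMeans(W)
  R1 <- build_lag_matrix(inferTRF:::standardize_eeg(trials[[1]]$eeg), sp)
  shat <- reconstruct_envelope(d_avg, R1)
  r1 <- pearson_r(shat, pad_envelope(trials[[1]]$env_target, sp))
  expect_equal(r[1], r1, tolerance = 1e-10)
})

test_that("two identical trials give identical held-out accuracies", {
  tr <- fixture_trials(n_trials = 1, n_channels = 3, snr = 1, seed = 9)[[1]]
  res <- loo_reconstruction_accuracy(list(tr, tr), "target")
  expect_equal(res$r[1], res$r[2])
  expect_equal(res$z, atanh(res$r))
  expect_error(loo_reconstruction_accuracy(list(tr), "target"), "2 trials")
})

test_that("decoder trained on the target beats the masker reference", {
  # EEG encodes only the target stream: reconstructions must correlate
  # better with the target than with the masker in nearly every trial
  trials <- fixture_trials(n_trials = 8, n_channels = 4, snr = 1, seed = 13)
  sp <- lag_spec()
  bundle <- loo_prepare(trials, spec = sp)
  envs <- lapply(trials, function(tr) tr$env_target$samples)
  r_target <- loo_scores(bundle, envs)
  # rescore the same reconstructions against the masker envelope
  W <- vapply(seq_along(trials), function(i) {
    as.numeric(inferTRF:::decoder_weights_from_prep(
      bundle$preps[[i]],
      {
        s <- pad_envelope(trials[[i]]$env_target, sp)
        s - mean(s)
      }))
  }, numeric(4 * 58))
  wsum <- rowSums(W)
  r_masker <- vapply(seq_along(trials), function(i) {
    d_avg <- (wsum - W[, i]) / (length(trials) - 1)
    shat <- as.numeric(crossprod(d_avg, bundle$preps[[i]]$R))
    pearson_r(shat, pad_envelope(trials[[i]]$env_masker, sp))
  }, numeric(1))
  expect_true(mean(r_target > r_masker) >= 0.95)
})

test_that("held-out accuracy does not improve as EEG noise grows", {
  mean_r <- vapply(c(10, 0.5, 0.05), function(snr) {
    rs <- vapply(1:6, function(seed) {
      trials <- fixture_trials(n_trials = 5, n_channels = 3, snr = snr,
                               seed = seed)
      mean(loo_reconstruction_accuracy(trials, "target")$r)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})
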