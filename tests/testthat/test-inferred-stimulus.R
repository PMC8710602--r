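test_that("response windows span the union of paired keywords", {
  w1 <- make_windows(
    list(keyword_interval(2.0, 2.5, "target"),
         keyword_interval(5.0, 5.4, "target"),
         keyword_interval(8.0, 8.4, "target")),
    list(keyword_interval(2.2, 2.8, "masker"),
         keyword_interval(5.0, 5.4, "masker"),
         keyword_interval(9.2, 9.6, "masker")),
    c("target", "masker", "extraneous"))
  # overlapping pair -> union
  expect_equal(w1$start_s[1], 2.0)
  expect_equal(w1$end_s[1], 2.8)
  # identical pair -> the interval itself
  expect_equal(w1$start_s[2], 5.0)
  expect_equal(w1$end_s[2], 5.4)
  # keywords separated by over a second still form one window
  expect_equal(w1$start_s[3], 8.0)
  expect_equal(w1$end_s[3], 9.6)
  expect_equal(w1$response, c("target", "masker", "extraneous"))

  # overlapping consecutive windows violate the task structure
  expect_error(make_windows(
    list(keyword_interval(2.0, 4.5, "target"),
         keyword_interval(4.0, 4.4, "target"),
         keyword_interval(8.0, 8.4, "target")),
    list(keyword_interval(2.0, 4.5, "masker"),
         keyword_interval(4.0, 4.4, "masker"),
         keyword_interval(8.0, 8.4, "masker")),
    rep("target", 3)), "overlap")
})

test_that("all-target responses give unit target weight for both scopes", {
  win <- fixture_windows(c("target", "target", "target"))
  for (scope in c("target_windows", "segments")) {
    for (sw in c(0, 1, 3)) {
      w <- attention_weights(win, inference_config(scope, "mixture", sw),
                             12, 64)
      expect_equal(w$w_T, rep(1, 768))
      expect_equal(w$w_M, rep(0, 768))
      expect_equal(w$w_F, rep(0, 768))
    }
  }
})

test_that("target-windows scope switches to the masker inside its window only", {
  win <- fixture_windows(c("target", "masker", "target"))
  # ramp short enough to leave a plateau inside the 0.6 s window
  w <- attention_weights(win, inference_config("target_windows", "mixture",
                                               0.4), 12, 64)
  t <- (seq_len(768) - 1) / 64
  plateau <- t >= win$start_s[2] + 0.25 & t <= win$end_s[2] - 0.25
  expect_true(any(plateau))
  expect_true(all(w$w_M[plateau] > 0.999))
  far <- t < win$start_s[2] - 1 | t > win$end_s[2] + 1
  expect_true(all(w$w_T[far] == 1))
  expect_equal(w$w_T + w$w_M, rep(1, 768), tolerance = 1e-12)

  # with a 2 s switch the ramps are truncated but stay complementary, and
  # the masker still dominates the window center
  w2 <- attention_weights(win, inference_config("target_windows", "mixture",
                                                2), 12, 64,
                          warn_truncation = FALSE)
  center <- which.min(abs(t - (win$start_s[2] + win$end_s[2]) / 2))
  expect_gt(w2$w_M[center], 0.9)
  expect_equal(w2$w_T + w2$w_M, rep(1, 768), tolerance = 1e-12)
})

test_that("segments scope holds each window's source up to the halfway cut", {
  kw <- list(
    tk = list(keyword_interval(2.7, 3.3, "target"),
              keyword_interval(8.7, 9.3, "target"),
              keyword_interval(11.0, 11.3, "target")),
    mk = list(keyword_interval(2.7, 3.3, "masker"),
              keyword_interval(8.7, 9.3, "masker"),
              keyword_interval(11.0, 11.3, "masker")))
  win <- make_windows(kw$tk, kw$mk, c("target", "masker", "masker"))
  w <- attention_weights(win, inference_config("segments", "mixture", 1),
                         12, 64, warn_truncation = FALSE)
  t <- (seq_len(768) - 1) / 64
  # cut point halfway between window 1 (ends 3.3) and window 2 (starts 8.7)
  cut <- (3.3 + 8.7) / 2
  expect_true(all(w$w_T[t < cut - 0.5] == 1))
  expect_true(all(w$w_M[t > cut + 0.5 & t < 9.9] == 1))
  # the crossfade is centered on the cut: weight exactly 0.5 there
  at_cut <- which.min(abs(t - cut))
  expect_equal(w$w_T[at_cut], 0.5, tolerance = 0.02)
})

test_that("crossfade weight is exactly 0.5 at the boundary instant", {
  # place a window edge exactly on a sample time
  tk <- list(keyword_interval(2, 3, "target"),
             keyword_interval(6, 7, "target"),
             keyword_interval(10, 10.5, "target"))
  win <- make_windows(tk, tk, c("target", "masker", "target"))
  w <- attention_weights(win, inference_config("target_windows", "mixture", 1),
                         12, 64)
  t <- (seq_len(768) - 1) / 64
  expect_equal(w$w_M[t == 6], 0.5)
  expect_equal(w$w_T[t == 6], 0.5)
  expect_equal(w$w_M[t == 7], 0.5)
})

test_that("weights form a partition of unity over random layouts", {
  for (seed in 1:200) {
    win <- random_windows(seed)
    cfg <- inference_config(
      scope = c("target_windows", "segments")[seed %% 2 + 1],
      filler = c("mixture", "noise")[seed %% 2 + 1],
      switch_duration_s = c(0, 1, 2, 3)[seed %% 4 + 1])
    w <- suppressWarnings(attention_weights(win, cfg, 12, 64))
    expect_lt(max(abs(w$w_T + w$w_M + w$w_F - 1)), 1e-9)
    expect_true(all(w$w_T >= 0 & w$w_T <= 1))
    expect_true(all(w$w_M >= 0 & w$w_M <= 1))
    expect_true(all(w$w_F >= 0 & w$w_F <= 1))
  }
})

test_that("ramps too long for the gaps are truncated with a warning", {
  win <- fixture_windows(c("target", "masker", "target"))
  expect_warning(
    attention_weights(win, inference_config("target_windows", "mixture", 10),
                      12, 64),
    "truncated")
})

test_that("fillers obey their definitions and RMS matching", {
  xt <- gen_stream(10, 1)
  xm <- gen_stream(10, 2)
  zero <- envelope(rep(0, 640), 64)

  mix <- make_filler(inference_config(filler = "mixture"), xt, zero)
  expect_identical(mix, xt$samples)
  expect_equal(make_filler(inference_config(filler = "mixture"), xt, xm),
               xt$samples + xm$samples)
  expect_identical(make_filler(inference_config(filler = "target"), xt, xm),
                   xt$samples)
  expect_identical(make_filler(inference_config(filler = "masker"), xt, xm),
                   xm$samples)

  nz <- make_filler(inference_config(filler = "noise"), xt, xm, seed = 9)
  expect_equal(sqrt(mean(nz^2)) / sqrt(mean(xt$samples^2)), 1,
               tolerance = 1e-6)
  nz2 <- make_filler(inference_config(filler = "noise"), xt, xm, seed = 9)
  expect_identical(nz, nz2)

  other <- gen_stream(4, 3)
  os <- make_filler(inference_config(filler = "other_speech"), xt, xm,
                    other_speech = other)
  expect_length(os, 640)
  expect_equal(sqrt(mean(os^2)) / sqrt(mean(xt$samples^2)), 1,
               tolerance = 1e-6)
  expect_error(make_filler(inference_config(filler = "other_speech"), xt, xm),
               "other_speech")
})

test_that("inferred signal reduces to the target under all-target responses", {
  xt <- gen_stream(12, 11)
  xm <- gen_stream(12, 12)
  win <- fixture_windows(c("target", "target", "target"))
  for (scope in c("target_windows", "segments")) {
    for (sw in c(0.5, 2)) {
      xi <- build_inferred_signal(xt, xm, win,
                                  inference_config(scope, "mixture", sw))
      expect_identical(xi, xt$samples)
    }
  }
})

test_that("extraneous windows carry the exact mixture on their plateau", {
  xt <- gen_stream(12, 21)
  xm <- gen_stream(12, 22)
  win <- fixture_windows(c("target", "extraneous", "target"))
  xi <- build_inferred_signal(xt, xm, win,
                              inference_config("target_windows", "mixture",
                                               0.2))
  t <- (seq_len(768) - 1) / 64
  plateau <- t >= win$start_s[2] + 0.15 & t <= win$end_s[2] - 0.15
  expect_true(any(plateau))
  expect_equal(xi[plateau], xt$samples[plateau] + xm$samples[plateau],
               tolerance = 1e-12)
})

test_that("zero-ramp limit matches a sample-by-sample piecewise oracle", {
  xt <- gen_stream(12, 31)
  xm <- gen_stream(12, 32)
  win <- fixture_windows(c("target", "masker", "extraneous"))
  cfg <- inference_config("target_windows", "mixture", 0)
  xi <- build_inferred_signal(xt, xm, win, cfg)

  # brute-force piecewise evaluator without crossfades
  t <- (seq_len(768) - 1) / 64
  oracle <- xt$samples
  for (i in 1:3) {
    inside <- t >= win$start_s[i] & t < win$end_s[i]
    oracle[inside] <- switch(win$response[i],
      target = xt$samples[inside],
      masker = xm$samples[inside],
      extraneous = xt$samples[inside] + xm$samples[inside])
  }
  expect_equal(xi, oracle, tolerance = 1e-12)
})

test_that("inferred construction is deterministic given the seed", {
  xt <- gen_stream(12, 41)
  xm <- gen_stream(12, 42)
  win <- fixture_windows(c("extraneous", "masker", "extraneous"))
  cfg <- inference_config("segments", "noise", 1.5)
  a <- build_inferred_signal(xt, xm, win, cfg, seed = 77)
  b <- build_inferred_signal(xt, xm, win, cfg, seed = 77)
  expect_identical(a, b)
  c <- build_inferred_signal(xt, xm, win, cfg, seed = 78)
  expect_false(identical(a, c))
})

test_that("waveform-domain and envelope-domain constructions agree", {
  fs <- 16000
  dur <- 12
  wt <- modulated_noise(dur, fs, seed = 51, mod_hz = 3)
  wm <- modulated_noise(dur, fs, seed = 52, mod_hz = 5)
  tk <- list(keyword_interval(2.0, 2.5, "target"),
             keyword_interval(6.0, 6.5, "target"),
             keyword_interval(10.0, 10.4, "target"))
  win <- make_windows(tk, tk, c("target", "masker", "extraneous"))
  cfg <- inference_config("target_windows", "mixture", 1)

  xi_wave <- build_inferred_signal(wt, wm, win, cfg, warn_truncation = FALSE)
  env_wave <- extract_envelope(waveform(xi_wave, fs))

  env_t <- extract_envelope(wt)
  env_m <- extract_envelope(wm)
  env_mixed <- build_inferred_signal(env_t, env_m, win, cfg,
                                     warn_truncation = FALSE)
  expect_gte(pearson_r(env_wave$samples, env_mixed), 0.95)
})
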