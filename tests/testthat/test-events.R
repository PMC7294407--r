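test_that("SO detection applies the duration-only criterion", {
  fs <- 200
  t <- seq(0, 30, by = 1 / fs)
  # 1 Hz: each 0.5-s negative half-wave qualifies
  so1 <- detect_so(sin(2 * pi * t), fs)
  expect_equal(nrow(so1), 29)                      # last cycle lacks a peak
  expect_true(all(abs(so1$zc_up - so1$zc_down - 0.5) < 0.02))
  expect_true(all(so1$trough_amp < 0 & so1$peak_amp > 0))
  # 3 Hz: half-waves of 0.167 s are below the 0.25-s bound
  expect_equal(nrow(detect_so(sin(2 * pi * 3 * t), fs)), 0)
  # constructed: one 0.9-s and one 1.2-s negative half-wave -> 1 event
  mk_half <- function(dur, amp) -amp * sin(pi * seq(0, 1, length.out = dur * fs))
  x <- c(numeric(fs), mk_half(0.9, 50), 30 * sin(pi * seq(0, 1, length.out = fs / 2)),
         mk_half(1.2, 50), 30 * sin(pi * seq(0, 1, length.out = fs / 2)),
         numeric(fs))
  so2 <- detect_so(x, fs)
  expect_equal(nrow(so2), 1)
  expect_lt(abs((so2$zc_up - so2$zc_down) - 0.9), 0.03)
  # amplitude blindness: scaling the trace changes nothing but amplitudes
  so3 <- detect_so(x / 10, fs)
  expect_equal(nrow(so3), 1)
  expect_equal(so3$trough_time, so2$trough_time)
})

test_that("spindle threshold is the 86.64th percentile", {
  expect_equal(spindle_threshold(rep(3.5, 2000)), 3.5)
  set.seed(6)
  u <- stats::runif(2e5)
  expect_lt(abs(spindle_threshold(u) - 0.8664), 0.005)
  z <- abs(stats::rnorm(1e6))
  # half-normal quantile at 0.8664 is 1.4996 ~ the 1.5 SD equivalence
  expect_lt(abs(spindle_threshold(z) - stats::qnorm(0.5 + 0.8664 / 2)), 0.01)
  expect_error(spindle_threshold(numeric(0)), "empty")
})

test_that("spindle detector keeps genuine bursts and drops impostors", {
  fs <- 200
  set.seed(13)
  n <- 60 * fs
  bg <- soclas:::.pink_noise(n, 6)
  burst <- function(freq, dur, amp, at) {
    w <- amp * soclas:::.hann(round(dur * fs)) *
      sin(2 * pi * freq * seq(0, dur, length.out = round(dur * fs)))
    x <- numeric(n); x[at:(at + length(w) - 1)] <- w; x
  }
  x <- bg + burst(13, 1.0, 30, 20 * fs)
  sp <- detect_spindles(x, fs, kernel = cached_kernel("spindle"))
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$onset - 20), 0.3)
  expect_lt(abs(sp$peak_freq - 13), 1)
  expect_gte(sp$n_oscillations, 9)
  expect_lte(sp$n_oscillations, 14)
  # 0.2-s burst: below the duration bound
  x2 <- bg + burst(13, 0.2, 30, 20 * fs)
  expect_equal(nrow(detect_spindles(x2, fs,
                                    kernel = cached_kernel("spindle"))), 0)
  # equal-power 13 + 22 Hz: bimodal wavelet spectrum, rejected
  x3 <- bg + burst(13, 1.0, 25, 20 * fs) + burst(22, 1.0, 25, 20 * fs)
  sp3 <- detect_spindles(x3, fs, kernel = cached_kernel("spindle"))
  expect_equal(nrow(sp3), 0)
  # scale invariance of the count (threshold is a percentile of the trace)
  sp_scaled <- detect_spindles(3 * x, fs, kernel = cached_kernel("spindle"))
  expect_equal(nrow(sp_scaled), nrow(sp))
})

test_that("trial assembly computes measures, lag and exclusions", {
  fs <- 200
  t <- seq(0, 120, by = 1 / fs)
  swa <- 80 * sin(2 * pi * t / 1.2)                 # 1.2-s period SO train
  so <- detect_so(swa, fs)
  hyp <- data.frame(epoch = 0:3, stage = c("N3", "N3", "N2", "N3"))
  spind <- data.frame(onset = c(10.0, 31.0), offset = c(10.8, 31.8),
                      duration = c(0.8, 0.8), rms = c(6, 7),
                      amplitude = c(20, 22), peak_freq = c(13, 13.5),
                      n_oscillations = c(10, 10))
  # peaks at 0.3 + 1.2 k, troughs at 0.9 + 1.2 k; clicks on peaks
  log <- data.frame(click1_time = c(9.0, 30.3, 99.9, 45.0),
                    click2_time = c(10.1, 31.4, 100.1, 46.1),
                    condition = "STIM")
  tr <- build_trials(log, so, spind, swa, fs, hyp)
  # trial 1: next trough at 9.3; spindle onset 10.0 inside [9.3, 10.5]
  expect_false(tr$excluded[1])
  expect_lt(abs(tr$post_trough_time[1] - 9.3), 0.05)
  expect_equal(tr$post_trough_amp[1], 80, tolerance = 0.01)
  expect_equal(tr$ss_likelihood_flag[1], 1L)
  expect_equal(tr$ss_latency[1], spind$onset[1] - 9.0, tolerance = 0.05)
  expect_equal(tr$ss_duration[1], 0.8)
  # lag to the previous spindle (trial 2 clicked 20.3 s after onset 10.0)
  expect_equal(tr$lag_s[2], 30.3 - 10.0, tolerance = 1e-6)
  # trial 3: second click (100.1) precedes the next trough (~100.5)
  expect_true(tr$excluded[3])
  expect_match(tr$excl_reason[3], "second click")
  # trial 4 is in an N2 epoch (epoch 2 covers 60-90 s? no: 45 s is epoch 1)
  # -> construct instead: click at 65 s lies in epoch 2 = N2
  tr2 <- build_trials(data.frame(click1_time = 65, click2_time = 66.1,
                                 condition = "STIM"), so, spind, swa, fs, hyp)
  expect_true(tr2$excluded[1])
  expect_equal(tr2$excl_reason[1], "stage")
  # artifact overlap
  tr3 <- build_trials(log[1, ], so, spind, swa, fs, hyp,
                      artifacts = data.frame(start = 9, end = 9.5))
  expect_true(tr3$excluded[1])
  expect_equal(tr3$excl_reason[1], "artifact")
  # spindle before the click does not count (but defines the lag)
  tr4 <- build_trials(data.frame(click1_time = 33.9, click2_time = 35.0,
                                 condition = "STIM"), so, spind, swa, fs, hyp)
  expect_equal(tr4$ss_likelihood_flag[1], 0L)
  expect_equal(tr4$lag_s[1], 33.9 - 31.0, tolerance = 1e-6)
  expect_error(build_trials(data.frame(click1_time = 500, click2_time = 501,
                                       condition = "STIM"),
                            so, spind, swa, fs, hyp), "outside")
})

test_that("threshold demandingness is a simple amplitude ratio", {
  expect_equal(threshold_demandingness(c(-120), c(-80, -120)), 120)
  expect_equal(threshold_demandingness(c(-90, -110), c(-90, -110)), 100)
  set.seed(3)
  all_tr <- -stats::rnorm(500, 100, 10)
  top <- all_tr[all_tr < -100]
  expect_gt(threshold_demandingness(top, all_tr), 100)
  expect_error(threshold_demandingness(numeric(0), -80), "empty")
})
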