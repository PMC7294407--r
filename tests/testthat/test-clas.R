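test_that("threshold update rules match the protocol descriptions", {
  ul <- protocol_config("uLub")
  # preceding-5-s minimum above default: stay at default
  expect_equal(update_threshold(c(-70, -50, -60), NA, ul), -80)
  expect_equal(update_threshold(c(-120, -50), NA, ul), -120)
  ua <- protocol_config("uAnd")
  expect_equal(update_threshold(-150, NA, ua), -75)   # half of -150 < -60
  expect_equal(update_threshold(-100, NA, ua), -60)   # half of -100 > -60
  expect_error(protocol_config("uLub", default_threshold = 10), "negative")
})

test_that("variant defaults follow the historical protocols", {
  expect_equal(protocol_config("uLub")$default_threshold, -80)
  expect_equal(protocol_config("uAnd")$default_threshold, -60)
  expect_equal(protocol_config("uLub")$isi_s, 1.076)
  expect_equal(protocol_config("uAnd")$isi_s, 1.053)
  expect_equal(protocol_config("uTub")$isi_s, 1.096)
  expect_equal(protocol_config("uLub")$stim_period_s, 12600)
  expect_equal(protocol_config("uAnd")$stim_period_s, 15000)
  expect_equal(protocol_config("uLub")$pause_s, 2.5)
})

test_that("streamed detection on sinusoids matches hand simulation", {
  fs <- 200
  dur <- 700
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  hyp <- data.frame(epoch = 0:(dur / 30 - 1), stage = "N3")
  proto <- protocol_config("uLub", click_delay_jitter_s = 0)
  # 60-uV sine never crosses the -80 uV threshold
  log0 <- stream_detect_troughs(60 * sin(2 * pi * 0.75 * t), fs, proto, hyp)
  expect_equal(nrow(log0), 0)
  # 100-uV sine: crossings after arming at 300 s; spacing at least the
  # trial span plus the 2.5-s pause
  x <- 100 * sin(2 * pi * 0.75 * t)
  log1 <- stream_detect_troughs(x, fs, proto, hyp)
  expect_gt(nrow(log1), 10)
  expect_true(all(log1$detected_trough_amp < -80))
  expect_lt(max(abs(log1$detected_trough_amp + 100)), 8)
  gaps <- diff(log1$first_click_time)
  span <- proto$isi_s + proto$pause_s
  expect_true(all(gaps >= span - 1e-6))
  # hand simulation: detection pauses until click2 + 2.5 s, then fires at
  # the next sine trough; one trial per ceiling(busy / period) periods
  period <- 1 / 0.75
  busy <- proto$click_delay_s + proto$isi_s + proto$pause_s
  expect_true(all(abs(gaps - ceiling(busy / period) * period) < 0.1))
  avail <- dur - 300
  expect_lt(abs(nrow(log1) - avail / (ceiling(busy / period) * period)), 4)
  # first click precedes trough detection by click_delay_s exactly
  expect_equal(log1$first_click_time - log1$detected_trough_time,
               rep(proto$click_delay_s, nrow(log1)), tolerance = 1e-6)
  expect_equal(log1$second_click_time - log1$first_click_time,
               rep(proto$isi_s, nrow(log1)), tolerance = 1e-6)
})

test_that("STIM and SHAM runs on identical input have identical timing", {
  cfg <- synth_config(duration_s = 600, seed = 21)
  gen <- generate_recording(cfg)
  proto <- protocol_config("uLub")
  set.seed(99)
  a <- stream_detect_troughs(gen$recording$channels$Fz, 200, proto,
                             gen$recording$hypnogram, condition = "STIM")
  set.seed(99)
  b <- stream_detect_troughs(gen$recording$channels$Fz, 200, proto,
                             gen$recording$hypnogram, condition = "SHAM")
  expect_equal(a$first_click_time, b$first_click_time)
  expect_equal(a$detected_trough_time, b$detected_trough_time)
  expect_equal(unique(b$condition), "SHAM")
})

test_that("clicks never fall outside N2/N3 or armed periods", {
  cfg <- synth_config(duration_s = 900, seed = 22)
  gen <- generate_recording(cfg)
  hyp <- gen$recording$hypnogram
  hyp$stage[15:18] <- "R"                    # carve a REM hole
  proto <- protocol_config("uLub")
  set.seed(1)
  log <- stream_detect_troughs(gen$recording$channels$Fz, 200, proto, hyp,
                               gen$recording$artifacts)
  ep <- floor(log$first_click_time / 30)
  expect_true(all(hyp$stage[ep + 1] %in% c("N2", "N3")))
  expect_true(all(log$first_click_time >= 300))
  if (nrow(gen$recording$artifacts))
    for (i in seq_len(nrow(gen$recording$artifacts)))
      expect_false(any(log$first_click_time >= gen$recording$artifacts$start[i] &
                         log$first_click_time <= gen$recording$artifacts$end[i]))
})

test_that("click waveform is a ramped pink-noise burst", {
  proto <- protocol_config("uLub")
  w <- make_click_waveform(proto, 44100, seed = 2)
  expect_length(w, 2205)                      # 50 ms at 44.1 kHz
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
  expect_lte(max(abs(w)), 1)
  # log-log amplitude spectral slope of a long pink stream ~ -1/2
  set.seed(3)
  x <- soclas:::.pink_noise(2^17, 1)
  sp <- Mod(stats::fft(x))[2:2^16]
  f <- seq_len(2^16 - 1)
  sel <- f > 2^6 & f < 2^14
  slope <- stats::coef(stats::lm(log(sp[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  expect_error(make_click_waveform(proto, 4000), "8 kHz")
})

test_that("causal online filter requires an adequate sampling rate", {
  expect_error(online_so_filter(numeric(100), fs = 6), "fs too low")
})
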