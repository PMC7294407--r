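test_that("SWA band-pass meets every printed response point", {
  k <- cached_kernel("swa")
  g0 <- abs(fir_amplitude(k, sqrt(0.5 * 2)))
  # -3 dB corners within 5%
  expect_lt(abs(k$corners_real[1] - 0.25) / 0.25, 0.05)
  expect_lt(abs(k$corners_real[2] - 3.08) / 3.08, 0.05)
  # stopband attenuation
  att4 <- -20 * log10(abs(fir_amplitude(k, 4)) / g0)
  expect_gte(att4, 37)
  expect_gte(min(k$stop_atten_db), 37)
  # passband gain at the geometric band centre within +-0.5 dB
  expect_lt(abs(20 * log10(abs(fir_amplitude(k, 1)) / 1)), 0.5)
})

test_that("spindle band-pass meets every printed response point", {
  k <- cached_kernel("spindle")
  g0 <- abs(fir_amplitude(k, sqrt(11 * 16)))
  expect_lt(abs(k$corners_real[1] - 10.62) / 10.62, 0.05)
  expect_lt(abs(k$corners_real[2] - 17.38) / 17.38, 0.05)
  att18 <- -20 * log10(abs(fir_amplitude(k, 18)) / g0)
  expect_gte(att18, 40)
  expect_gte(min(k$stop_atten_db), 40)
})

test_that("designed kernels are linear phase (tap symmetry)", {
  for (k in list(cached_kernel("swa"), cached_kernel("spindle"))) {
    h <- k$taps
    expect_lt(max(abs(h - rev(h))), 1e-12)       # type I symmetric
    expect_equal(length(h) %% 2, 1)
  }
  hh <- cached_kernel("hilbert")$taps
  expect_lt(max(abs(hh + rev(hh))), 1e-12)       # type III antisymmetric
})

test_that("infeasible band-pass spec errors", {
  expect_error(filter_spec(c(11, 16), c(10.62, 17.38), c(10.01, 18), 40,
                           "bandpass", fs = 30),
               "Nyquist|fs too low")
})

test_that("zero-phase application has unit gain, zero lag and same length", {
  k <- cached_kernel("swa")
  fs <- 200
  t <- seq(0, 120, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  y <- apply_zero_phase(k, x)
  expect_length(y, length(x))
  mid <- 5000:15000
  expect_lt(abs(max(y[mid]) - 1), 0.01)
  cc <- stats::ccf(x[mid], y[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # out-of-band tone is suppressed to the designed residual
  y10 <- apply_zero_phase(k, sin(2 * pi * 10 * t))
  expect_lt(max(abs(y10[mid])), 0.02)
  # constant zero in, zero out
  expect_equal(apply_zero_phase(k, numeric(10000)), numeric(10000))
  expect_error(apply_zero_phase(k, numeric(100)), "too short")
})

test_that("zero-phase filtering commutes with time reversal", {
  k <- cached_kernel("spindle")
  set.seed(42)
  x <- stats::rnorm(8000)
  y1 <- rev(apply_zero_phase(k, rev(x)))
  y2 <- apply_zero_phase(k, x)
  mid <- 2000:6000   # away from the differing edge paddings
  expect_lt(max(abs(y1[mid] - y2[mid])), 1e-8)
})

test_that("resampling preserves ramps and sine amplitude", {
  ramp <- seq(0, 1, length.out = 15001)          # 30 s at 500 Hz
  y <- resample_linear(ramp, 500, 200)
  expected <- stats::approx((0:15000) / 500, ramp,
                            xout = seq(0, 30, by = 1 / 200))$y
  expect_lt(max(abs(y - expected)[1000:5000]), 1e-9)
  t5 <- seq(0, 30, by = 1 / 500)
  ys <- resample_linear(sin(2 * pi * 1 * t5), 500, 200)
  t2 <- seq(0, 30, by = 1 / 200)
  expect_lt(max(abs(ys - sin(2 * pi * 1 * t2))[2000:4000]), 0.01)
  # rate-preserving call is identity up to passband ripple
  yi <- resample_linear(sin(2 * pi * 1 * t2), 200, 200)
  expect_lt(max(abs(yi - sin(2 * pi * 1 * t2))[2000:4000]), 0.01)
  expect_error(resample_linear(ramp, 200, 500), "upsampling")
})

test_that("moving RMS matches closed forms", {
  fs <- 200
  expect_equal(moving_rms(rep(-3, 1000), 0.2, fs), rep(3, 1000))
  t <- seq(0, 30, by = 1 / fs)
  r <- moving_rms(sin(2 * pi * 13 * t), 0.2, fs)
  expect_lt(abs(r[3000] - 1 / sqrt(2)), 0.02)
  z <- numeric(1000); z[500] <- 7
  n <- round(0.2 * fs)
  expect_equal(max(moving_rms(z, 0.2, fs)), 7 / sqrt(n))
})

test_that("Hilbert transformer: delay, in-band gain, quarter-cycle shift", {
  h <- cached_kernel("hilbert")
  expect_equal(h$delay, 50)                        # 0.25 s x 200 Hz
  amps <- fir_amplitude(h, seq(0.5, 2, by = 0.05))
  expect_true(all(amps >= 0.95 & amps <= 1.05))
  fs <- 200
  t <- seq(0, 60, by = 1 / fs)
  x <- cos(2 * pi * 1 * t)
  xh <- apply_hilbert(h, x)
  mid <- 3000:8000
  expect_lt(max(abs(xh[mid] - sin(2 * pi * 1 * t[mid]))), 0.06)
  expect_error(design_hilbert(200, delay_s = 0.2501), "integer")
})

test_that("phase at a click only uses samples up to click + delay", {
  h <- cached_kernel("hilbert")
  fs <- 200
  t <- seq(0, 40, by = 1 / fs)
  x <- sin(2 * pi * 0.75 * t)
  ph_full <- analytic_phase(x, h)
  click <- 5000
  ph_trunc <- analytic_phase(x[1:(click + h$delay)], h)
  expect_lt(abs(circ_diff(ph_full[click], ph_trunc[click])), 1)
})
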