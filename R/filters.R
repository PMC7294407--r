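#' Filter specification
#'
#' Describes a linear-phase FIR filter by its realized response contract:
#' the -3 dB corners, the stopband edges, and the minimum stopband
#' attenuation the designed kernel must attain. The design routine is free
#' to pick the kernel length; the spec is what is tested.
#'
#' @param passband numeric(2), nominal passband in Hz.
#' @param corner_3db numeric(2), frequencies (Hz) where the realized
#'   magnitude response must be 3 dB below the passband gain.
#' @param stop_edges numeric(2), frequencies (Hz) beyond which the response
#'   must be attenuated by at least `min_stop_atten_db`.
#' @param min_stop_atten_db minimum stopband attenuation in dB (positive).
#' @param kind `"bandpass"` or `"hilbert"`.
#' @param fs sampling rate in Hz.
#' @param delay_s group delay in seconds (hilbert kind only).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(passband, corner_3db, stop_edges, min_stop_atten_db,
                        kind = c("bandpass", "hilbert"), fs, delay_s = NULL) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    stopifnot(length(passband) == 2L, length(corner_3db) == 2L,
              length(stop_edges) == 2L)
    if (!(corner_3db[1] <= passband[1] && corner_3db[2] >= passband[2]))
      stop("corner_3db must straddle the passband")
    if (!(stop_edges[1] < corner_3db[1] && stop_edges[2] > corner_3db[2]))
      stop("stop_edges must lie outside corner_3db")
    if (stop_edges[2] > fs / 2)
      stop("upper stop edge beyond Nyquist: fs too low for this design")
  }
  structure(list(passband = passband, corner_3db = corner_3db,
                 stop_edges = stop_edges,
                 min_stop_atten_db = min_stop_atten_db,
                 kind = kind, fs = fs, delay_s = delay_s),
            class = "filter_spec")
}

#' Offline slow-wave-activity band-pass specification
#'
#' 0.5-2 Hz passband with -3 dB corners at 0.25 and 3.08 Hz and >= 37 dB
#' attenuation below 0.01 Hz and above 4 Hz.
#'
#' @param fs sampling rate in Hz (default 200).
#' @export
swa_filter_spec <- function(fs = 200) {
  filter_spec(passband = c(0.5, 2), corner_3db = c(0.25, 3.08),
              stop_edges = c(0.01, 4), min_stop_atten_db = 37,
              kind = "bandpass", fs = fs)
}

#' Offline sleep-spindle band-pass specification
#'
#' 11-16 Hz passband with -3 dB corners at 10.62 and 17.38 Hz and >= 40 dB
#' attenuation below 10.01 Hz and above 18 Hz.
#'
#' @param fs sampling rate in Hz (default 200).
#' @export
spindle_filter_spec <- function(fs = 200) {
  filter_spec(passband = c(11, 16), corner_3db = c(10.62, 17.38),
              stop_edges = c(10.01, 18), min_stop_atten_db = 40,
              kind = "bandpass", fs = fs)
}

#' Mono-component conditioning band-pass for the phase path
#'
#' A stricter 0.5-2 Hz band-pass applied before the Hilbert transformer.
#' The transformer's gain is only controlled inside the slow-wave band,
#' so the analytic pair is computed on this band-limited trace; event
#' measures still come from the broad SWA trace.
#'
#' @param fs sampling rate in Hz (default 200).
#' @export
phase_filter_spec <- function(fs = 200) {
  filter_spec(passband = c(0.6, 1.8), corner_3db = c(0.5, 2.0),
              stop_edges = c(0.15, 3.0), min_stop_atten_db = 30,
              kind = "bandpass", fs = fs)
}

## modified Bessel I0 via base besselI
.kaiser_window <- function(n, beta) {
  k <- seq(0, n - 1)
  x <- beta * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2))
  besselI(x, 0) / besselI(beta, 0)
}

.kaiser_beta <- function(atten_db) {
  if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
}

## ideal bandpass taps windowed by Kaiser; fc at ~ -6 dB points
.windowed_bandpass <- function(n, fc1, fc2, fs, beta) {
  m <- (n - 1) / 2
  k <- seq(0, n - 1) - m
  f1 <- fc1 / fs
  f2 <- fc2 / fs
  h <- ifelse(k == 0, 2 * (f2 - f1),
              (sin(2 * pi * f2 * k) - sin(2 * pi * f1 * k)) / (pi * k))
  h * .kaiser_window(n, beta)
}

#' Amplitude response of a linear-phase FIR kernel
#'
#' Evaluates the zero-phase amplitude `A(f)` (may be signed) of a symmetric
#' or antisymmetric kernel at arbitrary frequencies, by direct summation.
#'
#' @param kernel numeric taps or a `fir_kernel` object.
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz (taken from the kernel if available).
#' @return numeric vector of signed amplitudes.
#' @export
fir_amplitude <- function(kernel, f, fs = NULL) {
  if (inherits(kernel, "fir_kernel")) {
    if (is.null(fs)) fs <- kernel$fs
    h <- kernel$taps
  } else h <- as.numeric(kernel)
  if (is.null(fs)) stop("fs required")
  n <- length(h)
  m <- (n - 1) / 2
  w <- 2 * pi * f / fs
  sym <- max(abs(h + rev(h))) >= max(abs(h - rev(h)))
  out <- numeric(length(f))
  ## chunked to bound memory for long kernels / dense grids
  idx <- seq_along(f)
  for (chunk in split(idx, ceiling(idx / 256))) {
    if (sym) {
      ## A(w) = h[m] + 2 sum h[m+k] cos(kw)
      kk <- seq_len(m)
      cmat <- cos(outer(w[chunk], kk))
      out[chunk] <- h[m + 1] + 2 * drop(cmat %*% h[m + 1 + kk])
    } else {
      ## type III: H(w) = exp(-iwm) * (-i) * A(w), A(w) = 2 sum h[m+k] sin(kw)
      kk <- seq_len(m)
      smat <- sin(outer(w[chunk], kk))
      out[chunk] <- 2 * drop(smat %*% h[m + 1 + kk])
    }
  }
  out
}

.db <- function(x) 20 * log10(abs(x))

## locate the realized -3 dB crossing between f_lo and f_hi (Hz)
.find_3db <- function(taps, fs, g0, f_lo, f_hi) {
  target <- g0 / sqrt(2)
  fn <- function(f) abs(fir_amplitude(taps, f, fs)) - target
  stats::uniroot(fn, lower = f_lo, upper = f_hi, tol = 1e-7)$root
}

#' Design a linear-phase band-pass FIR filter
#'
#' Kaiser-windowed sinc design with automatic kernel length and numeric
#' calibration of the ideal cutoffs so that the realized magnitude response
#' has its -3 dB points on `spec$corner_3db` (within 5%) and attains
#' `spec$min_stop_atten_db` beyond `spec$stop_edges`. The realized response
#' is verified before returning; an infeasible spec raises an error.
#'
#' @param spec a [filter_spec()] of kind `"bandpass"`.
#' @return object of class `fir_kernel`: list with `taps`, `fs`, `spec`,
#'   and the measured `corners_real` / stopband attenuations.
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"), spec$kind == "bandpass")
  fs <- spec$fs
  atten <- spec$min_stop_atten_db + 8     # design margin over the contract
  beta <- .kaiser_beta(atten)
  ## transition width from stop edge to (reflected) passband edge
  df1 <- 2 * (spec$corner_3db[1] - spec$stop_edges[1])
  df2 <- 2 * (spec$stop_edges[2] - spec$corner_3db[2])
  dw <- 2 * pi * min(df1, df2) / fs
  n <- ceiling((atten - 7.95) / (2.285 * dw))
  if (n %% 2 == 0) n <- n + 1
  fc <- spec$corner_3db
  for (attempt in 1:4) {
    ok <- TRUE
    for (it in 1:6) {
      taps <- .windowed_bandpass(n, fc[1], fc[2], fs, beta)
      f0 <- sqrt(prod(spec$passband))
      g0 <- abs(fir_amplitude(taps, f0, fs))
      r1 <- tryCatch(.find_3db(taps, fs, g0, spec$stop_edges[1], f0),
                     error = function(e) NA_real_)
      r2 <- tryCatch(.find_3db(taps, fs, g0, f0, spec$stop_edges[2]),
                     error = function(e) NA_real_)
      if (anyNA(c(r1, r2))) { ok <- FALSE; break }
      err <- c(spec$corner_3db[1] - r1, spec$corner_3db[2] - r2)
      if (max(abs(err) / spec$corner_3db) < 5e-4) break
      fc <- fc + err
      if (fc[1] <= 0 || fc[2] >= fs / 2 || fc[1] >= fc[2]) { ok <- FALSE; break }
    }
    if (ok) {
      taps <- taps / abs(fir_amplitude(taps, sqrt(prod(spec$passband)), fs))
      meas <- .measure_bandpass(taps, spec)
      if (meas$ok) {
        kern <- structure(list(taps = taps, fs = fs, spec = spec,
                               corners_real = meas$corners,
                               stop_atten_db = meas$stop_atten_db,
                               n = n), class = "fir_kernel")
        return(kern)
      }
    }
    n <- as.integer(round(n * 1.3))
    if (n %% 2L == 0L) n <- n + 1L
  }
  stop("design error: could not meet the filter spec at fs = ", fs,
       " Hz (try a higher sampling rate or a looser spec)")
}

.measure_bandpass <- function(taps, spec) {
  fs <- spec$fs
  f0 <- sqrt(prod(spec$passband))
  g0 <- abs(fir_amplitude(taps, f0, fs))
  corners <- c(.find_3db(taps, fs, g0, spec$stop_edges[1], f0),
               .find_3db(taps, fs, g0, f0, spec$stop_edges[2]))
  lo_grid <- seq(1e-4, spec$stop_edges[1], length.out = 60)
  hi_grid <- seq(spec$stop_edges[2], fs / 2, length.out = 400)
  a_lo <- -.db(fir_amplitude(taps, lo_grid, fs) / g0)
  a_hi <- -.db(fir_amplitude(taps, hi_grid, fs) / g0)
  stop_atten_db <- c(lower = min(a_lo), upper = min(a_hi))
  corner_ok <- all(abs(corners - spec$corner_3db) / spec$corner_3db < 0.05)
  list(ok = corner_ok && all(stop_atten_db >= spec$min_stop_atten_db),
       corners = corners, stop_atten_db = stop_atten_db)
}

#' @export
print.fir_kernel <- function(x, ...) {
  cat("FIR kernel:", length(x$taps), "taps at fs =", x$fs, "Hz\n")
  if (!is.null(x$corners_real))
    cat("  -3 dB corners:", paste(signif(x$corners_real, 4), collapse = ", "),
        "Hz; stopband atten:",
        paste(signif(x$stop_atten_db, 4), collapse = "/"), "dB\n")
  invisible(x)
}

## FFT linear convolution, zero-padded to a power of two for speed
.conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

#' Apply an FIR kernel with zero phase
#'
#' Single-pass application of a linear-phase kernel with exact group-delay
#' compensation, using reflection padding of one kernel length at each end
#' to suppress onset transients. Output has the length of the input.
#'
#' @param kernel a `fir_kernel` or numeric taps (odd length, symmetric).
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
apply_zero_phase <- function(kernel, x) {
  h <- if (inherits(kernel, "fir_kernel")) kernel$taps else as.numeric(kernel)
  L <- length(h)
  n <- length(x)
  if (n <= 3 * L)
    stop("input too short: need length(x) > 3 * kernel length (", 3 * L, ")")
  pad <- L
  xp <- c(2 * x[1] - x[seq(pad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - pad)])
  y <- .conv(xp, h)
  d <- (L - 1) / 2
  y[seq(pad + d + 1, length.out = n)]
}

#' Resample by anti-aliased linear interpolation
#'
#' Applies a Kaiser low-pass FIR (cutoff `0.45 * fs_out`) with zero phase,
#' then linearly interpolates onto the uniform `fs_out` grid. Only
#' downsampling (or rate-preserving) is supported.
#'
#' @param x numeric signal sampled at `fs_in`.
#' @param fs_in,fs_out input/output sampling rates in Hz.
#' @return resampled signal.
#' @export
resample_linear <- function(x, fs_in, fs_out = 200) {
  if (fs_out > fs_in) stop("upsampling is not supported")
  cutoff <- 0.45 * fs_out
  ## lowpass as bandpass with fc1 = 0 is ill-posed; use sinc lowpass directly
  beta <- .kaiser_beta(65)
  dw <- 2 * pi * (0.5 * fs_out - cutoff) / fs_in
  n <- ceiling((65 - 7.95) / (2.285 * dw))
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  k <- seq(0, n - 1) - m
  f <- cutoff / fs_in
  h <- ifelse(k == 0, 2 * f, sin(2 * pi * f * k) / (pi * k))
  h <- h * .kaiser_window(n, beta)
  h <- h / sum(h)
  xf <- apply_zero_phase(h, x)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  stats::approx(t_in, xf, xout = t_out)$y
}

#' Centered moving RMS
#'
#' Sliding root-mean-square with a centered window; edge windows are
#' truncated to the available samples.
#'
#' @param x numeric signal.
#' @param window_s window length in seconds (default 0.2).
#' @param fs sampling rate in Hz.
#' @return RMS trace, same length as `x`.
#' @export
moving_rms <- function(x, window_s = 0.2, fs) {
  n <- max(1L, round(window_s * fs))
  N <- length(x)
  half <- (n - 1L) %/% 2L
  cs <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(N) - half, 1L)
  hi <- pmin(seq_len(N) - half + n - 1L, N)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Design the FIR Hilbert transformer
#'
#' Least-squares odd-symmetric (type III) FIR whose amplitude is fit to
#' unity over the slow-wave band, with group delay exactly `delay_s`. The
#' transformer shifts band-limited input by a quarter cycle (-90 degrees).
#'
#' @param fs sampling rate in Hz (>= 100).
#' @param band numeric(2), unity-gain band in Hz (default 0.5-2).
#' @param delay_s group delay in seconds; `delay_s * fs` must be integer.
#' @return object of class `fir_kernel` with `kind = "hilbert"` and the
#'   delay in samples in `$delay`.
#' @export
design_hilbert <- function(fs, band = c(0.5, 2), delay_s = 0.25) {
  if (fs < 100) stop("fs must be >= 100 Hz")
  D <- delay_s * fs
  if (abs(D - round(D)) > 1e-9)
    stop("delay_s is not an integer number of samples at fs = ", fs)
  D <- as.integer(round(D))
  w <- 2 * pi * seq(band[1], band[2], length.out = 24 * D) / fs
  S <- 2 * sin(outer(w, seq_len(D)))
  d <- rep(1, length(w))
  ## iteratively reweighted least squares (Lawson) pushes the fit toward
  ## minimax so the band-edge gain stays within +-5% of unity; a small
  ## ridge keeps the taps numerically benign
  wt <- d
  lam <- 1e-9
  for (it in 1:80) {
    sw <- sqrt(as.vector(wt / mean(wt)))
    Sw <- S * sw
    g <- solve(crossprod(Sw) + lam * diag(D), crossprod(Sw, d * sw))
    e <- abs(as.vector(S %*% g) - d)
    wt <- wt * (0.2 + e)
    wt <- wt / max(wt)
  }
  g <- as.vector(g)
  taps <- c(-rev(g), 0, g)
  structure(list(taps = taps, fs = fs, delay = D, band = band,
                 spec = filter_spec(band, band, band, 0, "hilbert", fs,
                                    delay_s = delay_s)),
            class = "fir_kernel")
}

#' Quarter-cycle (imaginary) component via the Hilbert transformer
#'
#' Causal application of the Hilbert FIR followed by compensation of its
#' `delay` samples, so the value at sample `t` uses input samples in
#' `[t - delay, t + delay]` only (250 ms look-ahead at the default design).
#' The final `delay` samples, for which no look-ahead exists, are `NA`.
#'
#' @param kernel kernel from [design_hilbert()].
#' @param x numeric signal (typically SWA-filtered).
#' @return the -90 degree shifted signal, same length as `x`, `NA` tail.
#' @export
apply_hilbert <- function(kernel, x) {
  stopifnot(inherits(kernel, "fir_kernel"), !is.null(kernel$delay))
  D <- kernel$delay
  n <- length(x)
  y <- .conv(c(x, numeric(D)), kernel$taps)   # causal, zero-padded tail
  out <- y[seq(D + 1, length.out = n)]        # y[t + D] aligned to x[t]
  out[seq(n - D + 1, n)] <- NA_real_
  out
}

#' Export FIR taps to CSV
#'
#' @param kernel `fir_kernel`.
#' @param path output CSV path (columns `tap`, `coefficient`).
#' @export
write_fir_csv <- function(kernel, path) {
  utils::write.csv(data.frame(tap = seq_along(kernel$taps) - 1L,
                              coefficient = kernel$taps),
                   path, row.names = FALSE)
  invisible(path)
}
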