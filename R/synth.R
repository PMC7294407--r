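#' Synthetic slow-wave-sleep recording configuration
#'
#' States the world the generator emulates: N2/N3 background EEG with 1/f
#' noise, slow oscillations as one-cycle biphasic raised-cosine waves
#' (negative half-wave 0.25-1 s, troughs around -90 uV), sleep spindles as
#' Hann-windowed 11-16 Hz bursts with a hard refractory dead time, and a
#' phase-dependent click response (von Mises amplitude gain and spindle
#' probability boost peaked at `gain_peak_phase` for the `young` profile;
#' a weaker, lag-dominated response for `older`; none for `null`).
#'
#' @param duration_s recording length in seconds (>= 60).
#' @param fs sampling rate in Hz (default 200; must exceed twice the
#'   spindle band upper edge).
#' @param so_rate SO events per minute of N3 (default 40: deep-N3 delta
#'   trains with a ~1.5-s trough-to-trough period, so the second click of
#'   a trial lands on the following wave as in the historical protocols).
#' @param so_trough_amp_mean,so_trough_amp_sd trough amplitude in uV
#'   (negative mean; default -100 +- 20, so that the online detector's
#'   -80 uV criterion selects the largest waves as in the historical
#'   protocols).
#' @param so_halfwave_s numeric(2), uniform range of half-wave durations
#'   in seconds, inside `[0.25, 1]` (default 0.3-0.8).
#' @param so_peak_frac peak amplitude as a fraction of |trough| (0.5).
#' @param spindle_rate spindle events per minute of N2/N3 (default 3).
#' @param spindle_freq,spindle_freq_sd spindle frequency draw (Hz).
#' @param spindle_dur_s numeric(2), uniform duration range in seconds.
#' @param spindle_amp burst peak amplitude in uV (default 25).
#' @param spindle_refractory_s hard dead time between spindles (s).
#' @param noise_1f_scale SD of the 1/f background in uV (default 15).
#' @param artifact_rate_per_min rate of 5-s artifact intervals.
#' @param response_profile `"young"`, `"older"` or `"null"`.
#' @param gain_peak_phase optimal click phase mu in degrees (default 90).
#' @param gain_kappa von Mises concentration of the response (default 2).
#' @param gain_max maximal amplitude gain (young; default 1.45). The
#'   older profile responds at `1 + 0.45 * (gain_max - 1)`.
#' @param spindle_boost_max maximal spindle probability increment (0.35,
#'   reproducing a ~21% vs ~8% STIM/SHAM likelihood in the effective
#'   phase interval).
#' @param lag_tau_s time constant (s) of the older profile's lag-dependent
#'   spindle response (default 4).
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 1200, fs = 200, so_rate = 40,
                         so_trough_amp_mean = -100, so_trough_amp_sd = 20,
                         so_halfwave_s = c(0.3, 0.8), so_peak_frac = 0.5,
                         spindle_rate = 3, spindle_freq = 13,
                         spindle_freq_sd = 1, spindle_dur_s = c(0.5, 1.5),
                         spindle_amp = 25, spindle_refractory_s = 1,
                         noise_1f_scale = 15, artifact_rate_per_min = 0.05,
                         response_profile = c("young", "older", "null"),
                         gain_peak_phase = 90, gain_kappa = 2,
                         gain_max = 1.45, spindle_boost_max = 0.35,
                         lag_tau_s = 4, seed = 1) {
  response_profile <- match.arg(response_profile)
  if (fs <= 2 * 16) stop("configuration error: fs must exceed 32 Hz")
  if (duration_s < 60) stop("configuration error: duration_s must be >= 60")
  if (so_halfwave_s[1] < 0.25 || so_halfwave_s[2] > 1 ||
      so_halfwave_s[1] > so_halfwave_s[2])
    stop("configuration error: so_halfwave_s outside [0.25, 1]")
  if (spindle_freq < 11 || spindle_freq > 16)
    stop("configuration error: spindle_freq outside [11, 16]")
  if (spindle_dur_s[1] < 0.3 || spindle_dur_s[2] > 3)
    stop("configuration error: spindle_dur_s outside [0.3, 3]")
  if (so_rate < 0 || spindle_rate < 0 || noise_1f_scale < 0)
    stop("configuration error: negative rate or scale")
  if (gain_max < 1) stop("configuration error: gain_max must be >= 1")
  structure(as.list(environment()), class = "synth_config")
}

## 1/f (pink) noise by spectral shaping of white noise
.pink_noise <- function(n, sd_target) {
  if (sd_target == 0) return(numeric(n))
  nfft <- 2^ceiling(log2(n))
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- c(1, seq_len(nfft - 1))            # avoid DC blowup
  f <- pmin(f, nfft - f + 1)              # two-sided symmetry
  W <- W / sqrt(f)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x * sd_target / stats::sd(x)
}

.raised_cos <- function(n) (1 - cos(2 * pi * seq(0, 1, length.out = n))) / 2

## one biphasic SO waveform; returns the sample vector
.so_wave <- function(amp_neg, amp_pos, dur_neg, dur_pos, fs) {
  n1 <- max(2L, round(dur_neg * fs))
  n2 <- max(2L, round(dur_pos * fs))
  c(-abs(amp_neg) * .raised_cos(n1), abs(amp_pos) * .raised_cos(n2))
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

.spindle_wave <- function(amp, freq, dur, fs, phase0 = 0) {
  n <- max(2L, round(dur * fs))
  tt <- seq(0, n - 1) / fs
  amp * .hann(n) * sin(2 * pi * freq * tt + phase0)
}

.make_hypnogram <- function(duration_s) {
  n_ep <- max(1L, floor(duration_s / 30))
  stage <- rep("N3", n_ep)
  if (n_ep >= 16) {
    stage[1:4] <- "N2"
    stage[(n_ep - 1):n_ep] <- "N2"
  }
  data.frame(epoch = seq_len(n_ep) - 1L, stage = stage,
             stringsAsFactors = FALSE)
}

## renewal process of event onsets inside [t0, t1], dead time included
.renewal_onsets <- function(t0, t1, rate_per_min, dead_s, dur_fun,
                            min_gap_mean = 0.5) {
  if (rate_per_min <= 0) return(data.frame(onset = numeric(),
                                           dur = numeric()))
  mean_iei <- 60 / rate_per_min
  onset <- numeric(); dur <- numeric()
  t <- t0 + stats::rexp(1, 1 / mean_iei)
  while (t < t1) {
    d <- dur_fun()
    if (t + d > t1) break
    onset <- c(onset, t); dur <- c(dur, d)
    gap <- stats::rexp(1, 1 / max(mean_iei - d - dead_s, min_gap_mean))
    t <- t + d + dead_s + gap
  }
  data.frame(onset = onset, dur = dur)
}

#' Generate a ground-truth-labelled synthetic recording
#'
#' Builds a two-channel (Fz, Cz) recording: 1/f background plus SO
#' waveforms during N3 and spindle bursts during N2/N3, with a hypnogram
#' (one contiguous N3 block) and sparse artifact intervals. The same
#' config and seed produce bit-identical output.
#'
#' @param config a [synth_config()].
#' @return list with `recording` (class `clas_recording`: `channels`
#'   (named list of uV traces), `fs`, `hypnogram`, `artifacts`,
#'   `duration_s`) and `truth` (class `clas_truth`: `so_events`,
#'   `spindle_events`, `stim_responses`).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  hyp <- .make_hypnogram(config$duration_s)
  stage_of <- function(t) hyp$stage[pmin(floor(t / 30), nrow(hyp) - 1) + 1]
  ## N3 blocks as second intervals
  n3 <- hyp$stage == "N3"
  nrem <- hyp$stage %in% c("N2", "N3")
  blocks <- function(mask) {
    r <- rle(mask)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    data.frame(start = (s[r$values] - 1) * 30, end = e[r$values] * 30)
  }
  n3b <- blocks(n3); nremb <- blocks(nrem)

  ## slow oscillations during N3: draw both half-wave durations inside the
  ## renewal so reserved and realized waveform lengths agree (no overlap)
  halves <- new.env(parent = emptyenv())
  halves$neg <- numeric(); halves$pos <- numeric()
  so_durfun <- function() {
    d1 <- stats::runif(1, config$so_halfwave_s[1], config$so_halfwave_s[2])
    d2 <- stats::runif(1, config$so_halfwave_s[1], config$so_halfwave_s[2])
    halves$neg <- c(halves$neg, d1)
    halves$pos <- c(halves$pos, d2)
    d1 + d2
  }
  so <- list()
  for (b in seq_len(nrow(n3b))) {
    halves$neg <- numeric(); halves$pos <- numeric()
    ev <- .renewal_onsets(n3b$start[b], n3b$end[b], config$so_rate, 0.05,
                          so_durfun, min_gap_mean = 0.15)
    ev$dur_neg <- halves$neg[seq_len(nrow(ev))]
    ev$dur_pos <- halves$pos[seq_len(nrow(ev))]
    so[[b]] <- ev
  }
  so <- do.call(rbind, so)
  so_events <- NULL
  so_tr <- numeric(n)
  if (!is.null(so) && nrow(so)) {
    m <- nrow(so)
    dur_neg <- so$dur_neg
    dur_pos <- so$dur_pos
    amp <- pmin(-20, stats::rnorm(m, config$so_trough_amp_mean,
                                  config$so_trough_amp_sd))
    pk <- config$so_peak_frac * abs(amp) * stats::runif(m, 0.9, 1.1)
    so_events <- data.frame(
      zc_down = so$onset, dur_neg = dur_neg, dur_pos = dur_pos,
      trough_time = so$onset + dur_neg / 2, trough_amp = amp,
      zc_up = so$onset + dur_neg,
      peak_time = so$onset + dur_neg + dur_pos / 2, peak_amp = pk)
    for (i in seq_len(m)) {
      w <- .so_wave(amp[i], pk[i], dur_neg[i], dur_pos[i], fs)
      i0 <- round(so_events$zc_down[i] * fs) + 1L
      idx <- i0:min(n, i0 + length(w) - 1L)
      so_tr[idx] <- so_tr[idx] + w[seq_along(idx)]
    }
  } else {
    so_events <- data.frame(zc_down = numeric(), dur_neg = numeric(),
                            dur_pos = numeric(), trough_time = numeric(),
                            trough_amp = numeric(), zc_up = numeric(),
                            peak_time = numeric(), peak_amp = numeric())
  }

  ## spindles during N2/N3
  sp <- list()
  for (b in seq_len(nrow(nremb))) {
    sp[[b]] <- .renewal_onsets(nremb$start[b], nremb$end[b],
                               config$spindle_rate,
                               config$spindle_refractory_s,
                               function() stats::runif(1, config$spindle_dur_s[1],
                                                       config$spindle_dur_s[2]))
  }
  sp <- do.call(rbind, sp)
  sp_tr <- numeric(n)
  if (!is.null(sp) && nrow(sp)) {
    m <- nrow(sp)
    freq <- pmin(15.5, pmax(11.5, stats::rnorm(m, config$spindle_freq,
                                               config$spindle_freq_sd)))
    spindle_events <- data.frame(onset = sp$onset, duration = sp$dur,
                                 freq = freq)
    for (i in seq_len(m)) {
      w <- .spindle_wave(config$spindle_amp, freq[i], sp$dur[i], fs,
                         stats::runif(1, 0, 2 * pi))
      i0 <- round(sp$onset[i] * fs) + 1L
      idx <- i0:min(n, i0 + length(w) - 1L)
      sp_tr[idx] <- sp_tr[idx] + w[seq_along(idx)]
    }
  } else {
    spindle_events <- data.frame(onset = numeric(), duration = numeric(),
                                 freq = numeric())
  }

  ## artifacts
  n_art <- stats::rpois(1, config$artifact_rate_per_min * config$duration_s / 60)
  artifacts <- if (n_art > 0) {
    st <- sort(stats::runif(n_art, 0, config$duration_s - 5))
    data.frame(start = st, end = st + 5)
  } else data.frame(start = numeric(), end = numeric())

  fz <- so_tr + 0.3 * sp_tr + .pink_noise(n, config$noise_1f_scale)
  cz <- 0.7 * so_tr + sp_tr + .pink_noise(n, config$noise_1f_scale)

  recording <- structure(list(channels = list(Fz = fz, Cz = cz), fs = fs,
                              hypnogram = hyp, artifacts = artifacts,
                              duration_s = config$duration_s),
                         class = "clas_recording")
  truth <- structure(list(so_events = so_events,
                          spindle_events = spindle_events,
                          stim_responses = data.frame(
                            click_time = numeric(), applied_gain = numeric(),
                            spindle_induced = integer())),
                     class = "clas_truth")
  list(recording = recording, truth = truth)
}

#' Ground-truth SO phase at arbitrary times
#'
#' Piecewise-linear phase over each ground-truth SO cycle: 180 degrees at
#' the positive-to-negative zero crossing, 270 (= -90) at the trough, 0 at
#' the upcrossing, 90 at the peak. `NA` outside SO cycles.
#'
#' @param truth `clas_truth` object.
#' @param t times in seconds.
#' @return phase in degrees, `[-90, 270)`, or `NA`.
#' @export
so_phase_at <- function(truth, t) {
  ev <- truth$so_events
  out <- rep(NA_real_, length(t))
  if (!nrow(ev)) return(out)
  for (j in seq_along(t)) {
    i <- which(ev$zc_down <= t[j] & t[j] < ev$zc_down + ev$dur_neg + ev$dur_pos)
    if (!length(i)) next
    i <- i[1]
    if (t[j] < ev$zc_up[i]) {
      out[j] <- 180 + 180 * (t[j] - ev$zc_down[i]) / ev$dur_neg[i]
    } else {
      out[j] <- 180 * (t[j] - ev$zc_up[i]) / ev$dur_pos[i]
    }
  }
  wrap_deg(out)
}

## von Mises response kernel, 1 at phi = mu
.vm_kernel <- function(phi_deg, mu_deg, kappa)
  exp(kappa * (cos((phi_deg - mu_deg) * pi / 180) - 1))

#' Apply the phase-dependent click response to a recording
#'
#' For the `young` profile the SO following each click is scaled by the
#' gain `g(phi) = 1 + (gain_max - 1) * exp(kappa * (cos(phi - mu) - 1))`
#' and a spindle may be induced in the trough-to-trough window after the
#' click with probability `spindle_boost_max * exp(kappa*(cos(phi-mu)-1))`
#' (subject to refractoriness). For `older` the gain is reduced and the
#' spindle increment depends only on the lag since the last spindle. For
#' `null` the recording is returned unchanged (SHAM semantics).
#'
#' @param recording,truth output of [generate_recording()].
#' @param clicks click times in seconds (first clicks of each trial).
#' @param config the [synth_config()] used for generation.
#' @return list with updated `recording` and `truth` (including
#'   `stim_responses`).
#' @export
apply_click_response <- function(recording, truth, clicks, config) {
  stopifnot(inherits(config, "synth_config"))
  if (any(clicks < 0 | clicks > recording$duration_s))
    stop("clicks outside the recording")
  prof <- config$response_profile
  if (prof == "null") {
    truth$stim_responses <- data.frame(click_time = clicks,
                                       applied_gain = 1,
                                       spindle_induced = 0L)
    return(list(recording = recording, truth = truth))
  }
  set.seed(config$seed + 104729L)
  fs <- recording$fs
  n <- length(recording$channels$Fz)
  ev <- truth$so_events
  sp <- truth$spindle_events
  gain_max <- if (prof == "older") 1 + 0.45 * (config$gain_max - 1)
              else config$gain_max
  resp <- data.frame(click_time = clicks, applied_gain = NA_real_,
                     spindle_induced = 0L)
  for (j in order(clicks)) {
    ck <- clicks[j]
    phi <- so_phase_at(truth, ck)
    vm <- if (is.na(phi)) 0 else .vm_kernel(phi, config$gain_peak_phase,
                                            config$gain_kappa)
    g <- 1 + (gain_max - 1) * vm
    resp$applied_gain[j] <- g
    ## next SO (the responding wave)
    i <- which(ev$trough_time > ck)
    if (!length(i)) next
    i <- i[1]
    if (g != 1) {
      w_old <- .so_wave(ev$trough_amp[i], ev$peak_amp[i],
                        ev$dur_neg[i], ev$dur_pos[i], fs)
      w_new <- g * w_old
      i0 <- round(ev$zc_down[i] * fs) + 1L
      idx <- i0:min(n, i0 + length(w_old) - 1L)
      dw <- (w_new - w_old)[seq_along(idx)]
      recording$channels$Fz[idx] <- recording$channels$Fz[idx] + dw
      recording$channels$Cz[idx] <- recording$channels$Cz[idx] + 0.7 * dw
      truth$so_events$trough_amp[i] <- g * ev$trough_amp[i]
      truth$so_events$peak_amp[i] <- g * ev$peak_amp[i]
      ev <- truth$so_events
    }
    ## spindle induction in the trough-to-trough window after the click
    lag <- if (nrow(sp) && any(sp$onset < ck)) ck - max(sp$onset[sp$onset < ck])
           else Inf
    p <- if (prof == "young") config$spindle_boost_max * vm
         else config$spindle_boost_max *
           (1 - exp(-min(lag, 50) / config$lag_tau_s))
    if (p > 0 && stats::runif(1) < p) {
      onset <- ev$zc_up[i] + stats::runif(1, 0.05, 0.3) * ev$dur_pos[i]
      dur <- stats::runif(1, config$spindle_dur_s[1], config$spindle_dur_s[2])
      recent <- nrow(sp) && any(abs(sp$onset - onset) <
                                  config$spindle_refractory_s + sp$duration)
      if (!recent && onset + dur < recording$duration_s) {
        freq <- min(15.5, max(11.5, stats::rnorm(1, config$spindle_freq,
                                                 config$spindle_freq_sd)))
        w <- .spindle_wave(config$spindle_amp, freq, dur, fs,
                           stats::runif(1, 0, 2 * pi))
        i0 <- round(onset * fs) + 1L
        idx <- i0:min(n, i0 + length(w) - 1L)
        recording$channels$Cz[idx] <- recording$channels$Cz[idx] +
          w[seq_along(idx)]
        recording$channels$Fz[idx] <- recording$channels$Fz[idx] +
          0.3 * w[seq_along(idx)]
        sp <- rbind(sp, data.frame(onset = onset, duration = dur,
                                   freq = freq))
        sp <- sp[order(sp$onset), ]
        resp$spindle_induced[j] <- 1L
      }
    }
  }
  truth$spindle_events <- sp
  truth$stim_responses <- resp
  list(recording = recording, truth = truth)
}
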