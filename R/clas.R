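#' Online stimulation protocol configuration
#'
#' The three historical protocol variants share the same trial structure
#' (two clicks, then a 2.5-s pause) and differ in their adaptive trough
#' threshold: `uLub`/`uTub` update every 0.5 s to the minimum of the
#' preceding 5 s when that is below the -80 uV default; `uAnd` updates to
#' half the detected trough when below the -60 uV default.
#'
#' @param variant `"uLub"`, `"uTub"` or `"uAnd"`.
#' @param default_threshold detection threshold in uV (negative);
#'   defaults: -80 (uLub/uTub), -60 (uAnd).
#' @param isi_s inter-stimulus interval between the two clicks of a trial
#'   (defaults: 1.076 uLub, 1.096 uTub, 1.053 uAnd).
#' @param pause_s pause after each trial before detection resumes (2.5).
#' @param click_dur_s click duration (0.050).
#' @param ramp_s click on/off ramp (0.005).
#' @param click_delay_s delay from trough detection to the first click
#'   (default 0.5 s, placing the click near the following up-state peak
#'   for a ~0.9-s-period SO; the historical protocols did not publish
#'   their values).
#' @param click_delay_jitter_s half-width of the uniform trial-to-trial
#'   jitter on `click_delay_s` (default 0.15 s), emulating the latency
#'   variability of real-time detection; draws come from the R RNG, so
#'   seed the session for reproducibility.
#' @param amp_resolution_uV amplitude resolution of the online comparator
#'   (default 0.1 uV): a deflection within half a resolution step of the
#'   threshold counts as surpassing it. Keeps the adaptive rule
#'   well-defined on stationary input, where the threshold equals the
#'   previous trough exactly.
#' @param detect_channel channel label used for online detection ("Fz").
#' @param min_nrem_s contiguous NREM required before stimulation starts
#'   (300 s).
#' @param stim_period_s total stimulation budget in seconds of eligible
#'   time (12600 for uLub/uTub, 15000 for uAnd).
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(variant = c("uLub", "uTub", "uAnd"),
                            default_threshold = NULL, isi_s = NULL,
                            pause_s = 2.5, click_dur_s = 0.050,
                            ramp_s = 0.005, click_delay_s = 0.5,
                            click_delay_jitter_s = 0.15,
                            amp_resolution_uV = 0.1,
                            detect_channel = "Fz", min_nrem_s = 300,
                            stim_period_s = NULL) {
  variant <- match.arg(variant)
  if (is.null(default_threshold))
    default_threshold <- if (variant == "uAnd") -60 else -80
  if (is.null(isi_s))
    isi_s <- switch(variant, uLub = 1.076, uTub = 1.096, uAnd = 1.053)
  if (is.null(stim_period_s))
    stim_period_s <- if (variant == "uAnd") 15000 else 12600
  if (default_threshold >= 0) stop("default_threshold must be negative")
  if (pause_s <= 0 || isi_s <= 0) stop("pause_s and isi_s must be positive")
  structure(list(variant = variant, default_threshold = default_threshold,
                 isi_s = isi_s, pause_s = pause_s, click_dur_s = click_dur_s,
                 ramp_s = ramp_s, click_delay_s = click_delay_s,
                 click_delay_jitter_s = click_delay_jitter_s,
                 amp_resolution_uV = amp_resolution_uV,
                 detect_channel = detect_channel, min_nrem_s = min_nrem_s,
                 stim_period_s = stim_period_s),
            class = "protocol_config")
}

#' Adaptive threshold update rule
#'
#' `uLub`/`uTub`: threshold becomes the minimum of the preceding 5-s
#' filtered history when that is below the default, else the default.
#' `uAnd`: threshold becomes half the detected trough amplitude when that
#' is below the default, else the default.
#'
#' @param history recent filtered samples (uV); for uLub/uTub the
#'   preceding 5-s window, for uAnd a single detected trough amplitude.
#' @param current_threshold current threshold (unused; the rule is
#'   memoryless, the argument documents the call site).
#' @param config a [protocol_config()].
#' @return updated threshold in uV.
#' @export
update_threshold <- function(history, current_threshold, config) {
  d <- config$default_threshold
  if (config$variant %in% c("uLub", "uTub")) {
    m <- min(history)
    if (m < d) m else d
  } else {
    half <- history[length(history)] / 2
    if (half < d) half else d
  }
}

## causal 2nd-order Butterworth biquads (HP then LP) for the online SO band
.butter2_coef <- function(fc, fs, type) {
  w <- tan(pi * fc / fs)
  d <- 1 + sqrt(2) * w + w^2
  if (type == "low") b <- c(w^2, 2 * w^2, w^2) / d
  else b <- c(1, -2, 1) / d
  a <- c(1, 2 * (w^2 - 1) / d, (1 - sqrt(2) * w + w^2) / d)
  list(b = b, a = a)
}

.iir_filter <- function(coef, x) {
  v <- stats::filter(c(numeric(length(coef$b) - 1), x), coef$b, sides = 1)
  v <- v[-seq_len(length(coef$b) - 1)]
  as.numeric(stats::filter(v, -coef$a[-1], method = "recursive"))
}

#' Causal online slow-oscillation filter
#'
#' Second-order Butterworth band-pass (0.25-4 Hz) applied causally, as a
#' high-pass/low-pass biquad cascade, mimicking the real-time filter of
#' the stimulation interface.
#'
#' @param x raw trace, uV.
#' @param fs sampling rate in Hz (must be > 8 for the filter to exist).
#' @param band numeric(2) band edges in Hz.
#' @return causally filtered trace.
#' @export
online_so_filter <- function(x, fs, band = c(0.25, 4)) {
  if (fs <= 2 * band[2]) stop("configuration error: fs too low for causal SO filter")
  hp <- .butter2_coef(band[1], fs, "high")
  lp <- .butter2_coef(band[2], fs, "low")
  .iir_filter(lp, .iir_filter(hp, x))
}

## per-sample stimulation eligibility from hypnogram + artifacts
.eligibility <- function(n, fs, hypnogram, artifacts, config) {
  t <- (seq_len(n) - 1) / fs
  ep <- pmin(floor(t / 30), nrow(hypnogram) - 1)
  stage <- hypnogram$stage[ep + 1]
  nrem <- stage %in% c("N2", "N3")
  ## require one initial run of min_nrem_s contiguous NREM before arming
  r <- rle(nrem)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  armed_from <- NA_integer_
  for (k in which(r$values)) {
    if (r$lengths[k] >= config$min_nrem_s * fs) {
      armed_from <- starts[k] + as.integer(config$min_nrem_s * fs)
      break
    }
  }
  elig <- nrem
  if (is.na(armed_from)) return(rep(FALSE, n))
  elig[seq_len(min(armed_from - 1L, n))] <- FALSE
  if (!is.null(artifacts) && nrow(artifacts))
    for (i in seq_len(nrow(artifacts))) {
      i0 <- max(1L, round(artifacts$start[i] * fs) + 1L)
      i1 <- min(n, round(artifacts$end[i] * fs) + 1L)
      if (i0 <= i1) elig[i0:i1] <- FALSE
    }
  ## stimulation period budget: eligible seconds only
  cum_elig <- cumsum(elig) / fs
  elig[cum_elig > config$stim_period_s] <- FALSE
  elig
}

#' Simulate the online trough-detection stimulation protocol
#'
#' Streams the detection channel through the causal SO filter, detects
#' negative deflections crossing the adaptive threshold, localizes the
#' trough as the first local minimum within 0.5 s of the crossing, and
#' schedules two clicks per trial (the first `click_delay_s` after the
#' detected trough, the second `isi_s` later), pausing `pause_s` after
#' each trial. Detection is gated to N2/N3 (after `min_nrem_s` of
#' contiguous NREM), halted inside artifact/arousal annotations, and
#' stopped once `stim_period_s` of eligible time is spent. STIM and SHAM
#' runs on identical input produce identical timing; `condition` only
#' labels whether the clicks were audible.
#'
#' @param signal detection-channel trace in uV.
#' @param fs sampling rate in Hz.
#' @param config a [protocol_config()].
#' @param hypnogram data.frame `epoch`, `stage`.
#' @param artifacts optional data.frame `start`, `end` in seconds.
#' @param condition `"STIM"` or `"SHAM"` label for the log.
#' @return data.frame trial log: `trial_id`, `first_click_time`,
#'   `second_click_time`, `detected_trough_time`, `detected_trough_amp`,
#'   `condition`, `stage_at_click`.
#' @export
stream_detect_troughs <- function(signal, fs, config, hypnogram,
                                  artifacts = NULL,
                                  condition = c("STIM", "SHAM")) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "protocol_config"))
  n <- length(signal)
  xf <- online_so_filter(signal, fs)
  elig <- .eligibility(n, fs, hypnogram, artifacts, config)
  stage_at <- function(idx) {
    ep <- pmin(floor((idx - 1) / fs / 30), nrow(hypnogram) - 1)
    hypnogram$stage[ep + 1]
  }
  adaptive <- config$variant %in% c("uLub", "uTub")
  thr_trace <- NULL
  if (adaptive) {
    ## threshold updated each 0.5 s to min over preceding 5 s (if < default)
    step <- round(0.5 * fs); win <- round(5 * fs)
    upd <- seq(win + 1, n, by = step)
    thr_at_upd <- vapply(upd, function(i)
      update_threshold(xf[(i - win):(i - 1)], NA, config), numeric(1))
    thr_trace <- rep(config$default_threshold, n)
    for (k in seq_along(upd)) {
      to <- if (k < length(upd)) upd[k + 1] - 1L else n
      thr_trace[upd[k]:to] <- thr_at_upd[k]
    }
  }
  thr <- config$default_threshold
  trials <- list()
  i <- 2L
  max_search <- round(0.5 * fs)
  eps <- config$amp_resolution_uV / 2
  while (i <= n) {
    th_i <- (if (adaptive) thr_trace[i] else thr) + eps
    if (elig[i] && xf[i] <= th_i && xf[i - 1] > th_i) {
      ## crossing: localize first local minimum within 0.5 s
      jmax <- min(n - 1L, i + max_search)
      seg <- xf[i:jmax]
      loc <- which(diff(sign(diff(seg))) > 0)
      ti <- if (length(loc)) i + loc[1] else i + which.min(seg) - 1L
      trough_t <- (ti - 1) / fs
      jit <- if (config$click_delay_jitter_s > 0)
        stats::runif(1, -config$click_delay_jitter_s,
                     config$click_delay_jitter_s) else 0
      c1 <- trough_t + config$click_delay_s + jit
      c2 <- c1 + config$isi_s
      c1i <- round(c1 * fs) + 1L; c2i <- round(c2 * fs) + 1L
      if (c2i <= n && elig[c1i] && elig[c2i]) {
        trials[[length(trials) + 1L]] <- data.frame(
          first_click_time = c1, second_click_time = c2,
          detected_trough_time = trough_t,
          detected_trough_amp = xf[ti],
          condition = condition, stage_at_click = stage_at(c1i),
          stringsAsFactors = FALSE)
        if (config$variant == "uAnd")
          thr <- update_threshold(xf[ti], thr, config)
        i <- c2i + round(config$pause_s * fs)
        next
      }
      i <- ti + 1L
      next
    }
    i <- i + 1L
  }
  if (!length(trials))
    return(data.frame(trial_id = integer(), first_click_time = numeric(),
                      second_click_time = numeric(),
                      detected_trough_time = numeric(),
                      detected_trough_amp = numeric(),
                      condition = character(), stage_at_click = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, trials)
  cbind(trial_id = seq_len(nrow(out)), out)
}

#' Pink-noise click waveform
#'
#' 50-ms burst of pink noise with 5-ms linear rising and falling ramps,
#' so the first and last samples are exactly zero. Spectral slope is
#' -3 dB/octave in power (amplitude ~ 1/sqrt(f)).
#'
#' @param config a [protocol_config()] (uses `click_dur_s`, `ramp_s`).
#' @param fs_audio audio sampling rate in Hz (>= 8000).
#' @param seed integer seed for the noise draw.
#' @return numeric waveform of `round(click_dur_s * fs_audio)` samples.
#' @export
make_click_waveform <- function(config, fs_audio = 44100, seed = 1) {
  if (fs_audio < 8000) stop("fs_audio must be >= 8 kHz")
  set.seed(seed)
  m <- round(config$click_dur_s * fs_audio)
  x <- .pink_noise(m, 1)
  nr <- round(config$ramp_s * fs_audio)
  ramp <- seq(0, 1, length.out = nr)
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[seq(m - nr + 1, m)] <- x[seq(m - nr + 1, m)] * rev(ramp)
  x / max(abs(x))
}
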