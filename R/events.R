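#' Detect slow oscillations from the SWA-filtered trace
#'
#' Every zero-crossing-delimited negative half-wave whose duration lies in
#' `[0.25, 1]` seconds becomes one SO event, regardless of amplitude. The
#' trough is the minimum between the crossings; the peak is the maximum of
#' the following positive half-wave.
#'
#' @param swa SWA band-filtered trace (microvolts).
#' @param fs sampling rate in Hz.
#' @param dur_range negative half-wave duration bounds in seconds.
#' @return data.frame with columns `zc_down`, `trough_time`, `trough_amp`,
#'   `zc_up`, `peak_time`, `peak_amp` (times in seconds from trace start).
#' @export
detect_so <- function(swa, fs, dur_range = c(0.25, 1)) {
  pos <- swa >= 0
  n <- length(swa)
  dn <- which(pos[-n] & !pos[-1])        # last positive sample before down
  up <- which(!pos[-n] & pos[-1])        # last negative sample before up
  out <- list()
  for (d in dn) {
    u <- up[up > d]
    if (!length(u)) next
    u <- u[1]
    dur <- (u - d) / fs
    if (dur < dur_range[1] || dur > dur_range[2]) next
    seg <- (d + 1):u
    ti <- seg[which.min(swa[seg])]
    ## following positive half-wave: up+1 .. next down crossing (or end)
    nxt_dn <- dn[dn > u]
    pend <- if (length(nxt_dn)) nxt_dn[1] else n
    pseg <- (u + 1):pend
    pk <- pseg[which.max(swa[pseg])]
    if (swa[pk] <= 0) next
    out[[length(out) + 1L]] <- data.frame(
      zc_down = d / fs, trough_time = (ti - 1) / fs,
      trough_amp = swa[ti], zc_up = u / fs,
      peak_time = (pk - 1) / fs, peak_amp = swa[pk])
  }
  if (!length(out))
    return(data.frame(zc_down = numeric(), trough_time = numeric(),
                      trough_amp = numeric(), zc_up = numeric(),
                      peak_time = numeric(), peak_amp = numeric()))
  do.call(rbind, out)
}

#' Empirical spindle RMS threshold
#'
#' The 86.64th percentile of the N3 spindle-band RMS distribution. (For a
#' Gaussian magnitude this percentile corresponds to 1.5 SD: the
#' two-sided standard-normal probability `2 * pnorm(1.5) - 1 = 0.8664`.)
#'
#' @param rms_n3 RMS samples during N3.
#' @param percentile percentile in `[0, 100]` (default 86.64).
#' @return threshold in the input units.
#' @export
spindle_threshold <- function(rms_n3, percentile = 86.64) {
  if (!length(rms_n3)) stop("empty RMS ensemble")
  unname(stats::quantile(rms_n3, percentile / 100, names = FALSE))
}

## precompute unit-energy Morlet wavelets for a frequency grid
.morlet_bank <- function(fs, freqs, n_cycles = 7) {
  lapply(freqs, function(f) {
    sd_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sd_t * fs)
    tt <- seq(-half, half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    list(w = w / sqrt(sum(Mod(w)^2)), half = half)
  })
}

## time-averaged Morlet scalogram of a short segment
.morlet_power <- function(x, fs, freqs, n_cycles = 7, bank = NULL) {
  if (is.null(bank)) bank <- .morlet_bank(fs, freqs, n_cycles)
  n <- length(x)
  vapply(bank, function(bk) {
    half <- bk$half; w <- bk$w
    xp <- c(numeric(half), x, numeric(half))
    co <- .conv(xp, Re(w)) + 1i * .conv(xp, Im(w))
    core <- co[seq(2 * half + 1, length.out = n)]
    mean(Mod(core)^2)
  }, numeric(1))
}

## local maxima above a prominence floor (fraction of the global max);
## minor noise bumps do not count against unimodality
.count_local_maxima <- function(p, floor_frac = 0) {
  if (length(p) < 3) return(0L)
  ismax <- p[2:(length(p) - 1)] > p[1:(length(p) - 2)] &
    p[2:(length(p) - 1)] >= p[3:length(p)]
  sum(ismax & p[2:(length(p) - 1)] >= floor_frac * max(p))
}

#' Detect sleep spindles
#'
#' Candidate events are maximal runs of the 0.2-s spindle-band RMS above
#' the N3 86.64-percentile threshold (runs separated by < 0.1 s merged).
#' Candidates are kept iff their duration is 0.3-3 s, they contain at
#' least five oscillations (upward zero crossings of the band-filtered
#' segment), their time-averaged Morlet spectrum (8-30 Hz, 0.5 Hz grid,
#' 7 cycles) has a single local maximum lying in 11-16 Hz, and mean power
#' above 16 Hz is non-increasing in octave steps toward 30 Hz.
#'
#' @param x raw trace (typically Cz), microvolts.
#' @param fs sampling rate in Hz.
#' @param n3_mask logical per sample, TRUE during N3 (used for the
#'   threshold ensemble).
#' @param kernel optional precomputed spindle band-pass `fir_kernel`.
#' @param threshold optional fixed RMS threshold (microvolts); when NULL
#'   it is estimated from `n3_mask` samples.
#' @param merge_gap_s candidate merge gap in seconds (default 0.1).
#' @return data.frame of spindle events: `onset`, `offset`, `duration`,
#'   `rms`, `amplitude`, `peak_freq`, `n_oscillations`.
#' @export
detect_spindles <- function(x, fs, n3_mask = NULL, kernel = NULL,
                            threshold = NULL, merge_gap_s = 0.1) {
  if (is.null(kernel)) kernel <- design_fir(spindle_filter_spec(fs))
  xb <- apply_zero_phase(kernel, x)
  rms <- moving_rms(xb, 0.2, fs)
  if (is.null(threshold)) {
    ens <- if (is.null(n3_mask)) rms else rms[n3_mask]
    threshold <- spindle_threshold(ens)
  }
  above <- rms > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(.empty_spindles())
  ## merge runs separated by short dips
  gap <- merge_gap_s * fs
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1 < gap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  freqs <- seq(8, 30, by = 0.5)
  bank <- .morlet_bank(fs, freqs)
  out <- list()
  for (i in seq_len(nrow(merged))) {
    s <- merged$start[i]; e <- merged$end[i]
    dur <- (e - s + 1) / fs
    if (dur < 0.3 || dur > 3) next
    seg <- xb[s:e]
    ## oscillation count on the run trimmed by the RMS window smear
    half_w <- round(0.1 * fs)
    core <- if (e - s > 2 * half_w) xb[(s + half_w):(e - half_w)] else seg
    n_osc <- sum(core[-length(core)] < 0 & core[-1] >= 0)
    if (n_osc < 5) next
    pw <- .morlet_power(x[max(1, s - fs %/% 2):min(length(x), e + fs %/% 2)],
                        fs, freqs, bank = bank)
    pws <- stats::filter(pw, rep(1 / 5, 5), sides = 2)
    pws[is.na(pws)] <- pw[is.na(pws)]
    pf <- freqs[which.max(pw)]
    if (.count_local_maxima(as.numeric(pws), floor_frac = 0.5) != 1L) next
    if (pf < 11 || pf > 16) next
    b1 <- mean(pw[freqs >= 16 & freqs < 22])
    b2 <- mean(pw[freqs >= 22 & freqs <= 30])
    if (b2 > b1 || b1 > max(pw)) next
    out[[length(out) + 1L]] <- data.frame(
      onset = (s - 1) / fs, offset = (e - 1) / fs, duration = dur,
      rms = sqrt(mean(seg^2)), amplitude = max(seg) - min(seg),
      peak_freq = pf, n_oscillations = n_osc)
  }
  if (!length(out)) return(.empty_spindles())
  do.call(rbind, out)
}

.empty_spindles <- function()
  data.frame(onset = numeric(), offset = numeric(), duration = numeric(),
             rms = numeric(), amplitude = numeric(), peak_freq = numeric(),
             n_oscillations = integer())

#' Assemble per-trial targeted measures
#'
#' For each stimulation trial: the post-stimulus trough is the trough of
#' the first detected SO (duration-gated negative half-wave) within
#' `search_s` seconds after the first click, and `post_trough_amp` is its
#' absolute amplitude. The spindle-association window is the
#' trough-to-trough cycle of the responding SO: from that trough to the
#' next detected SO trough (or one median SO period when none follows);
#' `ss_likelihood_flag` is 1 iff a detected spindle begins inside it.
#' Trials are excluded when the click falls outside the retained sleep
#' stage, overlaps an artifact, or the second click precedes the
#' post-stimulus trough.
#'
#' @param trial_log data.frame with `click1_time`, `click2_time`,
#'   `condition`.
#' @param so_events SO table from [detect_so()].
#' @param spindles spindle table from [detect_spindles()].
#' @param swa SWA-filtered trace.
#' @param fs sampling rate in Hz.
#' @param hypnogram data.frame `epoch` (0-based), `stage`.
#' @param artifacts optional data.frame `start`, `end` (seconds).
#' @param stages stages retained for analysis (default "N3").
#' @param search_s post-stimulus trough search window (default 2 s).
#' @return data.frame of trials with measures, `lag_s` (time since the
#'   previous spindle onset at click time) and exclusion flags.
#' @export
build_trials <- function(trial_log, so_events, spindles, swa, fs,
                         hypnogram, artifacts = NULL, stages = "N3",
                         search_s = 2) {
  n <- nrow(trial_log)
  dur_s <- length(swa) / fs
  if (any(trial_log$click1_time < 0 | trial_log$click1_time > dur_s))
    stop("trial outside recording")
  troughs <- so_events$trough_time
  tamps <- abs(so_events$trough_amp)
  res <- data.frame(
    click1_time = trial_log$click1_time,
    click2_time = trial_log$click2_time,
    condition = trial_log$condition,
    post_trough_time = NA_real_, post_trough_amp = NA_real_,
    ss_likelihood_flag = NA_integer_, ss_latency = NA_real_,
    ss_duration = NA_real_, ss_rms = NA_real_, ss_amplitude = NA_real_,
    lag_s = NA_real_,
    excluded = FALSE, excl_reason = NA_character_,
    stringsAsFactors = FALSE)
  excl <- function(i, why) {
    res$excluded[i] <<- TRUE
    res$excl_reason[i] <<- why
  }
  for (i in seq_len(n)) {
    t1 <- res$click1_time[i]
    ep <- floor(t1 / 30)
    stage <- hypnogram$stage[match(ep, hypnogram$epoch)]
    if (is.na(stage) || !(stage %in% stages)) { excl(i, "stage"); next }
    if (!is.null(artifacts) && nrow(artifacts) &&
        any(t1 >= artifacts$start & t1 <= artifacts$end)) {
      excl(i, "artifact"); next
    }
    cand <- which(troughs > t1 & troughs <= t1 + search_s)
    if (!length(cand)) { excl(i, "no post-stimulus trough"); next }
    k <- cand[1]
    res$post_trough_time[i] <- troughs[k]
    res$post_trough_amp[i] <- tamps[k]
    if (!is.na(res$click2_time[i]) &&
        res$click2_time[i] < res$post_trough_time[i]) {
      excl(i, "second click before post-stimulus trough"); next
    }
    ## spindle-association window: post trough -> next SO trough
    nxt <- which(troughs > troughs[k])
    wend <- if (length(nxt)) min(troughs[nxt[1]], troughs[k] + 3)
            else min(dur_s, troughs[k] + 1.2)
    win <- c(res$post_trough_time[i], wend)
    if (nrow(spindles)) {
      prev <- spindles$onset[spindles$onset < t1]
      if (length(prev)) res$lag_s[i] <- t1 - max(prev)
      hit <- which(spindles$onset > win[1] & spindles$onset <= win[2])
      if (length(hit)) {
        h <- hit[1]
        res$ss_likelihood_flag[i] <- 1L
        res$ss_latency[i] <- spindles$onset[h] - t1
        res$ss_duration[i] <- spindles$duration[h]
        res$ss_rms[i] <- spindles$rms[h]
        res$ss_amplitude[i] <- spindles$amplitude[h]
      } else res$ss_likelihood_flag[i] <- 0L
    } else res$ss_likelihood_flag[i] <- 0L
  }
  res
}

#' Demandingness of the online detection threshold
#'
#' Detected-trough amplitude as a percentage of the mean trough amplitude
#' over the whole detection period.
#'
#' @param detected_troughs amplitudes (microvolts) of online-detected
#'   troughs.
#' @param all_troughs amplitudes of all troughs in the detection period.
#' @return percentage (100 = detected match the average trough).
#' @export
threshold_demandingness <- function(detected_troughs, all_troughs) {
  if (!length(detected_troughs) || !length(all_troughs))
    stop("empty trough list")
  100 * mean(abs(detected_troughs)) / mean(abs(all_troughs))
}
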