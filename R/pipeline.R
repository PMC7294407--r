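## ---- EDF I/O ---------------------------------------------------------------

.pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, 1-s data records,
#' physical units microvolts. The hypnogram/artifacts are not part of EDF
#' and must be written separately (see [write_hypnogram_csv()]).
#'
#' @param recording `clas_recording`.
#' @param path output file.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$fs
  chans <- recording$channels
  ns <- length(chans)
  n_rec <- floor(length(chans[[1]]) / fs)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 * (1 + ns)
  wr <- function(x, w) writeChar(.pad_ascii(x, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("soclas", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(hdr_bytes, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  pmax_ <- vapply(chans, function(x) max(1, ceiling(max(abs(x)))), 1)
  for (nm in names(chans)) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-pmax_[i], 8)
  for (i in seq_len(ns)) wr(pmax_[i], 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- lapply(seq_len(ns), function(i) {
    x <- chans[[i]][seq_len(n_rec * fs)]
    as.integer(round((x + pmax_[i]) / (2 * pmax_[i]) * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    idx <- seq((r - 1) * fs + 1, r * fs)
    for (i in seq_len(ns))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @param channels optional channel labels to keep; an error lists the
#'   available labels when one is missing.
#' @return `clas_recording` (without hypnogram/artifacts).
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, labels)
    if (length(missing_ch))
      stop("channel(s) not in EDF: ", paste(missing_ch, collapse = ", "),
           "; available: ", paste(labels, collapse = ", "))
  }
  raw_all <- lapply(seq_len(ns), function(i) integer(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      raw_all[[i]][seq((r - 1) * spr[i] + 1, r * spr[i])] <- v
    }
  }
  chans <- lapply(seq_len(ns), function(i)
    (raw_all[[i]] - dmin_[i]) * (pmax_[i] - pmin_[i]) /
      (dmax_[i] - dmin_[i]) + pmin_[i])
  names(chans) <- labels
  if (!is.null(channels)) chans <- chans[channels]
  fs <- spr[1] / rec_dur
  structure(list(channels = chans, fs = fs, hypnogram = NULL,
                 artifacts = NULL, duration_s = n_rec * rec_dur),
            class = "clas_recording")
}

## ---- small CSV helpers -----------------------------------------------------

#' @rdname write_edf
#' @param hypnogram data.frame `epoch`, `stage`.
#' @export
write_hypnogram_csv <- function(hypnogram, path) {
  utils::write.csv(hypnogram, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edf
#' @export
read_hypnogram_csv <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch", "stage") %in% names(h)))
  h
}

#' @rdname write_edf
#' @param trial_log trial log data.frame from [stream_detect_troughs()].
#' @export
write_trial_log_csv <- function(trial_log, path) {
  utils::write.csv(trial_log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edf
#' @export
read_trial_log_csv <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

## cheap deterministic hash for config provenance (no external digest dep)
.config_hash <- function(x) {
  b <- serialize(x, NULL, version = 2)
  s <- as.integer(b)
  sprintf("%08x", sum(s * (seq_along(s) %% 97 + 1)) %% .Machine$integer.max)
}

## ---- subject-level simulation + analysis -----------------------------------

#' Simulate one stimulation session (one night, one condition)
#'
#' Generates a synthetic recording, streams it through the online
#' protocol to obtain the trial log, then (for STIM with a non-null
#' profile) applies the phase-dependent click response to the recording.
#' SHAM sessions run the identical detection with muted (inert) clicks.
#'
#' @param config a [synth_config()]; its `response_profile` is forced to
#'   `"null"` for SHAM.
#' @param protocol a [protocol_config()].
#' @param condition `"STIM"` or `"SHAM"`.
#' @return list with `recording`, `truth`, `trial_log`.
#' @export
simulate_session <- function(config, protocol, condition = c("STIM", "SHAM")) {
  condition <- match.arg(condition)
  gen <- generate_recording(config)
  log <- stream_detect_troughs(gen$recording$channels[[protocol$detect_channel]],
                               gen$recording$fs, protocol,
                               gen$recording$hypnogram,
                               gen$recording$artifacts, condition)
  if (condition == "STIM" && nrow(log)) {
    out <- apply_click_response(gen$recording, gen$truth,
                                log$first_click_time, config)
    gen <- out
  }
  list(recording = gen$recording, truth = gen$truth, trial_log = log)
}

#' Offline analysis of one session
#'
#' SWA filtering (Fz), SO and spindle detection (Cz), Hilbert phase,
#' trial assembly and click-phase annotation.
#'
#' @param recording `clas_recording` (with hypnogram).
#' @param trial_log trial log from [stream_detect_troughs()].
#' @param kernels optional list with `swa`, `spindle`, `hilbert` kernels
#'   (precompute once per cohort for speed).
#' @param stages retained sleep stages (default "N3").
#' @param with_spindles run spindle detection (default TRUE); disabling
#'   it speeds up amplitude-only analyses.
#' @return list with `trials`, `so_events`, `spindles`, `swa`, `phase`.
#' @export
analyze_session <- function(recording, trial_log, kernels = NULL,
                            stages = "N3", with_spindles = TRUE) {
  fs <- recording$fs
  if (is.null(kernels))
    kernels <- list(swa = design_fir(swa_filter_spec(fs)),
                    spindle = design_fir(spindle_filter_spec(fs)),
                    phase_band = design_fir(phase_filter_spec(fs)),
                    hilbert = design_hilbert(fs))
  swa <- apply_zero_phase(kernels$swa, recording$channels$Fz)
  so <- detect_so(swa, fs)
  t_all <- (seq_along(swa) - 1) / fs
  ep <- pmin(floor(t_all / 30), nrow(recording$hypnogram) - 1)
  n3_mask <- recording$hypnogram$stage[ep + 1] == "N3"
  spindles <- if (with_spindles)
    detect_spindles(recording$channels$Cz, fs, n3_mask,
                    kernel = kernels$spindle)
  else .empty_spindles()
  swa_mono <- apply_zero_phase(kernels$phase_band, recording$channels$Fz)
  ph <- analytic_phase(swa_mono, kernels$hilbert)
  tl <- data.frame(click1_time = trial_log$first_click_time,
                   click2_time = trial_log$second_click_time,
                   condition = trial_log$condition)
  trials <- build_trials(tl, so, spindles, swa, fs, recording$hypnogram,
                         recording$artifacts, stages = stages)
  trials <- click_phase(trials, ph, swa, fs)
  list(trials = trials, so_events = so, spindles = spindles, swa = swa,
       phase = ph)
}

#' Simulate and analyze one subject (STIM and SHAM nights)
#'
#' A per-subject log-normal amplitude factor (sdlog 0.15) scales SO and
#' spindle amplitudes; STIM and SHAM nights use different recording
#' seeds derived from `seed`.
#'
#' @param subject subject identifier.
#' @param config base [synth_config()].
#' @param protocol [protocol_config()].
#' @param seed per-subject integer seed.
#' @param kernels precomputed filter kernels (see [analyze_session()]).
#' @return data.frame of analyzed trials with `subject` and `condition`.
#' @export
simulate_subject <- function(subject, config, protocol, seed,
                             kernels = NULL, with_spindles = TRUE) {
  set.seed(seed)
  amp_factor <- stats::rlnorm(1, 0, 0.15)
  base <- config
  base$so_trough_amp_mean <- config$so_trough_amp_mean * amp_factor
  base$so_trough_amp_sd <- config$so_trough_amp_sd * amp_factor
  base$spindle_amp <- config$spindle_amp * amp_factor
  base$noise_1f_scale <- config$noise_1f_scale * amp_factor
  out <- list()
  for (cond in c("STIM", "SHAM")) {
    cfg <- base
    cfg$seed <- seed * 2L + (cond == "SHAM")
    if (cond == "SHAM") cfg$response_profile <- "null"
    ses <- simulate_session(cfg, protocol, cond)
    an <- analyze_session(ses$recording, ses$trial_log, kernels,
                          with_spindles = with_spindles)
    tr <- an$trials
    if (nrow(tr)) {
      tr$subject <- subject
      out[[cond]] <- tr
    }
  }
  do.call(rbind, out)
}

## ---- cohort-level statistics ----------------------------------------------

#' Between-condition phase-bin analysis across subjects
#'
#' For every subject and phase bin with at least `min_n` events in both
#' conditions, runs the Monte Carlo between-condition comparison
#' ([mc_between()]); bins are then tested across subjects with the Welch
#' t-test and corrected with Benjamini-Yekutieli FDR. The per-subject
#' peak-response phase is the bin center with maximal STIM-MC minus
#' SHAM-MC mean distance.
#'
#' @param trials cohort trial table (column `subject`).
#' @param grid phase [bin_grid()].
#' @param measure measure column (default `post_trough_amp`).
#' @param n_real Monte Carlo realizations (200).
#' @param q FDR level (0.05).
#' @param min_n minimal events per bin and condition (5; a Gaussian fit
#'   on fewer points is not meaningful).
#' @param seed integer seed.
#' @return list with `bin_table` (per-bin group stats), `sig_mask`,
#'   `peak_phase` (per subject), `group_peak` ([circ_mean_ci()]),
#'   `gain` (mean STIM-SHAM distance over significant bins).
#' @export
phase_response_between <- function(trials, grid, measure = "post_trough_amp",
                                   n_real = 200, q = 0.05, min_n = 5,
                                   seed = 1) {
  subjects <- sort(unique(trials$subject))
  nb <- grid$n_bins
  mean_stim <- matrix(NA_real_, length(subjects), nb)
  mean_sham <- matrix(NA_real_, length(subjects), nb)
  for (s in seq_along(subjects)) {
    tr <- trials[trials$subject == subjects[s], ]
    ps <- pool(tr[tr$condition == "STIM", ], grid, measure)
    ph <- pool(tr[tr$condition == "SHAM", ], grid, measure)
    for (k in seq_len(nb)) {
      if (ps$n_events[k] < min_n || ph$n_events[k] < min_n) next
      mc <- mc_between(ph$values[[k]], ps$values[[k]], n_real,
                       seed = seed + s * 1000L + k)
      mean_stim[s, k] <- mc$mean_stim
      mean_sham[s, k] <- mc$mean_sham
    }
  }
  pvals <- rep(NA_real_, nb)
  tvals <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    a <- mean_stim[, k]; b <- mean_sham[, k]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 4) next
    wt <- welch_t(a[ok], b[ok])
    pvals[k] <- wt$p; tvals[k] <- wt$t
  }
  sig <- fdr_by(pvals, q)
  diffm <- mean_stim - mean_sham
  ## per-subject peak among group-significant bins (all bins if none)
  cand <- if (any(sig)) sig else rep(TRUE, nb)
  peak <- vapply(seq_along(subjects), function(s) {
    d <- diffm[s, ]
    d[!cand] <- NA
    if (all(is.na(d))) NA_real_ else grid$centers[which.max(d)]
  }, numeric(1))
  peak <- peak[!is.na(peak)]
  group_peak <- if (length(peak) >= 3) circ_mean_ci(peak) else NULL
  gain <- if (any(sig)) mean(diffm[, sig, drop = FALSE], na.rm = TRUE)
          else NA_real_
  list(bin_table = data.frame(center = grid$centers, t = tvals, p = pvals,
                              sig = sig,
                              mean_diff = colMeans(diffm, na.rm = TRUE)),
       sig_mask = sig, peak_phase = peak, group_peak = group_peak,
       gain = gain, mean_stim = mean_stim, mean_sham = mean_sham)
}

#' Within-condition pairwise-bin analysis and PRI across subjects
#'
#' Runs the within-condition Monte Carlo pairwise comparison per subject
#' on STIM trials, extracts each subject's per-bin PRI and its peak
#' phase, and tests per-bin PRI against zero across subjects (BY-FDR).
#'
#' @inheritParams phase_response_between
#' @param condition condition analyzed (default "STIM").
#' @return list with `pri_matrix` (subjects x bins), `pri_mean`,
#'   `sig_mask`, `peak_phase` (per subject), `group_peak`.
#' @export
phase_response_within <- function(trials, grid, measure = "post_trough_amp",
                                  n_real = 200, q = 0.05, min_n = 3,
                                  seed = 1, condition = "STIM") {
  subjects <- sort(unique(trials$subject))
  nb <- grid$n_bins
  pri_m <- matrix(NA_real_, length(subjects), nb)
  for (s in seq_along(subjects)) {
    tr <- trials[trials$subject == subjects[s] &
                   trials$condition == condition, ]
    bs <- pool(tr, grid, measure)
    vals <- bs$values
    vals[bs$n_events < min_n] <- list(numeric(0))
    mw <- mc_within(vals, n_real, seed = seed + s * 977L)
    pri_m[s, ] <- pri(mw$t)
  }
  pvals <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    v <- pri_m[, k]; v <- v[!is.na(v)]
    if (length(v) < 4 || stats::sd(v) == 0) next
    tt <- stats::t.test(v)
    pvals[k] <- tt$p.value
  }
  sig <- fdr_by(pvals, q)
  peak <- vapply(seq_len(nrow(pri_m)), function(s) {
    d <- pri_m[s, ]
    if (all(is.na(d))) NA_real_ else grid$centers[which.max(d)]
  }, numeric(1))
  peak <- peak[!is.na(peak)]
  list(pri_matrix = pri_m, pri_mean = colMeans(pri_m, na.rm = TRUE),
       sig_mask = sig, p = pvals, peak_phase = peak,
       group_peak = if (length(peak) >= 3) circ_mean_ci(peak) else NULL)
}

#' Run configuration for an end-to-end synthetic cohort analysis
#'
#' @param n_subjects number of subjects (default 20).
#' @param synth base [synth_config()].
#' @param protocol [protocol_config()].
#' @param q FDR level (0.05).
#' @param n_real Monte Carlo realizations (200).
#' @param seed master seed; all per-subject seeds derive from it.
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_subjects = 20, synth = synth_config(),
                       protocol = protocol_config("uLub"), q = 0.05,
                       n_real = 200, seed = 1, outdir = NULL,
                       with_spindles = TRUE) {
  structure(list(n_subjects = n_subjects, synth = synth,
                 protocol = protocol, q = q, n_real = n_real, seed = seed,
                 outdir = outdir, with_spindles = with_spindles),
            class = "run_config")
}

#' End-to-end cohort simulation and phase-response analysis
#'
#' Simulates the cohort (STIM + SHAM nights per subject), runs the
#' offline detection/phase pipeline, pools post-stimulus trough
#' amplitudes and spindle flags into phase bins, and computes the
#' between-condition Monte Carlo comparison, the within-condition PRI,
#' and the circular-covariate logistic regression. When `outdir` is set,
#' writes per-subject trial tables, bin tables and a machine-readable
#' JSON summary embedding the config hash and seed.
#'
#' @param config a [run_config()].
#' @return list with `trials`, `between`, `within`, `logistic`,
#'   `spindle_likelihood`, `summary`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fs <- config$synth$fs
  kernels <- list(swa = design_fir(swa_filter_spec(fs)),
                  spindle = design_fir(spindle_filter_spec(fs)),
                  phase_band = design_fir(phase_filter_spec(fs)),
                  hilbert = design_hilbert(fs))
  all_tr <- list()
  for (s in seq_len(config$n_subjects)) {
    tr <- simulate_subject(s, config$synth, config$protocol,
                           seed = config$seed * 1000L + s, kernels = kernels,
                           with_spindles = isTRUE(config$with_spindles))
    all_tr[[s]] <- tr
  }
  trials <- do.call(rbind, all_tr)
  grid <- bin_grid("phase")
  between <- phase_response_between(trials, grid, n_real = config$n_real,
                                    q = config$q, seed = config$seed)
  within <- phase_response_within(trials, grid, n_real = config$n_real,
                                  q = config$q, seed = config$seed)
  ok <- !trials$excluded
  logistic <- tryCatch(
    fit_circular_logistic(trials$ss_likelihood_flag[ok], trials$lag_s[ok],
                          trials$click_phase[ok]),
    error = function(e) NULL)
  lik <- vapply(c("STIM", "SHAM"), function(cond) {
    fl <- trials$ss_likelihood_flag[ok & trials$condition == cond]
    fl <- fl[!is.na(fl)]
    if (length(fl) < 3) return(NA_real_)
    binomial_likelihood(fl, config$n_real,
                        seed = config$seed + 7L)$likelihood
  }, numeric(1))
  summary <- list(
    config_hash = .config_hash(config), seed = config$seed,
    n_subjects = config$n_subjects, n_trials = nrow(trials),
    n_analyzed = sum(ok),
    peak_phase = if (!is.null(between$group_peak)) between$group_peak$mean
                 else NA_real_,
    peak_phase_ci = if (!is.null(between$group_peak)) between$group_peak$ci
                    else c(NA_real_, NA_real_),
    amplitude_gain_uV = between$gain,
    pri_peak_phase = if (!is.null(within$group_peak)) within$group_peak$mean
                     else NA_real_,
    sig_phase_bins = grid$centers[between$sig_mask],
    spindle_likelihood = as.list(lik),
    logistic_acrophase = if (!is.null(logistic)) logistic$acrophase
                         else NA_real_)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(config$outdir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(between$bin_table,
                     file.path(config$outdir, "phase_bins_between.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(trials = trials, between = between, within = within,
       logistic = logistic, spindle_likelihood = lik, summary = summary)
}
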