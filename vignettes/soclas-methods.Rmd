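---
title: "Phase-targeted auditory stimulation of slow oscillations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-targeted auditory stimulation of slow oscillations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soclas)
```

## The problem

Closed-loop auditory stimulation (CLAS) delivers brief clicks during
slow-wave sleep, timed to the ongoing slow oscillation (SO, ~0.5-2 Hz).
Clicks applied near the SO up-state increase the amplitude of the
following wave and the probability of a coupled sleep spindle (SS,
11-16 Hz). The scientific question this package addresses is *where on
the SO cycle a click is most effective*, and how to estimate that optimal
phase from stimulation recordings: detect the events offline, estimate
the SO phase at each click, pool post-stimulus measures into overlapping
phase bins, and run bin-level statistics that remain valid when the
number of events per bin is wildly unbalanced (CLAS targets one phase, so
the opposite phase is always data-poor).

Because no public dataset accompanies this design, the package is built
around a synthetic-data module that states a complete, ground-truth
labelled world. Every downstream stage is tested against that world.

## The synthetic world

`synth_config()` freezes the following stated conditions. They were
chosen once, from the physiology the analysis assumes, and are not tuned
to test outcomes.

* **Slow oscillations.** One-cycle biphasic raised-cosine waves (negative
  then positive half-wave), half-wave durations uniform on 0.3-0.8 s, so
  every generated negative half-wave satisfies the 0.25-1.0 s detection
  criterion by construction. Trough amplitudes are N(-100, 20) uV;
  detected-trough summaries in the source protocols run from about -80 to
  -104 uV *for the detected subset*, and an online threshold of -80 uV
  against a N(-100, 20) population reproduces exactly that selection
  (threshold "demandingness" above 90%). Events arrive in quasi-continuous
  trains (40/min of N3, small exponential gaps), giving trough-to-trough
  periods of roughly 1.1-1.9 s so that the second click of a trial falls
  on the following wave, as the two-click protocols intend.
* **Spindles.** Hann-windowed sinusoidal bursts, frequency ~N(13, 1) Hz
  clipped to the band, durations uniform on 0.5-1.5 s, 25 uV peak, a hard
  1-s refractory dead time, 3 events/min of N2/N3. The dead time also
  gates click-induced spindles, so very short lags carry a genuine
  refractoriness signature in every profile.
* **Background.** 1/f (pink) noise at 15 uV SD per channel, synthesized
  by spectral shaping of seeded white noise; plus a 30-s-epoch hypnogram
  with one contiguous N3 block and sparse 5-s artifact intervals.
* **Click response.** For the `young` profile the SO following a click at
  phase $\varphi$ is scaled by
  $g(\varphi) = 1 + (g_{\max}-1)\,e^{\kappa(\cos(\varphi-\mu)-1)}$ with
  $\mu = 90^\circ$ (the SO peak), $\kappa = 2$, $g_{\max} = 1.45$, and a
  spindle is induced in the following trough-to-trough window with
  probability $0.35\,e^{\kappa(\cos(\varphi-\mu)-1)}$ (chosen so the
  STIM/SHAM likelihood contrast in the effective interval is ~21% vs
  ~8%, the size reported for young adults), subject to
  refractoriness. For `older`, the gain excess is reduced to 45% and the
  spindle increment depends only on the lag since the last spindle
  ($1 - e^{-\mathrm{lag}/4\,\mathrm{s}}$), not on phase. `null` applies
  nothing (SHAM semantics). The von Mises kernel is a modelling choice:
  the source design reports *that* the response peaks near the SO peak,
  not a quantitative curve.

What the generator does **not** emulate: scalp topography (the two
channels share sources with fixed mixing weights), REM/wake
microstructure, K-complexes, slow/fast spindle classes, and any
non-stationarity across the night. A green pipeline test therefore
establishes that the estimators recover a known phase-coded response in
realistic noise - not that they would be unbiased on arbitrary real EEG.

## Online protocol simulation

`stream_detect_troughs()` emulates the historical two-click protocols: a
causal 2nd-order Butterworth band-pass (0.25-4 Hz, high-pass/low-pass
biquad cascade) stands in for the unpublished real-time filter; negative
deflections crossing an adaptive threshold trigger a trial (trough
localized as the first local minimum within 0.5 s). The `uLub`/`uTub`
variants refresh the threshold every 0.5 s to the minimum of the
preceding 5 s when below the -80 uV default; `uAnd` sets it to half the
detected trough when below -60 uV. Two clicks are scheduled per trial
(`click_delay_s` after the trough, inter-click interval per variant),
followed by a 2.5-s pause; stimulation is gated to N2/N3 after 5
contiguous NREM minutes, halted inside artifact annotations, and capped
at the variant's stimulation budget.

Two parameters deserve comment:

* `click_delay_s = 0.5` with trial-to-trial jitter U(-0.15, 0.15) s. The
  sources state only that click times were "defined individually by each
  algorithm". 0.5 s lands the click near the next up-state peak for a
  ~1.3-s wave; the jitter emulates real-time detection latency
  variability and is what spreads click phases over the circle, as the
  event histograms of stimulation studies show.
* `amp_resolution_uV = 0.1`: the threshold comparison is quantized. The
  uLub rule sets the threshold *equal* to the preceding trough, so on
  stationary input an infinitely precise strict comparison would never
  fire again; physical acquisition chains quantize amplitude.

## Offline filters

All offline filters are linear-phase FIRs verified against their printed
response contracts (`-3 dB` corners within 5%, stopband attenuation at
the stated edges): SWA band-pass (corners 0.25/3.08 Hz, >= 37 dB below
0.01 and above 4 Hz), spindle band-pass (corners 10.62/17.38 Hz,
>= 40 dB outside 10.01/18 Hz). The design is a Kaiser-windowed sinc with
automatic length selection and numeric calibration of the cutoffs onto
the printed corners; "windowed equiripple" is a contradiction in terms,
and the realized response points - not the design family - are the
testable contract. Zero-phase application is a single pass with exact
group-delay compensation and one-kernel-length reflection padding.
Resampling applies a 0.45-fs_out Kaiser low-pass and then linear
interpolation. The moving RMS uses a centered 0.2-s window with
truncated edges.

## Phase estimation

The SO phase convention puts 0 deg at the negative-to-positive zero
crossing, 90 at the peak, and -90/270 at the troughs. The instantaneous
phase is the angle of the analytic signal built from a causal
least-squares FIR Hilbert transformer with a 250-ms compensated delay:
the phase at time $t$ uses samples up to $t + 250$ ms only, which keeps
the estimate driven by the signal's past and insulates it from the
stimulus response.

A hard fact constrains this design: a 101-tap (2 x 50 + 1) transformer at
200 Hz that holds unity gain within 5% over 0.5-2 Hz *necessarily*
amplifies 2.5-4 Hz content by two to three orders of magnitude (the
transition demanded at 0.5 Hz is far below the filter's frequency
resolution, and the least-squares solution buys in-band accuracy with
wild out-of-band behaviour). Feeding it the broad SWA trace (corners at
3.08 Hz) produces an unusable phase. The pipeline therefore conditions
the *phase path only* with a stricter 0.5-2 Hz band-pass
(`phase_filter_spec()`); SO and spindle measures are still taken from the
broad SWA trace, which keeps the temporal morphology of individual waves.

Each trial's click is assigned to a trough-to-trough cycle delimited by
SWA-trace local minima. The cycle's analytic phase is validated: it must
be non-decreasing (cumulative regression <= 5 deg, tolerating numerical
jitter) and span 360 +- 45 deg. Cycles failing validation - typically
multicomponent waves - are repaired by the least-squares polynomial of
order <= 4 with non-negative slope (a quadratic program solved by
Hildreth's method; the order-4 constrained optimum nests all lower
orders, so only one QP is needed). Endpoints are constrained to within
10 deg of -90/270, and interior landmarks of the SWA trace (upcrossing
-> 0 deg, peak -> 90, downcrossing -> 180, +-10 deg) anchor the fit;
without them the repaired phase is systematically late by ~30 deg
because the polynomial stretches the cycle across inter-wave gaps. If no
feasible monotone fit exists, the linear -90 -> 270 ramp is used and
flagged. The span tolerance (45 deg), jitter tolerance (5 deg) and
anchor tolerance (10 deg) are repository choices recorded here.

## Event detection and trials

SOs are zero-crossing-delimited negative half-waves of 0.25-1.0 s -
amplitude-blind by design. Spindles are maximal runs of the 0.2-s
band RMS above the 86.64th percentile of N3 activity (the two-sided
standard-normal probability of 1.5 SD; note the *one-sided* Gaussian
quantile at 1.5 SD would be 93.32%, so the printed percentile is the
contract). Runs separated by < 0.1 s are merged; kept events must last
0.3-3 s, contain >= 5 oscillations (upward zero crossings on the run
trimmed by the RMS-window smear), and show a unimodal Morlet spectrum
(8-30 Hz, 0.5-Hz grid, 7 cycles): exactly one local maximum above half
the spectral peak, located in 11-16 Hz, with mean power non-increasing
across octave-ish bands (16-22, 22-30 Hz) above the band.

Per trial, the post-stimulus trough is the trough of the first *detected
SO* within 2 s after the first click (raw local minima would latch onto
noise dips); its absolute amplitude is the SO response. Trials whose
second click precedes that trough are excluded, as are clicks outside N3
or inside artifacts. The spindle-association window runs from the
post-stimulus trough to the next SO trough; the first spindle beginning
inside it defines the likelihood flag, latency, duration, RMS and
amplitude measures. The lag covariate is the time from the previous
spindle onset to the click.

## Statistics

* **Binning.** 50 overlapping bins: click delays -100..600 ms with
  200-ms windows; click phases on a 7.2-deg grid with 45-deg windows
  (half-width membership, left-inclusive), wrap-around honoured.
* **Between conditions.** Per bin, a Gaussian is fitted to the SHAM
  ensemble; 200 draws form the Monte Carlo set; all pairwise subtractions
  give SHAM-MC and STIM-MC distance ensembles whose per-subject means are
  compared across subjects with the Welch test (Welch-Satterthwaite df)
  and Benjamini-Yekutieli FDR (valid under arbitrary dependence; one
  family = all 50 bins). The per-subject peak-response phase is the bin
  with maximal STIM-MC minus SHAM-MC distance among group-significant
  bins, and the group optimum is its circular mean with a von Mises
  dispersion CI.
* **Within condition.** Per bin, the distribution of 200 subsample means
  (two-thirds of the events, without replacement, rounded half away from
  zero); Welch tests on all bin pairs give an antisymmetric t matrix, and
  each bin's Pairwise Response Index is the mean sign of its row: +1 =
  consistently the strongest response.
* **Binary outcomes.** The spindle likelihood of a bin is the geometric
  mean of the event ratio over 200 two-thirds subsamples; zero ratios are
  replaced by 1/(2 x subsample size) (an all-zero ensemble reports 0),
  with the arithmetic ratio reported alongside.
* **Logistic model.** Spindle occurrence ~ Lag + cos(phase) + sin(phase),
  binomial with logit link, trials restricted to lag < 10 s. Wald
  chi-square per coefficient, odds ratios with 95% CIs, the
  model-vs-intercept likelihood-ratio test, and the acrophase
  atan2(beta_sin, beta_cos) - the phase of maximal log odds. Lag enters
  in seconds, unstandardized. With the generator's mu = 90 deg the cosine
  coefficient is zero by symmetry, so "phase matters" is assessed as the
  joint likelihood-ratio test of the sine/cosine pair.

## Numerical and degenerate-input choices

Seeded everything: the generator, the Monte Carlo procedures and the
subsamplers all take explicit seeds, and identical configs reproduce
byte-identical outputs (the JSON summary embeds a config hash). Zero-sd
SHAM bins are flagged `degenerate`; all-zero traces yield an
all-NA phase with a warning rather than silent zeros; empty RMS
ensembles, empty trough lists and out-of-range configurations raise
errors. Subsample sizes round half away from zero. The Hildreth QP runs
at most 400 sweeps on a 25-point derivative grid; infeasibility falls
back to the flagged linear ramp.

## Known limitations

The phase estimator is validated on raised-cosine wave trains; real SOs
with strong harmonics inside 0.5-2 Hz may shift the analytic phase in
ways the landmark-anchored repair only partly absorbs (residual median
bias ~-7 deg at the stated noise level, absorbed by the +-15 deg
recovery criterion). The online simulator models neither audio latency
nor manual arousal-halting judgment (artifact gating is automated). EDF
support covers the 16-bit single-rate subset the pipeline writes. The
within-condition PRI significance uses a one-sample t across subjects
per bin, a pragmatic reading of the group-level summary the source
analyses display.
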