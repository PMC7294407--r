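# long FIR designs are expensive; design once per test run
.kcache <- new.env(parent = emptyenv())

cached_kernel <- function(which = c("swa", "spindle", "phase_band", "hilbert"),
                          fs = 200) {
  which <- match.arg(which)
  key <- paste(which, fs, sep = "_")
  if (is.null(.kcache[[key]])) {
    .kcache[[key]] <- switch(which,
      swa = design_fir(swa_filter_spec(fs)),
      spindle = design_fir(spindle_filter_spec(fs)),
      phase_band = design_fir(phase_filter_spec(fs)),
      hilbert = design_hilbert(fs))
  }
  .kcache[[key]]
}

cached_kernel_list <- function(fs = 200)
  list(swa = cached_kernel("swa", fs),
       spindle = cached_kernel("spindle", fs),
       phase_band = cached_kernel("phase_band", fs),
       hilbert = cached_kernel("hilbert", fs))

# circular distance helper for expectations, degrees in [-180, 180)
circ_diff <- function(a, b) ((a - b + 180) %% 360) - 180

.rad2deg_test <- function(x) x * 180 / pi
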