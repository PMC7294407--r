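#' Instantaneous slow-oscillation phase from the analytic signal
#'
#' The analytic signal is composed of the SWA-filtered trace (real part)
#' and its quarter-cycle shifted representation from the FIR Hilbert
#' transformer (imaginary part). The phase convention places 0 degrees at
#' the negative-to-positive zero crossing, 90 at the peak and -90/270 at
#' the troughs, realized as `angle(x + i * x_h) + 90`.
#'
#' Because the transformer is causal with a compensated 250 ms delay, the
#' phase at time `t` depends on samples up to `t + delay` only; the final
#' `delay` samples are `NA`.
#'
#' @param swa SWA band-filtered trace.
#' @param hilbert_kernel kernel from [design_hilbert()].
#' @return numeric phase per sample in degrees, wrapped to `[-90, 270)`;
#'   `NA` where undefined (near-zero analytic amplitude or missing
#'   look-ahead).
#' @export
analytic_phase <- function(swa, hilbert_kernel) {
  xh <- apply_hilbert(hilbert_kernel, swa)
  amp <- sqrt(swa^2 + xh^2)
  amax <- max(amp, na.rm = TRUE)
  tiny <- !is.finite(amp) | amax == 0 | amp < 1e-9 * amax
  ph <- wrap_deg(atan2(xh, swa) * 180 / pi + 90)
  ph[tiny] <- NA_real_
  if (all(is.na(ph))) warning("all-zero input: phase undefined everywhere")
  ph
}

## unwrap degrees with the standard +-180 jump rule
.unwrap_deg <- function(x) {
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  c(x[1], x[1] + cumsum(d))
}

#' Classify a trough-to-trough phase cycle
#'
#' A cycle is kept as `"analytic"` when its unwrapped phase is
#' non-decreasing everywhere and spans 360 +- 45 degrees; otherwise the
#' multicomponent repair (`"needs_fit"`) is requested.
#'
#' @param phase_segment phase samples (degrees) across one cycle.
#' @param span_tol span tolerance in degrees (default 45).
#' @param drop_tol total phase regression (degrees, default 5) tolerated
#'   as numerical jitter before a cycle counts as non-monotone.
#' @return `"analytic"` or `"needs_fit"`.
#' @export
validate_cycle <- function(phase_segment, span_tol = 45, drop_tol = 5) {
  u <- .unwrap_deg(phase_segment)
  span <- u[length(u)] - u[1]
  backtrack <- max(cummax(u) - u)
  if (backtrack > drop_tol || abs(span - 360) > span_tol) "needs_fit"
  else "analytic"
}

## Hildreth dual coordinate ascent for  min 1/2 a'Qa + c'a  s.t.  A a >= b
.hildreth_qp <- function(Q, cc, A, b, iters = 3000, tol = 1e-9) {
  Qi <- solve(Q + 1e-10 * mean(diag(Q)) * diag(nrow(Q)))
  C <- -A; d <- -b                      # C a <= d
  M <- C %*% Qi %*% t(C)
  e <- as.vector(d + C %*% Qi %*% cc)
  m <- nrow(C)
  lam <- numeric(m)
  for (it in seq_len(iters)) {
    lam_old <- lam
    for (i in seq_len(m)) {
      if (M[i, i] <= 0) next
      w <- e[i] + sum(M[i, ] * lam) - M[i, i] * lam[i]
      lam[i] <- max(0, -w / M[i, i])
    }
    if (max(abs(lam - lam_old)) < tol) break
  }
  as.vector(-Qi %*% (cc + t(C) %*% lam))
}

#' Monotone polynomial repair of a multicomponent phase cycle
#'
#' Least-squares polynomial fit of order at most 4 with non-decreasing
#' slope over the cycle, endpoints constrained to within `end_tol` of
#' -90 and 270 degrees. Solved as a quadratic program (derivative
#' non-negativity enforced on a dense grid). If no feasible monotone fit
#' exists the linear interpolation between -90 and 270 is returned,
#' flagged via `attr(, "fallback")`.
#'
#' @param phase_segment phase samples (degrees) across one cycle; wrapped
#'   input is unwrapped internally.
#' @param max_order maximal polynomial order (default 4).
#' @param end_tol endpoint tolerance in degrees (default 10).
#' @param anchors optional data.frame with `pos` (sample index inside the
#'   segment), `value` (degrees) and `tol` (degrees): interior landmark
#'   constraints (e.g. 0 at the trace upcrossing, 90 at the peak) added
#'   to the quadratic program.
#' @return fitted phase samples, with attributes `order` and `fallback`.
#' @export
monotone_poly_fit <- function(phase_segment, max_order = 4, end_tol = 10,
                              anchors = NULL) {
  y <- .unwrap_deg(phase_segment)
  n <- length(y)
  ## anchor the unwrapped branch so a full cycle runs -90 -> 270
  y <- y - 360 * round((y[1] + 90) / 360)
  x <- seq(0, 1, length.out = n)
  grid <- seq(0, 1, length.out = 25)
  ## the constrained order-`max_order` problem nests every lower order, so
  ## its optimum has minimal RSS among all feasible orders <= max_order
  ord <- max_order
  V <- outer(x, 0:ord, `^`)
  Dg <- cbind(0, sapply(seq_len(ord), function(k) k * grid^(k - 1)))
  e0 <- c(1, rep(0, ord))                  # value at x = 0
  e1 <- rep(1, ord + 1)                    # value at x = 1
  A <- rbind(Dg, e0, -e0, e1, -e1)
  b <- c(rep(0, nrow(Dg)),
         -90 - end_tol, -( -90 + end_tol),
         270 - end_tol, -(270 + end_tol))
  if (!is.null(anchors) && nrow(anchors)) {
    Va <- outer(x[anchors$pos], 0:ord, `^`)
    A <- rbind(A, Va, -Va)
    b <- c(b, anchors$value - anchors$tol, -(anchors$value + anchors$tol))
  }
  Q <- crossprod(V)
  cc <- -crossprod(V, y)
  ## unconstrained solution first: usually feasible, and then exact
  a <- tryCatch(solve(Q, -cc), error = function(e) NULL)
  feasible <- function(a) !is.null(a) && all(A %*% a >= b - 1e-6)
  if (!feasible(a))
    a <- tryCatch(.hildreth_qp(Q, cc, A, b, iters = 400),
                  error = function(e) NULL)
  if (!is.null(a)) {
    fit <- as.vector(V %*% a)
    dmin <- min(Dg %*% a)
    ends_ok <- abs(fit[1] + 90) <= end_tol + 1 &&
      abs(fit[n] - 270) <= end_tol + 1
    if (dmin >= -1e-3 && ends_ok) {
      attr(fit, "order") <- ord
      attr(fit, "fallback") <- FALSE
      return(fit)
    }
  }
  out <- seq(-90, 270, length.out = n)
  attr(out, "order") <- NA_integer_
  attr(out, "fallback") <- TRUE
  out
}

## Trough-to-trough cycles of the SWA trace: consecutive negative local
## minima (the troughs of successive slow waves) delimit one phase cycle.
.phase_cycles <- function(phase, swa, fs, min_s = 0.5, max_s = 3) {
  dmin <- which(diff(sign(diff(swa))) > 0) + 1L
  dmin <- dmin[swa[dmin] < 0]
  if (length(dmin) < 2) return(data.frame(start = integer(), end = integer()))
  cyc <- data.frame(start = dmin[-length(dmin)], end = dmin[-1])
  len <- (cyc$end - cyc$start) / fs
  cyc <- cyc[len >= min_s & len <= max_s, , drop = FALSE]
  ok <- !is.na(phase)
  keep <- vapply(seq_len(nrow(cyc)), function(i)
    all(ok[cyc$start[i]:cyc$end[i]]), TRUE)
  cyc[keep, , drop = FALSE]
}

## landmark anchors for the monotone fit from the SWA trace segment:
## 0 deg at the upcrossing, 90 at the positive peak, 180 at the downcrossing
.swa_anchors <- function(sw_seg, tol = 10) {
  n <- length(sw_seg)
  up <- which(sw_seg[-n] < 0 & sw_seg[-1] >= 0)
  if (!length(up)) return(NULL)
  up <- up[1] + 1L
  out <- data.frame(pos = up, value = 0, tol = tol)
  dn <- which(sw_seg[-n] >= 0 & sw_seg[-1] < 0)
  dn <- dn[dn >= up]
  pk_end <- if (length(dn)) dn[1] else n
  pk <- up + which.max(sw_seg[up:pk_end]) - 1L
  if (pk > up && pk < pk_end)
    out <- rbind(out, data.frame(pos = pk, value = 90, tol = tol))
  if (length(dn) && dn[1] > pk && dn[1] < n)
    out <- rbind(out, data.frame(pos = dn[1] + 1L, value = 180, tol = tol))
  out
}

#' Click phase and delay for each trial
#'
#' Locates the trough-to-trough phase cycle containing each trial's first
#' click, repairs multicomponent cycles with [monotone_poly_fit()], and
#' annotates the trial with the click phase (degrees, -90..270) and the
#' delay from the cycle's negative-to-positive zero crossing (seconds;
#' negative when the click precedes the upcrossing). Clicks outside any
#' valid cycle are excluded with a reason.
#'
#' @param trials data.frame with a `click1_time` column (seconds).
#' @param phase phase trace from [analytic_phase()].
#' @param swa SWA-filtered trace the phase was computed from.
#' @param fs sampling rate in Hz.
#' @return `trials` with `click_phase`, `click_delay`, `phase_fitted`
#'   (logical) columns and updated `excluded`/`excl_reason`.
#' @export
click_phase <- function(trials, phase, swa, fs) {
  cyc <- .phase_cycles(phase, swa, fs)
  n <- nrow(trials)
  trials$click_phase <- NA_real_
  trials$click_delay <- NA_real_
  trials$phase_fitted <- FALSE
  if (!"excluded" %in% names(trials)) trials$excluded <- FALSE
  if (!"excl_reason" %in% names(trials)) trials$excl_reason <- NA_character_
  for (i in seq_len(n)) {
    if (isTRUE(trials$excluded[i])) next
    idx <- round(trials$click1_time[i] * fs) + 1L
    row <- which(cyc$start <= idx & cyc$end >= idx)
    if (length(row) != 1L) {
      trials$excluded[i] <- TRUE
      trials$excl_reason[i] <- "click outside validated phase cycle"
      next
    }
    seg_idx <- cyc$start[row]:cyc$end[row]
    seg <- phase[seg_idx]
    if (validate_cycle(seg) == "needs_fit") {
      seg <- monotone_poly_fit(seg, anchors = .swa_anchors(swa[seg_idx]))
      trials$phase_fitted[i] <- TRUE
    } else {
      seg <- .unwrap_deg(seg)
      seg <- seg - 360 * round((seg[1] + 90) / 360)
    }
    pos <- idx - cyc$start[row] + 1L
    trials$click_phase[i] <- wrap_deg(seg[pos])
    ## upcrossing of the SWA trace inside the cycle (delay reference)
    sw_seg <- swa[seg_idx]
    up <- which(sw_seg[-length(sw_seg)] < 0 & sw_seg[-1] >= 0)
    up <- if (length(up)) up[1] + 1L else which(seg >= 0)[1]
    if (is.na(up)) {
      trials$excluded[i] <- TRUE
      trials$excl_reason[i] <- "no upcrossing inside cycle"
      next
    }
    trials$click_delay[i] <- (pos - up) / fs
  }
  trials
}
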