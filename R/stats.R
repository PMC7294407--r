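## Circular helpers -----------------------------------------------------------

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees into a 360-degree window
#'
#' @param x angles in degrees.
#' @param lo lower edge of the target window (default -90, so the slow
#'   oscillation convention -90..270 is produced).
#' @export
wrap_deg <- function(x, lo = -90) ((x - lo) %% 360) + lo

## Fisher/Best approximation of the inverse of A(kappa) = I1/I0
.a1inv <- function(r) {
  if (r >= 1) return(Inf)
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

.circ_stats <- function(deg) {
  th <- .deg2rad(deg)
  C <- sum(cos(th)); S <- sum(sin(th))
  R <- sqrt(C^2 + S^2)
  list(mean = .rad2deg(atan2(S, C)), R = R, rbar = R / length(deg),
       n = length(deg))
}

#' Circular mean with confidence interval
#'
#' Mean direction of a sample of angles plus a von Mises dispersion-based
#' confidence interval (half-width `asin(z / sqrt(n * rbar * kappa))`).
#'
#' @param angles angles in degrees.
#' @param confidence confidence level (default 0.95).
#' @return list with `mean`, `ci` (length 2), `rbar`, `kappa`, `n`; angles
#'   reported in the -90..270 convention. If the resultant length is
#'   (numerically) zero the CI is `NA` and `defined` is `FALSE`.
#' @export
circ_mean_ci <- function(angles, confidence = 0.95) {
  if (length(angles) < 3) stop("need at least 3 angles")
  cs <- .circ_stats(angles)
  if (cs$rbar < 1e-8)
    return(list(mean = NA_real_, ci = c(NA_real_, NA_real_), rbar = cs$rbar,
                kappa = 0, n = cs$n, defined = FALSE))
  kappa <- .a1inv(cs$rbar)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  arg <- z / sqrt(cs$n * cs$rbar * kappa)
  if (arg >= 1)
    return(list(mean = wrap_deg(cs$mean), ci = c(NA_real_, NA_real_),
                rbar = cs$rbar, kappa = kappa, n = cs$n, defined = FALSE))
  hw <- .rad2deg(asin(arg))
  list(mean = wrap_deg(cs$mean), ci = wrap_deg(cs$mean + c(-hw, hw)),
       rbar = cs$rbar, kappa = kappa, n = cs$n, defined = TRUE)
}

#' Watson-Williams circular one-way ANOVA
#'
#' Tests equality of mean directions across two or more samples of angles,
#' with the standard concentration correction factor `1 + 3/(8 kappa)`.
#' A warning is issued when the pooled resultant length is outside the
#' test's recommended validity range (`rbar < 0.45`).
#'
#' @param groups list of numeric vectors of angles in degrees.
#' @return list with `F`, `df1`, `df2`, `p`, `kappa`, `rbar_within`.
#' @export
watson_williams <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 5))
    warning("Watson-Williams with group n < 5 is unreliable")
  st <- lapply(groups, .circ_stats)
  Rs <- vapply(st, `[[`, 1, "R")
  if (any(Rs < 1e-10)) stop("a group has zero resultant length")
  n <- sum(vapply(st, `[[`, 1L, "n"))
  k <- length(groups)
  all_deg <- unlist(groups)
  R <- .circ_stats(all_deg)$R
  sumR <- sum(Rs)
  rbar_w <- sumR / n
  if (rbar_w < 0.45)
    warning("pooled resultant length < 0.45: Watson-Williams may be invalid")
  kappa <- .a1inv(rbar_w)
  Fstat <- (1 + 3 / (8 * kappa)) * ((n - k) * (sumR - R)) /
    ((k - 1) * (n - sumR))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  list(F = Fstat, df1 = k - 1, df2 = n - k, p = p, kappa = kappa,
       rbar_within = rbar_w)
}

## Frequentist machinery ------------------------------------------------------

#' Welch unequal-variance t-test
#'
#' Plain Welch statistic with the Welch-Satterthwaite degrees of freedom
#' (the Moser-Stevens recommendation is to use this test always; no
#' alternative df formula is involved).
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = nx + ny - 2, p = 1))
    stop("zero variance in both samples")
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Yekutieli FDR rejection mask
#'
#' Rejects the `k` smallest p-values where `k` is the largest `i` with
#' `p(i) <= i * q / (m * c(m))`, `c(m) = sum_{j<=m} 1/j`. Valid under
#' arbitrary dependence of the tests.
#'
#' @param pvals p-values in `[0, 1]` (NA allowed; never rejected).
#' @param q target false discovery rate.
#' @return logical vector, `TRUE` where rejected.
#' @export
fdr_by <- function(pvals, q = 0.05) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  m <- length(p)
  out <- logical(length(pvals))
  if (m == 0) return(out)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  thr <- seq_len(m) * q / (m * cm)
  passed <- which(p[o] <= thr)
  if (length(passed)) {
    k <- max(passed)
    rej <- logical(m)
    rej[o[seq_len(k)]] <- TRUE
    out[ok] <- rej
  }
  out
}

## Monte Carlo bin machinery --------------------------------------------------

.round_half_away <- function(x) floor(x + 0.5)

#' Between-condition Monte Carlo comparison for one bin
#'
#' Fits a Gaussian to the SHAM ensemble of a bin, draws `n_real`
#' realizations as the bin's Monte Carlo (MC) set, and forms all pairwise
#' subtraction distances SHAM-MC and STIM-MC. The per-subject mean
#' distances are the representative statistics compared across subjects.
#'
#' @param sham_bin,stim_bin numeric ensembles of the targeted measure.
#' @param n_real number of MC realizations (default 200).
#' @param seed integer seed for the draws.
#' @return list with `mc`, `sham_dist`, `stim_dist`, `mean_sham`,
#'   `mean_stim`, and `degenerate` (TRUE when the SHAM sd is 0).
#' @export
mc_between <- function(sham_bin, stim_bin, n_real = 200, seed = NULL) {
  stopifnot(length(sham_bin) >= 3)
  if (!is.null(seed)) set.seed(seed)
  mu <- mean(sham_bin); sdv <- stats::sd(sham_bin)
  degenerate <- sdv == 0
  mc <- stats::rnorm(n_real, mu, sdv)
  sham_dist <- as.vector(outer(sham_bin, mc, `-`))
  stim_dist <- as.vector(outer(stim_bin, mc, `-`))
  list(mc = mc, sham_dist = sham_dist, stim_dist = stim_dist,
       mean_sham = mean(sham_dist), mean_stim = mean(stim_dist),
       degenerate = degenerate)
}

#' Within-condition Monte Carlo pairwise bin comparison
#'
#' For every bin, builds a distribution of `n_real` subsample means
#' (subsampling `frac` of the bin's events without replacement), then runs
#' the Welch t-test on every bin pair of these mean distributions.
#'
#' @param values_by_bin list of numeric ensembles, one per bin; bins with
#'   fewer than 3 values are skipped (NA rows/columns).
#' @param n_real realizations per bin (default 200).
#' @param frac subsample fraction (default 2/3); subsample size is
#'   rounded half away from zero.
#' @param seed integer seed.
#' @return list with `means` (n_real x nbin matrix) and antisymmetric `t`
#'   plus `p` matrices (diagonal NA).
#' @export
mc_within <- function(values_by_bin, n_real = 200, frac = 2 / 3,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- length(values_by_bin)
  means <- matrix(NA_real_, n_real, nb)
  for (b in seq_len(nb)) {
    v <- values_by_bin[[b]]
    if (length(v) < 3) next
    m <- max(2L, .round_half_away(frac * length(v)))
    means[, b] <- replicate(n_real, mean(sample(v, m)))
  }
  tmat <- matrix(NA_real_, nb, nb)
  pmat <- matrix(NA_real_, nb, nb)
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    if (a == b || anyNA(means[, a]) || anyNA(means[, b])) next
    if (b < a) { tmat[a, b] <- -tmat[b, a]; pmat[a, b] <- pmat[b, a]; next }
    wt <- welch_t(means[, a], means[, b])
    tmat[a, b] <- wt$t; pmat[a, b] <- wt$p
  }
  list(means = means, t = tmat, p = pmat)
}

#' Subsampled geometric-mean event likelihood of a binary ensemble
#'
#' Geometric mean of the event ratio over `n_real` subsample realizations
#' (`frac` of the events, without replacement). Zero ratios are replaced
#' by `1 / (2 * subsample size)` before the log-mean so the geometric mean
#' is informative; an all-zero ensemble returns exactly 0. The plain
#' arithmetic ratio is reported alongside.
#'
#' @param bin_flags 0/1 ensemble (n >= 3).
#' @inheritParams mc_within
#' @return list with `likelihood`, `arith_ratio`, `n`.
#' @export
binomial_likelihood <- function(bin_flags, n_real = 200, frac = 2 / 3,
                                seed = NULL) {
  stopifnot(length(bin_flags) >= 3, all(bin_flags %in% c(0, 1)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(bin_flags)
  if (all(bin_flags == 0))
    return(list(likelihood = 0, arith_ratio = 0, n = n))
  m <- max(2L, .round_half_away(frac * n))
  ratios <- replicate(n_real, mean(sample(bin_flags, m)))
  ratios[ratios == 0] <- 1 / (2 * m)
  list(likelihood = exp(mean(log(ratios))), arith_ratio = mean(bin_flags),
       n = n)
}

#' Pairwise Response Index
#'
#' Mean sign of a bin's pairwise Welch t-values against all other bins:
#' +1 means the bin's response is consistently the largest, -1 the
#' smallest.
#'
#' @param t_matrix antisymmetric t matrix from [mc_within()], or a numeric
#'   vector of one bin's pairwise t-values.
#' @param bin optional bin index; when missing and `t_matrix` is a matrix,
#'   the PRI of every bin is returned.
#' @return numeric PRI value(s) in `[-1, 1]`.
#' @export
pri <- function(t_matrix, bin = NULL) {
  if (is.matrix(t_matrix)) {
    f <- function(row) {
      v <- row[!is.na(row)]
      if (!length(v)) return(NA_real_)
      mean(sign(v))
    }
    if (is.null(bin)) return(apply(t_matrix, 1, f))
    return(f(t_matrix[bin, ]))
  }
  v <- t_matrix[!is.na(t_matrix)]
  mean(sign(v))
}

## Circular-covariate logistic regression -------------------------------------

#' Binomial logistic regression with a circular covariate
#'
#' Fits `outcome ~ lag + cos(phase) + sin(phase)` by maximum likelihood
#' (logit link). Trials with `lag >= max_lag_s` or missing lag are
#' excluded before fitting. The acrophase -- the phase at which the log
#' odds of the outcome peaks -- is `atan2(beta_sin, beta_cos)`.
#'
#' @param outcome 0/1 vector per trial.
#' @param lag numeric, seconds since the previous spindle at click time.
#' @param phase click phase in degrees.
#' @param extra optional data.frame of additional covariates.
#' @param max_lag_s lag inclusion threshold in seconds (default 10).
#' @return object of class `logistic_fit`: coefficient `table`
#'   (Estimate, SE, Wald chi2, df, p, OR and 95% CI), the
#'   model-vs-intercept likelihood-ratio `chi2`/`chi2_df`/`chi2_p`,
#'   `acrophase` in degrees (-90..270), `n`, `converged`.
#' @export
fit_circular_logistic <- function(outcome, lag, phase, extra = NULL,
                                  max_lag_s = 10) {
  keep <- !is.na(lag) & lag < max_lag_s & !is.na(outcome) & !is.na(phase)
  outcome <- outcome[keep]; lag <- lag[keep]; phase <- phase[keep]
  if (length(outcome) < 50)
    stop("need at least 50 trials with lag < ", max_lag_s, " s")
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  df <- data.frame(y = outcome, Lag = lag,
                   Cos = cos(.deg2rad(phase)), Sin = sin(.deg2rad(phase)))
  if (!is.null(extra)) df <- cbind(df, extra[keep, , drop = FALSE])
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15)
  sm <- summary(fit)$coefficients
  beta <- sm[, 1]; se <- sm[, 2]
  wald <- (beta / se)^2
  p <- stats::pchisq(wald, 1, lower.tail = FALSE)
  tab <- data.frame(term = rownames(sm), estimate = beta, se = se,
                    wald_chi2 = wald, df = 1,
                    p = p, odds_ratio = exp(beta),
                    or_lo = exp(beta - 1.96 * se),
                    or_hi = exp(beta + 1.96 * se), row.names = NULL)
  null_fit <- stats::glm(y ~ 1, data = df, family = stats::binomial())
  chi2 <- as.numeric(null_fit$deviance - fit$deviance)
  chi2_df <- length(beta) - 1
  acro <- wrap_deg(.rad2deg(atan2(beta[["Sin"]], beta[["Cos"]])))
  structure(list(table = tab, chi2 = chi2, chi2_df = chi2_df,
                 chi2_p = stats::pchisq(chi2, chi2_df, lower.tail = FALSE),
                 acrophase = acro, n = nrow(df), converged = !sep,
                 fit = fit), class = "logistic_fit")
}

#' Acrophase of sine/cosine regression coefficients
#'
#' @param beta_cos,beta_sin coefficients of the cosine and sine covariates.
#' @return angle in degrees (-90..270 convention) where the linear
#'   predictor is maximal.
#' @export
acrophase <- function(beta_cos, beta_sin) {
  wrap_deg(.rad2deg(atan2(beta_sin, beta_cos)))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binomial logistic regression (logit link), n =", x$n, "\n")
  cat(sprintf("model vs intercept: chi2(%d) = %.2f, p = %.4g\n",
              x$chi2_df, x$chi2, x$chi2_p))
  print(transform(x$table, estimate = round(estimate, 3),
                  se = round(se, 3), wald_chi2 = round(wald_chi2, 2),
                  p = signif(p, 3), odds_ratio = round(odds_ratio, 3),
                  or_lo = round(or_lo, 3), or_hi = round(or_hi, 3)))
  cat(sprintf("acrophase: %.1f deg\n", x$acrophase))
  if (!x$converged) cat("WARNING: possible separation / non-convergence\n")
  invisible(x)
}
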