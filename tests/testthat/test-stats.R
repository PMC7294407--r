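test_that("Welch t matches the hand formulas", {
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(w$df, (5 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2),
               tolerance = 1e-12)
  expect_equal(w$p, 2 * stats::pt(-abs(w$t), w$df))
  # identical samples
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # equal variances / equal n reduce to df = 2n - 2
  set.seed(1)
  x <- stats::rnorm(20)
  y <- x + 1                       # same variance exactly
  expect_equal(welch_t(x, y)$df, 38, tolerance = 1e-9)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("Watson-Williams behaves across regimes and vs permutation oracle", {
  set.seed(7)
  g1 <- c(350, 5, 10, 15, 355, 0, 8, 352, 3, 12)
  # identical groups: F ~ 0, p ~ 1
  ww0 <- watson_williams(list(g1, g1))
  expect_lt(ww0$F, 1e-9)
  expect_gt(ww0$p, 0.999)
  # rotation invariance
  g2 <- g1 + 25
  ww <- watson_williams(list(g1, g2))
  ww_rot <- watson_williams(list(g1 + 30, g2 + 30))
  expect_equal(ww$F, ww_rot$F, tolerance = 1e-9)
  # strongly separated concentrated groups: tiny p, agreeing with a
  # permutation oracle on the F statistic
  set.seed(11)
  a <- (stats::rnorm(20, 0, 10)) %% 360
  b <- (stats::rnorm(20, 90, 10)) %% 360
  wwab <- watson_williams(list(a, b))
  expect_lt(wwab$p, 0.001)
  pooled <- c(a, b)
  perm_f <- replicate(199, {
    idx <- sample(40, 20)
    watson_williams(list(pooled[idx], pooled[-idx]))$F
  })
  p_perm <- (1 + sum(perm_f >= wwab$F)) / 200
  expect_lt(p_perm, 0.01)
  expect_error(watson_williams(list(c(0, 90, 180, 270, 45, 135, 225, 315),
                                    a)),
               "zero resultant")
})

test_that("Benjamini-Yekutieli mask matches the closed form and brute force", {
  expect_equal(fdr_by(c(0.001, 0.01, 0.03, 0.2), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_by(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_equal(fdr_by(0.04, 0.05), TRUE)           # m = 1: p <= q
  expect_equal(fdr_by(0.06, 0.05), FALSE)
  # brute force: the BY rule rejects the k* smallest p where k* is the
  # largest i satisfying the inequality, checked exhaustively
  set.seed(5)
  for (rep in 1:20) {
    m <- sample(2:10, 1)
    p <- round(stats::runif(m)^2, 4)
    q <- 0.1
    cm <- sum(1 / seq_len(m))
    ps <- sort(p)
    ks <- which(ps <= seq_len(m) * q / (m * cm))
    kstar <- if (length(ks)) max(ks) else 0
    brute <- p %in% ps[seq_len(kstar)] & rank(p, ties.method = "first") <= kstar
    expect_equal(fdr_by(p, q), brute)
  }
})

test_that("between-condition Monte Carlo has the stated structure", {
  set.seed(2)
  sham <- stats::rnorm(10, 100, 15)
  stim <- sham + 20
  mc <- mc_between(sham, stim, n_real = 200, seed = 3)
  expect_length(mc$sham_dist, 2000)                # all pairs
  # location-shift identity of pairwise subtraction
  expect_equal(mc$mean_stim - mc$mean_sham, 20, tolerance = 1e-9)
  # null case: difference of mean distances is centred on zero
  diffs <- vapply(1:60, function(s) {
    set.seed(s)
    a <- stats::rnorm(12, 50, 10)
    b <- stats::rnorm(12, 50, 10)
    m <- mc_between(a, b, 200, seed = s + 1000)
    m$mean_stim - m$mean_sham
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
  # degenerate SHAM flagged
  expect_true(mc_between(rep(5, 5), 1:5, seed = 1)$degenerate)
})

test_that("within-condition Monte Carlo t-matrix is antisymmetric with power", {
  v <- stats::rnorm(30)
  mw <- mc_within(list(v, v + 0), n_real = 100, seed = 9)
  expect_true(is.na(mw$t[1, 1]) && is.na(mw$t[2, 2]))
  expect_equal(mw$t[1, 2], -mw$t[2, 1])
  expect_gt(mw$p[1, 2], 0.01)   # identical multisets: no real difference
  # clearly separated bins are detected after BY correction
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    a <- stats::rnorm(30, 0, 1); b <- stats::rnorm(30, 1, 1)
    m <- mc_within(list(a, b), n_real = 100, seed = s + 500)
    fdr_by(m$p[upper.tri(m$p)], 0.05)[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # skipped bins give NA rows
  m3 <- mc_within(list(v, numeric(0), v + 2), n_real = 50, seed = 1)
  expect_true(all(is.na(m3$t[2, ])))
  expect_false(is.na(m3$t[1, 3]))
})

test_that("binomial likelihood concentrates on the event ratio", {
  expect_equal(binomial_likelihood(rep(1, 20), seed = 1)$likelihood, 1)
  expect_equal(binomial_likelihood(rep(0, 20), seed = 1)$likelihood, 0)
  flags <- rep(c(1, 0), c(30, 70))
  liks <- vapply(1:10, function(s)
    binomial_likelihood(flags, n_real = 200, seed = s)$likelihood,
    numeric(1))
  expect_true(all(liks >= 0.25 & liks <= 0.35))
})

test_that("PRI is the mean sign of the pairwise t-values", {
  expect_equal(pri(c(2, -1, 3)), 1 / 3)
  expect_equal(pri(c(5, 4, 0.1)), 1)
  expect_equal(pri(c(-5, -4, -0.1)), -1)
  tm <- matrix(c(NA, 2, 3, -2, NA, 1, -3, -1, NA), 3, 3, byrow = TRUE)
  expect_equal(pri(tm), c(1, 0, -1))
  expect_equal(pri(tm, bin = 1), 1)
  # a stochastically dominant bin converges to PRI = 1
  set.seed(4)
  vals <- c(list(stats::rnorm(40, 3)), lapply(1:6, function(i) stats::rnorm(40)))
  mw <- mc_within(vals, n_real = 100, seed = 12)
  expect_equal(pri(mw$t)[1], 1)
})

test_that("circular mean and CI", {
  cm <- circ_mean_ci(rep(90, 10))
  expect_equal(cm$mean, 90)
  expect_equal(diff(cm$ci), 0, tolerance = 1e-9)
  expect_equal(circ_mean_ci(c(80, 100, 80, 100))$mean, 90)
  # wrap-around mean
  expect_lt(abs(circ_diff(circ_mean_ci(c(350, 10, 355, 5))$mean, 0)), 1e-6)
  # coverage of the von Mises interval (mu = 66, kappa = 4, n = 21)
  set.seed(31)
  cover <- vapply(1:200, function(i) {
    th <- 66 + .rad2deg_test(stats::rnorm(21) / sqrt(4))  # wrapped-normal approx
    ci <- circ_mean_ci(th)$ci
    d_lo <- circ_diff(66, ci[1]); d_hi <- circ_diff(ci[2], 66)
    d_lo >= 0 && d_hi >= 0
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1)
})

test_that("circular logistic regression recovers known coefficients", {
  simfit <- function(seed, beta = c(-0.8, 0, 0.12, 0.18), n = 5000) {
    set.seed(seed)
    lag <- stats::runif(n, 0, 9.9)
    phase <- stats::runif(n, -90, 270)
    eta <- beta[1] + beta[2] * lag + beta[3] * cos(phase * pi / 180) +
      beta[4] * sin(phase * pi / 180)
    y <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
    fit_circular_logistic(y, lag, phase)
  }
  covered <- vapply(1:8, function(s) {
    f <- simfit(s)
    tab <- f$table
    beta <- c(-0.8, 0, 0.12, 0.18)
    all(beta >= tab$estimate - 1.96 * tab$se &
          beta <= tab$estimate + 1.96 * tab$se)
  }, logical(1))
  expect_gte(sum(covered), 6)
  # acrophase identities
  expect_equal(acrophase(0.12, 0.18), atan2(0.18, 0.12) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(acrophase(2 * 0.12, 2 * 0.18), acrophase(0.12, 0.18))
  # uniform phases, constant-ish lag: circular terms vanish within CI
  set.seed(9)
  n <- 2000
  y <- stats::rbinom(n, 1, 0.3)
  f0 <- fit_circular_logistic(y, stats::runif(n, 4, 5),
                              stats::runif(n, -90, 270))
  tab <- f0$table[f0$table$term %in% c("Cos", "Sin"), ]
  expect_true(all(0 >= tab$estimate - 1.96 * tab$se &
                    0 <= tab$estimate + 1.96 * tab$se))
  expect_error(fit_circular_logistic(rep(1, 100), rep(1, 100),
                                     rep(0, 100)), "classes")
})
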