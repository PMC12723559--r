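make_spectrum <- function(freq, power, fs = 500) {
  structure(list(freq = freq, power = power, fs = fs),
            class = "power_spectrum")
}

# pink (1/f amplitude) noise via spectral shaping
make_pink <- function(n, fs, seed) {
  set.seed(seed)
  half <- n %/% 2
  shape <- c(1, 1 / sqrt(seq(fs / n, fs / 2, length.out = half)),
             1 / sqrt(rev(seq(fs / n, fs / 2, length.out = half - 1))))
  p <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE)) / n
  p / stats::sd(p)
}

test_that("Welch PSD of a pure tone obeys Parseval and peaks correctly", {
  fs <- 500
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  A <- 2.5
  ps <- welch_psd(A * sin(2 * pi * 10 * tt), window = 2, fs = fs)
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(df, 0.5)
  expect_equal(sum(ps$power) * df, A^2 / 2, tolerance = 0.01)
  expect_equal(ps$freq[which.max(ps$power)], 10)
})

test_that("a constant signal has all power at the zero bin", {
  ps <- welch_psd(rep(3.3, 2000), window = 2, fs = 500)
  expect_equal(sum(ps$power[ps$freq > 0]), 0, tolerance = 1e-20)
})

test_that("welch_psd is deterministic and validates input length", {
  x <- rnorm(5000)
  a <- welch_psd(x, 2, fs = 500)
  b <- welch_psd(x, 2, fs = 500)
  expect_identical(a$power, b$power)
  expect_error(welch_psd(rnorm(100), 2, fs = 500), "shorter")
})

test_that("spectral parameterization recovers generated aperiodic models", {
  f <- seq(0.5, 100, by = 0.5)
  fit <- parameterize_spectrum(make_spectrum(f, 1e-13 * f^(-1)))
  expect_equal(fit$offset, -13, tolerance = 1e-2)
  expect_equal(fit$exponent, 1, tolerance = 1e-2)
  expect_equal(nrow(fit$peaks), 0)

  # flat spectrum: exponent 0
  flat <- parameterize_spectrum(make_spectrum(f, rep(1e-12, length(f))))
  expect_equal(flat$exponent, 0, tolerance = 1e-3)

  # 1/f plus a 10 Hz Gaussian bump
  logp <- -13 - 1 * log10(f) + 0.6 * exp(-(f - 10)^2 / (2 * 1.5^2))
  fit2 <- parameterize_spectrum(make_spectrum(f, 10^logp))
  expect_equal(nrow(fit2$peaks), 1)
  expect_equal(fit2$peaks$cf[1], 10, tolerance = 0.25)
  expect_equal(fit2$offset, -13, tolerance = 0.05)
  expect_equal(fit2$exponent, 1, tolerance = 0.05)
})

test_that("parameter recovery is accurate across the model family", {
  set.seed(9)
  f <- seq(0.5, 50, by = 0.5)
  err_off <- err_exp <- err_cf <- numeric(0)
  for (i in 1:30) {
    off <- runif(1, -14, -12)
    expn <- runif(1, 0.5, 1.5)
    cf <- runif(1, 8, 12)
    amp <- runif(1, 0.4, 0.8)
    bw <- runif(1, 1.2, 2.5)
    logp <- off - expn * log10(f) + amp * exp(-(f - cf)^2 / (2 * bw^2))
    fit <- parameterize_spectrum(make_spectrum(f, 10^logp))
    err_off <- c(err_off, abs(fit$offset - off))
    err_exp <- c(err_exp, abs(fit$exponent - expn))
    if (nrow(fit$peaks)) err_cf <- c(err_cf, abs(fit$peaks$cf[1] - cf))
  }
  expect_lt(mean(err_off), 0.05)
  expect_lt(mean(err_exp), 0.05)
  expect_gt(length(err_cf), 25)
  expect_lt(mean(err_cf), 0.3)
})

test_that("non-positive power in the fit range is an error", {
  f <- seq(0.5, 50, by = 0.5)
  p <- 1e-13 * f^(-1)
  p[20] <- 0
  expect_error(parameterize_spectrum(make_spectrum(f, p)), "non-positive")
})

test_that("band areas match closed forms and add across shared edges", {
  f <- seq(0.5, 100, by = 0.5)
  expect_equal(band_auc(make_spectrum(f, rep(0, length(f))), c(4, 8)), 0)
  expect_equal(band_auc(make_spectrum(f, rep(1, length(f))), c(4, 8)), 4)
  # 1/f density: integral over 8-12 Hz is ln(12/8) (trapezoid converges)
  f_fine <- seq(1, 50, by = 0.01)
  expect_equal(band_auc(make_spectrum(f_fine, 1 / f_fine), c(8, 12)),
               log(12 / 8), tolerance = 1e-5)

  ps <- make_spectrum(f, 1e-12 * f^(-1.2))
  expect_identical(band_auc(ps, c(4, 12)),
                   band_auc(ps, c(4, 8)) + band_auc(ps, c(8, 12)))
  expect_error(band_auc(ps, c(12, 8)), "increasing")
})

test_that("aperiodic AUC closed form matches quadrature", {
  expect_equal(aperiodic_auc(list(offset = 0, exponent = 0)), 27)
  expect_equal(aperiodic_auc(list(offset = 0, exponent = 1)), log(10))
  set.seed(4)
  for (i in 1:20) {
    off <- runif(1, -14, -11)
    expn <- runif(1, 0, 2.5)
    q <- 10^off * stats::integrate(function(x) x^(-expn), 3, 30,
                                   rel.tol = 1e-13)$value
    a <- aperiodic_auc(list(offset = off, exponent = expn))
    expect_lt(abs(a - q) / q, 1e-9)
  }
  # the exponent = 1 branch agrees with its neighborhood
  near <- aperiodic_auc(list(offset = -13, exponent = 1 + 1e-9))
  at <- aperiodic_auc(list(offset = -13, exponent = 1))
  expect_equal(near, at, tolerance = 1e-6)
})

test_that("a constant trace yields no oscillation events", {
  ev <- detect_events(list(x = rep(1, 4000), fs = 500))
  expect_equal(nrow(ev), 0)
})

test_that("injected alpha bursts are each detected as one alpha event", {
  fs <- 500
  n <- 24 * fs
  for (seed in c(2, 5)) {
    pink <- make_pink(n, fs, seed)
    x <- pink
    for (t0 in c(8, 13)) {
      bi <- (t0 * fs):((t0 + 1) * fs)
      env <- exp(-((seq_along(bi) - length(bi) / 2) / (length(bi) / 5))^2)
      x[bi] <- x[bi] + 10 * sin(2 * pi * 10 * (seq_along(bi) - 1) / fs) * env
    }
    ev <- detect_events(list(x = x, fs = fs))
    alpha <- ev[ev$band == "alpha", ]
    expect_equal(nrow(alpha), 2)
    expect_true(any(alpha$t_stop > 8 & alpha$t_start < 9))
    expect_true(any(alpha$t_stop > 13 & alpha$t_start < 14))
    expect_true(all(alpha$wave_height > 0))
    expect_true(all(alpha$t_stop > alpha$t_start))
  }
})

test_that("pure pink noise yields at most one band event per 24 s", {
  fs <- 500
  n <- 24 * fs
  for (seed in c(3, 7)) {
    ev <- detect_events(list(x = make_pink(n, fs, seed), fs = fs))
    expect_lte(sum(ev$band %in% c("theta", "alpha", "beta")), 1)
  }
})

test_that("feature extraction composes the spectral fits", {
  fs <- 500
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  # band-limited 10 Hz rhythm on top of pink noise
  x <- make_pink(length(tt), fs, 8) + 0.8 * sin(2 * pi * 10 * tt)
  fx <- extract_features(list(x = x, fs = fs))
  expect_true(all(is.finite(fx)))
  expect_equal(unname(fx["peak_cf"]), 10, tolerance = 0.5)
  fx2 <- extract_features(list(x = x, fs = fs))
  expect_identical(fx, fx2)
  # pure noise trace: peak may be absent, other features finite
  fx3 <- extract_features(list(x = make_pink(length(tt), fs, 9), fs = fs))
  expect_true(all(is.finite(fx3[c("offset", "exponent", "aperiodic_auc")])))
})
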