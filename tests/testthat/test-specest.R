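test_that("Slepian tapers are orthonormal with near-unit concentrations", {
  ts <- dpss_tapers(64, 4 / 64, 7)          # NW = 4, K = 7 = 2NW - 1
  G <- ts$tapers %*% t(ts$tapers)
  expect_lt(max(abs(G - diag(7))), 1e-10)
  expect_true(all(diff(ts$concentrations) < 0))
  expect_true(all(ts$concentrations[1:7] > 0.5))
  # concentrations of the first K <= 2NW - 1 tapers computed via the exact
  # Toeplitz sinc quadratic form are >= 0.99 except the last
  expect_true(all(ts$concentrations[1:6] >= 0.99))
  expect_equal(ts$nw, 4)
})

test_that("the first Slepian maximizes spectral concentration (brute-force oracle)", {
  N <- 16; W <- 0.1
  ij <- outer(0:(N - 1), 0:(N - 1), "-")
  S <- sin(2 * pi * W * ij) / (pi * ij)
  diag(S) <- 2 * W
  u_true <- eigen(S, symmetric = TRUE)$vectors[, 1]   # dense concentration solve
  u <- dpss_tapers(N, W, 1)$tapers[1, ]
  expect_gte(abs(sum(u * u_true)), 1 - 1e-6)
  expect_error(dpss_tapers(16, 0.1, 17), "exceeds")
})

test_that("mtmfft satisfies Parseval and recovers the white-noise density", {
  # unit 10 Hz sinusoid, 1 s at 512 Hz: integrated one-sided PSD = variance 0.5
  rd <- make_sine_raw(10, ns = 512, fs = 512)
  fd <- mtmfft(rd, taper = "hann")
  df <- fd$freq[2] - fd$freq[1]
  expect_lt(abs(sum(fd$power) * df - 0.5) / 0.5, 0.02)

  # hann on an integer-period sinusoid: >= 99% of power within +/- 1 bin
  pk <- which.max(fd$power[1, ])
  expect_equal(fd$freq[pk], 10)
  expect_gte(sum(fd$power[1, (pk - 1):(pk + 1)]) / sum(fd$power[1, ]), 0.99)

  # white noise, known variance: flat density sigma^2/(fs/2) away from edges
  rdw <- make_noise_raw(trials = 100, n_channels = 2, ns = 500, fs = 500,
                        sd = 2, seed = 2)
  fw <- mtmfft(rdw, taper = "dpss", smoothing = 4)
  expect_equal(fw$taper_count, 7L)
  interior <- fw$freq > 8 & fw$freq < 242
  dev <- colMeans(fw$power[, interior]) / (4 / 250) - 1
  expect_lt(abs(mean(dev)), 0.01)
  expect_true(all(fw$power >= 0))

  # cross(i,i) equals power(i) exactly (definition)
  fc <- mtmfft(rdw, taper = "hann", output = c("power", "cross"))
  expect_equal(Re(get_cross(fc, 1, 1)), fc$power[1, ])
})

test_that("mtmfft rejects unequal trials, NA samples and out-of-band requests", {
  rd <- make_noise_raw(trials = 2, ns = 400)
  rd$trials[[2]] <- rd$trials[[2]][, 1:300]
  rd$time[[2]] <- rd$time[[2]][1:300]
  expect_error(mtmfft(rd, taper = "hann"), "mtmconvol")
  expect_error(mtmfft(make_noise_raw(), foi = c(10, 400), taper = "hann"),
               "Nyquist")
  expect_error(mtmfft(make_noise_raw(ns = 100), taper = "dpss", smoothing = 2),
               "smoothing")
})

test_that("cross-spectral matrices are positive semi-definite per frequency", {
  rd <- make_noise_raw(trials = 30, n_channels = 4, ns = 256, fs = 256, seed = 9)
  fd <- mtmfft(rd, taper = "dpss", smoothing = 8, output = c("power", "cross"))
  sm <- csd_matrix(fd)
  for (f in seq(1, length(sm$freq), by = 10)) {
    ev <- eigen(sm$S[, , f], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(Re(ev)), -1e-10 * sum(Re(ev)))
  }
})

test_that("doubling the trial count halves the jackknife variance of the PSD", {
  var_of_mean <- function(n, seed) {
    rd <- make_noise_raw(trials = n, n_channels = 1, ns = 256, fs = 256,
                         seed = seed)
    per_trial <- vapply(seq_len(n), function(k) {
      sub <- rd; sub$trials <- rd$trials[k]; sub$time <- rd$time[k]
      mean(mtmfft(sub, foi = c(20, 100), taper = "hann")$power)
    }, numeric(1))
    stats::var(per_trial) / n                 # jackknife variance of the mean
  }
  r <- mean(vapply(1:8, function(s) var_of_mean(40, 100 + s), numeric(1))) /
    mean(vapply(1:8, function(s) var_of_mean(80, 200 + s), numeric(1)))
  expect_gt(r, 1.6)
  expect_lt(r, 2.4)
})

test_that("sliding-window estimates are stationary where the signal is", {
  rd <- make_sine_raw(20, ns = 1000, fs = 500)
  mc <- mtmconvol(rd, toi = seq(0.4, 1.6, 0.1), t_window = 0.5, foi = 20,
                  taper = "hann")
  p <- mc$power[1, 1, ]
  expect_lt(diff(range(p)) / mean(p), 0.03)

  # burst in the second half: power ratio >= 10
  set.seed(12)
  tv <- (0:999) / 500
  x <- c(rnorm(500, sd = 0.1),
         sin(2 * pi * 10 * tv[501:1000] * 500 / 500 * 1) + rnorm(500, sd = 0.1))
  x <- matrix(c(rnorm(500, sd = 0.1), sin(2 * pi * 10 * tv[501:1000]) +
                  rnorm(500, sd = 0.1)), 1)
  rb <- raw_data(list(x), list(tv), "ch1", 500)
  mb <- mtmconvol(rb, toi = c(0.5, 1.5), t_window = 0.4, foi = 10, taper = "hann")
  expect_gte(mb$power[1, 1, 2] / mb$power[1, 1, 1], 10)

  # unsupported time points are missing, not numbers
  mo <- mtmconvol(rb, toi = c(0.05, 1.0), t_window = 0.4, foi = 10, taper = "hann")
  expect_true(is.na(mo$power[1, 1, 1]))
  expect_false(is.na(mo$power[1, 1, 2]))

  # infeasible smoothing for the window errors with the feasible bound
  expect_error(mtmconvol(rb, toi = 1, t_window = 0.2, foi = 10,
                         taper = "dpss", smoothing = 2), "smoothing")
})

test_that("Morlet wavelets localize frequency and match their analytic width", {
  rd <- make_sine_raw(10, ns = 1000, fs = 500)
  wt <- wavelet_tfr(rd, foi = c(5, 10, 20, 30), width = 7)
  mid <- 500
  expect_equal(wt$freq[which.max(wt$power[1, , mid])], 10)

  # peak density agrees with a resolution-matched sliding hann estimate
  sdt <- 7 / (2 * pi * 10)
  mc <- mtmconvol(rd, toi = 1.0, t_window = 3 * sdt * sqrt(pi), foi = 10,
                  taper = "hann")
  expect_lt(abs(wt$power[1, 2, mid] / mc$power[1, 1, 1] - 1), 0.05)

  # impulse response: temporal sd of the amplitude envelope = m/(2 pi f)
  imp <- matrix(0, 1, 1000); imp[500] <- 1
  ri <- raw_data(list(imp), list((0:999) / 500), "ch1", 500)
  wi <- wavelet_tfr(ri, foi = 10, width = 7)
  amp <- sqrt(wi$power[1, 1, ])
  ok <- !is.na(amp)
  tt <- (0:999) / 500
  w <- amp[ok] / sum(amp[ok])
  mu <- sum(w * tt[ok])
  sd_meas <- sqrt(sum(w * (tt[ok] - mu)^2))
  expect_lt(abs(sd_meas - sdt) / sdt, 0.1)

  # two sinusoids: distinct ridges, no spurious mid-frequency power
  rd2 <- make_sine_raw(10, ns = 1000, fs = 500)
  rd2$trials[[1]] <- rd2$trials[[1]] +
    matrix(sin(2 * pi * 30 * (0:999) / 500), 1)
  w2 <- wavelet_tfr(rd2, foi = c(10, 20, 30), width = 7)
  expect_lt(w2$power[1, 2, mid], 0.05 * min(w2$power[1, 1, mid], w2$power[1, 3, mid]))

  # support edges are missing cells
  expect_true(is.na(wt$power[1, 1, 2]))
})
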