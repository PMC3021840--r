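# A pure delay of a bin-frequency sinusoid is periodic, so the delayed copy
# is the same sinusoid with an exact phase shift: coherence magnitude 1 and
# phase 2 pi f tau at that bin, to machine precision.
delayed_pair_raw <- function(f_bin, tau_samples, trials = 12, ns = 256,
                             fs = 256, seed = 1) {
  set.seed(seed)
  tv <- (0:(ns - 1)) / fs
  trl <- lapply(seq_len(trials), function(k) {
    ph <- runif(1, 0, 2 * pi)
    rbind(sin(2 * pi * f_bin * tv + ph),
          sin(2 * pi * f_bin * (tv - tau_samples / fs) + ph))
  })
  raw_data(trl, rep(list(tv), trials), c("x", "y"), fs)
}

test_that("coherence is exact for duplicated and delayed channels", {
  # duplicated channel: magnitude 1 at all frequencies
  rd <- make_noise_raw(trials = 10, n_channels = 1, ns = 256, fs = 256, seed = 3)
  rd2 <- raw_data(lapply(rd$trials, function(tr) rbind(tr, tr)),
                  rd$time, c("a", "b"), 256)
  fd <- mtmfft(rd2, foi = c(8, 100), taper = "hann", output = c("power", "cross"))
  co <- coherence(csd_matrix(fd))
  expect_lt(max(abs(co$values - 1)), 1e-10)

  # delayed bin-frequency sinusoid: |C| = 1, arg C = 2 pi f tau
  # (the bin sits far from its negative-frequency image so taper leakage
  # is below the tolerance)
  dp <- delayed_pair_raw(64, 1)
  fdd <- mtmfft(dp, foi = c(64, 64), taper = "hann", output = c("power", "cross"))
  cc <- coherence(csd_matrix(fdd), form = "complex")
  expect_lt(abs(Mod(cc$values[1, 1]) - 1), 1e-6)
  expect_lt(abs(Arg(cc$values[1, 1]) - 2 * pi * 64 * 1 / 256), 1e-6)

  # magnitude-squared option squares, imaginary is the imaginary part
  cm <- coherence(csd_matrix(fdd))
  cs <- coherence(csd_matrix(fdd), form = "magnitude_squared")
  expect_equal(cs$values, cm$values^2)

  # zero auto-spectrum errors with channel and frequency
  fz <- fdd
  fz$power[2, 1] <- 0
  expect_error(coherence(csd_matrix(fz)), "channel 2")
})

test_that("null coherence bias matches the small-sample scale", {
  rd <- make_noise_raw(trials = 100, n_channels = 2, ns = 256, fs = 256, seed = 14)
  fd <- mtmfft(rd, foi = c(10, 110), taper = "hann", output = c("power", "cross"))
  co <- coherence(csd_matrix(fd))
  expect_lte(mean(co$values), 0.15)      # ~ sqrt(pi/(4 n)) = 0.089 at n = 100
})

test_that("phase locking value separates locked from jittered oscillations", {
  sim <- simulate_oscillation(50, 200, 10, phase_jitter = 0, noise_sd = 0.01,
                              n_channels = 2, seed = 5)
  fd <- mtmfft(sim$data, foi = c(2, 40), taper = "hann",
               output = c("power", "fourier"))
  pl <- plv(fd)
  expect_gte(pl$values[1, which.min(abs(pl$freq - 10))], 1 - 1e-4)

  # independent uniform phases: PLV near sqrt(pi)/(2 sqrt(n))
  ok <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    four <- array(exp(1i * runif(400 * 2 * 3, 0, 2 * pi)), c(400, 2, 3))
    pv <- plv(four)
    if (all(pv$values <= 0.1)) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.9)

  # symmetry under channel exchange is exact by construction
  four <- array(exp(1i * runif(50 * 3 * 2, 0, 2 * pi)), c(50, 3, 2))
  pv <- plv(four)
  expect_equal(nrow(pv$values), 3)       # pairs (1,2),(1,3),(2,3) stored once
  expect_error(plv(array(0i, c(3, 2, 2))), "phase undefined")
})

test_that("phase slope index signs the lead-lag direction", {
  set.seed(31)
  fs <- 256; ns <- 256; tau <- 4
  trl <- lapply(1:20, function(k) {
    x <- stats::filter(rnorm(ns + tau + 50), rep(1 / 3, 3), sides = 1)
    x[is.na(x)] <- 0
    rbind(x[(tau + 51):(tau + 50 + ns)], x[51:(50 + ns)])  # ch2 lags ch1
  })
  rd <- raw_data(trl, rep(list((0:(ns - 1)) / fs), 20), c("x", "y"), fs)
  fd <- mtmfft(rd, foi = c(8, 60), taper = "hann",
               output = c("power", "fourier"))
  ps <- psi(fd, band = c(10, 50))
  expect_gt(ps$psi[1, 2], 0)                       # x leads y
  expect_equal(ps$psi[1, 2], -ps$psi[2, 1])        # antisymmetry exact
  expect_equal(ps$psi[1, 1], 0)
  expect_gt(ps$psi_norm[1, 2], 2)
  expect_error(psi(fd, band = c(10, 11)), "3 adjacent")
})

test_that("normalized PSI is calibrated on independent signals", {
  inside <- 0
  n_runs <- 60
  for (s in 1:n_runs) {
    rd <- make_noise_raw(trials = 30, n_channels = 2, ns = 128, fs = 128,
                         seed = 800 + s)
    fd <- mtmfft(rd, foi = c(8, 60), taper = "hann",
                 output = c("power", "fourier"))
    ps <- psi(fd, band = c(10, 50))
    if (abs(ps$psi_norm[1, 2]) <= 2) inside <- inside + 1
  }
  expect_gte(inside / n_runs, 0.9)
})

test_that("MVAR least squares recovers known coefficients and noise", {
  A1 <- matrix(c(0.55, 0, 0.5, 0.55), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.8, 0, 0, -0.8), 2, 2, byrow = TRUE)
  m0 <- mvar_model(list(A1, A2), diag(2), 200)
  expect_true(m0$stable)
  d <- simulate_mvar(m0, trials = 100, samples = 500, seed = 7)
  mf <- fit_mvar(d, 2)
  expect_lte(max(abs(mf$A[[1]] - A1)), 0.05)
  expect_lte(max(abs(mf$A[[2]] - A2)), 0.05)
  expect_true(mf$stable)

  # white noise: coefficients ~ 0, Sigma ~ sample covariance
  dw <- make_noise_raw(trials = 20, n_channels = 2, ns = 1000, seed = 41)
  mw <- fit_mvar(dw, 1)
  expect_lte(max(abs(mw$A[[1]])), 0.05)
  X <- do.call(cbind, lapply(dw$trials, function(tr) tr - rowMeans(tr)))
  expect_lt(max(abs(mw$noise_cov - tcrossprod(X) / ncol(X))) /
              max(abs(mw$noise_cov)), 0.02)

  # deterministic (noiseless) extension is ill-posed
  det_tr <- matrix(0, 2, 300)
  det_tr[, 1] <- c(1, 0.5)
  for (t in 2:300) det_tr[, t] <- A1 %*% det_tr[, t - 1] * 0 # decays to 0
  rd_det <- raw_data(list(det_tr), list((0:299) / 200), c("a", "b"), 200)
  expect_error(fit_mvar(rd_det, 1), "singular|degenerate")
})

test_that("MVAR spectra match the AR(1) closed form and are Hermitian PSD", {
  m1 <- mvar_model(list(matrix(0.5, 1, 1)), matrix(2, 1, 1), 100)
  fr <- c(0, 10, 25, 50)
  sp <- mvar_spectra(m1, fr)
  closed <- 2 / 100 / Mod(1 - 0.5 * exp(-2i * pi * fr / 100))^2
  expect_lt(max(abs(Re(sp$S[1, 1, ]) - closed)), 1e-10)

  # zero coefficients: flat spectrum Sigma/fs
  mz <- mvar_model(list(matrix(0, 2, 2)), diag(c(1, 3)), 100)
  sz <- mvar_spectra(mz, fr)
  for (f in seq_along(fr))
    expect_equal(Re(sz$S[, , f]), diag(c(1, 3)) / 100)

  # S(f) Hermitian positive semi-definite at every frequency
  A1 <- matrix(c(0.55, 0, 0.5, 0.55), 2, 2, byrow = TRUE)
  m2 <- mvar_model(list(A1), diag(2), 200)
  s2 <- mvar_spectra(m2, seq(5, 95, 10))
  for (f in seq_along(s2$freq)) {
    M <- s2$S[, , f]
    expect_lt(max(Mod(M - Conj(t(M)))), 1e-12)
    expect_gte(min(Re(eigen(M, symmetric = TRUE, only.values = TRUE)$values)),
               -1e-12)
  }
})

test_that("PDC and DTF normalize exactly and recover coupling direction", {
  A1 <- matrix(c(0.55, 0, 0.5, 0.55), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.8, 0, 0, -0.8), 2, 2, byrow = TRUE)
  d <- simulate_mvar(mvar_model(list(A1, A2), diag(2), 200), 100, 500, seed = 7)
  mf <- fit_mvar(d, 2)
  pd <- pdc_dtf(mvar_spectra(mf, seq(1, 99, 2)))
  expect_true(all(pd$pdc >= 0 & pd$pdc <= 1))
  expect_true(all(pd$dtf >= 0 & pd$dtf <= 1))
  expect_lt(max(abs(apply(pd$pdc^2, c(2, 3), sum) - 1)), 1e-12)
  expect_lt(max(abs(apply(pd$dtf^2, c(1, 3), sum) - 1)), 1e-12)
  expect_gte(mean(pd$pdc[2, 1, ]), 5 * mean(pd$pdc[1, 2, ]))
  expect_gte(mean(pd$dtf[2, 1, ]), 5 * mean(pd$dtf[1, 2, ]))

  # diagonal (uncoupled) model: zero off-diagonal PDC and DTF
  md <- mvar_model(list(diag(c(0.5, -0.3))), diag(2), 100)
  pdd <- pdc_dtf(mvar_spectra(md, c(10, 30)))
  expect_equal(max(abs(pdd$pdc[1, 2, ]), abs(pdd$pdc[2, 1, ])), 0)
  expect_equal(max(abs(pdd$dtf[1, 2, ]), abs(pdd$dtf[2, 1, ])), 0)
})

test_that("spectral Granger causality is directed and integrates to Geweke's measure", {
  A1 <- matrix(c(0.55, 0, 0.5, 0.55), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.8, 0, 0, -0.8), 2, 2, byrow = TRUE)
  d <- simulate_mvar(mvar_model(list(A1, A2), diag(2), 200), 100, 500, seed = 7)
  mf <- fit_mvar(d, 2)
  freqs <- seq(0, 100, length.out = 64)
  g <- granger_spectral(mvar_spectra(mf, freqs))
  expect_true(all(g$gc >= 0))
  expect_gte(mean(g$gc[2, 1, ]), 10 * mean(g$gc[1, 2, ]))

  # no coupling (H_xy = 0): exactly zero
  md <- mvar_model(list(diag(c(0.5, -0.3))), diag(2), 100)
  gd <- granger_spectral(mvar_spectra(md, c(10, 30)))
  expect_equal(max(gd$gc), 0)

  # frequency average ~ time-domain Geweke log variance ratio from explicit
  # restricted/full regressions (independent oracle)
  p <- 2
  mkX <- function(M, chs) {
    n <- ncol(M)
    Reduce(cbind, lapply(1:p, function(k) t(M[chs, (p + 1 - k):(n - k), drop = FALSE])))
  }
  Y <- c(); Xf <- list(); Xr <- list()
  for (tr in d$trials) {
    tr <- tr - rowMeans(tr); n <- ncol(tr)
    Y <- c(Y, tr[2, (p + 1):n])
    Xf[[length(Xf) + 1]] <- mkX(tr, 1:2)
    Xr[[length(Xr) + 1]] <- mkX(tr, 2)
  }
  rf <- resid(lm.fit(do.call(rbind, Xf), Y))
  rr <- resid(lm.fit(do.call(rbind, Xr), Y))
  geweke_td <- log(var(rr) / var(rf))
  expect_lt(abs(mean(g$gc[2, 1, ]) - geweke_td) / geweke_td, 0.1)

  # >2 channels go through pairwise refits
  d3 <- make_noise_raw(trials = 10, n_channels = 3, ns = 500, seed = 77)
  g3 <- granger_pairwise(d3, 2, c(20, 60))
  expect_equal(dim(g3), c(3, 3, 2))
  expect_true(all(g3 >= 0))
  expect_error(granger_spectral(mvar_spectra(fit_mvar(d3, 1), 10)), "bivariate")
})

test_that("connectivity metrics are invariant to per-channel rescaling", {
  dp <- delayed_pair_raw(16, 4, seed = 5)
  sc <- dp
  sc$trials <- lapply(sc$trials, function(tr) tr * c(3, 0.2))
  f1 <- mtmfft(dp, foi = c(8, 100), taper = "hann", output = c("power", "cross", "fourier"))
  f2 <- mtmfft(sc, foi = c(8, 100), taper = "hann", output = c("power", "cross", "fourier"))
  expect_equal(coherence(csd_matrix(f1))$values,
               coherence(csd_matrix(f2))$values, tolerance = 1e-10)
  expect_equal(plv(f1)$values, plv(f2)$values, tolerance = 1e-10)
})
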