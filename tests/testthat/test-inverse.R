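# Closed-loop reconstructions: simulate through the package's own forward
# model, invert, compare against the known source.

sens64 <- default_meg_sensors(64)
sphere <- sphere_model(radii = 0.1)
true_pos <- c(0.025, 0.015, 0.055)
true_mom <- c(1e-8, -5e-9, 3e-9)

coarse_grid <- make_grid(c(-0.06, -0.06, 0.01), c(0.06, 0.06, 0.08), 0.02)
coarse_lfg <- leadfield_grid(coarse_grid, sens64, sphere)

simulate_dipole_trials <- function(noise_frac, trials, seed,
                                   pos = true_pos, mom = true_mom) {
  lf <- meg_single_sphere(pos, sens64, sphere)
  rms <- sqrt(mean((lf$gain %*% mom)^2)) * sqrt(0.5)
  rec <- sim_recipe(sens64, sphere,
                    list(list(position = pos, moment = mom,
                              timecourse = list(type = "sine", freq = 11))),
                    noise_sd = rms * noise_frac, trials = trials,
                    sample_rate = 250, trial_length = 1, seed = seed)
  simulate_raw(rec)
}

test_that("a noiseless dipole is recovered to sub-millimeter accuracy", {
  sim <- simulate_dipole_trials(0, 1, seed = 21)
  X <- sim$data$trials[[1]]
  fit <- fit_dipole(X, sens64, sphere, 1, coarse_lfg)
  expect_lt(sqrt(sum((fit$positions - true_pos)^2)), 1e-3)
  expect_lt(fit$residual_variance, 1e-10)
  expect_true(fit$converged)
  # refinement can only improve on the grid scan
  gs_rv <- {
    L <- meg_single_sphere(fit$grid_scan_best[1, ], sens64, sphere)$gain
    sum((X - L %*% (meegflow:::pinv_mat(L) %*% X))^2) / sum(X^2)
  }
  expect_lte(fit$residual_variance, gs_rv + 1e-15)

  expect_error(fit_dipole(matrix(0, 64, 5), sens64, sphere, 1, coarse_lfg),
               "zero")
})

test_that("dipole fitting tolerates sensor noise (median over seeds)", {
  errs <- vapply(1:5, function(s) {
    sim <- simulate_dipole_trials(0.1, 1, seed = 500 + s)
    fit <- fit_dipole(sim$data$trials[[1]], sens64, sphere, 1, coarse_lfg)
    sqrt(sum((fit$positions - true_pos)^2))
  }, numeric(1))
  expect_lt(median(errs), 5e-3)
})

test_that("minimum-norm estimates fit the data and shrink with regularization", {
  sim <- simulate_dipole_trials(0, 1, seed = 23)
  X <- sim$data$trials[[1]]
  # small lambda: fitted data reproduce the measurements (rowspace identity)
  mn <- minimum_norm(coarse_lfg, X, lambda = 1e-6 * sqrt(mean(X^2)))
  L <- do.call(cbind, lapply(coarse_lfg$leadfields[coarse_lfg$inside],
                             function(x) x$gain))
  expect_lt(max(abs(L %*% mn$moments - X)) / max(abs(X)), 1e-6)

  # estimates shrink monotonically as lambda doubles (lambda on the scale
  # of the Gram matrix so the prior actually bites)
  lam0 <- sqrt(sum(diag(L %*% t(L))) / nrow(L))
  nrm <- vapply(lam0 * 2^(-2:4), function(l)
    sqrt(sum(minimum_norm(coarse_lfg, X, lambda = l)$moments^2)), numeric(1))
  expect_true(all(diff(nrm) < 0))

  # lambda = 0 with a rank-deficient Gram matrix (2 sources, 64 channels)
  tiny <- leadfield_grid(rbind(c(0.02, 0, 0.05), c(-0.02, 0, 0.05)),
                         sens64, sphere)
  expect_error(minimum_norm(tiny, X, lambda = 0), "regulari")
})

test_that("depth-weighted minimum norm resolves two well-separated sources", {
  p1 <- c(0.03, 0.01, 0.05); p2 <- c(-0.03, -0.01, 0.03)
  lf1 <- meg_single_sphere(p1, sens64, sphere)
  lf2 <- meg_single_sphere(p2, sens64, sphere)
  set.seed(61)
  tv <- (0:199) / 200
  s1 <- sin(2 * pi * 9 * tv); s2 <- sin(2 * pi * 17 * tv)
  X <- lf1$gain %*% true_mom %*% matrix(s1, 1) +
    lf2$gain %*% c(0, 1e-8, -4e-9) %*% matrix(s2, 1)
  X <- X + matrix(rnorm(length(X), sd = 0.05 * sd(X)), nrow(X))
  mn <- minimum_norm(coarse_lfg, X, lambda = 0.1 * sqrt(mean(X^2)),
                     depth_weight = 1)
  ins <- coarse_lfg$positions[coarse_lfg$inside, , drop = FALSE]
  d1 <- sqrt(colSums((t(ins) - p1)^2))
  d2 <- sqrt(colSums((t(ins) - p2)^2))
  step <- 0.02 * sqrt(3) + 1e-9
  # a top-value point within one grid step of each source
  top <- order(mn$values, decreasing = TRUE)[1:6]
  expect_true(any(d1[top] <= step))
  expect_true(any(d2[top] <= step))
})

test_that("LCMV localizes an oscillatory source and is flat on noise", {
  sim <- simulate_dipole_trials(0.1, 10, seed = 22)
  Xall <- do.call(cbind, sim$data$trials)
  C <- tcrossprod(Xall - rowMeans(Xall)) / (ncol(Xall) - 1)
  lc <- lcmv(coarse_lfg, C, lambda_reg = 0.05)
  ins <- coarse_lfg$positions[coarse_lfg$inside, , drop = FALSE]
  pk <- ins[which.max(lc$values), ]
  expect_lte(sqrt(sum((pk - true_pos)^2)), 0.02 * sqrt(3) + 1e-9)

  # beamformer map invariant (up to scale) to scaling the data
  lc2 <- lcmv(coarse_lfg, C * 25, lambda_reg = 0.05)
  expect_equal(lc2$nai, lc$nai, tolerance = 1e-8)
  expect_equal(lc2$power / lc$power, rep(25, length(lc$power)), tolerance = 1e-8)

  # pure sensor noise: NAI ~ 1 everywhere
  set.seed(33)
  Xn <- matrix(rnorm(64 * 2500), 64)
  lcn <- lcmv(coarse_lfg, tcrossprod(Xn) / 2499, 0.05)
  expect_lte(max(lcn$values, na.rm = TRUE) / min(lcn$values, na.rm = TRUE), 1.5)
})

test_that("the beamformer weights satisfy unit gain where lead fields are full rank", {
  # EEG concentric-sphere lead fields have rank 3, so W L = I exactly;
  # (MEG sphere lead fields are rank 2 - radial silence - and use the
  # truncated inverse, which the singular flag records)
  emod <- sphere_model(radii = c(0.088, 0.094, 0.1),
                       conductivities = c(0.33, 0.0042, 0.33))
  esens <- sensor_array("eeg", default_meg_sensors(32, 0.1)$positions)
  eg <- leadfield_grid(rbind(c(0.02, 0, 0.04), c(-0.03, 0.01, 0.03)),
                       esens, emod)
  set.seed(4)
  Xe <- matrix(rnorm(32 * 500), 32)
  lce <- lcmv(eg, tcrossprod(Xe) / 499, 0.05)
  expect_false(any(lce$singular))
  for (k in 1:2) {
    expect_lt(max(abs(lce$weights[[k]] %*% eg$leadfields[[k]]$gain - diag(3))),
              1e-8)
  }

  meg_lc <- lcmv(coarse_lfg, diag(64), 0.05)
  expect_true(all(meg_lc$singular))       # rank-2 physics, flagged
})

test_that("DICS matches LCMV on a real CSD and maps a coherent source pair", {
  p1 <- c(0.03, 0, 0.05); p2 <- c(-0.03, 0.01, 0.04)
  lf1 <- meg_single_sphere(p1, sens64, sphere)
  lf2 <- meg_single_sphere(p2, sens64, sphere)
  m1 <- c(1e-8, 0, 0); m2 <- c(0, 1e-8, 0)
  rms <- sqrt(mean((lf1$gain %*% m1)^2))
  fs <- 250; tv <- (0:249) / fs
  set.seed(8)
  trials <- lapply(1:40, function(k) {
    ph <- runif(1, 0, 2 * pi)
    dph <- rnorm(1, 0.6, 1.0)             # partially coherent pair
    lf1$gain %*% m1 %*% matrix(sin(2 * pi * 20 * tv + ph), 1) +
      lf2$gain %*% m2 %*% matrix(sin(2 * pi * 20 * tv + ph - dph), 1) +
      matrix(rnorm(64 * 250, sd = rms / 5), 64)
  })
  rd <- raw_data(trials, rep(list(tv), 40), sens64$labels, fs)
  fd <- mtmfft(rd, foi = c(18, 22), taper = "hann", output = c("power", "cross"))
  sm <- csd_matrix(fd)
  csd <- sm$S[, , which.min(abs(sm$freq - 20))]

  grid <- make_grid(c(-0.06, -0.06, 0.01), c(0.06, 0.06, 0.08), 0.01)
  lfg <- leadfield_grid(grid, sens64, sphere)
  dc <- dics(lfg, csd, 0.05)
  ins <- lfg$positions[lfg$inside, , drop = FALSE]
  d1 <- sqrt(colSums((t(ins) - p1)^2))
  d2 <- sqrt(colSums((t(ins) - p2)^2))
  rk <- rank(-dc$nai)
  expect_lte(min(rk[d1 < 0.011]), 3)      # both sources among the top peaks
  expect_lte(min(rk[d2 < 0.011]), 3)

  # real-valued CSD reduces DICS power to LCMV power on the same matrix
  lcv <- lcmv(lfg, Re(csd), 0.05)
  dcv <- dics(lfg, Re(csd) + 0i, 0.05)
  expect_rel_equal(dcv$power, lcv$power, 1e-10)

  # source-reference coherence highlights the coupled position; weaker
  # regularization keeps the spatial filter sharp enough that leakage does
  # not inflate the uncoupled floor
  dcc <- dics(lfg, csd, 0.01, ref_pos = p1, sensors = sens64, model = sphere)
  coupled <- max(dcc$coherence[d2 < 0.011])
  floor_coh <- median(dcc$coherence[d1 > 0.02 & d2 > 0.02], na.rm = TRUE)
  expect_gte(coupled, 3 * floor_coh)

  expect_error(dics(lfg, csd + matrix(0.1, 64, 64) * 1i, 0.05), "Hermitian")
})
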