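test_that("injected SQUID-jump steps are detected and padded segments merge", {
  sim <- simulate_oscillation(10, 500, 10, amplitude = 0, noise_sd = 1,
                              n_channels = 4, trial_length = 2, seed = 101)
  inj <- inject_artifacts(sim$data, "jump", count = 3, magnitude = 20, seed = 201)
  seg <- detect_artifacts_z(inj$data, "jump", z_threshold = 10, pad_s = 0.1)
  for (r in seq_len(nrow(inj$truth))) {
    expect_true(any(seg$trial_index == inj$truth$trial[r] &
                      seg$begin_sample <= inj$truth$sample[r] &
                      seg$end_sample > inj$truth$sample[r]))
  }
  expect_true(all(seg$peak_z >= 10))

  # two jumps 50 ms apart merge into one segment under 0.1 s padding
  sim1 <- simulate_oscillation(1, 500, 10, amplitude = 0, noise_sd = 1,
                               n_channels = 2, trial_length = 2, seed = 7)
  d <- sim1$data
  d$trials[[1]][1, 400:1000] <- d$trials[[1]][1, 400:1000] + 30
  d$trials[[1]][1, 425:1000] <- d$trials[[1]][1, 425:1000] + 30
  expect_equal(nrow(detect_artifacts_z(d, "jump", 10, pad_s = 0.1)), 1)
})

test_that("detection is invariant under global rescaling", {
  sim <- simulate_oscillation(5, 500, 10, amplitude = 0, noise_sd = 1,
                              n_channels = 3, trial_length = 2, seed = 55)
  d <- sim$data
  d$trials[[2]][2, 500:1000] <- d$trials[[2]][2, 500:1000] + 25
  seg <- detect_artifacts_z(d, "jump", 10, 0.1)
  d2 <- d
  d2$trials <- lapply(d$trials, function(x) x * 1e6)
  seg2 <- detect_artifacts_z(d2, "jump", 10, 0.1)
  expect_equal(seg[, 1:3], seg2[, 1:3])
  expect_gte(nrow(seg), 1)
})

test_that("pure noise rarely trips the detector at z = 10", {
  hits <- 0
  for (s in 1:25) {
    sim <- simulate_oscillation(10, 500, 10, amplitude = 0, noise_sd = 1,
                                n_channels = 4, trial_length = 2, seed = 300 + s)
    if (nrow(detect_artifacts_z(sim$data, "jump", 10, 0.1)) > 0) hits <- hits + 1
  }
  expect_lte(hits / 25, 0.12)
})

test_that("muscle transform requires an adequate sampling rate", {
  sim <- simulate_oscillation(2, 200, 10, noise_sd = 1, n_channels = 2, seed = 3)
  expect_error(detect_artifacts_z(sim$data, "muscle", 10), "220")
})

test_that("segment rejection removes trials or marks samples", {
  sim <- simulate_oscillation(5, 200, 10, noise_sd = 1, n_channels = 2, seed = 3)
  segs <- data.frame(trial_index = 3L, begin_sample = 10L, end_sample = 20L,
                     peak_z = 12)
  rt <- reject_segments(sim$data, segs, "remove_trial")
  expect_length(rt$trials, 4)
  expect_match(rt$provenance$step_name, "reject_segments")

  nf <- reject_segments(sim$data, segs, "nan_fill")
  expect_equal(sum(is.na(nf$trials[[3]])), 2 * 10)
  expect_error(mtmfft(nf, taper = "hann"), "excluded")

  none <- reject_segments(sim$data, segs[0, ], "remove_trial")
  expect_identical(none$trials, sim$data$trials)
})

test_that("PCA finds rank structure and satisfies Eckart-Young", {
  # rank-1 construction
  set.seed(21)
  a <- rnorm(16)
  s <- sin(2 * pi * 5 * (0:999) / 500)
  r1 <- raw_data(list(a %o% s + matrix(rnorm(16000, sd = 1e-4), 16)),
                 list((0:999) / 500), sprintf("c%d", 1:16), 500)
  d1 <- pca_decompose(r1)
  expect_gte(d1$explained_variance[1], 0.999)
  expect_true(all(diff(d1$explained_variance) <= 1e-12))
  expect_lt(sum(d1$explained_variance), 1 + 1e-10)

  # unmixing . mixing = identity; timecourses decorrelated
  rd <- make_noise_raw(n_channels = 8, trials = 6, seed = 22)
  dec <- pca_decompose(rd)
  expect_lt(max(abs(dec$unmixing %*% dec$mixing - diag(8))), 1e-8)
  tc <- do.call(cbind, dec$timecourses)
  cc <- cor(t(tc))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)   # demeaning-free timecourses

  # reconstruction error with k components = sum of discarded eigenvalues
  demeaned <- lapply(rd$trials, function(tr) tr - rowMeans(tr))
  X <- do.call(cbind, demeaned)
  k <- 3
  recon <- dec$mixing[, 1:k] %*% (t(dec$mixing[, 1:k]) %*% X)
  errv <- sum((X - recon)^2) / (ncol(X) - 1)
  expect_lt(abs(errv - sum(dec$eigenvalues[(k + 1):8])) / errv, 1e-8)

  # isotropic noise: equal variance shares
  big <- make_noise_raw(n_channels = 8, trials = 20, ns = 2000, seed = 23)
  ev <- pca_decompose(big)$explained_variance
  expect_true(all(abs(ev - 1 / 8) < 3 * sd(ev)))

  # requesting more components than rank errors with the rank
  expect_error(pca_decompose(r1, 17), "17")
  rank_def <- raw_data(list(rbind(s, s, rnorm(1000))), list((0:999) / 500),
                       c("a", "b", "c"), 500)
  expect_error(pca_decompose(rank_def, 3), "rank is 2")
})

test_that("component removal is exact at the extremes and removes a blink", {
  sens <- default_meg_sensors(64)
  lfb <- meg_single_sphere(c(0.02, -0.05, 0.04), sens, sphere_model(radii = 0.1))
  a <- as.numeric(lfb$gain %*% c(1e-8, 0, 0))
  topo <- exp(-rowSums(sweep(sens$positions, 2, c(0, 0.09, 0.04))^2) / 0.06^2)
  th <- topo / sqrt(sum(topo^2))
  a <- a - sum(a * th) * th        # brain pattern orthogonal to the blink
  fs <- 250; tv <- (0:249) / fs
  set.seed(31)
  brms0 <- sqrt(mean((a %o% sin(2 * pi * 10 * tv))^2))
  trials <- lapply(1:10, function(k)
    a %o% sin(2 * pi * 10 * tv + runif(1, 0, 2 * pi)) +
      matrix(rnorm(64 * 250, sd = 0.05 * brms0), 64))
  brain <- raw_data(trials, rep(list(tv), 10),
                    channel_info(sens$labels, sens$positions, "meg_mag", "T"), fs)
  brms <- sqrt(mean(do.call(cbind, brain$trials)^2))
  inj <- inject_artifacts(brain, "blink", count = 6, magnitude = 60 * brms,
                          seed = 32)
  dec <- pca_decompose(inj$data)

  # identity / annihilation
  keep <- remove_components(inj$data, dec, integer(0))
  expect_identical(keep$trials, inj$data$trials)
  full <- remove_components(inj$data, dec, 1:64)
  expect_lt(max(abs(do.call(cbind, full$trials))),
            1e-10 * max(abs(do.call(cbind, inj$data$trials))))

  # the blink topography is captured by one component and removed
  cs <- abs(apply(dec$mixing, 2, function(v)
    sum(v * inj$topography) / sqrt(sum(v^2) * sum(inj$topography^2))))
  expect_gt(max(cs), 0.95)
  blinkdat <- do.call(cbind, inj$data$trials) - do.call(cbind, brain$trials)
  pc <- dec$mixing[, which.max(cs)]
  expect_gte(sum((pc %*% blinkdat)^2) / sum(blinkdat^2), 0.99)
  cleaned <- remove_components(inj$data, dec, which.max(cs))
  resid <- do.call(cbind, cleaned$trials) - do.call(cbind, brain$trials)
  expect_lte(sqrt(mean(resid^2)) / brms, 0.05)
})
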