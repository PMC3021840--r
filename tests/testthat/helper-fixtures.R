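# Shared fixture builders; everything is generated in code at test time.

make_noise_raw <- function(trials = 5, n_channels = 4, ns = 500, fs = 500,
                           sd = 1, seed = 1) {
  set.seed(seed)
  tvec <- (0:(ns - 1)) / fs
  trl <- lapply(seq_len(trials), function(k)
    matrix(rnorm(n_channels * ns, sd = sd), n_channels, ns))
  raw_data(trl, rep(list(tvec), trials),
           sprintf("ch%02d", seq_len(n_channels)), fs)
}

make_sine_raw <- function(freq, trials = 1, ns = 500, fs = 500, amp = 1,
                          n_channels = 1, noise_sd = 0, seed = 1) {
  set.seed(seed)
  tvec <- (0:(ns - 1)) / fs
  trl <- lapply(seq_len(trials), function(k) {
    sig <- amp * sin(2 * pi * freq * tvec)
    matrix(rep(sig, each = n_channels), n_channels, ns) +
      if (noise_sd > 0) matrix(rnorm(n_channels * ns, sd = noise_sd),
                               n_channels, ns) else 0
  })
  raw_data(trl, rep(list(tvec), trials),
           sprintf("ch%02d", seq_len(n_channels)), fs)
}

chain_positions <- function(n, spacing = 0.04) {
  cbind(seq_len(n) * spacing, 0, 0)
}

# uniform spherical quadrature: Gauss-Legendre in cos(theta) x uniform phi
sphere_quadrature <- function(n_theta = 48, n_phi = 96, radius = 1) {
  # Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
  k <- seq_len(n_theta - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n_theta)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  eg <- eigen(J, symmetric = TRUE)
  x <- eg$values
  w <- 2 * eg$vectors[1, ]^2
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  pts <- do.call(rbind, lapply(seq_len(n_theta), function(i) {
    st <- sqrt(1 - x[i]^2)
    cbind(st * cos(phi), st * sin(phi), x[i])
  }))
  wts <- rep(w / n_phi, each = n_phi) / 2   # normalized surface measure
  list(points = pts * radius, weights = wts)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
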