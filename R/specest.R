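# Nonparametric spectral estimation: discrete prolate spheroidal (Slepian)
# tapers, multitaper FFT spectra and cross-spectra, sliding-window
# time-frequency estimates, and Morlet wavelets.  All spectra are one-sided
# densities (unit^2/Hz): scale 2 / (fs * sum(taper^2)) per coefficient,
# without doubling at DC and Nyquist.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the classical symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences: diagonal
#' `((N-1-2t)/2)^2 cos(2 pi W)` for t = 0..N-1 and off-diagonal
#' `t (N - t) / 2`.  The K eigenvectors of largest eigenvalue are returned,
#' orthonormal, with polarity fixed so that each taper's mean (for
#' antisymmetric tapers: its first lobe) is positive.  The spectral
#' concentration of each taper in the band [-W, W] is evaluated exactly via
#' the sinc-kernel Toeplitz quadratic form.
#'
#' @param window_length N, samples.
#' @param half_bandwidth W in cycles/sample (0 < W < 0.5).  The time
#'   half-bandwidth product is NW = N * W.
#' @param taper_count K; K <= 2 N W - 1 recommended for concentrations
#'   near 1.
#' @return list of class `taper_set`: tapers (K x N, orthonormal rows),
#'   concentrations (in (0,1), decreasing), nw.
#' @export
dpss_tapers <- function(window_length, half_bandwidth, taper_count) {
  N <- as.integer(window_length)
  W <- half_bandwidth
  K <- as.integer(taper_count)
  stopifnot(W > 0, W < 0.5, K >= 1)
  if (K > N) stop("taper_count exceeds window length")
  t0 <- 0:(N - 1)
  dg <- ((N - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  od <- (1:(N - 1)) * (N - (1:(N - 1))) / 2
  M <- diag(dg)
  M[cbind(1:(N - 1), 2:N)] <- od
  M[cbind(2:N, 1:(N - 1))] <- od
  eg <- eigen(M, symmetric = TRUE)
  tap <- t(eg$vectors[, seq_len(K), drop = FALSE])   # K x N, orthonormal
  # polarity convention
  for (k in seq_len(K)) {
    s <- sum(tap[k, ])
    if (abs(s) < 1e-8) s <- sum(tap[k, seq_len(ceiling(N / 2))])
    if (s < 0) tap[k, ] <- -tap[k, ]
  }
  # exact in-band concentration via the Toeplitz sinc kernel
  ij <- outer(t0, t0, "-")
  S <- sin(2 * pi * W * ij) / (pi * ij)
  diag(S) <- 2 * W
  conc <- vapply(seq_len(K), function(k) {
    u <- tap[k, ]
    drop(u %*% S %*% u)
  }, numeric(1))
  structure(list(tapers = tap, concentrations = conc, nw = N * W),
            class = "taper_set")
}

hann_taper <- function(N) {
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(N) / (N + 1))
  matrix(h, nrow = 1)
}

check_no_na <- function(data) {
  if (any(vapply(data$trials, anyNA, logical(1))))
    stop("data contain excluded (NA) samples; remove affected trials first")
}

taper_matrix <- function(N, taper, smoothing, sample_rate) {
  if (identical(taper, "hann")) return(hann_taper(N))
  T_s <- N / sample_rate
  K <- floor(2 * smoothing * T_s) - 1
  if (K < 1)
    stop(sprintf(paste0("smoothing %g Hz gives no taper for a %.3g s window; ",
                        "need smoothing >= %.3g Hz"),
                 smoothing, T_s, 1 / T_s))
  dpss_tapers(N, smoothing / sample_rate, K)$tapers
}

#' Multitaper FFT spectrum
#'
#' Per trial and taper the data are demeaned, tapered, Fourier transformed
#' and reduced to the requested frequency bins; power and (optionally)
#' cross-spectra are averaged over tapers and trials.  One-sided density
#' scaling (unit^2/Hz).
#'
#' @param data `meeg_raw`, all trials of equal length.
#' @param foi frequency band `c(fmin, fmax)` in Hz (bins inside are kept).
#' @param taper "dpss" (with `smoothing`) or "hann".
#' @param smoothing spectral half-bandwidth in Hz for dpss (K =
#'   floor(2 * smoothing * T) - 1 tapers).
#' @param output any of "power", "cross", "fourier"; power is always
#'   computed.
#' @return `meeg_freq`.
#' @export
mtmfft <- function(data, foi = NULL, taper = "dpss", smoothing = 4,
                   output = "power") {
  stopifnot(inherits(data, "meeg_raw"))
  check_no_na(data)
  lens <- vapply(data$trials, ncol, integer(1))
  if (length(unique(lens)) != 1)
    stop("mtmfft requires equal-length trials; use mtmconvol for variable-length data")
  N <- lens[1]
  fs <- data$sample_rate
  nch <- n_channels(data)
  freqs <- (0:(N %/% 2)) * fs / N
  if (is.null(foi)) foi <- c(0, fs / 2)
  if (max(foi) > fs / 2) stop("requested frequencies above Nyquist")
  if (length(foi) == 2) {
    bins <- which(freqs >= foi[1] & freqs <= foi[2])
  } else {
    bins <- unique(vapply(foi, function(f) which.min(abs(freqs - f)), integer(1)))
  }
  if (!length(bins)) stop("no frequency bins in the requested band")
  tapers <- taper_matrix(N, taper, smoothing, fs)
  K <- nrow(tapers)
  want_cross <- "cross" %in% output
  want_fourier <- "fourier" %in% output
  nfoi <- length(bins)
  ntr <- length(data$trials)
  scale_bin <- rep(2 / fs, nfoi)
  scale_bin[freqs[bins] == 0] <- 1 / fs
  if (N %% 2 == 0) scale_bin[freqs[bins] == fs / 2] <- 1 / fs
  power <- matrix(0, nch, nfoi)
  pairs <- if (want_cross && nch > 1) t(utils::combn(nch, 2)) else NULL
  cross <- if (!is.null(pairs)) matrix(0 + 0i, nrow(pairs), nfoi) else NULL
  fourier <- if (want_fourier) array(0 + 0i, c(ntr * K, nch, nfoi)) else NULL
  obs <- 0L
  obs_trial <- integer(0)
  for (tr_i in seq_len(ntr)) {
    tr <- data$trials[[tr_i]]
    tr <- tr - rowMeans(tr)
    for (k in seq_len(K)) {
      tap <- tapers[k, ]
      co <- stats::mvfft(t(tr * rep(tap, each = nch)))[bins, , drop = FALSE]
      co <- t(co) / sqrt(sum(tap^2))     # ch x nfoi, taper-power normalized
      power <- power + sweep(Mod(co)^2, 2, scale_bin, "*")
      if (!is.null(cross)) {
        cross <- cross + sweep(co[pairs[, 1], , drop = FALSE] *
                                 Conj(co[pairs[, 2], , drop = FALSE]),
                               2, scale_bin, "*")
      }
      obs <- obs + 1L
      obs_trial <- c(obs_trial, tr_i)
      if (want_fourier) fourier[obs, , ] <- co * sqrt(rep(scale_bin, each = nch))
    }
  }
  power <- power / obs
  if (!is.null(cross)) cross <- cross / obs
  freq_data(power, freqs[bins], data$channels, cross = cross, pairs = pairs,
            fourier = fourier, obs_trial = if (want_fourier) obs_trial else NULL,
            taper_count = K,
            provenance = append_provenance(list(data$provenance), "mtmfft",
                                           list(taper = taper, smoothing = smoothing,
                                                foi = foi, output = output)))
}

#' Sliding-window multitaper time-frequency estimate
#'
#' A multitaper spectral estimate in a window of length `t_window` centered
#' at each requested time point.  Time points where the window does not fit
#' inside the trial are returned as NA (missing), not extrapolated.
#'
#' @param data `meeg_raw` (trials may differ in length; each toi/trial cell
#'   is computed only where supported).
#' @param toi time points of interest, seconds.
#' @param t_window window length in seconds (scalar, or one per frequency).
#' @param foi frequencies of interest, Hz (vector).
#' @param taper "dpss" or "hann".
#' @param smoothing Hz half-bandwidth for dpss tapers.
#' @return `meeg_freq` with a time axis; power is channel x freq x time.
#' @export
mtmconvol <- function(data, toi, t_window, foi, taper = "dpss", smoothing = 4) {
  stopifnot(inherits(data, "meeg_raw"))
  check_no_na(data)
  fs <- data$sample_rate
  nch <- n_channels(data)
  if (max(foi) > fs / 2) stop("requested frequencies above Nyquist")
  t_window <- rep_len(t_window, length(foi))
  power <- array(NA_real_, c(nch, length(foi), length(toi)))
  count <- array(0L, c(length(foi), length(toi)))
  acc <- array(0, c(nch, length(foi), length(toi)))
  for (fi in seq_along(foi)) {
    Nw <- max(3L, round(t_window[fi] * fs))
    tapers <- taper_matrix(Nw, taper, smoothing, fs)
    K <- nrow(tapers)
    kbin <- round(foi[fi] * Nw / fs) + 1L
    kbin <- min(max(kbin, 1L), Nw %/% 2 + 1L)
    f_act <- (kbin - 1) * fs / Nw
    sc <- if (f_act == 0 || (Nw %% 2 == 0 && f_act == fs / 2)) 1 / fs else 2 / fs
    half_lo <- (Nw - 1L) %/% 2L
    carrier <- exp(-2i * pi * (kbin - 1) * (0:(Nw - 1)) / Nw)
    for (tr_i in seq_along(data$trials)) {
      tr <- data$trials[[tr_i]]
      tm <- data$time[[tr_i]]
      tr <- tr - rowMeans(tr)
      for (ti in seq_along(toi)) {
        c_idx <- which.min(abs(tm - toi[ti]))
        if (abs(tm[c_idx] - toi[ti]) > 0.5 / fs + 1e-12) next
        b <- c_idx - half_lo
        e <- b + Nw - 1L
        if (b < 1 || e > ncol(tr)) next
        seg <- tr[, b:e, drop = FALSE]
        for (k in seq_len(K)) {
          tap <- tapers[k, ]
          co <- seg %*% (tap * carrier) / sqrt(sum(tap^2))
          acc[, fi, ti] <- acc[, fi, ti] + Mod(co)^2 * sc
          count[fi, ti] <- count[fi, ti] + 1L
        }
      }
    }
  }
  has <- count > 0
  for (fi in seq_along(foi)) for (ti in seq_along(toi)) {
    if (has[fi, ti]) power[, fi, ti] <- acc[, fi, ti] / count[fi, ti]
  }
  ord <- order(foi)
  freq_data(power[, ord, , drop = FALSE], foi[ord], data$channels,
            time = toi, taper_count = 1L,
            provenance = append_provenance(list(data$provenance), "mtmconvol",
                                           list(toi_n = length(toi), foi = foi,
                                                t_window = t_window,
                                                taper = taper,
                                                smoothing = smoothing)))
}

#' Morlet wavelet time-frequency estimate
#'
#' Convolution with complex Morlet templates: Gaussian envelope of temporal
#' standard deviation `m / (2 pi f)` (m cycles), carrier at f.  Power is
#' scaled as a one-sided density with the Gaussian envelope as the taper,
#' making the peak response to a unit sinusoid comparable with a
#' matched-resolution [mtmconvol()] estimate.  Cells whose wavelet support
#' (+/- 3 sd) extends beyond the trial are NA.
#'
#' @param data `meeg_raw` with equal-length trials.
#' @param foi frequencies of interest, Hz.
#' @param width m, cycles per wavelet (>= 3 recommended).
#' @return `meeg_freq` with time axis of the first trial.
#' @export
wavelet_tfr <- function(data, foi, width = 7) {
  stopifnot(inherits(data, "meeg_raw"))
  check_no_na(data)
  fs <- data$sample_rate
  lens <- vapply(data$trials, ncol, integer(1))
  if (length(unique(lens)) != 1)
    stop("wavelet_tfr requires equal-length trials")
  N <- lens[1]
  nch <- n_channels(data)
  if (max(foi) > fs / 2) stop("requested frequencies above Nyquist")
  power <- array(NA_real_, c(nch, length(foi), N))
  for (fi in seq_along(foi)) {
    f <- foi[fi]
    sd_t <- width / (2 * pi * f)
    hs <- ceiling(3 * sd_t * fs)
    if (2 * hs + 1 > N)
      next                               # wavelet support exceeds the trial
    tt <- (-hs:hs) / fs
    g <- exp(-tt^2 / (2 * sd_t^2))
    w <- g * exp(2i * pi * f * tt)
    sc <- 2 / (fs * sum(g^2))
    acc <- matrix(0, nch, N)
    for (tr in data$trials) {
      tr <- tr - rowMeans(tr)
      for (ch in seq_len(nch)) {
        co <- stats::convolve(tr[ch, ], w, type = "open")  # conv with conj(rev(w))
        co <- co[(hs + 1):(hs + N)]
        acc[ch, ] <- acc[ch, ] + Mod(co)^2 * sc
      }
    }
    acc <- acc / length(data$trials)
    acc[, c(seq_len(hs), (N - hs + 1):N)] <- NA   # unsupported edges
    power[, fi, ] <- acc
  }
  ord <- order(foi)
  freq_data(power[, ord, , drop = FALSE], foi[ord], data$channels,
            time = data$time[[1]], taper_count = 1L,
            provenance = append_provenance(list(data$provenance), "wavelet_tfr",
                                           list(foi = foi, width = width)))
}
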