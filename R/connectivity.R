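# Frequency-domain connectivity from spectral decompositions (coherence,
# PLV, phase slope index) and from fitted multivariate autoregressive
# models (PDC, DTF, spectral Granger causality).

#' Build a full cross-spectral density array from a freq object
#'
#' @param fd `meeg_freq` with power and cross-spectra.
#' @return list of class `spectral_matrix`: S (channel x channel x freq
#'   complex, Hermitian per frequency), freq, labels, dof.
#' @export
csd_matrix <- function(fd) {
  stopifnot(inherits(fd, "meeg_freq"))
  if (is.null(fd$cross)) stop("freq object has no cross-spectra; rerun with output='cross'")
  nch <- n_channels(fd)
  nf <- length(fd$freq)
  S <- array(0 + 0i, c(nch, nch, nf))
  for (f in seq_len(nf)) {
    M <- matrix(0 + 0i, nch, nch)
    diag(M) <- fd$power[, f]
    for (r in seq_len(nrow(fd$pairs))) {
      i <- fd$pairs[r, 1]; j <- fd$pairs[r, 2]
      M[i, j] <- fd$cross[r, f]
      M[j, i] <- Conj(fd$cross[r, f])
    }
    S[, , f] <- M
  }
  structure(list(S = S, freq = fd$freq, labels = fd$channels$label,
                 dof = NULL), class = "spectral_matrix")
}

pair_table <- function(nch) t(utils::combn(nch, 2))

#' Coherence / coherency between channel pairs
#'
#' Coherency `C_ij(f) = S_ij / sqrt(S_ii S_jj)`; the magnitude lies in
#' [0, 1], the imaginary part is insensitive to instantaneous (zero-lag)
#' mixing.
#'
#' @param sm `spectral_matrix` (see [csd_matrix()]).
#' @param form "magnitude" (default), "complex", "imaginary", or
#'   "magnitude_squared".
#' @return list: values (pair x freq), pairs, freq, labels, form.
#' @export
coherence <- function(sm, form = c("magnitude", "complex", "imaginary",
                                   "magnitude_squared")) {
  form <- match.arg(form)
  stopifnot(inherits(sm, "spectral_matrix"))
  nch <- dim(sm$S)[1]
  nf <- dim(sm$S)[3]
  auto <- vapply(seq_len(nf), function(f) Re(diag(sm$S[, , f])), numeric(nch))
  if (any(auto <= 0)) {
    bad <- which(auto <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero auto-spectrum for channel %d at %g Hz",
                 bad[1], sm$freq[bad[2]]))
  }
  pr <- pair_table(nch)
  vals <- matrix(if (form == "complex") 0 + 0i else 0, nrow(pr), nf)
  for (f in seq_len(nf)) {
    den <- sqrt(auto[pr[, 1], f] * auto[pr[, 2], f])
    C <- sm$S[, , f][pr] / den
    vals[, f] <- switch(form,
                        magnitude = Mod(C),
                        magnitude_squared = Mod(C)^2,
                        imaginary = Im(C),
                        complex = C)
  }
  list(values = vals, pairs = pr, freq = sm$freq, labels = sm$labels,
       form = form)
}

#' Phase locking value
#'
#' PLV_ij(f) = | mean over observations of exp(i (phi_i - phi_j)) |, where
#' observations are trial-taper Fourier coefficients.  Symmetric, in [0,1].
#'
#' @param fourier complex array observations x channels x freq (e.g. the
#'   `fourier` field of [mtmfft()] output), or a `meeg_freq` carrying one.
#' @return list: values (pair x freq in [0,1]), pairs, freq (if known).
#' @export
plv <- function(fourier) {
  freq <- NULL
  if (inherits(fourier, "meeg_freq")) {
    freq <- fourier$freq
    fourier <- fourier$fourier
  }
  if (is.null(fourier)) stop("no Fourier coefficients; rerun mtmfft with output='fourier'")
  stopifnot(length(dim(fourier)) == 3, dim(fourier)[1] >= 2)
  if (any(Mod(fourier) == 0))
    stop("zero-magnitude Fourier coefficient: phase undefined")
  ph <- fourier / Mod(fourier)
  nch <- dim(fourier)[2]
  pr <- pair_table(nch)
  nf <- dim(fourier)[3]
  vals <- matrix(0, nrow(pr), nf)
  for (r in seq_len(nrow(pr))) {
    rel <- ph[, pr[r, 1], , drop = FALSE] * Conj(ph[, pr[r, 2], , drop = FALSE])
    vals[r, ] <- Mod(apply(rel, 3, mean))
  }
  list(values = vals, pairs = pr, freq = freq)
}

psi_raw_from_fourier <- function(fourier, rows, band_idx) {
  co <- fourier[rows, , band_idx, drop = FALSE]
  nch <- dim(co)[2]
  S <- array(0 + 0i, c(nch, nch, length(band_idx)))
  for (f in seq_along(band_idx)) {
    X <- co[, , f]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    # S_ij = mean over observations of x_i * conj(x_j)
    S[, , f] <- t(crossprod(Conj(X), X)) / nrow(X)
  }
  auto <- vapply(seq_along(band_idx), function(f) Re(diag(S[, , f])),
                 numeric(nch))
  psi <- matrix(0, nch, nch)
  for (f in seq_len(length(band_idx) - 1)) {
    C1 <- S[, , f] / sqrt(auto[, f] %o% auto[, f])
    C2 <- S[, , f + 1] / sqrt(auto[, f + 1] %o% auto[, f + 1])
    psi <- psi + Im(Conj(C1) * C2)
  }
  psi
}

#' Phase slope index over a frequency band
#'
#' Raw `psi_ij = Im( sum_f conj(C_ij(f)) C_ij(f + df) )` over adjacent bins
#' in the band; positive values indicate channel i leads channel j.  The
#' normalized index divides by a leave-one-trial-out jackknife standard
#' deviation.
#'
#' @param fd `meeg_freq` with Fourier coefficients and per-observation trial
#'   indices (run [mtmfft()] with `output = c("power","fourier")`).
#' @param band `c(fmin, fmax)` Hz; must span >= 3 frequency bins.
#' @return list: psi (channel x channel antisymmetric, raw), psi_norm
#'   (jackknife-normalized), sd_jackknife, band_bins.
#' @export
psi <- function(fd, band) {
  stopifnot(inherits(fd, "meeg_freq"))
  if (is.null(fd$fourier) || is.null(fd$obs_trial))
    stop("psi needs trial-resolved Fourier coefficients (output='fourier')")
  idx <- which(fd$freq >= band[1] & fd$freq <= band[2])
  if (length(idx) < 3) stop("band must contain at least 3 adjacent frequency bins")
  all_rows <- seq_len(dim(fd$fourier)[1])
  raw <- psi_raw_from_fourier(fd$fourier, all_rows, idx)
  trials <- unique(fd$obs_trial)
  n <- length(trials)
  jk <- array(0, c(dim(raw), n))
  for (t in seq_len(n)) {
    rows <- all_rows[fd$obs_trial != trials[t]]
    jk[, , t] <- psi_raw_from_fourier(fd$fourier, rows, idx)
  }
  jkm <- apply(jk, c(1, 2), mean)
  sd_jk <- sqrt((n - 1) / n *
                  apply(sweep(jk, c(1, 2), jkm, "-")^2, c(1, 2), sum))
  psi_norm <- raw / ifelse(sd_jk > 0, sd_jk, 1)
  diag(psi_norm) <- 0
  list(psi = raw, psi_norm = psi_norm, sd_jackknife = sd_jk,
       band_bins = idx, labels = fd$channels$label)
}

#' Fit a multivariate autoregressive model
#'
#' Joint least squares over all trials (each trial contributes rows
#' predicting x_t from x_{t-1..t-p} strictly within-trial); trials are
#' demeaned per trial.  The innovation covariance uses the unbiased
#' denominator rows - p * channels.
#'
#' @param data `meeg_raw` (or channels x samples matrix).
#' @param order model order p.
#' @return list of class `mvar_model`: order, A (list of p channel x channel
#'   matrices), noise_cov, sample_rate, stable (logical), labels.
#' @export
fit_mvar <- function(data, order) {
  p <- as.integer(order)
  if (is.matrix(data)) {
    data <- raw_data(list(data), list(seq_len(ncol(data)) - 1), # 1 Hz default
                     sprintf("ch%d", seq_len(nrow(data))), 1)
  }
  stopifnot(inherits(data, "meeg_raw"), p >= 1)
  check_no_na(data)
  nch <- n_channels(data)
  rows_per <- vapply(data$trials, function(tr) max(0L, ncol(tr) - p), integer(1))
  nrows <- sum(rows_per)
  total <- sum(vapply(data$trials, ncol, integer(1)))
  if (total - p * length(data$trials) <= p * nch^2)
    stop("not enough samples to identify an MVAR(", p, ") model")
  X <- matrix(0, nrows, p * nch)
  Y <- matrix(0, nrows, nch)
  r0 <- 0L
  for (tr in data$trials) {
    tr <- tr - rowMeans(tr)
    nT <- ncol(tr)
    if (nT <= p) next
    idx <- (p + 1):nT
    Y[r0 + seq_along(idx), ] <- t(tr[, idx, drop = FALSE])
    for (k in seq_len(p)) {
      X[r0 + seq_along(idx), (k - 1) * nch + seq_len(nch)] <-
        t(tr[, idx - k, drop = FALSE])
    }
    r0 <- r0 + length(idx)
  }
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-14)
    stop("regressor matrix is (numerically) singular; the process is deterministic or data degenerate")
  B <- solve(XtX, crossprod(X, Y))        # (p*nch) x nch
  resid <- Y - X %*% B
  Sigma <- crossprod(resid) / (nrows - p * nch)
  A <- lapply(seq_len(p), function(k) t(B[(k - 1) * nch + seq_len(nch), , drop = FALSE]))
  comp <- companion_matrix(A)
  stable <- max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
  if (!stable) warning("fitted MVAR model is unstable")
  structure(list(order = p, A = A, noise_cov = Sigma,
                 sample_rate = data$sample_rate, stable = stable,
                 labels = data$channels$label),
            class = "mvar_model")
}

companion_matrix <- function(A) {
  p <- length(A)
  nch <- nrow(A[[1]])
  comp <- matrix(0, p * nch, p * nch)
  comp[seq_len(nch), ] <- do.call(cbind, A)
  if (p > 1)
    comp[(nch + 1):(p * nch), seq_len((p - 1) * nch)] <- diag((p - 1) * nch)
  comp
}

#' AIC over candidate MVAR orders (helper; never auto-applied)
#'
#' @param data `meeg_raw` or matrix.
#' @param orders candidate orders.
#' @return data.frame order, aic.
#' @export
mvar_aic <- function(data, orders = 1:10) {
  res <- vapply(orders, function(p) {
    m <- fit_mvar(data, p)
    nch <- nrow(m$noise_cov)
    n_eff <- if (inherits(data, "meeg_raw"))
      sum(vapply(data$trials, ncol, integer(1))) else ncol(data)
    log(det(m$noise_cov)) + 2 * p * nch^2 / n_eff
  }, numeric(1))
  data.frame(order = orders, aic = res)
}

#' Spectral decomposition of an MVAR model
#'
#' `Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`, transfer function
#' `H(f) = Abar(f)^-1`, and model spectrum `S(f) = H Sigma H^H / fs`.
#'
#' @param model `mvar_model`.
#' @param freqs frequencies (Hz), at most Nyquist.
#' @return list of class `mvar_spectra`: freq, Abar, H, S (each channel x
#'   channel x freq), noise_cov, sample_rate.
#' @export
mvar_spectra <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"))
  fs <- model$sample_rate
  if (max(freqs) > fs / 2 + 1e-12) stop("frequencies above Nyquist")
  nch <- nrow(model$A[[1]])
  nf <- length(freqs)
  Abar <- array(0 + 0i, c(nch, nch, nf))
  H <- array(0 + 0i, c(nch, nch, nf))
  S <- array(0 + 0i, c(nch, nch, nf))
  for (f in seq_len(nf)) {
    Af <- diag(nch) + 0i
    for (k in seq_len(model$order)) {
      Af <- Af - model$A[[k]] * exp(-2i * pi * freqs[f] * k / fs)
    }
    if (rcond(Af) < 1e-14)
      stop(sprintf("singular spectral matrix Abar at %g Hz", freqs[f]))
    Hf <- solve(Af)
    Abar[, , f] <- Af
    H[, , f] <- Hf
    S[, , f] <- Hf %*% model$noise_cov %*% Conj(t(Hf)) / fs
  }
  structure(list(freq = freqs, Abar = Abar, H = H, S = S,
                 noise_cov = model$noise_cov, sample_rate = fs),
            class = "mvar_spectra")
}

#' Partial directed coherence and directed transfer function
#'
#' `PDC_{i<-j}(f) = |Abar_ij| / sqrt(sum_k |Abar_kj|^2)` (column
#' normalized); `DTF_{i<-j}(f) = |H_ij| / sqrt(sum_k |H_ik|^2)` (row
#' normalized).  Both lie in [0,1]; columns of PDC^2 and rows of DTF^2 sum
#' to one.
#'
#' @param spectra `mvar_spectra`.
#' @return list: pdc, dtf (channel x channel x freq arrays, entry [i,j,f] =
#'   influence of j on i), freq.
#' @export
pdc_dtf <- function(spectra) {
  stopifnot(inherits(spectra, "mvar_spectra"))
  nf <- length(spectra$freq)
  nch <- dim(spectra$Abar)[1]
  pdc <- array(0, c(nch, nch, nf))
  dtf <- array(0, c(nch, nch, nf))
  for (f in seq_len(nf)) {
    Am <- Mod(spectra$Abar[, , f])
    Hm <- Mod(spectra$H[, , f])
    pdc[, , f] <- Am / rep(sqrt(colSums(Am^2)), each = nch)
    dtf[, , f] <- Hm / sqrt(rowSums(Hm^2))
  }
  list(pdc = pdc, dtf = dtf, freq = spectra$freq)
}

#' Spectral Granger causality (bivariate, Geweke)
#'
#' For a 2-channel model, the causal influence of y on x at frequency f is
#' `ln[ S_xx(f) / (S_xx(f) - (Sigma_yy - Sigma_xy^2/Sigma_xx) |H_xy(f)|^2 / fs) ]`
#' and symmetrically for x on y.  Non-negative; zero when the corresponding
#' transfer-function entry vanishes.
#'
#' @param spectra `mvar_spectra` of a 2-channel model.
#' @return list: gc (2 x 2 x freq; gc[i,j,f] = influence of channel j on
#'   channel i), freq, clipped (logical flag, TRUE if a non-positive log
#'   argument was clipped).
#' @export
granger_spectral <- function(spectra) {
  stopifnot(inherits(spectra, "mvar_spectra"))
  nch <- dim(spectra$S)[1]
  if (nch != 2)
    stop("granger_spectral is bivariate; use granger_pairwise for >2 channels")
  fs <- spectra$sample_rate
  Sg <- spectra$noise_cov
  nf <- length(spectra$freq)
  gc <- array(0, c(2, 2, nf))
  clipped <- FALSE
  for (f in seq_len(nf)) {
    Sf <- spectra$S[, , f]
    Hf <- spectra$H[, , f]
    for (i in 1:2) {
      j <- 3 - i
      # partialized innovation variance of the sender
      sig_j <- Sg[j, j] - Sg[i, j]^2 / Sg[i, i]
      arg <- Re(Sf[i, i]) / (Re(Sf[i, i]) - sig_j * Mod(Hf[i, j])^2 / fs)
      if (!is.finite(arg) || arg <= 0) {
        arg <- 1e-12
        clipped <- TRUE
      }
      gc[i, j, f] <- log(arg)
    }
  }
  gc[gc < 0] <- 0
  list(gc = gc, freq = spectra$freq, clipped = clipped)
}

#' Pairwise spectral Granger causality for >= 2 channels
#'
#' Each channel pair is refit as a bivariate MVAR model of the given order
#' and Geweke's spectral measure computed on the refit.
#'
#' @param data `meeg_raw`.
#' @param order MVAR order.
#' @param freqs frequencies (Hz).
#' @return array channel x channel x freq: `[i, j, f]` = influence of j on i
#'   (diagonal 0).
#' @export
granger_pairwise <- function(data, order, freqs) {
  nch <- n_channels(data)
  out <- array(0, c(nch, nch, length(freqs)))
  for (i in seq_len(nch - 1)) for (j in (i + 1):nch) {
    sub <- select_channels(data, data$channels$label[c(i, j)])
    m <- fit_mvar(sub, order)
    g <- granger_spectral(mvar_spectra(m, freqs))
    out[i, j, ] <- g$gc[1, 2, ]
    out[j, i, ] <- g$gc[2, 1, ]
  }
  out
}
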