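# Source reconstruction: equivalent current dipole fitting (grid scan +
# simplex refinement), minimum-norm distributed estimates, and LCMV/DICS
# beamformers.  Lead fields come from the forward module; positions are in
# meters.

pinv_mat <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

dipole_rv <- function(positions, data, sensors, model, lf_fun) {
  L <- do.call(cbind, lapply(seq_len(nrow(positions)), function(k) {
    lf_fun(positions[k, ], sensors, model)$gain
  }))
  fit <- L %*% (pinv_mat(L) %*% data)
  sum((data - fit)^2) / sum(data^2)
}

#' Fit equivalent current dipoles
#'
#' Two stages: an exhaustive scan over a candidate grid (residual variance
#' of the linear moment fit at each position; for several dipoles the
#' seeding is greedy-sequential), followed by derivative-free Nelder-Mead
#' refinement of all positions jointly, with two restarts from the perturbed
#' optimum.  Moments are recovered linearly at the optimum.
#'
#' @param data channels x timepoints matrix (or a single topography vector).
#' @param sensors `sensor_array`.
#' @param model `sphere_model`.
#' @param n_dipoles number of dipoles to fit.
#' @param grid candidate positions (M x 3) or a `leadfield_grid()` result.
#' @return list of class `dipole_fit`: positions (n x 3), moments (3n x
#'   time), residual_variance, grid_scan_best, converged.
#' @export
fit_dipole <- function(data, sensors, model, n_dipoles = 1, grid) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  if (sum(data^2) == 0) stop("data are identically zero: residual variance undefined")
  nch <- nrow(data)
  if (nch < 6 * n_dipoles)
    stop("need at least 6 channels per dipole")
  if (is.list(grid) && !is.null(grid$positions)) {
    inside <- grid$inside
    gpos <- grid$positions[inside, , drop = FALSE]
    glf <- grid$leadfields[inside]
  } else {
    gp <- leadfield_grid(as.matrix(grid), sensors, model)
    gpos <- gp$positions[gp$inside, , drop = FALSE]
    glf <- gp$leadfields[gp$inside]
  }
  if (!nrow(gpos)) stop("grid contains no positions inside the source compartment")
  lf_fun <- if (sensors$kind == "meg") meg_single_sphere else eeg_concentric_spheres
  ss_data <- sum(data^2)
  rv_single <- vapply(glf, function(lf) {
    L <- lf$gain
    fit <- L %*% (pinv_mat(L) %*% data)
    sum((data - fit)^2) / ss_data
  }, numeric(1))
  # greedy-sequential seeding for multiple dipoles
  seeds <- matrix(0, n_dipoles, 3)
  seeds[1, ] <- gpos[which.min(rv_single), ]
  if (n_dipoles > 1) {
    resid <- data
    Lacc <- lf_fun(seeds[1, ], sensors, model)$gain
    for (d in 2:n_dipoles) {
      resid <- data - Lacc %*% (pinv_mat(Lacc) %*% data)
      rv_d <- vapply(glf, function(lf) {
        L <- lf$gain
        f <- L %*% (pinv_mat(L) %*% resid)
        sum((resid - f)^2)
      }, numeric(1))
      seeds[d, ] <- gpos[which.min(rv_d), ]
      Lacc <- cbind(Lacc, lf_fun(seeds[d, ], sensors, model)$gain)
    }
  }
  ctr <- model$center
  rin <- model$radii[1]
  objective <- function(par) {
    P <- matrix(par, ncol = 3, byrow = TRUE)
    rel <- sweep(P, 2, ctr)
    dep <- sqrt(rowSums(rel^2))
    if (any(dep >= rin * 0.995)) {
      # push back inside with a smooth penalty
      return(1 + 10 * sum(pmax(dep / (rin * 0.995) - 1, 0)))
    }
    dipole_rv(P, data, sensors, model, lf_fun)
  }
  par0 <- as.numeric(t(seeds))
  best <- stats::optim(par0, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  rv_grid <- objective(par0)
  converged <- TRUE
  for (restart in 1:2) {
    # deterministic alternating perturbation of the current optimum
    shift <- rep_len(c(1, -1), length(best$par)) * (-1)^restart * 1e-3 * rin
    cand <- stats::optim(best$par + shift, objective, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    if (cand$value < best$value - 1e-9) best <- cand
  }
  positions <- matrix(best$par, ncol = 3, byrow = TRUE)
  L <- do.call(cbind, lapply(seq_len(n_dipoles), function(k) {
    lf_fun(positions[k, ], sensors, model)$gain
  }))
  moments <- pinv_mat(L) %*% data
  rv <- min(best$value, rv_grid)
  structure(list(positions = positions, moments = moments,
                 residual_variance = rv, grid_scan_best = seeds,
                 converged = converged && best$convergence == 0),
            class = "dipole_fit")
}

#' Minimum-norm estimate
#'
#' Linear inverse `M = R L' (L R L' + lambda^2 C)^-1` with identity source
#' covariance R (optionally depth-weighted by the lead-field norm raised to
#' a negative exponent); the source map holds the per-source moment norm
#' averaged over time.  `lambda` is dimensionless: the noise covariance is
#' internally rescaled to the trace of the Gram matrix `L R L'`, so the
#' same value works across measurement units (cf. the beamformers'
#' fractional regularization).
#'
#' @param leadfields `leadfield_grid()` result (or stacked channels x
#'   3*n_sources matrix with an `inside` attribute).
#' @param data channels x timepoints matrix.
#' @param noise_cov channels x channels symmetric PSD matrix (identity
#'   default).
#' @param lambda dimensionless regularization weight (>= 0).
#' @param depth_weight exponent gamma >= 0; R_ii = ||L_i||^(-2 gamma)
#'   per source (0 = off).
#' @return list of class `source_map`: positions, inside, values, moments
#'   (3*n_inside x time), method.
#' @export
minimum_norm <- function(leadfields, data, noise_cov = NULL, lambda = 0.01,
                         depth_weight = 0) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  stopifnot(lambda >= 0)
  lfs <- leadfields$leadfields[leadfields$inside]
  L <- do.call(cbind, lapply(lfs, function(x) x$gain))
  nch <- nrow(L)
  nsrc <- length(lfs)
  if (is.null(noise_cov)) noise_cov <- diag(nch)
  rdiag <- rep(1, 3 * nsrc)
  if (depth_weight > 0) {
    for (k in seq_len(nsrc)) {
      nrm2 <- sum(lfs[[k]]$gain^2)
      rdiag[(3 * k - 3) + 1:3] <- nrm2^(-depth_weight)
    }
  }
  LR <- L * rep(rdiag, each = nch)
  gram <- LR %*% t(L)
  scale <- sum(diag(gram)) / sum(diag(noise_cov))
  G <- gram + lambda^2 * scale * noise_cov
  if (lambda == 0 && rcond(G) < 1e-14)
    stop("singular Gram matrix with lambda = 0; use a positive regularization")
  M <- t(LR) %*% solve(G)
  est <- M %*% data
  vals <- vapply(seq_len(nsrc), function(k) {
    mom <- est[(3 * k - 3) + 1:3, , drop = FALSE]
    mean(sqrt(colSums(mom^2)))
  }, numeric(1))
  structure(list(positions = leadfields$positions, inside = leadfields$inside,
                 values = vals, moments = est, method = "mne"),
            class = "source_map")
}

regularized_cov <- function(C, lambda_reg) {
  C + lambda_reg * sum(diag(Re(C))) / nrow(C) * diag(nrow(C))
}

beamformer_maps <- function(lfs, Cinv, Creg, noise_mat) {
  nsrc <- length(lfs)
  power <- numeric(nsrc)
  nai <- numeric(nsrc)
  flags <- logical(nsrc)
  weights <- vector("list", nsrc)
  for (k in seq_len(nsrc)) {
    L <- lfs[[k]]$gain
    if (all(L == 0)) {                  # e.g. the exact sphere center (MEG)
      power[k] <- NA_real_; nai[k] <- NA_real_; flags[k] <- TRUE
      next
    }
    CiL <- Cinv %*% L
    G <- Re(Conj(t(L)) %*% CiL)
    if (rcond(G) < 1e-12) {
      Gi <- pinv_mat(G)
      flags[k] <- TRUE
    } else {
      Gi <- solve(G)
    }
    W <- Gi %*% Conj(t(CiL))              # 3 x channels
    # power through the regularized matrix, so the real-valued-CSD case
    # reduces exactly to the time-domain beamformer
    power[k] <- Re(sum(diag(W %*% Creg %*% Conj(t(W)))))
    nai[k] <- power[k] / Re(sum(diag(W %*% noise_mat %*% Conj(t(W)))))
    weights[[k]] <- W
  }
  list(power = power, nai = nai, flags = flags, weights = weights)
}

#' LCMV beamformer source map
#'
#' Vector (three-orientation) linearly constrained minimum-variance
#' beamformer: `W_p = (L_p' C'^-1 L_p)^-1 L_p' C'^-1` with
#' `C' = C + lambda_reg * trace(C)/channels * I`.  Source power is
#' `trace(W C' W')`; the neural activity index divides by the projected
#' noise power (smallest eigenvalue of C' times identity by default).
#'
#' @param leadfields `leadfield_grid()` result.
#' @param data_cov channels x channels covariance of the sensor data.
#' @param lambda_reg regularization as a fraction of the mean sensor
#'   variance (default 0.05).
#' @param noise_cov optional noise covariance; default smallest eigenvalue
#'   of the regularized covariance times identity.
#' @return `source_map` with values = NAI, plus power, nai, weights.
#' @export
lcmv <- function(leadfields, data_cov, lambda_reg = 0.05, noise_cov = NULL) {
  Creg <- regularized_cov(data_cov, lambda_reg)
  ev <- eigen(Creg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance not positive definite after regularization")
  if (is.null(noise_cov)) noise_cov <- min(ev) * diag(nrow(Creg))
  Cinv <- solve(Creg)
  lfs <- leadfields$leadfields[leadfields$inside]
  bm <- beamformer_maps(lfs, Cinv, Creg, noise_cov)
  structure(list(positions = leadfields$positions, inside = leadfields$inside,
                 values = bm$nai, power = bm$power, nai = bm$nai,
                 weights = bm$weights, singular = bm$flags, method = "lcmv"),
            class = "source_map")
}

#' DICS beamformer (frequency domain)
#'
#' The LCMV weight formula applied to a (complex, Hermitian) cross-spectral
#' density at the target frequency, regularized through the real part of its
#' trace.  Source power is `Re trace(W csd W^H)`.  Optionally, source
#' coherence with a reference position is computed from the 2x2
#' source-level CSD between each position and the reference.
#'
#' @param leadfields `leadfield_grid()` result.
#' @param csd channels x channels Hermitian cross-spectral matrix at the
#'   frequency of interest.
#' @param lambda_reg regularization fraction.
#' @param ref_pos optional 3-vector: reference position for source
#'   coherence.
#' @param sensors,model needed when `ref_pos` is given.
#' @return `source_map` with values = power; `coherence` present when a
#'   reference was supplied.
#' @export
dics <- function(leadfields, csd, lambda_reg = 0.05, ref_pos = NULL,
                 sensors = NULL, model = NULL) {
  if (max(Mod(csd - Conj(t(csd)))) > 1e-8 * max(Mod(csd)))
    stop("cross-spectral density must be Hermitian")
  Creg <- csd + lambda_reg * sum(diag(Re(csd))) / nrow(csd) * diag(nrow(csd))
  Cinv <- solve(Creg)
  ev <- eigen(Re(Creg), symmetric = TRUE, only.values = TRUE)$values
  noise_mat <- min(ev) * diag(nrow(Creg))
  lfs <- leadfields$leadfields[leadfields$inside]
  bm <- beamformer_maps(lfs, Cinv, Creg, noise_mat)
  out <- structure(list(positions = leadfields$positions,
                        inside = leadfields$inside,
                        values = bm$power, power = bm$power, nai = bm$nai,
                        weights = bm$weights, singular = bm$flags,
                        method = "dics"),
                   class = "source_map")
  if (!is.null(ref_pos)) {
    stopifnot(!is.null(sensors), !is.null(model))
    lf_fun <- if (sensors$kind == "meg") meg_single_sphere else eeg_concentric_spheres
    Lr <- lf_fun(ref_pos, sensors, model)$gain
    CiLr <- Cinv %*% Lr
    Gr <- Re(Conj(t(Lr)) %*% CiLr)
    Wr <- pinv_mat(Gr) %*% Conj(t(CiLr))
    # scalar source signals along each position's dominant orientation
    # (principal eigenvector of its 3x3 source CSD), then the 2x2
    # source-level CSD with the reference, all through the raw CSD
    Sr <- Wr %*% csd %*% Conj(t(Wr))
    ur <- eigen(Sr, symmetric = TRUE)$vectors[, 1]
    pr <- Re(Conj(ur) %*% Sr %*% ur)[1]
    coh <- numeric(length(lfs))
    for (k in seq_along(lfs)) {
      W <- bm$weights[[k]]
      if (is.null(W)) { coh[k] <- NA_real_; next }
      Sk <- W %*% csd %*% Conj(t(W))
      uk <- eigen(Sk, symmetric = TRUE)$vectors[, 1]
      pk <- Re(Conj(uk) %*% Sk %*% uk)[1]
      crossp <- (Conj(uk) %*% (W %*% csd %*% Conj(t(Wr))) %*% ur)[1]
      coh[k] <- Mod(crossp) / sqrt(pk * pr)
    }
    out$coherence <- coh
    out$ref_pos <- ref_pos
  }
  out
}

#' Local maxima of a source map
#'
#' Positions whose value is at least that of every other inside position
#' within the given neighbourhood radius.  Distributed inverse maps
#' (minimum norm in particular) are interpreted through their local maxima:
#' the global peak of a minimum-norm map carries a well-known radial bias
#' on volumetric grids.
#'
#' @param map `source_map`.
#' @param radius neighbourhood radius in meters (e.g. just over one grid
#'   step).
#' @return integer indices (into the inside positions) of local maxima,
#'   ordered by decreasing value.
#' @export
source_local_maxima <- function(map, radius) {
  pos <- map$positions[map$inside, , drop = FALSE]
  vals <- map$values
  idx <- which(vapply(seq_along(vals), function(i) {
    nb <- which(sqrt(colSums((t(pos) - pos[i, ])^2)) <= radius)
    nb <- setdiff(nb, i)
    length(nb) > 0 && all(vals[i] >= vals[nb], na.rm = TRUE) && !is.na(vals[i])
  }, logical(1)))
  idx[order(vals[idx], decreasing = TRUE)]
}

#' Export a source map as a plain-text table
#'
#' @param map `source_map`.
#' @param path output path (TSV: x, y, z, value; inside positions only).
#' @return invisible path.
#' @export
write_source_map <- function(map, path) {
  df <- data.frame(map$positions[map$inside, , drop = FALSE],
                   value = map$values)
  names(df)[1:3] <- c("x", "y", "z")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
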