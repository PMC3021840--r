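# Analytic lead fields for spherical volume conductors: the MEG single
# sphere (Sarvas closed form) and the EEG concentric-sphere Legendre
# series.  All positions in meters in a common head frame; the sphere
# center is subtracted internally.  MEG gains in T/(A*m), EEG gains in
# V/(A*m); the gain matrix columns correspond to unit dipole moments along
# x, y, z.

MU0 <- 4 * pi * 1e-7

#' Spherical volume-conductor model
#'
#' @param center 3-vector, meters.
#' @param radii strictly increasing shell radii (1 = single sphere, up to 4
#'   concentric shells, innermost first).
#' @param conductivities S/m per shell (EEG only); a conventional 3-shell
#'   example is `c(0.33, 0.0042, 0.33)` (brain, skull, scalp).
#' @return list of class `sphere_model`.
#' @export
sphere_model <- function(center = c(0, 0, 0), radii, conductivities = NULL) {
  stopifnot(length(center) == 3, length(radii) >= 1, length(radii) <= 4)
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be strictly increasing")
  if (!is.null(conductivities)) {
    stopifnot(length(conductivities) == length(radii), all(conductivities > 0))
  }
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 conductivities = conductivities),
            class = "sphere_model")
}

#' Sensor array description
#'
#' @param kind "meg" (point magnetometers with orientations) or "eeg"
#'   (electrodes; positions are projected onto the outer shell surface
#'   before use).
#' @param positions N x 3 matrix, meters.
#' @param orientations N x 3 unit coil normals (MEG only).
#' @param labels channel labels.
#' @return list of class `sensor_array`.
#' @export
sensor_array <- function(kind = c("meg", "eeg"), positions,
                         orientations = NULL, labels = NULL) {
  kind <- match.arg(kind)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  n <- nrow(positions)
  if (kind == "meg") {
    stopifnot(!is.null(orientations))
    orientations <- as.matrix(orientations)
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-10))
      orientations <- orientations / nrm
  }
  if (is.null(labels)) labels <- sprintf("S%03d", seq_len(n))
  structure(list(kind = kind, positions = positions,
                 orientations = orientations, labels = labels),
            class = "sensor_array")
}

#' MEG lead field of a single dipole in a homogeneous sphere
#'
#' Closed-form external magnetic field of a current dipole in a spherically
#' symmetric conductor; volume currents are accounted for analytically, and
#' the radial source component is magnetically silent.  With sphere-centered
#' sensor position r and source position r0: a = r - r0, a = |a|, r = |r|,
#' F = a (r a + r^2 - r0 . r),
#' grad F = (a^2/r + a.r/a + 2a + 2r) r - (a + 2r + a.r/a) r0, and
#' B = mu0 / (4 pi F^2) (F (Q x r0) - ((Q x r0) . r) grad F),
#' projected on each coil orientation.
#'
#' @param source_pos 3-vector, meters (strictly inside the sphere).
#' @param sensors `sensor_array` of kind "meg" (strictly outside).
#' @param model `sphere_model` (outermost radius used).
#' @return list of class `lead_field`: gain (N x 3, T/(A*m)), source
#'   position, unit.
#' @export
meg_single_sphere <- function(source_pos, sensors, model) {
  stopifnot(inherits(sensors, "sensor_array"), sensors$kind == "meg")
  ctr <- model$center
  r0 <- as.numeric(source_pos) - ctr
  R <- max(model$radii)
  if (sqrt(sum(r0^2)) >= R) stop("source must be strictly inside the sphere")
  pos <- sweep(sensors$positions, 2, ctr)
  n <- nrow(pos)
  gain <- matrix(0, n, 3)
  for (s in seq_len(n)) {
    r <- pos[s, ]
    rn <- sqrt(sum(r^2))
    if (rn <= R) stop("sensor ", s, " not strictly outside the sphere")
    a_vec <- r - r0
    a <- sqrt(sum(a_vec^2))
    adotr <- sum(a_vec * r)
    F <- a * (rn * a + rn^2 - sum(r0 * r))
    gF <- (a^2 / rn + adotr / a + 2 * a + 2 * rn) * r -
      (a + 2 * rn + adotr / a) * r0
    for (m in 1:3) {
      Q <- c(0, 0, 0); Q[m] <- 1
      Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
                Q[3] * r0[1] - Q[1] * r0[3],
                Q[1] * r0[2] - Q[2] * r0[1])
      B <- MU0 / (4 * pi * F^2) * (F * Qxr0 - sum(Qxr0 * r) * gF)
      gain[s, m] <- sum(B * sensors$orientations[s, ])
    }
  }
  structure(list(gain = gain, source_pos = as.numeric(source_pos),
                 unit = "T/(A*m)"), class = "lead_field")
}

# Surface potential of a dipole in a homogeneous conducting sphere
# (closed form obtained by summing the (2n+1)/n Legendre series):
#   V(r) = 1/(4 pi sigma) [ 2 (q.a)/a^3
#          + ( q.r/R + (q.a)/a ) / (a R + r.a) / R * R ... ]
# with a = r - r0 on the surface |r| = R.  Used as the collapse oracle for
# the multi-shell series.
eeg_homogeneous_potential <- function(r, r0, q, sigma) {
  R <- sqrt(sum(r^2))
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  term1 <- 2 * sum(q * a_vec) / a^3
  D <- a * R + sum(r * a_vec)
  term2 <- (sum(q * r) + R * sum(q * a_vec) / a) / (R * D)
  (term1 + term2) / (4 * pi * sigma)
}

# Legendre polynomials P_1..P_nmax and derivatives at x, via recurrence.
legendre_upto <- function(nmax, x) {
  P <- numeric(nmax + 1)
  dP <- numeric(nmax + 1)
  P[1] <- 1; dP[1] <- 0            # P_0
  if (nmax >= 1) { P[2] <- x; dP[2] <- 1 }
  for (n in 2:nmax) {
    P[n + 1] <- ((2 * n - 1) * x * P[n] - (n - 1) * P[n - 1]) / n
    dP[n + 1] <- ((2 * n - 1) * (P[n] + x * dP[n]) - (n - 1) * dP[n - 1]) / n
  }
  list(P = P[-1], dP = dP[-1])     # orders 1..nmax
}

# Per-order radial transfer: solve the boundary-condition linear system for
# m concentric shells.  The dipole sits in shell 1; the potential in shell
# k is expanded in a per-shell normalized basis, a_k (rho/r_k)^n +
# b_k (rho/r_k)^{-(n+1)} (shell 1 additionally carries the primary term
# (rho/r_1)^{-(n+1)}), which keeps the system well conditioned at high n.
# Continuity of potential and normal current at every interface,
# insulating outer boundary.  Returns the outer-surface value a_m + b_m,
# so that with normalized radii rh = radii/max(radii) and bh = b/max(radii)
# the order-n surface term is
# (bh/rh_1)^(n-1) * (a_m + b_m) / (rh_1^2 * Rout^2) * [angular part].
concentric_transfer <- function(n, rh, cond) {
  m <- length(rh)
  if (m == 1) {
    return((2 * n + 1) / n)
  }
  # unknowns: a_1, a_2, b_2, ..., a_m, b_m  (2m - 1)
  nu <- 2 * m - 1
  M <- matrix(0, nu, nu)
  rhs <- numeric(nu)
  iA <- function(k) if (k == 1) 1L else 2L * (k - 1L)
  iB <- function(k) 2L * (k - 1L) + 1L   # k >= 2
  row <- 0L
  for (k in seq_len(m - 1)) {            # interface at rh_k between k, k+1
    xi <- rh[k] / rh[k + 1]              # < 1
    # potential continuity: shell k side evaluated at its own outer radius
    row <- row + 1L
    M[row, iA(k)] <- 1
    if (k > 1) M[row, iB(k)] <- 1
    M[row, iA(k + 1)] <- -xi^n
    M[row, iB(k + 1)] <- -xi^(-(n + 1))
    if (k == 1) rhs[row] <- -1           # primary term, value 1 at rh_1
    # normal current continuity (row multiplied by rh_k)
    row <- row + 1L
    M[row, iA(k)] <- cond[k] * n
    if (k > 1) M[row, iB(k)] <- -cond[k] * (n + 1)
    M[row, iA(k + 1)] <- -cond[k + 1] * n * xi^n
    M[row, iB(k + 1)] <- cond[k + 1] * (n + 1) * xi^(-(n + 1))
    if (k == 1) rhs[row] <- cond[1] * (n + 1)
  }
  # outer boundary: zero radial current at rh_m
  row <- row + 1L
  M[row, iA(m)] <- n
  M[row, iB(m)] <- -(n + 1)
  sol <- solve(M, rhs)
  sol[iA(m)] + sol[iB(m)]
}

#' EEG lead field for concentric-sphere models
#'
#' Surface potential of a current dipole inside the innermost shell of up to
#' four concentric spheres, via the Legendre series in the cosine of the
#' angle between source and electrode, with per-shell radial transfer
#' factors obtained from the continuity boundary conditions (potential and
#' normal current at every interface, insulating outer boundary).  The
#' series is truncated at `n_max` terms (default 60, giving <= 1e-8 relative
#' error for sources within 90% of the innermost radius).  Electrodes are
#' projected radially onto the outer surface.
#'
#' @param source_pos 3-vector, meters, inside the innermost shell.
#' @param electrodes `sensor_array` of kind "eeg".
#' @param model `sphere_model` with conductivities.
#' @param n_max series truncation order.
#' @return `lead_field` with gain in V/(A*m).
#' @export
eeg_concentric_spheres <- function(source_pos, electrodes, model, n_max = 60) {
  stopifnot(inherits(electrodes, "sensor_array"), electrodes$kind == "eeg")
  if (is.null(model$conductivities)) stop("EEG model needs conductivities")
  ctr <- model$center
  r0 <- as.numeric(source_pos) - ctr
  b <- sqrt(sum(r0^2))
  r1 <- model$radii[1]
  if (b >= r1 * 0.998)
    stop("source within 0.2% of the innermost shell radius: series would diverge")
  Rout <- max(model$radii)
  sigma1 <- model$conductivities[1]
  # project electrodes radially onto the outer surface
  pos <- sweep(electrodes$positions, 2, ctr)
  pos <- pos * (Rout / sqrt(rowSums(pos^2)))
  nS <- nrow(pos)
  gain <- matrix(0, nS, 3)
  rh <- model$radii / Rout
  bh <- b / Rout
  trans <- vapply(seq_len(n_max), concentric_transfer,
                  numeric(1), rh = rh, cond = model$conductivities)
  # source-local frame: radial unit vector (or z for a central source)
  if (b > 1e-12) {
    er <- r0 / b
  } else {
    er <- c(0, 0, 1)
  }
  for (s in seq_len(nS)) {
    r <- pos[s, ]
    cosg <- sum(r * er) / Rout
    cosg <- min(1, max(-1, cosg))
    leg <- legendre_upto(n_max, cosg)
    # tangential direction in the source-electrode plane
    t_vec <- r / Rout - cosg * er
    tn <- sqrt(sum(t_vec^2))
    if (tn > 1e-12) t_vec <- t_vec / tn else t_vec <- c(0, 0, 0)
    sing <- tn                     # sin of the angle (>= 0)
    for (m in 1:3) {
      q <- c(0, 0, 0); q[m] <- 1
      qr <- sum(q * er)            # radial moment component
      qt <- sum(q * t_vec)         # tangential, in-plane component
      # primary (infinite homogeneous medium) expansion coefficients:
      # V_inf = 1/(4 pi s1) sum_n b^{n-1} / rho^{n+1} [n qr P_n + qt P_n^1]
      # with P_n^1(x) = -sin(g) dP_n/dx (Ferrers, sign absorbed below)
      n_idx <- seq_len(n_max)
      radial <- (bh / rh[1])^(n_idx - 1) / (rh[1]^2 * Rout^2)
      series <- sum(radial * trans *
                      (n_idx * qr * leg$P + qt * sing * leg$dP))
      gain[s, m] <- series / (4 * pi * sigma1)
    }
  }
  structure(list(gain = gain, source_pos = as.numeric(source_pos),
                 unit = "V/(A*m)"), class = "lead_field")
}

#' Lead fields on a regular 3D grid
#'
#' Positions outside the innermost source compartment are masked and
#' skipped.
#'
#' @param grid_pos M x 3 matrix of candidate positions (meters), e.g. from
#'   [make_grid()].
#' @param sensors `sensor_array`.
#' @param model `sphere_model`.
#' @param ... passed to the single-source lead-field routine.
#' @return list: leadfields (list, NULL for outside points), inside
#'   (logical), positions.
#' @export
leadfield_grid <- function(grid_pos, sensors, model, ...) {
  grid_pos <- as.matrix(grid_pos)
  ctr <- model$center
  rel <- sweep(grid_pos, 2, ctr)
  inside <- sqrt(rowSums(rel^2)) < model$radii[1]
  lf <- vector("list", nrow(grid_pos))
  for (i in which(inside)) {
    lf[[i]] <- if (sensors$kind == "meg") {
      meg_single_sphere(grid_pos[i, ], sensors, model)
    } else {
      eeg_concentric_spheres(grid_pos[i, ], sensors, model, ...)
    }
  }
  list(leadfields = lf, inside = inside, positions = grid_pos)
}

#' Regular grid positions from a bounding box and spacing
#'
#' @param lower,upper 3-vectors, meters.
#' @param spacing grid step, meters (> 0).
#' @return M x 3 matrix.
#' @export
make_grid <- function(lower, upper, spacing) {
  stopifnot(spacing > 0)
  ax <- lapply(1:3, function(d) seq(lower[d], upper[d], by = spacing))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}
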