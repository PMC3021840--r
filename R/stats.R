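# Statistical inference on channel x time(-frequency) maps: per-sample t
# statistics, Bonferroni correction, and the nonparametric cluster-based
# permutation framework controlling the family-wise error rate.

#' Per-sample t statistic between two conditions
#'
#' Observations are rows (subjects or trials), samples are columns (e.g.
#' flattened channel x time).  The independent design uses the two-sample
#' Welch statistic; the dependent design the paired t statistic.  Samples
#' with zero difference variance in the dependent design get statistic 0 by
#' convention (flagged via the `degenerate` attribute).
#'
#' @param condition_a observations x samples matrix.
#' @param condition_b observations x samples matrix.
#' @param design "independent" or "dependent".
#' @return numeric vector of t statistics per sample.
#' @export
sample_statistic <- function(condition_a, condition_b,
                             design = c("independent", "dependent")) {
  design <- match.arg(design)
  A <- as.matrix(condition_a); B <- as.matrix(condition_b)
  stopifnot(ncol(A) == ncol(B))
  if (design == "dependent") {
    if (nrow(A) != nrow(B)) stop("dependent design requires paired observations")
    stopifnot(nrow(A) >= 2)
    D <- A - B
    n <- nrow(D)
    m <- colMeans(D)
    s2 <- (colSums(D^2) - n * m^2) / (n - 1)
    t <- ifelse(s2 > 0, m / sqrt(s2 / n), 0)
    attr(t, "degenerate") <- s2 <= 0 & abs(m) > 0
    t
  } else {
    stopifnot(nrow(A) >= 2, nrow(B) >= 2)
    na <- nrow(A); nb <- nrow(B)
    va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
    se <- sqrt(va / na + vb / nb)
    t <- ifelse(se > 0, (colMeans(A) - colMeans(B)) / se, 0)
    attr(t, "degenerate") <- se <= 0 & abs(colMeans(A) - colMeans(B)) > 0
    t
  }
}

#' Spatial adjacency from channel positions
#'
#' Channels are neighbours iff their Euclidean distance is strictly below
#' the threshold.  Symmetric with a false diagonal.
#'
#' @param positions channels x 3 matrix, meters.
#' @param distance_threshold meters (> 0).
#' @return logical channels x channels matrix.
#' @export
build_adjacency <- function(positions, distance_threshold) {
  if (distance_threshold <= 0) stop("distance threshold must be > 0")
  positions <- as.matrix(positions)
  d <- as.matrix(stats::dist(positions))
  adj <- d < distance_threshold
  diag(adj) <- FALSE
  adj
}

#' Connected clusters of suprathreshold samples (pure R)
#'
#' Reference implementation of the clustering step over a channel x time
#' map: samples are adjacent along time (consecutive) and across spatially
#' neighbouring channels at the same time point.  Positive and negative
#' suprathreshold samples cluster separately.
#'
#' @param stat channel x time statistic matrix.
#' @param adjacency logical channel x channel matrix.
#' @param threshold positive cluster-forming threshold (applied as |t| >
#'   threshold).
#' @return list of clusters: members (2-column matrix of channel, time
#'   indices), mass, sign.
#' @export
find_clusters <- function(stat, adjacency, threshold) {
  nch <- nrow(stat); nt <- ncol(stat)
  visited <- matrix(FALSE, nch, nt)
  nbs <- lapply(seq_len(nch), function(c) which(adjacency[c, ]))
  clusters <- list()
  for (c0 in seq_len(nch)) for (t0 in seq_len(nt)) {
    v0 <- stat[c0, t0]
    if (visited[c0, t0] || abs(v0) <= threshold) next
    sgn <- sign(v0)
    stack <- list(c(c0, t0))
    visited[c0, t0] <- TRUE
    members <- matrix(0L, 0, 2)
    mass <- 0
    while (length(stack)) {
      s <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members <- rbind(members, s)
      mass <- mass + stat[s[1], s[2]]
      cand <- rbind(
        if (s[2] > 1) c(s[1], s[2] - 1),
        if (s[2] < nt) c(s[1], s[2] + 1),
        if (length(nbs[[s[1]]])) cbind(nbs[[s[1]]], s[2]))
      for (r in seq_len(NROW(cand))) {
        cc <- cand[r, 1]; tt <- cand[r, 2]
        if (!visited[cc, tt] && sign(stat[cc, tt]) == sgn &&
            abs(stat[cc, tt]) > threshold) {
          visited[cc, tt] <- TRUE
          stack[[length(stack) + 1]] <- c(cc, tt)
        }
      }
    }
    dimnames(members) <- list(NULL, c("channel", "time"))
    clusters[[length(clusters) + 1]] <- list(members = members, mass = mass,
                                             sign = sgn)
  }
  clusters
}

permute_tmaps <- function(A, B, design, nperm) {
  S <- ncol(A)
  if (design == "dependent") {
    D <- A - B
    n <- nrow(D)
    ss <- colSums(D^2)
    # Bernoulli(0.5) within-pair swaps = sign flips of the differences
    signs <- matrix(sample(c(-1, 1), nperm * n, replace = TRUE), nperm, n)
    sums <- signs %*% D
    m <- sums / n
    s2 <- sweep(-n * m^2, 2, ss, "+") / (n - 1)
    t <- m / sqrt(pmax(s2, 0) / n)
    t[!is.finite(t)] <- 0
    t
  } else {
    X <- rbind(A, B)
    N <- nrow(X); na <- nrow(A)
    X2 <- X^2
    t <- matrix(0, nperm, S)
    csum <- colSums(X); csum2 <- colSums(X2)
    for (p in seq_len(nperm)) {
      idx <- sample.int(N, na)
      sa <- colSums(X[idx, , drop = FALSE])
      sa2 <- colSums(X2[idx, , drop = FALSE])
      sb <- csum - sa; sb2 <- csum2 - sa2
      nb <- N - na
      ma <- sa / na; mb <- sb / nb
      va <- (sa2 - na * ma^2) / (na - 1)
      vb <- (sb2 - nb * mb^2) / (nb - 1)
      se <- sqrt(pmax(va, 0) / na + pmax(vb, 0) / nb)
      tp <- (ma - mb) / se
      tp[!is.finite(tp)] <- 0
      t[p, ] <- tp
    }
    t
  }
}

#' Cluster-based permutation test
#'
#' Nonparametric control of the family-wise error over a channel x time
#' map: (1) per-sample t statistics; (2) two-sided cluster-forming
#' threshold at the `cluster_alpha` quantile of the t reference
#' distribution; (3) suprathreshold samples clustered by spatial adjacency
#' and temporal contiguity; (4) cluster mass = summed statistic; (5) a
#' permutation distribution of the maximum |mass| built by relabeling
#' (independent design: random reassignment of condition labels; dependent:
#' Bernoulli(0.5) within-pair swaps); (6) Monte-Carlo cluster p-values with
#' the +1/+1 convention (never zero, bounded below by 1/(n_permutations+1)).
#'
#' @param condition_a,condition_b observations x (channels * times)
#'   matrices, channel-major flattening (sample = channel + nchan * time).
#' @param n_channels number of channels (columns = n_channels * n_times).
#' @param adjacency logical channel x channel matrix.
#' @param design "independent" or "dependent".
#' @param cluster_alpha cluster-forming alpha (two-sided; default 0.05).
#' @param n_permutations Monte-Carlo permutations (>= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `cluster_result`: clusters (members as channel,
#'   time index matrix; mass; sign), p_values, threshold,
#'   observed_stat (channel x time), perm_max (permutation maxima of
#'   |mass|), n_permutations.
#' @export
cluster_permutation_test <- function(condition_a, condition_b, n_channels,
                                     adjacency,
                                     design = c("independent", "dependent"),
                                     cluster_alpha = 0.05,
                                     n_permutations = 1000, seed) {
  design <- match.arg(design)
  stopifnot(n_permutations >= 100, cluster_alpha > 0, cluster_alpha < 1)
  if (missing(seed)) stop("an explicit seed is required")
  A <- as.matrix(condition_a); B <- as.matrix(condition_b)
  S <- ncol(A)
  stopifnot(S %% n_channels == 0)
  nt <- S %/% n_channels
  if (design == "dependent" && nrow(A) != nrow(B))
    stop("dependent design requires equal (paired) observation counts")
  dof <- if (design == "dependent") nrow(A) - 1 else nrow(A) + nrow(B) - 2
  threshold <- stats::qt(1 - cluster_alpha / 2, dof)
  t_obs <- sample_statistic(A, B, design)
  obs_map <- matrix(t_obs, n_channels, nt)
  clusters <- find_clusters(obs_map, adjacency, threshold)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tperm <- permute_tmaps(A, B, design, n_permutations)
  ext <- perm_cluster_extremes(tperm, n_channels, nt, adjacency, threshold)
  perm_max <- pmax(ext[, 1], -ext[, 2])
  p_values <- vapply(clusters, function(cl) {
    (sum(perm_max >= abs(cl$mass)) + 1) / (n_permutations + 1)
  }, numeric(1))
  structure(list(clusters = clusters, p_values = p_values,
                 threshold = threshold, observed_stat = obs_map,
                 perm_max = perm_max, n_permutations = n_permutations,
                 design = design, seed = seed),
            class = "cluster_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Parametric multiple-comparison correction
#'
#' @param p numeric vector/array of p-values in [0, 1].
#' @param alpha family-wise alpha.
#' @param method "none" or "bonferroni".
#' @return logical significance mask of the same shape (closed threshold:
#'   p equal to the corrected level counts as significant).
#' @export
parametric_correction <- function(p, alpha = 0.05,
                                  method = c("bonferroni", "none")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  thr <- if (method == "bonferroni") alpha / length(p) else alpha
  mask <- p <= thr
  mask
}

#' Export a cluster result as JSON
#'
#' @param result `cluster_result`.
#' @param path output path.
#' @return invisible path.
#' @export
write_cluster_result <- function(result, path) {
  out <- list(
    n_permutations = result$n_permutations,
    threshold = result$threshold,
    clusters = lapply(seq_along(result$clusters), function(i) {
      cl <- result$clusters[[i]]
      list(channel = cl$members[, 1], time = cl$members[, 2],
           mass = cl$mass, sign = cl$sign, p = result$p_values[i])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
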