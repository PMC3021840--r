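# Semi-automatic artifact handling: channels are transformed to emphasize a
# given artifact class (SQUID jumps, muscle), z-scored against statistics
# pooled over all trials (so artifact-free data calibrate the null),
# summed over channels and thresholded.

analytic_envelope <- function(v) {
  n <- length(v)
  X <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# median filter with edge-replication padding: avoids the inflated
# first-difference values the shrinking-window edge rule produces, which
# would otherwise dominate the null distribution of the jump statistic
medfilt_padded <- function(tr, k) {
  h <- (k - 1L) %/% 2L
  t(apply(tr, 1, function(v) {
    vp <- c(rep(v[1], h), v, rep(v[length(v)], h))
    as.numeric(stats::runmed(vp, k, endrule = "keep"))[(h + 1):(h + length(v))]
  }))
}

artifact_transform <- function(tr, transform, sample_rate, jump_kernel = 9L) {
  if (inherits(transform, "filter_spec")) {
    return(abs(filter_data(tr, sample_rate, transform)))
  }
  switch(transform,
    jump = {
      # median filtering suppresses noise and physiology but preserves the
      # sharp step of a flux jump; its first difference spikes at the edge
      sm <- medfilt_padded(tr, jump_kernel)
      t(apply(sm, 1, function(v) c(0, abs(diff(v)))))
    },
    muscle = {
      if (sample_rate <= 220)
        stop("muscle transform needs sample_rate > 220 Hz (110-140 Hz band unreachable)")
      hi <- min(140, sample_rate / 2 * 0.95)
      spec <- filter_spec("butterworth_iir", "bandpass", c(110, hi), order = 4)
      flt <- filter_data(tr, sample_rate, spec)
      t(apply(flt, 1, analytic_envelope))
    },
    none = abs(tr),
    stop("unknown transform: ", transform)
  )
}

#' Detect artifacts by z-value thresholding
#'
#' Per channel the data are transformed to emphasize the artifact
#' (`"jump"`: absolute first difference of the median-filtered signal;
#' `"muscle"`: 110-140 Hz bandpass, analytic-signal amplitude
#' envelope; `"none"`: absolute value; or a custom [filter_spec()]),
#' z-scored with mean and standard deviation pooled over all trials, and
#' accumulated over channels as `sum(z) / sqrt(n_channels)` (so the
#' statistic stays unit-variance under the null whatever the channel
#' count).  Samples whose accumulated z exceeds the threshold form
#' artifact segments; segments closer than `pad_s` are merged and each
#' segment is expanded by `pad_s` on both sides.
#'
#' @param data `meeg_raw`.
#' @param transform "jump", "muscle", "none", or a `filter_spec`.
#' @param z_threshold positive z cutoff on the channel-summed z score.
#' @param pad_s padding/merging window in seconds.
#' @param jump_kernel median-filter kernel for the jump transform (samples).
#' @return data.frame of class `artifact_segments`: trial_index,
#'   begin_sample, end_sample (trial-local, 0-based half-open), peak_z.
#' @export
detect_artifacts_z <- function(data, transform = "jump", z_threshold = 10,
                               pad_s = 0.1, jump_kernel = 9L) {
  stopifnot(inherits(data, "meeg_raw"), z_threshold > 0)
  tf <- lapply(data$trials, artifact_transform, transform = transform,
               sample_rate = data$sample_rate, jump_kernel = jump_kernel)
  pooled <- do.call(cbind, tf)
  mu <- rowMeans(pooled)
  sd <- apply(pooled, 1, stats::sd)
  sd[sd == 0] <- 1
  pad <- round(pad_s * data$sample_rate)
  out <- list()
  for (k in seq_along(tf)) {
    z <- colSums((tf[[k]] - mu) / sd) / sqrt(nrow(tf[[k]]))
    above <- which(z > z_threshold)
    if (!length(above)) next
    # group samples whose gaps are < merge window
    grp <- cumsum(c(1, diff(above) > pad))
    for (g in unique(grp)) {
      s <- above[grp == g]
      b <- max(0L, min(s) - 1L - pad)
      e <- min(ncol(tf[[k]]), max(s) + pad)
      out[[length(out) + 1]] <- data.frame(
        trial_index = k, begin_sample = b, end_sample = e,
        peak_z = max(z[s]))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(trial_index = integer(0), begin_sample = integer(0),
               end_sample = integer(0), peak_z = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("artifact_segments", "data.frame")
  res
}

#' Remove detected artifact segments
#'
#' @param data `meeg_raw`.
#' @param segments `artifact_segments` table.
#' @param mode "remove_trial" drops every trial touched by a segment;
#'   "nan_fill" replaces the samples inside segments with NA (downstream
#'   spectral/statistics operations error on such samples by contract).
#' @return `meeg_raw`.
#' @export
reject_segments <- function(data, segments, mode = c("remove_trial", "nan_fill")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "meeg_raw"))
  if (nrow(segments) && any(segments$trial_index > length(data$trials)))
    stop("segment references a nonexistent trial")
  if (mode == "remove_trial") {
    bad <- unique(segments$trial_index)
    keep <- setdiff(seq_along(data$trials), bad)
    data$trials <- data$trials[keep]
    data$time <- data$time[keep]
    prm <- list(mode = mode, removed_trials = bad)
  } else {
    for (r in seq_len(nrow(segments))) {
      k <- segments$trial_index[r]
      cols <- (segments$begin_sample[r] + 1):segments$end_sample[r]
      cols <- cols[cols >= 1 & cols <= ncol(data$trials[[k]])]
      data$trials[[k]][, cols] <- NA_real_
    }
    prm <- list(mode = mode, n_segments = nrow(segments))
  }
  data$provenance <- append_provenance(list(data$provenance),
                                       "reject_segments", prm)
  data
}

#' Principal component decomposition of multichannel data
#'
#' Components are eigenvectors of the channel covariance pooled over trials
#' (per-trial demeaned), ordered by decreasing eigenvalue.  Component time
#' courses are obtained by applying the unmixing matrix to the (raw,
#' un-demeaned) data, so that back-projecting all components reproduces the
#' data exactly.
#'
#' @param data `meeg_raw`.
#' @param n_components number of components to keep (default: all).
#' @return list of class `meeg_decomposition`: mixing (channels x comp),
#'   unmixing (comp x channels), timecourses (per trial, comp x samples),
#'   explained_variance (fraction per component), eigenvalues.
#' @export
pca_decompose <- function(data, n_components = NULL) {
  stopifnot(inherits(data, "meeg_raw"))
  nch <- n_channels(data)
  if (is.null(n_components)) n_components <- nch
  if (n_components > nch)
    stop(sprintf("n_components (%d) exceeds channel count (%d)",
                 n_components, nch))
  total <- sum(vapply(data$trials, ncol, integer(1)))
  if (total < nch) stop("fewer total samples than channels")
  demeaned <- lapply(data$trials, function(tr) tr - rowMeans(tr))
  X <- do.call(cbind, demeaned)
  C <- tcrossprod(X) / (ncol(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  if (n_components > rank)
    stop(sprintf("covariance rank is %d, cannot extract %d components",
                 rank, n_components))
  V <- eg$vectors[, seq_len(n_components), drop = FALSE]
  structure(list(
    mixing = V,
    unmixing = t(V),
    timecourses = lapply(data$trials, function(tr) t(V) %*% tr),
    explained_variance = ev[seq_len(n_components)] / sum(ev),
    eigenvalues = ev
  ), class = "meeg_decomposition")
}

#' Remove components from the data
#'
#' Subtracts the back-projection of the selected components:
#' `data - mixing[, idx] %*% timecourses[idx, ]`.  Removing no components is
#' the identity; removing all components (full decomposition) zeroes the
#' data.
#'
#' @param data `meeg_raw` (the object the decomposition was computed from).
#' @param decomposition `meeg_decomposition`.
#' @param indices integer component indices to remove (may be empty).
#' @return `meeg_raw`.
#' @export
remove_components <- function(data, decomposition, indices) {
  stopifnot(inherits(data, "meeg_raw"),
            inherits(decomposition, "meeg_decomposition"))
  ncomp <- ncol(decomposition$mixing)
  stopifnot(all(indices >= 1), all(indices <= ncomp))
  if (length(indices)) {
    M <- decomposition$mixing[, indices, drop = FALSE]
    data$trials <- mapply(function(tr, tc) {
      tr - M %*% tc[indices, , drop = FALSE]
    }, data$trials, decomposition$timecourses, SIMPLIFY = FALSE)
  }
  data$provenance <- append_provenance(list(data$provenance),
                                       "remove_components",
                                       list(indices = indices))
  data
}

#' Export an artifact report as CSV
#'
#' @param segments `artifact_segments`.
#' @param sample_rate Hz, to convert samples to seconds.
#' @param path output CSV path.
#' @return invisible path.
#' @export
write_artifact_report <- function(segments, sample_rate, path) {
  df <- data.frame(trial = segments$trial_index,
                   begin_s = segments$begin_sample / sample_rate,
                   end_s = segments$end_sample / sample_rate,
                   peak_z = segments$peak_z)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
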