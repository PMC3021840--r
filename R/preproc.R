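#' Filter specification
#'
#' @param family "butterworth_iir" or "windowed_sinc_fir".
#' @param band "lowpass", "highpass", "bandpass" or "bandstop".
#' @param cutoffs one cutoff in Hz (lowpass/highpass) or two, low < high.
#' @param order filter order (default 4; twopass doubles the effective
#'   order).
#' @param direction "twopass_zerophase" (default) or "onepass".
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(family = "butterworth_iir", band, cutoffs, order = 4L,
                        direction = "twopass_zerophase") {
  family <- match.arg(family, c("butterworth_iir", "windowed_sinc_fir"))
  band <- match.arg(band, c("lowpass", "highpass", "bandpass", "bandstop"))
  direction <- match.arg(direction, c("onepass", "twopass_zerophase"))
  if (band %in% c("bandpass", "bandstop")) {
    stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  } else {
    stopifnot(length(cutoffs) == 1)
  }
  stopifnot(all(cutoffs > 0), order >= 1)
  structure(list(family = family, band = band, cutoffs = cutoffs,
                 order = as.integer(order), direction = direction),
            class = "filter_spec")
}

design_filter <- function(spec, sample_rate) {
  nyq <- sample_rate / 2
  if (any(spec$cutoffs >= nyq))
    stop(sprintf("cutoff %g Hz at or above Nyquist (%g Hz)",
                 max(spec$cutoffs), nyq))
  W <- spec$cutoffs / nyq
  type <- switch(spec$band, lowpass = "low", highpass = "high",
                 bandpass = "pass", bandstop = "stop")
  if (spec$family == "butterworth_iir") {
    flt <- signal::butter(spec$order, W, type = type)
    poles <- polyroot(rev(flt$a))
    if (any(Mod(poles) >= 1 - 1e-12))
      stop("unstable IIR design (pole magnitude >= 1); lower the filter order")
    flt
  } else {
    b <- signal::fir1(spec$order, W, type = type)
    list(b = as.numeric(b), a = 1)
  }
}

apply_filter_1d <- function(x, flt, direction, order, npad) {
  npad <- min(npad, length(x) - 1L)
  # mirror padding bounds edge transients without changing length
  pad <- c(2 * x[1] - x[seq(npad + 1, 2)], x, 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)])
  y <- as.numeric(signal::filter(flt$b, flt$a, pad))
  if (direction == "twopass_zerophase") {
    y <- rev(as.numeric(signal::filter(flt$b, flt$a, rev(y))))
  }
  y[(npad + 1):(npad + length(x))]
}

#' Filter multichannel data
#'
#' Applies the specified filter to every row (channel) of a continuous data
#' matrix.  The default two-pass direction runs the filter forward and
#' backward, giving zero phase distortion at the cost of doubling the
#' effective order.  Data are mirror-padded by three filter orders before
#' filtering to bound edge transients.
#'
#' @param x channels x samples numeric matrix.
#' @param sample_rate Hz.
#' @param spec a `filter_spec`.
#' @return filtered matrix, same shape.
#' @export
filter_data <- function(x, sample_rate, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) <= 3 * spec$order)
    stop("too few samples for the requested filter order")
  flt <- design_filter(spec, sample_rate)
  # the mean sits in the stopband of highpass/bandpass filters; removing it
  # beforehand kills the DC edge transient exactly
  mu <- if (spec$band %in% c("highpass", "bandpass")) rowMeans(x) else
    numeric(nrow(x))
  # padding long enough for the slowest transient (low cutoffs need more)
  npad <- max(3L * spec$order,
              ceiling(sample_rate / min(spec$cutoffs)))
  out <- t(apply(x - mu, 1, apply_filter_1d, flt = flt,
                 direction = spec$direction, order = spec$order, npad = npad))
  dimnames(out) <- dimnames(x)
  out
}

#' Re-reference channels
#'
#' Subtracts the mean of the reference channels (or the mean across all
#' channels, `reference = "average"`) from every channel.
#'
#' @param x channels x samples matrix.
#' @param labels channel labels matching the rows of `x`.
#' @param reference "average" or a character vector of reference labels.
#' @return re-referenced matrix, same shape.
#' @export
rereference <- function(x, labels, reference = "average") {
  stopifnot(nrow(x) == length(labels))
  if (identical(reference, "average")) {
    ref <- colMeans(x)
  } else {
    idx <- match(reference, labels)
    if (anyNA(idx))
      stop("unknown reference label(s): ",
           paste(reference[is.na(idx)], collapse = ", "))
    ref <- colMeans(x[idx, , drop = FALSE])
  }
  sweep(x, 2, ref, "-")
}

#' Baseline-correct using a time window
#'
#' Subtracts, per channel, the mean over the samples whose time falls in the
#' closed interval `[t0, t1]` (endpoints inclusive, with half-a-sample
#' tolerance).
#'
#' @param x channels x samples matrix.
#' @param time time axis in seconds (length = ncol(x)).
#' @param window numeric length-2, `c(t0, t1)`.
#' @return corrected matrix.
#' @export
baseline_correct <- function(x, time, window) {
  stopifnot(length(time) == ncol(x), length(window) == 2)
  half <- if (length(time) > 1) (time[2] - time[1]) / 2 else 0
  sel <- time >= window[1] - half & time <= window[2] + half
  if (!any(sel)) stop("baseline window does not overlap the time axis")
  sweep(x, 1, rowMeans(x[, sel, drop = FALSE]), "-")
}

#' Remove a linear trend per channel
#'
#' Least-squares removal of intercept and slope; the output is orthogonal to
#' the constant and linear regressors.
#'
#' @param x channels x samples matrix.
#' @return detrended matrix.
#' @export
detrend_linear <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  stopifnot(n >= 2)
  t <- seq_len(n) - (n + 1) / 2           # centered regressor
  slope <- (x %*% t) / sum(t * t)
  x - rowMeans(x) %o% rep(1, n) - slope %*% t
}

#' Sliding median filter per channel
#'
#' Interior samples use the full odd-length kernel; edges use a symmetric
#' window shrunk to fit (so the first and last samples pass through
#' unchanged).
#'
#' @param x channels x samples matrix (or vector).
#' @param kernel_length odd integer >= 3.
#' @return filtered data, same shape.
#' @export
median_filter <- function(x, kernel_length) {
  if (kernel_length %% 2 == 0 || kernel_length < 3)
    stop("kernel_length must be an odd integer >= 3")
  vec_in <- is.vector(x)
  if (vec_in) x <- matrix(x, nrow = 1)
  h <- (kernel_length - 1) %/% 2
  n <- ncol(x)
  out <- t(apply(x, 1, function(v) {
    if (n >= kernel_length) {
      y <- as.numeric(stats::runmed(v, kernel_length, endrule = "keep"))
    } else {
      y <- v
    }
    edge <- seq_len(min(h, n))
    for (i in edge) {                      # symmetric shrinking window
      hh <- i - 1
      y[i] <- stats::median(v[(i - hh):(i + hh)])
      j <- n - i + 1
      y[j] <- stats::median(v[(j - hh):(j + hh)])
    }
    y
  }))
  if (vec_in) out[1, ] else out
}

#' Segment continuous data into trials
#'
#' Cuts the columns of a continuous recording into (possibly variable
#' length) trials according to a trial table (0-based half-open sample
#' ranges, see [define_trials()]).  The time axis of trial k is
#' `(offset_k + 0:(len-1)) / sample_rate`, so t = 0 marks the trigger.
#'
#' @param continuous channels x samples matrix.
#' @param sample_rate Hz.
#' @param channels `meeg_channels` or character labels.
#' @param trial_table data.frame begin_sample, end_sample, offset_samples.
#' @param provenance optional provenance of the continuous input.
#' @return `meeg_raw`.
#' @export
segment_data <- function(continuous, sample_rate, channels, trial_table,
                         provenance = NULL) {
  ns <- ncol(continuous)
  trials <- vector("list", nrow(trial_table))
  time <- vector("list", nrow(trial_table))
  for (k in seq_len(nrow(trial_table))) {
    b <- trial_table$begin_sample[k]
    e <- trial_table$end_sample[k]
    if (b < 0 || e > ns)
      stop(sprintf("trial row %d out of bounds: [%d, %d) vs %d samples",
                   k, b, e, ns))
    trials[[k]] <- continuous[, (b + 1):e, drop = FALSE]
    off <- trial_table$offset_samples[k]
    time[[k]] <- (off + seq_len(e - b) - 1) / sample_rate
  }
  prev <- if (is.null(provenance)) list() else list(provenance)
  raw_data(trials, time, channels, sample_rate,
           append_provenance(prev, "segment_data",
                             list(n_trials = nrow(trial_table))))
}

#' Apply a per-channel operation to every trial of a raw object
#'
#' Convenience wrapper keeping channel metadata, time axes and provenance
#' consistent.
#'
#' @param data `meeg_raw`.
#' @param fun function(matrix, time) -> matrix of the same shape.
#' @param step_name provenance step name.
#' @param parameters provenance parameters.
#' @return `meeg_raw`.
#' @export
apply_to_trials <- function(data, fun, step_name = "apply_to_trials",
                            parameters = list()) {
  stopifnot(inherits(data, "meeg_raw"))
  data$trials <- mapply(function(tr, tm) fun(tr, tm), data$trials, data$time,
                        SIMPLIFY = FALSE)
  data$provenance <- append_provenance(list(data$provenance), step_name,
                                       parameters)
  data
}
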