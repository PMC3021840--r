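#' Channel description table
#'
#' Channels are identified by unique labels; positions (meters, head frame)
#' are optional, the kind distinguishes EEG electrodes from MEG magnetometers
#' and gradiometers, and the unit records the SI unit of the stored samples.
#'
#' @param label character vector of unique channel labels.
#' @param position optional numeric matrix n x 3 (meters), NA rows allowed.
#' @param kind character vector in `c("eeg","meg_mag","meg_grad","other")`.
#' @param unit character vector of SI unit strings ("V", "T", ...).
#' @return data.frame of class `meeg_channels` with columns label, kind,
#'   unit, x, y, z.
#' @export
channel_info <- function(label, position = NULL, kind = "other", unit = "V") {
  label <- as.character(label)
  n <- length(label)
  if (anyDuplicated(label))
    stop("channel labels must be unique; duplicated: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  kind <- rep_len(as.character(kind), n)
  bad <- setdiff(unique(kind), c("eeg", "meg_mag", "meg_grad", "other"))
  if (length(bad)) stop("unknown channel kind: ", paste(bad, collapse = ", "))
  unit <- rep_len(as.character(unit), n)
  if (is.null(position)) {
    position <- matrix(NA_real_, n, 3)
  } else {
    position <- as.matrix(position)
    stopifnot(nrow(position) == n, ncol(position) == 3)
    if (any(!is.finite(position) & !is.na(position)))
      stop("channel positions must be finite when present")
  }
  structure(
    data.frame(label = label, kind = kind, unit = unit,
               x = position[, 1], y = position[, 2], z = position[, 3],
               stringsAsFactors = FALSE),
    class = c("meeg_channels", "data.frame")
  )
}

channel_positions <- function(channels) {
  as.matrix(channels[, c("x", "y", "z")])
}

#' Trial-based raw data object
#'
#' The central container: a list of channels x timepoints matrices (one per
#' trial, lengths may differ across trials), a matching list of time axes in
#' seconds (t = 0 marks the trigger; spacing 1/sample_rate), channel
#' metadata, and nested provenance.
#'
#' @param trials list of numeric matrices, each channels x timepoints.
#' @param time list of numeric vectors (seconds), one per trial.
#' @param channels a `meeg_channels` table (or character labels).
#' @param sample_rate sampling rate in Hz.
#' @param provenance optional `meeg_prov`; a root node is created if NULL.
#' @return object of class `meeg_raw`.
#' @export
raw_data <- function(trials, time, channels, sample_rate, provenance = NULL) {
  if (is.character(channels)) channels <- channel_info(channels)
  if (is.matrix(trials)) trials <- list(trials)
  if (is.numeric(time) && !is.list(time)) time <- list(time)
  if (is.null(provenance))
    provenance <- append_provenance(list(), "raw_data",
                                    list(sample_rate = sample_rate))
  obj <- structure(
    list(trials = trials, time = time, channels = channels,
         sample_rate = sample_rate, provenance = provenance),
    class = "meeg_raw"
  )
  v <- validate(obj)
  if (length(v)) stop("invalid raw data: ", paste(v, collapse = "; "))
  obj
}

#' Trial-averaged (timelocked) data
#'
#' @param average channels x timepoints matrix.
#' @param variance same shape, across-trial variance (>= 0).
#' @param dof integer vector per timepoint (trials contributing).
#' @param time time axis in seconds, shared across channels.
#' @param channels `meeg_channels` table.
#' @param provenance `meeg_prov`.
#' @return object of class `meeg_timelock`.
#' @export
timelock_data <- function(average, variance, dof, time, channels, provenance = NULL) {
  if (is.character(channels)) channels <- channel_info(channels)
  if (is.null(provenance))
    provenance <- append_provenance(list(), "timelock_data", list())
  obj <- structure(
    list(average = average, variance = variance, dof = as.integer(dof),
         time = time, channels = channels, provenance = provenance),
    class = "meeg_timelock"
  )
  v <- validate(obj)
  if (length(v)) stop("invalid timelock data: ", paste(v, collapse = "; "))
  obj
}

#' Frequency-domain data
#'
#' Holds a one-sided power spectral density (unit^2/Hz) per channel and
#' frequency (optionally x time for time-frequency estimates), optionally the
#' cross-spectral density for ordered channel pairs (i < j; the (j,i) entry
#' is the conjugate, returned on query), and optionally the raw complex
#' Fourier coefficients per trial-taper observation.
#'
#' @param power channel x freq (or channel x freq x time) non-negative array.
#' @param freq strictly increasing frequency axis, Hz.
#' @param channels `meeg_channels`.
#' @param cross optional pair x freq (x time) complex array; rows follow
#'   `pairs`.
#' @param pairs optional 2-column integer matrix of (i, j), i < j.
#' @param fourier optional complex array obs x channel x freq.
#' @param obs_trial optional integer vector mapping fourier rows to trials.
#' @param time optional time axis (seconds) for time-resolved estimates.
#' @param taper_count integer, tapers per frequency.
#' @param provenance `meeg_prov`.
#' @return object of class `meeg_freq`.
#' @export
freq_data <- function(power, freq, channels, cross = NULL, pairs = NULL,
                      fourier = NULL, obs_trial = NULL, time = NULL,
                      taper_count = 1L, provenance = NULL) {
  if (is.character(channels)) channels <- channel_info(channels)
  if (is.null(provenance))
    provenance <- append_provenance(list(), "freq_data", list())
  obj <- structure(
    list(power = power, freq = freq, channels = channels, cross = cross,
         pairs = pairs, fourier = fourier, obs_trial = obs_trial,
         time = time, taper_count = as.integer(taper_count),
         provenance = provenance),
    class = "meeg_freq"
  )
  v <- validate(obj)
  if (length(v)) stop("invalid freq data: ", paste(v, collapse = "; "))
  obj
}

#' Query the cross-spectrum of an ordered channel pair
#'
#' Cross-spectra are stored once per unordered pair (i < j); querying (j, i)
#' returns the complex conjugate, and (i, i) returns the power spectrum.
#'
#' @param fd `meeg_freq` with cross spectra.
#' @param i,j channel indices or labels.
#' @return complex vector over frequency (x time).
#' @export
get_cross <- function(fd, i, j) {
  stopifnot(inherits(fd, "meeg_freq"))
  if (is.character(i)) i <- match(i, fd$channels$label)
  if (is.character(j)) j <- match(j, fd$channels$label)
  if (is.na(i) || is.na(j)) stop("unknown channel label")
  if (i == j) {
    return(if (length(dim(fd$power)) == 3) fd$power[i, , ] + 0i else fd$power[i, ] + 0i)
  }
  if (is.null(fd$cross)) stop("no cross-spectra stored in this object")
  conj_it <- i > j
  key <- if (conj_it) c(j, i) else c(i, j)
  row <- which(fd$pairs[, 1] == key[1] & fd$pairs[, 2] == key[2])
  if (!length(row)) stop("pair not stored: ", i, ",", j)
  val <- if (length(dim(fd$cross)) == 3) fd$cross[row, , ] else fd$cross[row, ]
  if (conj_it) Conj(val) else val
}

n_channels <- function(data) nrow(data$channels)

#' Validate a data object against its invariants
#'
#' Returns a character vector describing every violated invariant (empty for
#' a valid object); never raises on malformed content.
#'
#' @param data a `meeg_raw`, `meeg_timelock` or `meeg_freq` object.
#' @return character vector of violation descriptions.
#' @export
validate <- function(data) UseMethod("validate")

#' @export
validate.meeg_raw <- function(data) {
  v <- character(0)
  if (anyDuplicated(data$channels$label))
    v <- c(v, "duplicate channel labels")
  if (length(data$trials) != length(data$time))
    v <- c(v, sprintf("trial count (%d) != time axis count (%d)",
                      length(data$trials), length(data$time)))
  nch <- n_channels(data)
  for (k in seq_along(data$trials)) {
    tr <- data$trials[[k]]
    if (!is.matrix(tr) || nrow(tr) != nch)
      v <- c(v, sprintf("trial %d: row count != channel count (%d)", k, nch))
    if (k <= length(data$time)) {
      tm <- data$time[[k]]
      if (is.matrix(tr) && ncol(tr) != length(tm))
        v <- c(v, sprintf("trial %d: %d columns but %d time points", k, ncol(tr), length(tm)))
      if (length(tm) > 1) {
        d <- diff(tm)
        if (any(d <= 0))
          v <- c(v, sprintf("trial %d: time axis not strictly increasing", k))
        if (any(abs(d - 1 / data$sample_rate) > 1e-9))
          v <- c(v, sprintf("trial %d: time spacing != 1/sample_rate", k))
      }
    }
  }
  v
}

#' @export
validate.meeg_timelock <- function(data) {
  v <- character(0)
  if (!all(dim(data$average) == dim(data$variance)))
    v <- c(v, "average and variance shapes differ")
  if (any(data$variance < 0, na.rm = TRUE))
    v <- c(v, "negative variance entries")
  if (any(data$dof < 1))
    v <- c(v, "dof < 1")
  if (nrow(data$average) != n_channels(data))
    v <- c(v, "average row count != channel count")
  if (ncol(data$average) != length(data$time))
    v <- c(v, "average column count != time axis length")
  v
}

#' @export
validate.meeg_freq <- function(data) {
  v <- character(0)
  neg <- which(data$power < -1e-300, arr.ind = TRUE)
  if (NROW(neg))
    v <- c(v, sprintf("negative power at index [%s]",
                      paste(neg[1, ], collapse = ",")))
  if (is.unsorted(data$freq, strictly = TRUE))
    v <- c(v, "frequency axis not strictly increasing")
  if (dim(data$power)[1] != n_channels(data))
    v <- c(v, "power first dimension != channel count")
  if (!is.null(data$cross) && is.null(data$pairs))
    v <- c(v, "cross present without pair table")
  v
}

#' Select channels by label patterns
#'
#' Patterns are exact labels or glob-style wildcards ("MEG*"); the output
#' contains exactly the matched channels, in selection order, with all
#' arrays sliced consistently and a provenance step appended.
#'
#' @param data a `meeg_raw`, `meeg_timelock` or `meeg_freq` object.
#' @param selection non-empty character vector of label patterns.
#' @return object of the same class, restricted to the matched channels.
#' @export
select_channels <- function(data, selection) UseMethod("select_channels")

match_selection <- function(labels, selection) {
  stopifnot(length(selection) >= 1)
  idx <- integer(0)
  unmatched <- character(0)
  for (pat in selection) {
    hits <- if (grepl("[*?]", pat)) {
      grep(utils::glob2rx(pat), labels)
    } else {
      which(labels == pat)
    }
    if (!length(hits)) unmatched <- c(unmatched, pat)
    idx <- c(idx, hits)
  }
  if (length(unmatched))
    stop("no channel matches pattern(s): ", paste(unmatched, collapse = ", "))
  idx[!duplicated(idx)]
}

#' @export
select_channels.meeg_raw <- function(data, selection) {
  idx <- match_selection(data$channels$label, selection)
  data$trials <- lapply(data$trials, function(tr) tr[idx, , drop = FALSE])
  data$channels <- data$channels[idx, , drop = FALSE]
  rownames(data$channels) <- NULL
  data$provenance <- append_provenance(list(data$provenance), "select_channels",
                                       list(selection = selection))
  data
}

#' @export
select_channels.meeg_timelock <- function(data, selection) {
  idx <- match_selection(data$channels$label, selection)
  data$average <- data$average[idx, , drop = FALSE]
  data$variance <- data$variance[idx, , drop = FALSE]
  data$channels <- data$channels[idx, , drop = FALSE]
  rownames(data$channels) <- NULL
  data$provenance <- append_provenance(list(data$provenance), "select_channels",
                                       list(selection = selection))
  data
}

#' @export
select_channels.meeg_freq <- function(data, selection) {
  idx <- match_selection(data$channels$label, selection)
  nd <- length(dim(data$power))
  data$power <- if (nd == 3) data$power[idx, , , drop = FALSE] else data$power[idx, , drop = FALSE]
  if (!is.null(data$fourier))
    data$fourier <- data$fourier[, idx, , drop = FALSE]
  if (!is.null(data$cross)) {
    # keep pairs whose channels both survive; remap and reorient to i < j
    old2new <- match(seq_len(n_channels(data)), idx)
    keep <- !is.na(old2new[data$pairs[, 1]]) & !is.na(old2new[data$pairs[, 2]])
    pr <- cbind(old2new[data$pairs[keep, 1]], old2new[data$pairs[keep, 2]])
    cr <- data$cross[keep, , drop = FALSE]
    flip <- pr[, 1] > pr[, 2]
    if (any(flip)) {
      pr[flip, ] <- pr[flip, c(2, 1), drop = FALSE]
      cr[flip, ] <- Conj(cr[flip, , drop = FALSE])
    }
    ord <- order(pr[, 1], pr[, 2])
    data$pairs <- pr[ord, , drop = FALSE]
    data$cross <- cr[ord, , drop = FALSE]
  }
  data$channels <- data$channels[idx, , drop = FALSE]
  rownames(data$channels) <- NULL
  data$provenance <- append_provenance(list(data$provenance), "select_channels",
                                       list(selection = selection))
  data
}

#' Average trials into a timelocked (evoked) response
#'
#' All trials must share one time axis.  The across-trial variance and the
#' per-sample degrees of freedom accompany the average.
#'
#' @param data `meeg_raw` with equal-length trials on a common time axis.
#' @return `meeg_timelock`.
#' @export
timelock_average <- function(data) {
  stopifnot(inherits(data, "meeg_raw"))
  lens <- vapply(data$trials, ncol, integer(1))
  if (length(unique(lens)) != 1)
    stop("trials have different lengths; segment to a common window first")
  arr <- simplify2array(data$trials)              # ch x time x trial
  avg <- apply(arr, c(1, 2), mean)
  vr <- apply(arr, c(1, 2), stats::var)
  if (length(data$trials) == 1) vr[] <- 0
  timelock_data(avg, vr, rep(length(data$trials), ncol(avg)),
                data$time[[1]], data$channels,
                append_provenance(list(data$provenance), "timelock_average",
                                  list(n_trials = length(data$trials))))
}

#' @export
print.meeg_raw <- function(x, ...) {
  cat(sprintf("meeg_raw: %d trials, %d channels, %g Hz\n",
              length(x$trials), n_channels(x), x$sample_rate))
  invisible(x)
}

#' @export
print.meeg_freq <- function(x, ...) {
  cat(sprintf("meeg_freq: %d channels, %d frequencies (%g-%g Hz)%s\n",
              n_channels(x), length(x$freq), min(x$freq), max(x$freq),
              if (!is.null(x$time)) sprintf(", %d time points", length(x$time)) else ""))
  invisible(x)
}
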