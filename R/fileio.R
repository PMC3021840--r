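# BrainVision Analyzer triplet (.vhdr INI header, .vmrk INI markers, .eeg
# binary).  Supported dialect: DataFormat BINARY, BinaryFormat INT_16 or
# IEEE_FLOAT_32, DataOrientation MULTIPLEXED or VECTORIZED.  Marker
# positions are 1-based in the files and converted to 0-based exactly once,
# at parse/serialize time.

parse_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("[;#].*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]$", ln))[[1]]
    if (length(m)) {
      sec <- m[2]
      out[[sec]] <- list(entries = character(0), lineno = integer(0))
      next
    }
    if (!is.null(sec)) {
      out[[sec]]$entries <- c(out[[sec]]$entries, ln)
      out[[sec]]$lineno <- c(out[[sec]]$lineno, i)
    }
  }
  out
}

ini_value <- function(section, key) {
  hits <- grep(paste0("^", key, "\\s*="), section$entries, value = TRUE)
  if (!length(hits)) return(NULL)
  trimws(sub("^[^=]*=", "", hits[[1]]))
}

#' Read a BrainVision header (.vhdr)
#'
#' @param path path to the .vhdr file.
#' @return a list of class `bv_header`: channel_count, sample_rate (Hz),
#'   labels, resolution (volts per stored count, SI), binary_format
#'   ("int16"/"float32"), orientation ("multiplexed"/"vectorized"),
#'   data_file, marker_file.
#' @export
read_header <- function(path) {
  stopifnot(file.exists(path))
  ini <- parse_ini(readLines(path, warn = FALSE, encoding = "latin1"))
  for (need in c("Common Infos", "Binary Infos", "Channel Infos")) {
    if (is.null(ini[[need]]))
      stop("header parse error: missing mandatory section [", need, "]")
  }
  ci <- ini[["Common Infos"]]
  fmt <- ini_value(ci, "DataFormat")
  if (!is.null(fmt) && toupper(fmt) != "BINARY")
    stop("unsupported BrainVision dialect: DataFormat ", fmt,
         " (only BINARY is supported)")
  orient <- toupper(ini_value(ci, "DataOrientation") %||% "MULTIPLEXED")
  if (!orient %in% c("MULTIPLEXED", "VECTORIZED"))
    stop("unsupported BrainVision dialect: DataOrientation ", orient)
  nchan <- as.integer(ini_value(ci, "NumberOfChannels"))
  interval_us <- as.numeric(ini_value(ci, "SamplingInterval"))
  bfmt <- toupper(ini_value(ini[["Binary Infos"]], "BinaryFormat") %||% "INT_16")
  if (!bfmt %in% c("INT_16", "IEEE_FLOAT_32"))
    stop("unsupported BrainVision dialect: BinaryFormat ", bfmt)
  labels <- character(nchan)
  resol <- rep(1, nchan)
  for (e in ini[["Channel Infos"]]$entries) {
    m <- regmatches(e, regexec("^Ch([0-9]+)\\s*=\\s*(.*)$", e))[[1]]
    if (!length(m)) next
    k <- as.integer(m[2])
    parts <- strsplit(m[3], ",")[[1]]
    labels[k] <- parts[1]
    res <- if (length(parts) >= 3 && nzchar(trimws(parts[3]))) as.numeric(parts[3]) else 1
    unit <- if (length(parts) >= 4) trimws(parts[4]) else "µV"
    # convert channel resolution to SI volts per count
    scale <- switch(unit,
                    "V" = 1, "mV" = 1e-3,
                    "µV" = 1e-6, "uV" = 1e-6, "nV" = 1e-9,
                    1e-6)
    resol[k] <- res * scale
  }
  if (any(resol <= 0)) stop("channel resolution must be > 0")
  structure(list(
    channel_count = nchan,
    sample_rate = 1e6 / interval_us,
    labels = labels,
    resolution = resol,
    binary_format = if (bfmt == "INT_16") "int16" else "float32",
    orientation = tolower(orient),
    data_file = ini_value(ci, "DataFile"),
    marker_file = ini_value(ci, "MarkerFile")
  ), class = "bv_header")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read BrainVision events (.vmrk)
#'
#' Marker positions are converted from the file's 1-based convention to
#' 0-based sample indices; events are returned sorted by sample.
#'
#' @param path path to the .vmrk file.
#' @return data.frame with columns kind, value, sample (0-based), duration.
#' @export
read_events <- function(path) {
  stopifnot(file.exists(path))
  ini <- parse_ini(readLines(path, warn = FALSE, encoding = "latin1"))
  mi <- ini[["Marker Infos"]]
  if (is.null(mi)) stop("marker parse error: missing section [Marker Infos]")
  ev <- list()
  for (k in seq_along(mi$entries)) {
    e <- mi$entries[k]
    m <- regmatches(e, regexec("^Mk([0-9]+)\\s*=\\s*(.*)$", e))[[1]]
    if (!length(m))
      stop("malformed marker line ", mi$lineno[k], ": ", e)
    parts <- strsplit(m[3], ",")[[1]]
    if (length(parts) < 4)
      stop("malformed marker line ", mi$lineno[k], ": ", e)
    pos <- suppressWarnings(as.integer(parts[3]))
    dur <- suppressWarnings(as.integer(parts[4]))
    if (is.na(pos) || pos < 1 || is.na(dur))
      stop("malformed marker line ", mi$lineno[k], ": ", e)
    ev[[length(ev) + 1]] <- data.frame(
      kind = parts[1], value = parts[2],
      sample = pos - 1L, duration = dur, stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(kind = character(0), value = character(0),
                      sample = integer(0), duration = integer(0)))
  out <- do.call(rbind, ev)
  out <- out[order(out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

bv_total_samples <- function(header, path) {
  bytes <- file.size(path)
  width <- if (header$binary_format == "int16") 2L else 4L
  bytes %/% (width * header$channel_count)
}

#' Read a sample range from a BrainVision binary data file (.eeg)
#'
#' Stored values are scaled by the per-channel resolution to SI volts.
#' Sample indices are 0-based, the interval half-open `[begin, end)`.
#'
#' @param header a `bv_header`.
#' @param path path to the .eeg file.
#' @param begin_sample,end_sample 0-based half-open range; NULL reads all.
#' @return channels x samples numeric matrix in volts.
#' @export
read_data <- function(header, path, begin_sample = NULL, end_sample = NULL) {
  stopifnot(file.exists(path))
  total <- bv_total_samples(header, path)
  if (is.null(begin_sample)) begin_sample <- 0L
  if (is.null(end_sample)) end_sample <- total
  if (begin_sample < 0 || end_sample <= begin_sample || end_sample > total)
    stop(sprintf("sample range [%d, %d) out of bounds: file has %d samples",
                 begin_sample, end_sample, total))
  nch <- header$channel_count
  ns <- end_sample - begin_sample
  width <- if (header$binary_format == "int16") 2L else 4L
  what <- if (header$binary_format == "int16") integer() else numeric()
  con <- file(path, "rb")
  on.exit(close(con))
  if (header$orientation == "multiplexed") {
    seek(con, begin_sample * nch * width)
    raw <- readBin(con, what, n = nch * ns, size = width, endian = "little")
    mat <- matrix(as.numeric(raw), nrow = nch, ncol = ns)
  } else {
    mat <- matrix(0, nch, ns)
    for (ch in seq_len(nch)) {
      seek(con, ((ch - 1) * total + begin_sample) * width)
      raw <- readBin(con, what, n = ns, size = width, endian = "little")
      mat[ch, ] <- as.numeric(raw)
    }
  }
  mat * header$resolution
}

#' Write a BrainVision triplet
#'
#' Data are written as IEEE_FLOAT_32 MULTIPLEXED with resolution 1 volt per
#' stored value (lossless up to float32 precision); events are written with
#' the format's 1-based positions.
#'
#' @param data channels x samples numeric matrix (volts) or a single-trial
#'   `meeg_raw` object.
#' @param events data.frame with columns kind, value, sample (0-based),
#'   duration (may be empty).
#' @param path base path without extension; `.vhdr`, `.vmrk`, `.eeg` are
#'   appended.
#' @param sample_rate Hz (taken from `data` when it is a `meeg_raw`).
#' @param labels channel labels (taken from `data` when it is a `meeg_raw`).
#' @return invisible list of the three file paths.
#' @export
write_brainvision <- function(data, events = NULL, path, sample_rate = NULL,
                              labels = NULL) {
  if (inherits(data, "meeg_raw")) {
    stopifnot(length(data$trials) == 1)
    sample_rate <- data$sample_rate
    labels <- data$channels$label
    data <- data$trials[[1]]
  }
  stopifnot(is.matrix(data), !is.null(sample_rate))
  if (!all(is.finite(data)))
    stop("non-finite samples; refusing to write")
  nch <- nrow(data)
  if (is.null(labels)) labels <- sprintf("Ch%d", seq_len(nch))
  if (is.null(events))
    events <- data.frame(kind = character(0), value = character(0),
                         sample = integer(0), duration = integer(0))
  base <- sub("\\.(vhdr|vmrk|eeg)$", "", path)
  vhdr <- paste0(base, ".vhdr"); vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  hl <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    sprintf("SamplingInterval=%.10g", 1e6 / sample_rate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,V", seq_len(nch), labels)
  )
  writeLines(hl, vhdr)
  ml <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    "[Marker Infos]"
  )
  if (nrow(events)) {
    ml <- c(ml, sprintf("Mk%d=%s,%s,%d,%d,0", seq_len(nrow(events)),
                        events$kind, events$value,
                        events$sample + 1L, events$duration))
  }
  writeLines(ml, vmrk)
  con <- file(eeg, "wb")
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  close(con)
  invisible(list(vhdr = vhdr, vmrk = vmrk, eeg = eeg))
}

#' Read a full BrainVision dataset as continuous raw data
#'
#' @param path path to the .vhdr (or base path).
#' @return list with `data` (channels x samples matrix, volts), `header`,
#'   `events`, `sample_rate`, `labels`.
#' @export
read_brainvision <- function(path) {
  base <- sub("\\.(vhdr|vmrk|eeg)$", "", path)
  header <- read_header(paste0(base, ".vhdr"))
  dir <- dirname(base)
  events <- read_events(file.path(dir, header$marker_file %||% paste0(basename(base), ".vmrk")))
  data <- read_data(header, file.path(dir, header$data_file %||% paste0(basename(base), ".eeg")))
  list(data = data, header = header, events = events,
       sample_rate = header$sample_rate, labels = header$labels)
}

#' Define trials from an event list
#'
#' Either a declarative rule (event kind/value filter plus pre/post windows
#' around the event sample) or a user-supplied function mapping the event
#' data.frame to a trial table.  Sample indices are 0-based and the trial
#' interval is half-open `[begin, end)`; `offset` gives the position of
#' t = 0 relative to `begin` (so `offset = -50` puts the trigger 50 samples
#' into the trial).
#'
#' @param events event data.frame (kind, value, sample, duration).
#' @param rule a list with elements `kind` and/or `value` (filters),
#'   `pre` and `post` (seconds), or a function(events) returning a trial
#'   table.
#' @param sample_rate Hz (required for the declarative rule).
#' @return data.frame with columns begin_sample, end_sample, offset_samples,
#'   sorted by begin_sample.
#' @export
define_trials <- function(events, rule, sample_rate = NULL) {
  if (is.function(rule)) {
    tab <- rule(events)
    tab <- as.data.frame(tab)
    names(tab)[1:3] <- c("begin_sample", "end_sample", "offset_samples")
  } else {
    stopifnot(!is.null(sample_rate))
    sel <- rep(TRUE, nrow(events))
    if (!is.null(rule$kind)) sel <- sel & events$kind %in% rule$kind
    if (!is.null(rule$value)) sel <- sel & events$value %in% rule$value
    ev <- events[sel, , drop = FALSE]
    pre <- round(rule$pre * sample_rate)
    post <- round(rule$post * sample_rate)
    tab <- data.frame(
      begin_sample = ev$sample - pre,
      end_sample = ev$sample + post,
      offset_samples = rep(-pre, nrow(ev))
    )
  }
  bad <- which(tab$end_sample <= tab$begin_sample)
  if (length(bad))
    stop("negative-length trial for event/row ", bad[1])
  tab <- tab[order(tab$begin_sample), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
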