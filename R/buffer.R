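#' Describe an input stream
#'
#' @param stream_id Text label of the stream.
#' @param channel_count Number of channels (>= 1).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Optional character vector of length `channel_count`.
#' @return An object of class `stream_info`.
#' @export
stream_info <- function(stream_id, channel_count, sampling_rate,
                        channel_labels = NULL) {
  stopifnot(is.character(stream_id), length(stream_id) == 1L)
  channel_count <- as.integer(channel_count)
  if (is.na(channel_count) || channel_count < 1L)
    ib_config_error("stream '", stream_id, "': channel_count must be >= 1")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    ib_config_error("stream '", stream_id, "': sampling_rate must be > 0")
  if (!is.null(channel_labels) && length(channel_labels) != channel_count)
    ib_config_error("stream '", stream_id,
                    "': channel_labels length != channel_count")
  structure(list(stream_id = stream_id, channel_count = channel_count,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "stream_info")
}

#' @export
print.stream_info <- function(x, ...) {
  cat(sprintf("<stream_info> %s: %d ch @ %g Hz\n",
              x$stream_id, x$channel_count, x$sampling_rate))
  invisible(x)
}

#' Create a rolling sample buffer for one stream
#'
#' Holds the most recent `capacity_seconds` of samples; older samples are
#' evicted as new chunks arrive via [push_samples()].
#'
#' @param stream A [stream_info()] object.
#' @param capacity_seconds Buffer capacity in seconds (default 30).
#' @return An object of class `ring_buffer`.
#' @export
ring_buffer <- function(stream, capacity_seconds = 30) {
  stopifnot(inherits(stream, "stream_info"), capacity_seconds > 0)
  structure(list(
    stream = stream,
    capacity_seconds = capacity_seconds,
    capacity_samples = as.integer(round(capacity_seconds * stream$sampling_rate)),
    data = matrix(numeric(0), nrow = 0L, ncol = stream$channel_count),
    end_index = 0L  # index (1-based) of the newest sample since stream start
  ), class = "ring_buffer")
}

#' Push a chunk of samples into a ring buffer
#'
#' Appends `chunk` (rows = time, columns = channels) to the buffer and evicts
#' the oldest samples beyond capacity. Missing values (NA/NaN) are repaired by
#' carrying the previous sample forward, with a warning.
#'
#' @param buffer A [ring_buffer()].
#' @param chunk Numeric matrix (or vector for a single-channel stream),
#'   samples x channels.
#' @return The updated `ring_buffer`.
#' @export
push_samples <- function(buffer, chunk) {
  stopifnot(inherits(buffer, "ring_buffer"))
  if (is.null(dim(chunk))) chunk <- matrix(chunk, ncol = 1L)
  if (nrow(chunk) == 0L) return(buffer)
  if (ncol(chunk) != buffer$stream$channel_count)
    ib_config_error("chunk has ", ncol(chunk), " channels; stream '",
                    buffer$stream$stream_id, "' expects ",
                    buffer$stream$channel_count)
  if (anyNA(chunk)) {
    ib_warn("missing samples in chunk for stream '",
            buffer$stream$stream_id, "'; carrying previous value forward",
            class = "ibsync_missing_samples")
    last <- if (nrow(buffer$data) > 0L) buffer$data[nrow(buffer$data), ] else
      rep(0, ncol(chunk))
    for (j in seq_len(ncol(chunk))) {
      col <- chunk[, j]
      bad <- which(is.na(col))
      for (i in bad) col[i] <- if (i == 1L) last[j] else col[i - 1L]
      chunk[, j] <- col
    }
  }
  data <- rbind(buffer$data, chunk)
  extra <- nrow(data) - buffer$capacity_samples
  if (extra > 0L) data <- data[-seq_len(extra), , drop = FALSE]
  buffer$data <- data
  buffer$end_index <- buffer$end_index + nrow(chunk)
  buffer
}

#' Number of seconds of data currently buffered
#' @param buffer A [ring_buffer()].
#' @return Stored duration in seconds.
#' @export
buffered_seconds <- function(buffer) {
  nrow(buffer$data) / buffer$stream$sampling_rate
}

#' Extract the most recent analysis window from a buffer
#'
#' Returns the latest `window_size + pad` seconds as a [sample_window].
#' The leading `pad` seconds are a margin that downstream filtering and the
#' Hilbert transform consume to absorb edge transients; they are discarded by
#' [analytic_signal()]. If the buffer does not yet hold enough data a
#' `ibsync_warming_up` warning is raised and `NULL` is returned (no frame).
#'
#' @param buffer A [ring_buffer()].
#' @param window_size Analysis window length in seconds (default 3).
#' @param pad Leading margin in seconds (default 0).
#' @return A `sample_window`, or `NULL` while warming up.
#' @export
latest_window <- function(buffer, window_size = 3, pad = 0) {
  stopifnot(inherits(buffer, "ring_buffer"), window_size > 0, pad >= 0)
  fs <- buffer$stream$sampling_rate
  need <- as.integer(round((window_size + pad) * fs))
  if (nrow(buffer$data) < need) {
    ib_warn("stream '", buffer$stream$stream_id, "' warming up: have ",
            nrow(buffer$data), " samples, need ", need,
            class = "ibsync_warming_up")
    return(NULL)
  }
  idx <- (nrow(buffer$data) - need + 1L):nrow(buffer$data)
  sample_window(buffer$data[idx, , drop = FALSE], fs,
                start_time = (buffer$end_index - need) / fs,
                pad = pad,
                channel_labels = buffer$stream$channel_labels)
}

#' Construct a sample window
#'
#' A real-valued block of samples x channels at a known sampling rate -- the
#' unit the analysis chain operates on.
#'
#' @param data Numeric matrix, samples x channels (a vector is treated as one
#'   channel).
#' @param sampling_rate Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds (default 0).
#' @param pad Leading margin in seconds carried within the window (default 0).
#' @param channel_labels Optional channel labels.
#' @return An object of class `sample_window`.
#' @export
sample_window <- function(data, sampling_rate, start_time = 0, pad = 0,
                          channel_labels = NULL) {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  stopifnot(is.numeric(data), sampling_rate > 0)
  if (anyNA(data)) ib_stop("sample_window must not contain missing values")
  structure(list(data = data, sampling_rate = sampling_rate,
                 start_time = start_time, pad = pad,
                 channel_labels = channel_labels),
            class = "sample_window")
}

#' @export
print.sample_window <- function(x, ...) {
  cat(sprintf("<sample_window> %d samples x %d ch @ %g Hz (%.3f s, pad %g s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              nrow(x$data) / x$sampling_rate, x$pad))
  invisible(x)
}

#' @export
dim.sample_window <- function(x) dim(x$data)

#' Create an in-memory stream registry (mock transport)
#'
#' A registry stands in for a live network transport: tests and simulations
#' register named streams with backing data, and [discover_streams()] lists
#' them the way a live adapter would enumerate visible inlets.
#'
#' @return An object of class `stream_registry`.
#' @export
stream_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = "stream_registry")
}

#' Register a stream in a registry
#'
#' @param registry A [stream_registry()].
#' @param info A [stream_info()], or a bare list with the same fields (as a
#'   transport might advertise before validation).
#' @param data Optional backing matrix (samples x channels) served in chunks.
#' @return The registry, invisibly.
#' @export
register_stream <- function(registry, info, data = NULL) {
  stopifnot(inherits(registry, "stream_registry"))
  if (!all(c("stream_id", "channel_count", "sampling_rate") %in% names(info)))
    ib_config_error("stream metadata needs stream_id, channel_count, sampling_rate")
  assign(info$stream_id, list(info = info, data = data), envir = registry$env)
  invisible(registry)
}

#' List visible streams in deterministic order
#'
#' @param registry A [stream_registry()] (or other transport handle providing
#'   the same contract).
#' @return A list of [stream_info()] objects sorted by stream id; streams
#'   advertising zero channels are dropped with a warning. An empty transport
#'   yields an empty list.
#' @export
discover_streams <- function(registry) {
  stopifnot(inherits(registry, "stream_registry"))
  ids <- sort(ls(registry$env))
  infos <- lapply(ids, function(id) get(id, envir = registry$env)$info)
  ok <- vapply(infos, function(x) x$channel_count >= 1L, logical(1))
  if (any(!ok))
    ib_warn("ignoring stream(s) advertising zero channels: ",
            paste(ids[!ok], collapse = ", "))
  infos[ok]
}
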