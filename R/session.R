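#' Session configuration
#'
#' Bundles every parameter of an analysis session: the band table, metric,
#' electrode-pairing scheme, window geometry and cadence, normalization and
#' output options.
#'
#' @param bands List of [band_spec()]s (default [default_bands()]).
#' @param metric Metric name (default `"envelope_correlation"`, the validated
#'   neurofeedback configuration); see [connectivity_metrics()].
#' @param connectivity_type `"one-to-one"` (default) or `"all-to-all"`.
#' @param window_size Analysis window in seconds (default 3).
#' @param buffer_seconds Ring-buffer capacity in seconds (default 30).
#' @param hop_seconds Analysis cadence in seconds (default 0.25). The
#'   original engine recomputes as fast as the host allows; a fixed hop makes
#'   runs reproducible.
#' @param pad_seconds Leading margin absorbed by filter/Hilbert transients
#'   (default 1). No frame is emitted before `window_size + pad_seconds` of
#'   data exist.
#' @param normalization Optional [normalization_spec()]; when present,
#'   emitted values are min-max normalized into \[0, 1\].
#' @param send_power If `TRUE`, per-channel band power is attached to each
#'   packed frame as a separate vector.
#' @param chunk_seconds Chunk size used when simulating live ingestion
#'   (default 0.1).
#' @param seed Optional integer seed (forwarded to synthetic sources).
#' @return An object of class `session_config`.
#' @export
session_config <- function(bands = default_bands(),
                           metric = "envelope_correlation",
                           connectivity_type = "one-to-one",
                           window_size = 3, buffer_seconds = 30,
                           hop_seconds = 0.25, pad_seconds = 1,
                           normalization = NULL, send_power = FALSE,
                           chunk_seconds = 0.1, seed = NULL) {
  cfg <- structure(list(bands = bands, metric = metric,
                        connectivity_type = connectivity_type,
                        window_size = window_size,
                        buffer_seconds = buffer_seconds,
                        hop_seconds = hop_seconds, pad_seconds = pad_seconds,
                        normalization = normalization,
                        send_power = send_power,
                        chunk_seconds = chunk_seconds, seed = seed),
                   class = "session_config")
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(paste0("<session_config> metric %s (%s), window %g s, ",
                     "hop %g s, pad %g s, buffer %g s\n"),
              x$metric, x$connectivity_type, x$window_size, x$hop_seconds,
              x$pad_seconds, x$buffer_seconds))
  cat("  bands:", paste(vapply(x$bands, `[[`, character(1), "name"),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Validate a session configuration
#'
#' Checks every configuration invariant and reports all violations at once
#' rather than stopping at the first.
#'
#' @param config A [session_config()].
#' @param fs Optional sampling rate in Hz; when given, band edges are also
#'   checked against the Nyquist frequency.
#' @return A data.frame with columns `field` and `problem`; zero rows for a
#'   valid configuration.
#' @export
validate_config <- function(config, fs = NULL) {
  bad <- list()
  flag <- function(field, problem)
    bad[[length(bad) + 1L]] <<- data.frame(field = field, problem = problem,
                                           stringsAsFactors = FALSE)
  if (!config$window_size > 0) flag("window_size", "must be > 0")
  if (!config$hop_seconds > 0) flag("hop_seconds", "must be > 0")
  if (config$pad_seconds < 0) flag("pad_seconds", "must be >= 0")
  if (config$window_size + config$pad_seconds > config$buffer_seconds)
    flag("window_size", "window_size + pad_seconds exceeds buffer_seconds")
  if (!config$metric %in% connectivity_metrics())
    flag("metric", paste0("unknown metric '", config$metric, "'; allowed: ",
                          paste(connectivity_metrics(), collapse = ", ")))
  if (!config$connectivity_type %in% c("one-to-one", "all-to-all"))
    flag("connectivity_type", "must be 'one-to-one' or 'all-to-all'")
  if (length(config$bands) == 0L) flag("bands", "at least one band required")
  for (b in config$bands) {
    if (!inherits(b, "band_spec")) {
      flag("bands", "entries must be band_spec objects")
      next
    }
    if (!is.null(fs) && b$f_hi >= fs / 2)
      flag(paste0("bands.", b$name),
           sprintf("f_hi (%g Hz) must be below Nyquist (%g Hz)", b$f_hi, fs / 2))
  }
  if (!is.null(config$normalization) &&
      !inherits(config$normalization, "normalization_spec"))
    flag("normalization", "must be a normalization_spec")
  if (length(bad) == 0L)
    data.frame(field = character(0), problem = character(0))
  else do.call(rbind, bad)
}

stop_if_invalid <- function(config, fs = NULL) {
  rep <- validate_config(config, fs)
  if (nrow(rep) > 0L)
    ib_config_error("invalid session config:\n",
                    paste0("  - ", rep$field, ": ", rep$problem,
                           collapse = "\n"))
  invisible(config)
}

# resolve file paths / sample_windows into a named list of full-length
# sample_windows with a common sampling rate
resolve_streams <- function(sources) {
  if (is.character(sources)) {
    missing <- sources[!file.exists(sources)]
    if (length(missing) > 0L)
      ib_stop("cannot read file(s): ", paste(missing, collapse = ", "))
    nm <- names(sources) %||% basename(sources)
    sources <- stats::setNames(lapply(sources, read_eeg_csv), nm)
  }
  if (!is.list(sources) || length(sources) < 2L)
    ib_config_error("need at least 2 streams")
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    ib_config_error("streams must be named")
  if (!all(vapply(sources, inherits, logical(1), "sample_window")))
    ib_config_error("streams must be file paths or sample_window objects")
  fs <- unique(vapply(sources, function(w) w$sampling_rate, numeric(1)))
  if (length(fs) != 1L)
    ib_config_error("streams have unequal sampling rates: ",
                    paste(fs, collapse = ", "),
                    "; resample before analysis")
  sources
}

# sample indices at which frames are emitted: first frame once
# window + pad samples exist, then every hop
emission_indices <- function(n, fs, window_size, pad, hop) {
  first <- window_size + pad
  k_max <- floor((n / fs - first) / hop + 1e-9)
  if (k_max < 0) return(integer(0))
  idx <- as.integer(round((first + (0:k_max) * hop) * fs))
  idx[idx <= n]
}

# one frame of the analysis chain at emission sample index e
frame_at <- function(streams, e, config, fs) {
  nw <- as.integer(round(config$window_size * fs))
  np <- as.integer(round(config$pad_seconds * fs))
  need <- nw + np
  windows <- lapply(streams, function(s)
    sample_window(s$data[(e - need + 1L):e, , drop = FALSE], fs,
                  start_time = (e - need) / fs, pad = config$pad_seconds,
                  channel_labels = s$channel_labels))
  frame <- compute_connectivity(windows, config$bands, config$metric,
                                config$connectivity_type,
                                pad = config$pad_seconds,
                                window_time = e / fs)
  if (!is.null(config$normalization))
    frame <- normalize_frame(frame, config$normalization)
  packed <- pack_frame(frame)
  if (isTRUE(config$send_power))
    packed$power <- window_band_power(windows, config$bands,
                                      config$pad_seconds)
  packed
}

# per-channel band power of every (stream, band), as one named flat vector
window_band_power <- function(windows, bands, pad) {
  out <- numeric(0)
  for (band in bands) {
    for (id in names(windows)) {
      w <- select_channels(windows[[id]], band, id)
      p <- band_power(analytic_signal(bandpass(w, band), pad = pad))
      names(p) <- paste(id, band$name, seq_along(p), sep = ".")
      out <- c(out, p)
    }
  }
  out
}

#' Batch (offline) analysis of recorded streams
#'
#' Runs the full analysis chain over recorded files or in-memory streams at a
#' fixed hop cadence and returns the complete long-format result table. The
#' computation is sample-for-sample identical to [run_session()] feeding the
#' same data chunk-by-chunk through ring buffers.
#'
#' @param sources Character vector of CSV paths (see [read_eeg_csv()]) or a
#'   named list of [sample_window()]s, one per stream.
#' @param config A [session_config()].
#' @return A data.frame with columns `timestamp`, `pair`, `band`, `value`,
#'   one row per (frame, pair, band).
#' @export
run_offline <- function(sources, config = session_config()) {
  streams <- resolve_streams(sources)
  fs <- streams[[1L]]$sampling_rate
  stop_if_invalid(config, fs)
  n <- min(vapply(streams, function(s) nrow(s$data), integer(1)))
  idx <- emission_indices(n, fs, config$window_size, config$pad_seconds,
                          config$hop_seconds)
  if (length(idx) == 0L)
    ib_warn("recording shorter than window + pad; no frames produced",
            class = "ibsync_warming_up")
  rows <- lapply(idx, function(e) {
    packed <- frame_at(streams, e, config, fs)
    df <- as.data.frame(unpack_frame(packed))
    data.frame(timestamp = packed$timestamp, pair = df$pair, band = df$band,
               value = df$value, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(timestamp = numeric(0), pair = character(0),
                      band = character(0), value = numeric(0)))
  do.call(rbind, rows)
}

#' Simulated-live analysis session
#'
#' Feeds the sources chunk-by-chunk through per-stream ring buffers exactly
#' as a live transport would, extracts the most recent window at every hop,
#' runs the analysis chain, and delivers each packed frame to the configured
#' sinks. Produces sample-identical frames to [run_offline()] on the same
#' data.
#'
#' @param sources As in [run_offline()].
#' @param config A [session_config()].
#' @param sinks List of sinks (see [memory_sink()], [csv_sink()]); default a
#'   single memory sink.
#' @return Invisibly, a list with `frames` (the packed frames emitted),
#'   `delivery` (per-sink success counts) and `sinks`.
#' @export
run_session <- function(sources, config = session_config(),
                        sinks = list(memory_sink())) {
  streams <- resolve_streams(sources)
  fs <- streams[[1L]]$sampling_rate
  stop_if_invalid(config, fs)
  buffers <- lapply(names(streams), function(id)
    ring_buffer(stream_info(id, ncol(streams[[id]]$data), fs,
                            streams[[id]]$channel_labels),
                config$buffer_seconds))
  names(buffers) <- names(streams)
  n <- min(vapply(streams, function(s) nrow(s$data), integer(1)))
  idx <- emission_indices(n, fs, config$window_size, config$pad_seconds,
                          config$hop_seconds)
  nc <- max(1L, as.integer(round(config$chunk_seconds * fs)))

  frames <- list()
  delivered <- NULL
  pos <- 0L
  next_i <- 1L
  while (pos < n) {
    # push up to the next emission boundary so windows align exactly
    upto <- min(pos + nc, n,
                if (next_i <= length(idx)) idx[next_i] else n)
    for (id in names(buffers))
      buffers[[id]] <- push_samples(
        buffers[[id]], streams[[id]]$data[(pos + 1L):upto, , drop = FALSE])
    pos <- upto
    while (next_i <= length(idx) && idx[next_i] == pos) {
      windows <- lapply(buffers, latest_window,
                        window_size = config$window_size,
                        pad = config$pad_seconds)
      frame <- compute_connectivity(windows, config$bands, config$metric,
                                    config$connectivity_type,
                                    pad = config$pad_seconds,
                                    window_time = pos / fs)
      if (!is.null(config$normalization))
        frame <- normalize_frame(frame, config$normalization)
      packed <- pack_frame(frame)
      if (isTRUE(config$send_power))
        packed$power <- window_band_power(windows, config$bands,
                                          config$pad_seconds)
      rep <- emit(packed, sinks)
      delivered <- if (is.null(delivered)) rep else
        data.frame(sink = rep$sink, ok = delivered$ok + rep$ok)
      frames[[length(frames) + 1L]] <- packed
      next_i <- next_i + 1L
    }
  }
  invisible(list(frames = frames, delivery = delivered, sinks = sinks))
}
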