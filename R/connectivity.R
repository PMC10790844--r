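#' Enumerate unordered subject pairs in lexicographic order
#'
#' Pair ordering is the packed-frame contract: (1,2), (1,3), ..., (2,3), ...
#' by stream position.
#'
#' @param ids Character vector of stream ids, in configuration order.
#' @return A data.frame with columns `a`, `b` (stream ids) and `pair`
#'   (`"a|b"` label), one row per unordered pair.
#' @export
subject_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2L) ib_config_error("need at least 2 streams, got ", n)
  idx <- utils::combn(n, 2L)
  data.frame(a = ids[idx[1L, ]], b = ids[idx[2L, ]],
             pair = paste(ids[idx[1L, ]], ids[idx[2L, ]], sep = "|"),
             stringsAsFactors = FALSE)
}

# Average a metric over the configured electrode-pair set of one subject pair.
# ax, ay: complex matrices samples x channels.
pair_average <- function(ax, ay, metric, connectivity_type) {
  f <- metric_fun(metric)
  if (connectivity_type == "one-to-one") {
    k <- min(ncol(ax), ncol(ay))
    if (ncol(ax) != ncol(ay))
      ib_warn("one-to-one with unequal channel counts (", ncol(ax), " vs ",
              ncol(ay), "); pairing first ", k, " channels",
              class = "ibsync_channel_mismatch")
    vals <- lapply(seq_len(k), function(i) f(ax[, i], ay[, i]))
  } else if (connectivity_type == "all-to-all") {
    vals <- list()
    for (i in seq_len(ncol(ax)))
      for (j in seq_len(ncol(ay)))
        vals[[length(vals) + 1L]] <- f(ax[, i], ay[, j])
  } else {
    ib_config_error("connectivity_type must be 'one-to-one' or 'all-to-all', got '",
                    connectivity_type, "'")
  }
  list(value = mean(vapply(vals, as.numeric, numeric(1))),
       degenerate = any(vapply(vals, function(v) isTRUE(attr(v, "degenerate")),
                               logical(1))))
}

#' Compute a connectivity frame from one multi-stream window
#'
#' Runs the per-window analysis chain for every configured band: select the
#' band's channels per stream, band-pass filter, take the analytic signal
#' (discarding the pad margin), evaluate the chosen metric over the electrode
#' pairs of every unordered subject pair, average the pairs arithmetically,
#' and multiply by the band weight. The result is one value per
#' (subject pair, band).
#'
#' @param windows Named list of [sample_window()] objects, one per stream,
#'   covering the same time window at the same sampling rate.
#' @param bands List of [band_spec()] objects (configuration order is the
#'   band order of the output).
#' @param metric Metric name; see [connectivity_metrics()].
#' @param connectivity_type `"one-to-one"` (matched channel positions) or
#'   `"all-to-all"` (every cross-subject channel combination).
#' @param pad Leading margin in seconds discarded after the Hilbert
#'   transform; defaults to each window's own pad.
#' @param window_time Optional timestamp (seconds) attached to the frame;
#'   defaults to the end time of the first window.
#' @return A `connectivity_frame`: a data.frame with columns `pair`, `band`,
#'   `value`, `degenerate` and metadata attributes (`metric`,
#'   `connectivity_type`, `bands`, `window_time`).
#' @export
compute_connectivity <- function(windows, bands, metric = "plv",
                                 connectivity_type = "one-to-one",
                                 pad = NULL, window_time = NULL) {
  if (is.null(names(windows)) || any(!nzchar(names(windows))))
    ib_config_error("windows must be a named list (names = stream ids)")
  if (length(windows) < 2L)
    ib_config_error("need at least 2 streams, got ", length(windows))
  fs <- unique(vapply(windows, function(w) w$sampling_rate, numeric(1)))
  if (length(fs) != 1L)
    ib_config_error("streams have unequal sampling rates: ",
                    paste(fs, collapse = ", "))
  metric_fun(metric)  # validate name early
  ids <- names(windows)
  pairs <- subject_pairs(ids)
  if (is.null(window_time)) {
    w1 <- windows[[1L]]
    window_time <- w1$start_time + nrow(w1$data) / w1$sampling_rate
  }

  # analytic signal once per (band, stream), then metric per pair
  analytic <- lapply(bands, function(band) {
    lapply(stats::setNames(ids, ids), function(id) {
      w <- select_channels(windows[[id]], band, id)
      analytic_signal(bandpass(w, band), pad = pad)$values
    })
  })

  rows <- vector("list", nrow(pairs) * length(bands))
  k <- 0L
  for (p in seq_len(nrow(pairs))) {
    for (bi in seq_along(bands)) {
      band <- bands[[bi]]
      res <- pair_average(analytic[[bi]][[pairs$a[p]]],
                          analytic[[bi]][[pairs$b[p]]],
                          metric, connectivity_type)
      k <- k + 1L
      rows[[k]] <- data.frame(pair = pairs$pair[p], band = band$name,
                              value = res$value * band$weight,
                              degenerate = res$degenerate,
                              stringsAsFactors = FALSE)
    }
  }
  connectivity_frame(do.call(rbind, rows), metric = metric,
                     connectivity_type = connectivity_type,
                     bands = vapply(bands, `[[`, character(1), "name"),
                     pairs = pairs$pair, window_time = window_time)
}

#' Construct a connectivity frame
#'
#' Mostly used internally by [compute_connectivity()]; exposed so frames can
#' be rebuilt from recorded tables.
#'
#' @param df data.frame with columns `pair`, `band`, `value` (and optionally
#'   `degenerate`).
#' @param metric,connectivity_type,window_time Frame metadata.
#' @param bands Band names in configuration order.
#' @param pairs Pair labels in lexicographic order.
#' @return An object of class `connectivity_frame`.
#' @export
connectivity_frame <- function(df, metric, connectivity_type, bands, pairs,
                               window_time = NA_real_) {
  stopifnot(all(c("pair", "band", "value") %in% names(df)))
  if (is.null(df$degenerate)) df$degenerate <- FALSE
  structure(df[, c("pair", "band", "value", "degenerate")],
            class = c("connectivity_frame", "data.frame"),
            metric = metric, connectivity_type = connectivity_type,
            bands = bands, pairs = pairs, window_time = window_time)
}

#' @export
print.connectivity_frame <- function(x, ...) {
  cat(sprintf("<connectivity_frame> %s (%s), t = %s\n",
              attr(x, "metric"), attr(x, "connectivity_type"),
              format(attr(x, "window_time"))))
  print.data.frame(x, ...)
  invisible(x)
}
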