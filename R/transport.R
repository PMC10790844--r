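#' Pack a connectivity frame into the flat output vector
#'
#' Output frames are flat numeric vectors of length
#' `choose(n_subjects, 2) * n_bands` in pair-major, band-minor order: all
#' bands of pair (1,2), then all bands of pair (1,3), and so on, pairs
#' lexicographic by stream position and bands in configuration order. The
#' ordering is part of the frame's metadata so consumers need not guess.
#'
#' @param frame A `connectivity_frame` with a complete (pair x band) grid.
#' @return An object of class `packed_frame`: the numeric `vector` plus
#'   `pairs`, `bands`, `metric` and `timestamp` metadata.
#' @export
pack_frame <- function(frame) {
  stopifnot(inherits(frame, "connectivity_frame"))
  pairs <- attr(frame, "pairs")
  bands <- attr(frame, "bands")
  key <- paste(frame$pair, frame$band, sep = "\r")
  want <- as.vector(t(outer(pairs, bands, paste, sep = "\r")))
  idx <- match(want, key)
  if (anyNA(idx))
    ib_stop("frame is missing (pair, band) entries; cannot pack")
  structure(list(vector = frame$value[idx],
                 pairs = pairs, bands = bands,
                 metric = attr(frame, "metric"),
                 connectivity_type = attr(frame, "connectivity_type"),
                 timestamp = attr(frame, "window_time")),
            class = "packed_frame")
}

#' Unpack a flat frame back into a connectivity frame
#'
#' Inverse of [pack_frame()].
#'
#' @param packed A `packed_frame`.
#' @return A `connectivity_frame`.
#' @export
unpack_frame <- function(packed) {
  stopifnot(inherits(packed, "packed_frame"))
  df <- data.frame(
    pair = rep(packed$pairs, each = length(packed$bands)),
    band = rep(packed$bands, times = length(packed$pairs)),
    value = packed$vector, stringsAsFactors = FALSE)
  connectivity_frame(df, metric = packed$metric,
                     connectivity_type = packed$connectivity_type,
                     bands = packed$bands, pairs = packed$pairs,
                     window_time = packed$timestamp)
}

#' @export
print.packed_frame <- function(x, ...) {
  cat(sprintf("<packed_frame> length %d (%d pairs x %d bands), t = %s\n",
              length(x$vector), length(x$pairs), length(x$bands),
              format(x$timestamp)))
  invisible(x)
}

#' Output sinks
#'
#' Sinks receive packed frames from the analysis loop. `memory_sink()` keeps
#' frames in memory (tests, programmatic use); `csv_sink()` appends one row
#' per (timestamp, pair, band, value) to a CSV recording that
#' [read_frames_csv()] can round-trip. Both implement the `emit_frame()`
#' contract used by [emit()].
#'
#' @return A sink object.
#' @export
memory_sink <- function() {
  structure(list(env = new.env(parent = emptyenv()), name = "memory"),
            class = c("memory_sink", "ibsync_sink"))
}

#' @rdname memory_sink
#' @param path CSV file path.
#' @param append If `FALSE` (default) an existing file is replaced and a
#'   header written; if `TRUE` frames are concatenated chronologically.
#' @export
csv_sink <- function(path, append = FALSE) {
  if (!append || !file.exists(path)) {
    ok <- tryCatch({
      writeLines("timestamp,pair,band,value", path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) ib_stop("cannot write recording to ", path)
  }
  structure(list(path = path, name = paste0("csv:", path)),
            class = c("csv_sink", "ibsync_sink"))
}

emit_frame <- function(sink, packed) UseMethod("emit_frame")

#' @export
emit_frame.memory_sink <- function(sink, packed) {
  n <- length(sink$env$frames)
  sink$env$frames[[n + 1L]] <- packed
  invisible(TRUE)
}

#' @export
emit_frame.csv_sink <- function(sink, packed) {
  df <- as.data.frame(unpack_frame(packed))
  dt <- data.table::data.table(
    timestamp = rep(packed$timestamp, nrow(df)),
    pair = df$pair, band = df$band, value = df$value)
  data.table::fwrite(dt, sink$path, append = TRUE, col.names = FALSE)
  invisible(TRUE)
}

#' Frames held by a memory sink
#' @param sink A [memory_sink()].
#' @return List of `packed_frame`s in arrival order.
#' @export
sink_frames <- function(sink) {
  stopifnot(inherits(sink, "memory_sink"))
  sink$env$frames %||% list()
}

#' Deliver a packed frame to every sink
#'
#' A failing sink is reported in the delivery report and does not stop
#' delivery to the remaining sinks (the live loop must keep running).
#'
#' @param packed A `packed_frame`.
#' @param sinks List of sink objects.
#' @return A data.frame report with columns `sink` and `ok`.
#' @export
emit <- function(packed, sinks) {
  stopifnot(inherits(packed, "packed_frame"))
  ok <- vapply(sinks, function(s) {
    tryCatch({ emit_frame(s, packed); TRUE },
             error = function(e) {
               ib_warn("sink '", s$name %||% class(s)[1], "' failed: ",
                       conditionMessage(e), class = "ibsync_sink_failure")
               FALSE
             })
  }, logical(1))
  data.frame(sink = vapply(sinks, function(s) s$name %||% class(s)[1],
                           character(1)),
             ok = ok, stringsAsFactors = FALSE)
}

#' Read a recorded session back from CSV
#'
#' @param path Path written by a [csv_sink()].
#' @return A data.frame with columns `timestamp`, `pair`, `band`, `value`,
#'   in chronological order.
#' @export
read_frames_csv <- function(path) {
  if (!file.exists(path)) ib_stop("file not found: ", path)
  as.data.frame(data.table::fread(path, header = TRUE))
}
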