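#' Write a multichannel recording to CSV
#'
#' The on-disk format is plain CSV with a one-line metadata header
#' (`# sampling_rate=<Hz>`), then a channel-label header row, then one row per
#' sample. It round-trips through [read_eeg_csv()].
#'
#' @param x A [sample_window()] or a numeric matrix (samples x channels).
#' @param path Output file path.
#' @param sampling_rate Required when `x` is a bare matrix.
#' @param channel_labels Optional channel labels; defaults to `ch1..chK`.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(x, path, sampling_rate = NULL, channel_labels = NULL) {
  if (inherits(x, "sample_window")) {
    sampling_rate <- x$sampling_rate
    channel_labels <- channel_labels %||% x$channel_labels
    x <- x$data
  }
  if (is.null(sampling_rate))
    ib_config_error("sampling_rate required when writing a bare matrix")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  labels <- channel_labels %||% paste0("ch", seq_len(ncol(x)))
  writeLines(c(sprintf("# sampling_rate=%.10g", sampling_rate),
               paste(labels, collapse = ",")), path)
  data.table::fwrite(data.table::as.data.table(x), path,
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a multichannel CSV recording
#'
#' Expects the format written by [write_eeg_csv()]: a `# sampling_rate=` line,
#' a channel-label row, then sample rows.
#'
#' @param path Input file path.
#' @return A [sample_window()] covering the whole file.
#' @export
read_eeg_csv <- function(path) {
  if (!file.exists(path)) ib_stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*sampling_rate\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L)
    ib_config_error(path, ": missing '# sampling_rate=' header line")
  fs <- as.numeric(m[2])
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  if (nrow(dt) == 0L) ib_stop(path, ": no samples")
  sample_window(as.matrix(dt), fs, channel_labels = names(dt))
}

# read file metadata without loading samples (adapter-level peek)
eeg_csv_info <- function(path, stream_id = basename(path)) {
  hdr <- readLines(path, n = 2L)
  m <- regmatches(hdr[1], regexec("^#\\s*sampling_rate\\s*=\\s*([0-9.eE+-]+)", hdr[1]))[[1]]
  if (length(m) < 2L)
    ib_config_error(path, ": missing '# sampling_rate=' header line")
  labels <- strsplit(hdr[2], ",", fixed = TRUE)[[1]]
  stream_info(stream_id, length(labels), as.numeric(m[2]), labels)
}
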