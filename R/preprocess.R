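#' Band-pass filter a window into one frequency band
#'
#' Applies a causal 4th-order Butterworth band-pass per channel. Filtering is
#' stateless per window; the leading pad region of the window absorbs the
#' filter's settling transient and is discarded later by [analytic_signal()].
#'
#' @param window A [sample_window()].
#' @param band A [band_spec()]; `f_hi` must be below the Nyquist frequency.
#' @return A band-limited `sample_window` of the same shape.
#' @export
bandpass <- function(window, band) {
  stopifnot(inherits(window, "sample_window"), inherits(band, "band_spec"))
  fs <- window$sampling_rate
  if (band$f_hi >= fs / 2)
    ib_config_error("band '", band$name, "': f_hi (", band$f_hi,
                    " Hz) must be below Nyquist (", fs / 2, " Hz)")
  filt <- signal::butter(2, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  out <- apply(window$data, 2L, function(ch) as.numeric(signal::filter(filt, ch)))
  out <- matrix(out, nrow = nrow(window$data))
  w <- window
  w$data <- out
  w$band <- band
  w
}

#' Compute the instantaneous analytic signal
#'
#' Builds the complex analytic signal (real part = input, imaginary part =
#' Hilbert transform) of each channel via the standard FFT construction, then
#' discards the leading pad region where the filter transient and the
#' transform's circular edge effects live.
#'
#' @param window A band-limited [sample_window()].
#' @param pad Leading margin to discard, in seconds. Defaults to the pad the
#'   window was extracted with.
#' @return An object of class `analytic_window` with complex `values`
#'   (samples x channels).
#' @export
analytic_signal <- function(window, pad = NULL) {
  stopifnot(inherits(window, "sample_window"))
  pad <- pad %||% window$pad %||% 0
  fs <- window$sampling_rate
  vals <- apply(window$data, 2L, analytic_1d)
  vals <- matrix(vals, nrow = nrow(window$data))
  n_pad <- as.integer(round(pad * fs))
  if (n_pad >= nrow(vals))
    ib_stop("pad (", pad, " s) consumes the whole window")
  if (n_pad > 0L) vals <- vals[-seq_len(n_pad), , drop = FALSE]
  structure(list(values = vals, sampling_rate = fs,
                 band = window$band %||% NULL,
                 start_time = window$start_time + n_pad / fs,
                 channel_labels = window$channel_labels),
            class = "analytic_window")
}

# FFT-based analytic signal of one real channel:
# zero the negative frequencies, double the positive ones.
analytic_1d <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' @export
print.analytic_window <- function(x, ...) {
  cat(sprintf("<analytic_window> %d samples x %d ch @ %g Hz%s\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              if (!is.null(x$band)) paste0(" [", x$band$name, "]") else ""))
  invisible(x)
}

#' Instantaneous envelope, power, phasor and phase
#'
#' Per-sample derived quantities of an analytic window: `envelope()` is the
#' magnitude |X(t)|, `inst_power()` its square, `unit_phasor()` the normalized
#' complex X/|X| (NA where the envelope is 0), and `phase_angle()` the phase
#' in (-pi, pi].
#'
#' @param aw An [analytic_signal()] result.
#' @return A numeric (or complex, for `unit_phasor`) matrix of the same shape
#'   as `aw$values`.
#' @export
envelope <- function(aw) {
  stopifnot(inherits(aw, "analytic_window"))
  abs(aw$values)
}

#' @rdname envelope
#' @export
inst_power <- function(aw) envelope(aw)^2

#' @rdname envelope
#' @export
unit_phasor <- function(aw) {
  e <- envelope(aw)
  out <- aw$values / e
  out[e == 0] <- NA_complex_
  out
}

#' @rdname envelope
#' @export
phase_angle <- function(aw) {
  stopifnot(inherits(aw, "analytic_window"))
  Arg(aw$values)
}

#' Mean band power per channel
#'
#' The band-power estimate is the time-averaged power of the band-limited
#' real signal, computed from the envelope as `mean(|X(t)|^2) / 2` per
#' channel (the analytic envelope squared is twice the real signal's
#' instantaneous power, so a unit-amplitude in-band sinusoid reports 0.5).
#'
#' @param aw An [analytic_signal()] result.
#' @return Non-negative numeric vector, one value per channel.
#' @export
band_power <- function(aw) {
  colMeans(inst_power(aw)) / 2
}

#' Subset a window to a band's configured channels
#'
#' @param window A [sample_window()].
#' @param band A [band_spec()].
#' @param stream_id Stream id used to look up the band's channel selection.
#' @return A `sample_window` holding only the selected channels, order
#'   preserved.
#' @export
select_channels <- function(window, band, stream_id) {
  stopifnot(inherits(window, "sample_window"))
  sel <- band_channel_indices(band, stream_id, ncol(window$data))
  w <- window
  w$data <- window$data[, sel, drop = FALSE]
  if (!is.null(w$channel_labels)) w$channel_labels <- w$channel_labels[sel]
  w
}
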