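#' Define an analysis frequency band
#'
#' A band specification names a frequency range, a relative weight applied to
#' connectivity values computed in that band, and (optionally) the channel
#' indices each stream contributes to the band.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param f_lo Lower band edge in Hz (> 0).
#' @param f_hi Upper band edge in Hz (> `f_lo`; must stay below the Nyquist
#'   frequency of every stream it is applied to, checked at filter time).
#' @param weight Non-negative multiplier applied to the band's averaged
#'   connectivity values. Default 1.
#' @param channels Optional named list mapping stream id to an integer vector
#'   of channel indices (1-based) used for this band. Streams absent from the
#'   list contribute all channels.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 12)
#' @export
band_spec <- function(name, f_lo, f_hi, weight = 1, channels = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    ib_config_error("band '", name, "': need 0 < f_lo < f_hi (got ",
                    f_lo, ", ", f_hi, ")")
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0)
    ib_config_error("band '", name, "': weight must be a single value >= 0")
  if (!is.null(channels)) {
    if (!is.list(channels) || is.null(names(channels)))
      ib_config_error("band '", name, "': channels must be a named list")
    channels <- lapply(channels, function(ix) {
      ix <- as.integer(ix)
      if (length(ix) == 0L || anyNA(ix) || any(ix < 1L))
        ib_config_error("band '", name, "': channel indices must be positive")
      ix
    })
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 weight = weight, channels = channels),
            class = "band_spec")
}

#' Default EEG band table
#'
#' The standard four-band setup: delta 1-4 Hz, theta 4-8 Hz, alpha 8-12 Hz,
#' beta 12-20 Hz, all with weight 1 and all channels.
#'
#' @return A named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(
    delta = band_spec("delta", 1, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 12),
    beta  = band_spec("beta", 12, 20)
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz, weight %g\n",
              x$name, x$f_lo, x$f_hi, x$weight))
  if (!is.null(x$channels))
    for (id in names(x$channels))
      cat("  ", id, ": channels ", paste(x$channels[[id]], collapse = ","),
          "\n", sep = "")
  invisible(x)
}

# channels a band selects for a given stream; NULL channel spec = all channels
band_channel_indices <- function(band, stream_id, n_channels) {
  sel <- band$channels[[stream_id]] %||% seq_len(n_channels)
  if (length(sel) == 0L)
    ib_config_error("band '", band$name, "': empty channel selection for stream '",
                    stream_id, "'")
  if (any(sel > n_channels))
    ib_config_error("band '", band$name, "': channel index out of range for stream '",
                    stream_id, "' (", n_channels, " channels)")
  as.integer(sel)
}
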