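#' Specify min-max normalization limits
#'
#' Normalization maps raw connectivity values into \[0, 1\] feedback values
#' with min-max limits blended between a manual setting and limits derived
#' from a recorded baseline: `eff = w * manual + (1 - w) * baseline`,
#' applied to the min and the max separately.
#'
#' @param manual_min,manual_max Manual limits (`manual_min < manual_max`).
#' @param baseline Optional per-(pair, band) limits table from
#'   [limits_from_baseline()]. When absent, the manual limits are used alone
#'   regardless of `weight`.
#' @param weight Blend weight w in \[0, 1\]: 1 = manual only, 0 = baseline
#'   only.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(manual_min = 0, manual_max = 1,
                               baseline = NULL, weight = 1) {
  if (!is.numeric(manual_min) || !is.numeric(manual_max) ||
      manual_min >= manual_max)
    ib_config_error("need manual_min < manual_max")
  if (!is.numeric(weight) || weight < 0 || weight > 1)
    ib_config_error("weight must be in [0, 1]")
  if (!is.null(baseline) &&
      !all(c("pair", "band", "min", "max") %in% names(baseline)))
    ib_config_error("baseline must have columns pair, band, min, max")
  structure(list(manual_min = manual_min, manual_max = manual_max,
                 baseline = baseline, weight = weight),
            class = "normalization_spec")
}

#' Derive per-(pair, band) limits from a recorded baseline
#'
#' @param frames A list of `connectivity_frame`s (a recorded baseline
#'   session), or a long data.frame with columns `pair`, `band`, `value`.
#' @param probs Optional length-2 probability vector (e.g. `c(0.05, 0.95)`)
#'   to use percentile limits instead of the observed min/max.
#' @return A data.frame with columns `pair`, `band`, `min`, `max`. A
#'   degenerate key (constant recording) gets `max = min + 1e-6` with a
#'   warning.
#' @export
limits_from_baseline <- function(frames, probs = NULL) {
  if (inherits(frames, "connectivity_frame")) frames <- list(frames)
  df <- if (is.data.frame(frames)) frames else
    do.call(rbind, lapply(frames, as.data.frame))
  if (is.null(df) || nrow(df) == 0L)
    ib_config_error("empty baseline recording")
  if (!is.null(probs)) stopifnot(length(probs) == 2L, probs[1] < probs[2])
  key <- interaction(df$pair, df$band, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    lim <- if (is.null(probs)) range(g$value) else
      unname(quantile(g$value, probs, type = 7))
    data.frame(pair = g$pair[1L], band = g$band[1L],
               min = lim[1L], max = lim[2L], stringsAsFactors = FALSE)
  }))
  flat <- out$max <= out$min
  if (any(flat)) {
    ib_warn("constant baseline for ", sum(flat),
            " (pair, band) key(s); inflating max to min + 1e-6",
            class = "ibsync_degenerate_limits")
    out$max[flat] <- out$min[flat] + 1e-6
  }
  rownames(out) <- NULL
  out
}

#' Effective limits after blending manual and baseline
#'
#' @param spec A [normalization_spec()].
#' @param pair,band Key to look up in the baseline table; a key absent from
#'   the table falls back to the global (all-key) baseline range.
#' @return Numeric `c(min, max)`, guarded against degeneracy.
#' @export
blend_limits <- function(spec, pair = NULL, band = NULL) {
  stopifnot(inherits(spec, "normalization_spec"))
  w <- spec$weight
  if (is.null(spec$baseline)) {
    lim <- c(spec$manual_min, spec$manual_max)
  } else {
    b <- spec$baseline
    hit <- if (!is.null(pair) && !is.null(band))
      which(b$pair == pair & b$band == band) else integer(0)
    base <- if (length(hit) >= 1L)
      c(b$min[hit[1L]], b$max[hit[1L]]) else c(min(b$min), max(b$max))
    lim <- w * c(spec$manual_min, spec$manual_max) + (1 - w) * base
  }
  if (lim[2L] <= lim[1L]) {
    ib_warn("degenerate effective limits; inflating max to min + 1e-6",
            class = "ibsync_degenerate_limits")
    lim[2L] <- lim[1L] + 1e-6
  }
  lim
}

#' Min-max normalize connectivity values
#'
#' `minmax()` maps a numeric vector through
#' `clip((r - min) / (max - min), 0, 1)`; `normalize_frame()` applies it to
#' every value of a frame using that value's (pair, band) effective limits.
#'
#' @param r Numeric vector of raw connectivity values.
#' @param limits Numeric `c(min, max)` with `min < max`.
#' @return Values in \[0, 1\].
#' @export
minmax <- function(r, limits) {
  stopifnot(length(limits) == 2L)
  if (limits[2L] <= limits[1L]) ib_config_error("need min < max limits")
  pmin(1, pmax(0, (r - limits[1L]) / (limits[2L] - limits[1L])))
}

#' @rdname minmax
#' @param frame A `connectivity_frame`.
#' @param spec A [normalization_spec()].
#' @export
normalize_frame <- function(frame, spec) {
  stopifnot(inherits(frame, "connectivity_frame"))
  frame$value <- vapply(seq_len(nrow(frame)), function(i) {
    minmax(frame$value[i], blend_limits(spec, frame$pair[i], frame$band[i]))
  }, numeric(1))
  frame
}
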