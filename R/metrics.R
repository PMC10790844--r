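#' Pairwise connectivity metrics on analytic signals
#'
#' Each metric takes two complex analytic-signal vectors of equal length
#' (one channel from each subject) and returns a single synchrony value.
#' Degenerate inputs (zero power, flat envelope, zero circular variance)
#' return 0 with attribute `degenerate = TRUE` rather than NaN, so a live
#' feedback loop keeps emitting frames.
#'
#' Definitions, with `*` the complex conjugate and sums over the window's N
#' samples:
#' * `coherence`: |sum(X Y*)| / sqrt(sum|X|^2 sum|Y|^2) -- the summed
#'   cross-spectrum magnitude normalized by the auto-powers; in \[0, 1\].
#' * `imaginary_coherence`: |Im(sum(X Y*))| / sqrt(sum|X|^2 sum|Y|^2);
#'   discards the zero-lag (real) component; in \[0, 1\].
#' * `envelope_correlation`: Pearson correlation of |X| and |Y|; in \[-1, 1\].
#' * `power_correlation`: Pearson correlation of |X|^2 and |Y|^2.
#' * `plv`: |mean(phi_x phi_y*)| with phi = X/|X| -- magnitude of the mean
#'   relative phasor; in \[0, 1\]. Samples where either envelope is 0 are
#'   excluded.
#' * `ccorr`: circular correlation of the instantaneous phases,
#'   sum(sin(tx - mx) sin(ty - my)) / sqrt(sum sin^2(tx - mx) sum sin^2(ty - my))
#'   with mx, my the circular means; in \[-1, 1\].
#'
#' @param x,y Complex vectors of equal length (analytic samples of one
#'   channel each).
#' @return A single numeric value; attribute `degenerate` is TRUE when the
#'   input was degenerate and 0 was returned by convention.
#' @name metrics
NULL

degenerate_zero <- function() structure(0, degenerate = TRUE)

check_pair <- function(x, y) {
  if (length(x) != length(y))
    ib_stop("channel sample counts differ (", length(x), " vs ", length(y), ")")
  if (length(x) < 2L) ib_stop("need at least 2 samples")
}

#' @rdname metrics
#' @export
coherence <- function(x, y) {
  check_pair(x, y)
  px <- sum(abs(x)^2); py <- sum(abs(y)^2)
  if (px == 0 || py == 0) return(degenerate_zero())
  abs(sum(x * Conj(y))) / sqrt(px * py)
}

#' @rdname metrics
#' @export
imaginary_coherence <- function(x, y) {
  check_pair(x, y)
  px <- sum(abs(x)^2); py <- sum(abs(y)^2)
  if (px == 0 || py == 0) return(degenerate_zero())
  abs(Im(sum(x * Conj(y)))) / sqrt(px * py)
}

#' @rdname metrics
#' @export
envelope_correlation <- function(x, y) {
  check_pair(x, y)
  ex <- abs(x); ey <- abs(y)
  if (sd(ex) == 0 || sd(ey) == 0) return(degenerate_zero())
  cor(ex, ey)
}

#' @rdname metrics
#' @export
power_correlation <- function(x, y) {
  check_pair(x, y)
  ax <- abs(x)^2; ay <- abs(y)^2
  if (sd(ax) == 0 || sd(ay) == 0) return(degenerate_zero())
  cor(ax, ay)
}

#' @rdname metrics
#' @export
plv <- function(x, y) {
  check_pair(x, y)
  ok <- abs(x) > 0 & abs(y) > 0
  if (!any(ok)) return(degenerate_zero())
  px <- x[ok] / abs(x[ok])
  py <- y[ok] / abs(y[ok])
  abs(mean(px * Conj(py)))
}

#' Circular (angular) mean of a phase series
#'
#' The argument of the resultant vector `sum(exp(1i * theta))`.
#'
#' @param theta Numeric vector of angles in radians.
#' @return The circular mean in (-pi, pi].
#' @export
circular_mean <- function(theta) {
  Arg(sum(exp(1i * theta)))
}

#' @rdname metrics
#' @export
ccorr <- function(x, y) {
  check_pair(x, y)
  ok <- abs(x) > 0 & abs(y) > 0
  if (!any(ok)) return(degenerate_zero())
  tx <- Arg(x[ok]); ty <- Arg(y[ok])
  sx <- sin(tx - circular_mean(tx))
  sy <- sin(ty - circular_mean(ty))
  dx <- sum(sx^2); dy <- sum(sy^2)
  if (dx == 0 || dy == 0) return(degenerate_zero())
  sum(sx * sy) / sqrt(dx * dy)
}

#' Names of the available connectivity metrics
#' @return Character vector of metric names accepted by [compute_connectivity()].
#' @export
connectivity_metrics <- function() {
  c("coherence", "imaginary_coherence", "envelope_correlation",
    "power_correlation", "plv", "ccorr")
}

metric_fun <- function(name) {
  switch(name,
    coherence = coherence,
    imaginary_coherence = imaginary_coherence,
    envelope_correlation = envelope_correlation,
    power_correlation = power_correlation,
    plv = plv,
    ccorr = ccorr,
    ib_config_error("unknown metric '", name, "'; allowed: ",
                    paste(connectivity_metrics(), collapse = ", "))
  )
}
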