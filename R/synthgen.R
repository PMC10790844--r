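#' Ground-truth coupling parameters for synthetic dyads
#'
#' Describes a pair of synthetic EEG-like streams: a common narrowband
#' oscillation whose two copies differ by a slowly varying von Mises phase
#' offset (concentration `kappa`), log-normal amplitude envelopes with a
#' target Pearson correlation `env_corr`, and 1/f background noise at a given
#' signal-to-noise ratio.
#'
#' @param base_freq Oscillation frequency in Hz.
#' @param kappa Von Mises phase concentration (>= 0; 0 = independent phases).
#' @param env_corr Target Pearson correlation of the two envelopes, in
#'   \[-1, 1\] (the log-normal marginals bound how negative it can be; an
#'   unattainable target is a configuration error).
#' @param snr Ratio of oscillation power to background-noise power (> 0;
#'   `Inf` = noiseless).
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz (> 2 * `base_freq`).
#' @param seed Optional integer seed for reproducible generation.
#' @param env_sigma Log-scale SD of the log-normal envelopes (default 0.4).
#' @param env_cutoff Bandwidth (Hz) of the envelope modulation (default 2,
#'   the timescale of alpha-burst amplitude dynamics).
#' @param jitter_cutoff Bandwidth (Hz) of the phase-offset process
#'   (default 1); the offset is low-passed so the coupled stream stays
#'   narrowband.
#' @param drift_sd SD (radians) of the slow common phase drift (default 0.3).
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(base_freq = 10, kappa = 0, env_corr = 0, snr = 5,
                          duration = 60, fs = 250, seed = NULL,
                          env_sigma = 0.4, env_cutoff = 2,
                          jitter_cutoff = 1, drift_sd = 0.3) {
  if (kappa < 0) ib_config_error("kappa must be >= 0")
  if (abs(env_corr) > 1) ib_config_error("env_corr must be in [-1, 1]")
  if (!(snr > 0)) ib_config_error("snr must be > 0")
  if (fs <= 2 * base_freq)
    ib_config_error("fs must exceed 2 * base_freq (", 2 * base_freq, " Hz)")
  if (duration <= 0) ib_config_error("duration must be > 0")
  # feasibility of the Pearson target under log-normal marginals
  ev <- exp(env_sigma^2)
  if (1 + env_corr * (ev - 1) <= exp(-env_sigma^2))
    ib_config_error("env_corr = ", env_corr,
                    " is below the attainable range for env_sigma = ",
                    env_sigma)
  structure(list(base_freq = base_freq, kappa = kappa, env_corr = env_corr,
                 snr = snr, duration = duration, fs = fs, seed = seed,
                 env_sigma = env_sigma, env_cutoff = env_cutoff,
                 jitter_cutoff = jitter_cutoff, drift_sd = drift_sd),
            class = "coupling_spec")
}

#' Expected phase-locking value for a von Mises phase offset
#'
#' The mean resultant length of a von Mises(0, kappa) distribution,
#' `I1(kappa) / I0(kappa)` -- the population PLV of two signals whose phase
#' difference has that distribution.
#'
#' @param kappa Concentration parameter (vectorized, >= 0).
#' @return Values in \[0, 1); 0 at `kappa = 0`, approaching 1 as
#'   `kappa -> Inf`.
#' @export
expected_plv <- function(kappa) {
  stopifnot(all(kappa >= 0))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian process with exactly unit marginal variance and (two-sided)
# bandwidth `cutoff` Hz: ideal low-pass of white noise in the frequency
# domain. The mask's retained-bin count gives the output variance exactly
# (Parseval), so no empirical standardization is needed.
smooth_gaussian <- function(n, fs, cutoff) {
  x <- rnorm(n)
  if (cutoff >= fs / 2) return(x)
  X <- fft(x)
  freqs <- (seq_len(n) - 1L) / n * fs
  freqs <- pmin(freqs, fs - freqs)      # two-sided frequency axis
  mask <- as.numeric(freqs <= cutoff)
  keep <- sum(mask)
  if (keep < 3L) ib_stop("cutoff too low for this duration")
  Re(fft(X * mask, inverse = TRUE) / n) / sqrt(keep / n)
}

# quantile function of von Mises(0, kappa) via numerical CDF inversion
vonmises_quantile <- function(kappa, n_grid = 4096L) {
  if (kappa == 0) return(function(u) (u - 0.5) * 2 * pi)
  th <- seq(-pi, pi, length.out = n_grid)
  dens <- exp(kappa * (cos(th) - 1))    # scaled for numerical stability
  cdf <- cumsum(c(0, (dens[-1] + dens[-n_grid]) / 2 * diff(th)))
  cdf <- cdf / cdf[n_grid]
  approxfun(cdf, th, rule = 2, ties = "ordered")
}

# slowly varying phase-offset series with an exact von Mises marginal:
# Gaussian copula (low-passed standard normal -> uniform -> vM quantile)
vonmises_process <- function(n, fs, kappa, cutoff) {
  g <- smooth_gaussian(n, fs, cutoff)
  qf <- vonmises_quantile(kappa)
  qf(stats::pnorm(g))
}

# 1/f ("pink") noise with approximately unit variance
pink_noise <- function(n, fs) {
  x <- rnorm(n)
  X <- fft(x)
  freqs <- (seq_len(n) - 1L) / n * fs
  freqs <- pmin(freqs, fs - freqs)
  scale <- ifelse(freqs > 0, 1 / sqrt(pmax(freqs, fs / n)), 0)
  y <- Re(fft(X * scale, inverse = TRUE) / n)
  y / sd(y)
}

# correlated log-normal envelope pair with unit mean and target Pearson rho
envelope_pair <- function(n, fs, rho, sigma, cutoff) {
  ev <- exp(sigma^2)
  r_g <- log(1 + rho * (ev - 1)) / sigma^2   # Gaussian corr giving Pearson rho
  r_g <- max(-1, min(1, r_g))
  z1 <- smooth_gaussian(n, fs, cutoff)
  z0 <- smooth_gaussian(n, fs, cutoff)
  z2 <- r_g * z1 + sqrt(1 - r_g^2) * z0
  list(a = exp(sigma * z1 - sigma^2 / 2),
       b = exp(sigma * z2 - sigma^2 / 2))
}

#' Generate a synthetic coupled dyad
#'
#' Produces two single-channel streams: subject A carries an
#' amplitude-modulated oscillation at `base_freq` plus pink noise; subject B
#' carries the same oscillation offset by a slowly varying von Mises(0,
#' `kappa`) phase series (Gaussian-copula construction, so the offset's
#' marginal distribution is exactly von Mises and the population PLV is
#' exactly [expected_plv()]`(kappa)`), an envelope with Pearson correlation
#' `env_corr` to A's, and independent pink noise.
#'
#' @param spec A [coupling_spec()].
#' @return A named list of two [sample_window()]s (`A`, `B`) with the spec
#'   attached as attribute `truth`.
#' @export
generate_dyad <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  with_seed(spec$seed, {
    n <- as.integer(round(spec$duration * spec$fs))
    t <- (seq_len(n) - 1L) / spec$fs
    drift <- if (spec$drift_sd > 0)
      spec$drift_sd * smooth_gaussian(n, spec$fs, 0.3) else numeric(n)
    # shared slow phase wander: cancels within the dyad but decorrelates the
    # dyad from any other stream at the same base frequency (real oscillators
    # are not phase-coherent across subjects)
    wander <- vonmises_process(n, spec$fs, 0, spec$jitter_cutoff)
    phi <- 2 * pi * spec$base_freq * t + drift + wander
    delta <- vonmises_process(n, spec$fs, spec$kappa, spec$jitter_cutoff)
    env <- envelope_pair(n, spec$fs, spec$env_corr, spec$env_sigma,
                         spec$env_cutoff)
    sa <- env$a * cos(phi)
    sb <- env$b * cos(phi + delta)
    if (is.finite(spec$snr)) {
      nscale <- sqrt(mean(sa^2) / spec$snr)
      sa <- sa + nscale * pink_noise(n, spec$fs)
      sb <- sb + nscale * pink_noise(n, spec$fs)
    }
    out <- list(A = sample_window(sa, spec$fs),
                B = sample_window(sb, spec$fs))
    attr(out, "truth") <- spec
    out
  })
}

#' Generate a multi-subject synthetic session
#'
#' Builds `n_subjects` streams (named `S1`, `S2`, ...) where selected pairs
#' are phase/envelope coupled according to per-pair [coupling_spec()]s and
#' every other subject carries an independent oscillation plus noise. Each
#' subject may belong to at most one coupled pair.
#'
#' @param n_subjects Number of streams (>= 2).
#' @param coupling Named list of [coupling_spec()]s keyed `"Si|Sj"` (i < j).
#' @param duration,fs Session length (s) and sampling rate (Hz); every
#'   coupling spec must agree with `fs` and `duration`.
#' @param seed Optional integer seed.
#' @param background A [coupling_spec()] template for uncoupled subjects
#'   (its `kappa`/`env_corr` are ignored); defaults to `kappa = 0`,
#'   `env_corr = 0` with `fs`, `duration` and `snr` from the first coupling
#'   spec.
#' @return A list with `streams` (named list of [sample_window()]s) and
#'   `truth` (data.frame: pair, kappa, env_corr, expected_plv; uncoupled
#'   pairs have kappa 0).
#' @export
generate_session <- function(n_subjects, coupling, duration = NULL, fs = NULL,
                             seed = NULL, background = NULL) {
  stopifnot(n_subjects >= 2L, is.list(coupling), length(coupling) >= 1L)
  ids <- paste0("S", seq_len(n_subjects))
  template <- coupling[[1L]]
  fs <- fs %||% template$fs
  duration <- duration %||% template$duration
  for (key in names(coupling)) {
    sp <- coupling[[key]]
    if (sp$fs != fs || sp$duration != duration)
      ib_config_error("coupling spec '", key,
                      "' disagrees on fs/duration with the session")
  }
  members <- unlist(strsplit(names(coupling), "|", fixed = TRUE))
  if (anyDuplicated(members))
    ib_config_error("each subject may appear in at most one coupled pair")
  if (!all(members %in% ids))
    ib_config_error("coupling keys must reference subjects ",
                    paste(ids, collapse = ", "))

  with_seed(seed, {
    streams <- stats::setNames(vector("list", n_subjects), ids)
    for (key in names(coupling)) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      sp <- coupling[[key]]
      sp$seed <- NULL                     # session RNG governs
      dyad <- generate_dyad(sp)
      streams[[ab[1L]]] <- dyad$A
      streams[[ab[2L]]] <- dyad$B
    }
    bg <- background %||% coupling_spec(
      base_freq = template$base_freq, kappa = 0, env_corr = 0,
      snr = template$snr, duration = duration, fs = fs,
      env_sigma = template$env_sigma, env_cutoff = template$env_cutoff,
      jitter_cutoff = template$jitter_cutoff, drift_sd = template$drift_sd)
    for (id in ids[vapply(streams, is.null, logical(1))]) {
      bg$seed <- NULL
      solo <- generate_dyad(bg)           # independent stream: take one side
      streams[[id]] <- solo$A
    }
    pairs <- subject_pairs(ids)
    truth <- data.frame(pair = pairs$pair, kappa = 0, env_corr = 0,
                        stringsAsFactors = FALSE)
    for (key in names(coupling)) {
      i <- match(key, truth$pair)
      truth$kappa[i] <- coupling[[key]]$kappa
      truth$env_corr[i] <- coupling[[key]]$env_corr
    }
    truth$expected_plv <- expected_plv(truth$kappa)
    list(streams = streams, truth = truth)
  })
}
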