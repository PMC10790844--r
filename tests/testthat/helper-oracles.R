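# Independent oracles, written as plain loops over the metric definitions.
# These deliberately share no code with the package's vectorized paths.

oracle_coherence <- function(x, y) {
  s <- 0 + 0i; px <- 0; py <- 0
  for (t in seq_along(x)) {
    s <- s + x[t] * Conj(y[t])
    px <- px + abs(x[t])^2
    py <- py + abs(y[t])^2
  }
  Mod(s) / sqrt(px * py)
}

oracle_imaginary_coherence <- function(x, y) {
  s <- 0 + 0i; px <- 0; py <- 0
  for (t in seq_along(x)) {
    s <- s + x[t] * Conj(y[t])
    px <- px + abs(x[t])^2
    py <- py + abs(y[t])^2
  }
  abs(Im(s)) / sqrt(px * py)
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (t in seq_len(n)) {
    num <- num + (a[t] - ma) * (b[t] - mb)
    da <- da + (a[t] - ma)^2
    db <- db + (b[t] - mb)^2
  }
  num / sqrt(da * db)
}

oracle_envelope_correlation <- function(x, y) oracle_pearson(Mod(x), Mod(y))
oracle_power_correlation <- function(x, y) oracle_pearson(Mod(x)^2, Mod(y)^2)

oracle_plv <- function(x, y) {
  s <- 0 + 0i
  for (t in seq_along(x))
    s <- s + (x[t] / Mod(x[t])) * Conj(y[t] / Mod(y[t]))
  Mod(s) / length(x)
}

oracle_circ_mean <- function(theta) {
  s <- 0 + 0i
  for (t in seq_along(theta)) s <- s + exp(1i * theta[t])
  Arg(s)
}

oracle_ccorr <- function(x, y) {
  tx <- Arg(x); ty <- Arg(y)
  mx <- oracle_circ_mean(tx); my <- oracle_circ_mean(ty)
  num <- 0; dx <- 0; dy <- 0
  for (t in seq_along(tx)) {
    num <- num + sin(tx[t] - mx) * sin(ty[t] - my)
    dx <- dx + sin(tx[t] - mx)^2
    dy <- dy + sin(ty[t] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_metrics <- list(
  coherence = oracle_coherence,
  imaginary_coherence = oracle_imaginary_coherence,
  envelope_correlation = oracle_envelope_correlation,
  power_correlation = oracle_power_correlation,
  plv = oracle_plv,
  ccorr = oracle_ccorr
)

# random complex analytic-like window with non-degenerate envelope
random_complex_window <- function(n = 100L) {
  complex(real = rnorm(n), imaginary = rnorm(n))
}

# --- chance-level simulation oracle for the synthetic null (kappa = 0) -----
# Simulates the generator's documented phase-offset process from its
# definition (Gaussian copula over an ideal 1 Hz low-pass, uniform marginal)
# with independently written code, and returns per-rep PLV and CCorr values
# for windows of n samples at rate fs.

oracle_lowpass_unit_gaussian <- function(n, fs, cutoff) {
  z <- rnorm(n)
  spec <- fft(z)
  f <- (seq_len(n) - 1L) * fs / n
  f <- ifelse(f > fs / 2, fs - f, f)
  spec[f > cutoff] <- 0 + 0i
  kept <- sum(f <= cutoff)
  Re(fft(spec, inverse = TRUE)) / n / sqrt(kept / n)
}

oracle_null_chance <- function(n_rep, n, fs, cutoff = 1, base_freq = 10) {
  plv_vals <- numeric(n_rep)
  cc_vals <- numeric(n_rep)
  carrier <- 2 * pi * base_freq * (seq_len(n) - 1L) / fs
  for (r in seq_len(n_rep)) {
    g <- oracle_lowpass_unit_gaussian(n, fs, cutoff)
    delta <- (pnorm(g) - 0.5) * 2 * pi        # uniform marginal offset
    plv_vals[r] <- Mod(mean(exp(1i * delta)))
    zx <- exp(1i * carrier)
    zy <- exp(1i * (carrier + delta))
    cc_vals[r] <- oracle_ccorr_fast(Arg(zx), Arg(zy))
  }
  list(plv = plv_vals, ccorr = cc_vals)
}

# vectorized ccorr used only inside the chance oracle loop (1000 reps of
# element loops would be slow); still independent of the package code path
oracle_ccorr_fast <- function(tx, ty) {
  mx <- Arg(sum(exp(1i * tx))); my <- Arg(sum(exp(1i * ty)))
  sx <- sin(tx - mx); sy <- sin(ty - my)
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# numerical-integration oracle for the von Mises mean resultant length,
# independent of besselI
oracle_resultant <- function(kappa) {
  num <- integrate(function(th) cos(th) * exp(kappa * (cos(th) - 1)),
                   -pi, pi)$value
  den <- integrate(function(th) exp(kappa * (cos(th) - 1)), -pi, pi)$value
  num / den
}
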