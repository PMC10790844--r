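# Small fixtures built in code at test time.

# deterministic multichannel sine-mixture window
fixture_window <- function(n_channels = 2L, duration = 4, fs = 250,
                           freqs = c(10, 6), pad = 0) {
  t <- (seq_len(duration * fs) - 1L) / fs
  data <- sapply(seq_len(n_channels), function(k)
    sin(2 * pi * freqs[((k - 1L) %% length(freqs)) + 1L] * t + k))
  sample_window(data, fs, pad = pad)
}

# quick low-cost dyad for unit tests (not the calibration protocol)
fixture_dyad <- function(kappa = 4, env_corr = 0.5, duration = 10, seed = 42,
                         snr = 20) {
  generate_dyad(coupling_spec(kappa = kappa, env_corr = env_corr, snr = snr,
                              duration = duration, fs = 250, seed = seed))
}

single_band <- function(f_lo = 2, f_hi = 30, weight = 1)
  list(wide = band_spec("wide", f_lo, f_hi, weight))
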