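test_that("generation is bit-identical under a fixed seed", {
  sp <- coupling_spec(kappa = 2, env_corr = 0.5, snr = 5, duration = 4,
                      fs = 250, seed = 99)
  d1 <- generate_dyad(sp)
  d2 <- generate_dyad(sp)
  expect_identical(d1$A$data, d2$A$data)
  expect_identical(d1$B$data, d2$B$data)
  ses1 <- generate_session(3, list(`S1|S2` = sp), seed = 7)
  ses2 <- generate_session(3, list(`S1|S2` = sp), seed = 7)
  expect_identical(lapply(ses1$streams, `[[`, "data"),
                   lapply(ses2$streams, `[[`, "data"))
})

test_that("expected_plv is the von Mises mean resultant length", {
  expect_equal(expected_plv(0), 0)
  # against a numerical-integration oracle, independent of besselI
  for (k in c(0.5, 1, 2, 4, 8))
    expect_equal(expected_plv(k), oracle_resultant(k), tolerance = 1e-8)
  expect_equal(expected_plv(2), 0.6978, tolerance = 1e-4)
  # monotone, approaching 1
  ks <- c(0, 0.5, 1, 2, 4, 16, 64, 256)
  expect_true(all(diff(expected_plv(ks)) > 0))
  expect_gt(expected_plv(1000), 0.999)
})

test_that("invalid coupling specifications are rejected", {
  expect_error(coupling_spec(kappa = -1), class = "ibsync_config_error")
  expect_error(coupling_spec(env_corr = 1.2), class = "ibsync_config_error")
  expect_error(coupling_spec(snr = 0), class = "ibsync_config_error")
  expect_error(coupling_spec(base_freq = 10, fs = 15),
               class = "ibsync_config_error")
  # Pearson targets unattainable under the log-normal marginals
  expect_error(coupling_spec(env_corr = -0.99, env_sigma = 0.4),
               class = "ibsync_config_error")
})

test_that("the phase-offset process has the exact von Mises marginal", {
  set.seed(13)
  for (k in c(0.5, 2)) {
    # 800 s at a 20 Hz offset bandwidth: ~32000 effective samples, so the
    # resultant's Monte-Carlo SE is ~0.005 and 0.02 is a 4-sigma band
    delta <- ibsync:::vonmises_process(200000L, 250, k, cutoff = 20)
    expect_lt(abs(Mod(mean(exp(1i * delta))) - expected_plv(k)), 0.02)
    expect_lt(abs(Arg(mean(exp(1i * delta)))), 0.1)   # centred on zero
  }
})

test_that("near-deterministic coupling drives pipeline PLV towards 1", {
  d <- generate_dyad(coupling_spec(kappa = 1000, snr = 50, duration = 12,
                                   fs = 250, seed = 3))
  tab <- run_offline(d, session_config(bands = single_band(), metric = "plv",
                                       window_size = 3, hop_seconds = 1))
  expect_gte(mean(tab$value), 0.95)
})

test_that("measured PLV is ordered by the coupling strength", {
  # coarse, quick version of the calibration study (full run in acceptance)
  means <- sapply(c(0, 1, 4), function(k) {
    d <- generate_dyad(coupling_spec(kappa = k, snr = Inf, duration = 66,
                                     fs = 250, seed = 20 + k))
    tab <- run_offline(d, session_config(bands = single_band(),
                                         metric = "plv", window_size = 10,
                                         hop_seconds = 5))
    mean(tab$value)
  })
  expect_true(all(diff(means) > 0))
})

test_that("pipeline envelope correlation recovers the target over replicates", {
  cfg <- session_config(bands = single_band(), metric = "envelope_correlation",
                        window_size = 10, hop_seconds = 2, pad_seconds = 1)
  for (rho in c(0, 0.8)) {   # middle target exercised in the acceptance suite
    est <- mean(sapply(1:4, function(s) {
      d <- generate_dyad(coupling_spec(kappa = 4, env_corr = rho, snr = 50,
                                       duration = 60, fs = 250,
                                       seed = 1000 + s))
      mean(run_offline(d, cfg)$value)
    }))
    expect_lt(abs(est - rho), 0.1)
  }
})

test_that("sessions mark the coupled pair and rank it highest", {
  sp <- coupling_spec(kappa = 8, env_corr = 0.8, snr = 20, duration = 30,
                      fs = 250)
  ses <- generate_session(4, list(`S2|S3` = sp), seed = 31)
  expect_named(ses$streams, paste0("S", 1:4))
  expect_equal(nrow(ses$truth), 6L)
  expect_equal(ses$truth$kappa[ses$truth$pair == "S2|S3"], 8)
  expect_equal(ses$truth$expected_plv[ses$truth$pair != "S2|S3"], rep(0, 5))

  tab <- run_offline(ses$streams,
                     session_config(bands = single_band(), metric = "plv",
                                    window_size = 5, hop_seconds = 2.5))
  by_pair <- tapply(tab$value, tab$pair, mean)
  expect_equal(names(which.max(by_pair)), "S2|S3")
})

test_that("subjects cannot belong to two coupled pairs", {
  sp <- coupling_spec(duration = 2, fs = 250)
  expect_error(generate_session(3, list(`S1|S2` = sp, `S1|S3` = sp)),
               class = "ibsync_config_error")
  sp2 <- coupling_spec(duration = 3, fs = 250)
  expect_error(generate_session(3, list(`S1|S2` = sp, `S2|S3` = sp2)),
               class = "ibsync_config_error")
})

test_that("snr controls the background noise power", {
  base <- coupling_spec(kappa = 4, snr = Inf, duration = 8, fs = 250, seed = 55)
  noisy <- coupling_spec(kappa = 4, snr = 1, duration = 8, fs = 250, seed = 55)
  clean <- generate_dyad(base)
  loud <- generate_dyad(noisy)
  # at snr 1 the added noise roughly doubles total power
  ratio <- mean(loud$A$data^2) / mean(clean$A$data^2)
  expect_equal(ratio, 2, tolerance = 0.25)
})
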