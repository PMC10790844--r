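test_that("configuration validation reports every violation at once", {
  cfg <- session_config(metric = "nope", connectivity_type = "sideways",
                        window_size = 40, buffer_seconds = 30,
                        hop_seconds = -1)
  rep <- validate_config(cfg)
  expect_gte(nrow(rep), 3L)
  expect_true(any(grepl("unknown metric", rep$problem)))
  expect_true(any(grepl("one-to-one", rep$problem)))
  expect_true(any(grepl("buffer_seconds", rep$problem)))
  # band edge above Nyquist is caught once the sampling rate is known
  cfg2 <- session_config(bands = list(band_spec("hi", 100, 140)))
  expect_equal(nrow(validate_config(cfg2)), 0L)
  rep2 <- validate_config(cfg2, fs = 250)
  expect_true(any(grepl("Nyquist", rep2$problem)))
})

test_that("the default configuration is valid with a 3 s window and 30 s buffer", {
  cfg <- session_config()
  expect_equal(nrow(validate_config(cfg, fs = 250)), 0L)
  expect_equal(cfg$window_size, 3)
  expect_equal(cfg$buffer_seconds, 30)
})

test_that("hop arithmetic yields (duration - window) / hop + 1 frames", {
  set.seed(44)
  streams <- list(S1 = sample_window(rnorm(60 * 250), 250),
                  S2 = sample_window(rnorm(60 * 250), 250))
  cfg <- session_config(bands = single_band(), metric = "plv",
                        window_size = 3, hop_seconds = 0.25, pad_seconds = 0)
  tab <- run_offline(streams, cfg)
  expect_equal(length(unique(tab$timestamp)), (60 - 3) / 0.25 + 1)  # 229
})

test_that("no frame is emitted before window + pad seconds exist", {
  set.seed(45)
  streams <- list(S1 = sample_window(rnorm(10 * 250), 250),
                  S2 = sample_window(rnorm(10 * 250), 250))
  cfg <- session_config(bands = single_band(), metric = "plv",
                        window_size = 3, hop_seconds = 1, pad_seconds = 1)
  tab <- run_offline(streams, cfg)
  expect_equal(min(tab$timestamp), 4)          # window + pad
  # a recording shorter than window + pad yields zero frames with a warning
  short <- list(S1 = sample_window(rnorm(500), 250),
                S2 = sample_window(rnorm(500), 250))
  expect_warning(tab0 <- run_offline(short, cfg),
                 class = "ibsync_warming_up")
  expect_equal(nrow(tab0), 0L)
})

test_that("simulated-live and offline analysis agree value-for-value", {
  dyad <- fixture_dyad(duration = 12, seed = 77)
  files <- c(A = withr::local_tempfile(fileext = ".csv"),
             B = withr::local_tempfile(fileext = ".csv"))
  write_eeg_csv(dyad$A, files[["A"]])
  write_eeg_csv(dyad$B, files[["B"]])
  cfg <- session_config(bands = list(alpha = band_spec("alpha", 8, 12)),
                        metric = "ccorr", window_size = 3,
                        hop_seconds = 0.5, pad_seconds = 1)
  offline <- run_offline(files, cfg)

  rec <- withr::local_tempfile(fileext = ".csv")
  res <- run_session(files, cfg, sinks = list(memory_sink(), csv_sink(rec)))
  live <- do.call(rbind, lapply(res$frames, function(p) {
    df <- as.data.frame(unpack_frame(p))
    data.frame(timestamp = p$timestamp, pair = df$pair, band = df$band,
               value = df$value)
  }))
  # in-memory frames are exactly the offline table
  expect_equal(live$value, offline$value, tolerance = 1e-14)
  expect_equal(live$timestamp, offline$timestamp)
  # the CSV recording matches value-for-value (up to text round-trip)
  tab <- read_frames_csv(rec)
  expect_equal(tab$value, offline$value, tolerance = 1e-12)
  expect_equal(tab$pair, offline$pair)
})

test_that("normalization and band power flow through the live loop", {
  dyad <- fixture_dyad(duration = 8, seed = 78)
  cfg <- session_config(bands = single_band(), metric = "plv",
                        window_size = 3, hop_seconds = 1, pad_seconds = 1,
                        normalization = normalization_spec(0.2, 0.8),
                        send_power = TRUE)
  res <- run_session(dyad, cfg)
  vals <- unlist(lapply(res$frames, `[[`, "vector"))
  expect_true(all(vals >= 0 & vals <= 1))
  pw <- res$frames[[1]]$power
  expect_length(pw, 2L)                         # 1 band x 2 streams x 1 ch
  expect_true(all(pw > 0))
  expect_match(names(pw)[1], "^A\\.wide")
})

test_that("unreadable sources and unequal rates are rejected up front", {
  expect_error(run_offline(c(A = "no-such-file.csv", B = "other.csv")),
               "cannot read")
  streams <- list(S1 = sample_window(rnorm(1000), 250),
                  S2 = sample_window(rnorm(1000), 200))
  expect_error(run_offline(streams), class = "ibsync_config_error")
  expect_error(run_offline(list(S1 = sample_window(rnorm(1000), 250))),
               class = "ibsync_config_error")
})

test_that("identical configuration and seed give identical frame sequences", {
  sp <- coupling_spec(kappa = 3, env_corr = 0.4, snr = 10, duration = 8,
                      fs = 250, seed = 11)
  cfg <- session_config(bands = single_band(), metric = "plv",
                        window_size = 3, hop_seconds = 1)
  t1 <- run_offline(generate_dyad(sp), cfg)
  t2 <- run_offline(generate_dyad(sp), cfg)
  expect_identical(t1, t2)
})
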