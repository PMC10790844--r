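test_that("every metric matches the direct-summation oracle on random windows", {
  set.seed(11)
  for (rep in seq_len(200)) {
    x <- random_complex_window(100L)
    y <- random_complex_window(100L)
    for (m in connectivity_metrics()) {
      f <- get(m, asNamespace("ibsync"))
      got <- as.numeric(f(x, y))
      want <- oracle_metrics[[m]](x, y)
      expect_equal(got, want, tolerance = 1e-10,
                   label = sprintf("%s (rep %d)", m, rep))
    }
  }
})

test_that("analytic limit cases hold exactly", {
  set.seed(3)
  x <- random_complex_window(200L)
  expect_equal(coherence(x, x), 1)
  expect_equal(coherence(x, 3 * x), 1)            # amplitude-scale invariance
  expect_equal(imaginary_coherence(x, x), 0)
  expect_equal(imaginary_coherence(x, 1i * x), coherence(x, 1i * x))
  expect_equal(envelope_correlation(x, x), 1)
  expect_equal(power_correlation(x, x), 1)
  # anti-modulated envelopes
  t <- seq_len(300)
  ex <- 1 + 0.5 * sin(t / 10)
  x2 <- ex * exp(1i * t)
  y2 <- (3 - ex) * exp(1i * t)
  expect_equal(envelope_correlation(x2, y2), -1)
  # constant relative phase
  expect_equal(plv(x, x * exp(1i * 0.7)), 1)
  expect_equal(ccorr(x, x * exp(1i * 0.7)), 1, tolerance = 1e-9)
})

test_that("metrics are symmetric and respect their ranges", {
  set.seed(21)
  for (rep in seq_len(50)) {
    x <- random_complex_window(80L)
    y <- random_complex_window(80L)
    for (m in c("coherence", "imaginary_coherence", "plv")) {
      f <- get(m, asNamespace("ibsync"))
      v <- as.numeric(f(x, y))
      expect_equal(v, as.numeric(f(y, x)), tolerance = 1e-12)
      expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    }
    for (m in c("envelope_correlation", "power_correlation", "ccorr")) {
      f <- get(m, asNamespace("ibsync"))
      v <- as.numeric(f(x, y))
      expect_equal(v, as.numeric(f(y, x)), tolerance = 1e-12)
      expect_gte(v, -1 - 1e-12); expect_lte(v, 1 + 1e-12)
    }
  }
})

test_that("PLV is invariant to independent amplitude rescaling", {
  set.seed(5)
  x <- random_complex_window(150L)
  y <- random_complex_window(150L)
  ax <- runif(150, 0.1, 5)
  ay <- runif(150, 0.1, 5)
  expect_equal(plv(ax * x, ay * y), plv(x, y), tolerance = 1e-12)
})

test_that("degenerate inputs return flagged zeros instead of NaN", {
  n <- 50L
  zero <- complex(real = rep(0, n), imaginary = rep(0, n))
  x <- random_complex_window(n)
  for (m in c("coherence", "imaginary_coherence", "plv", "ccorr")) {
    v <- get(m, asNamespace("ibsync"))(zero, x)
    expect_identical(as.numeric(v), 0)
    expect_true(isTRUE(attr(v, "degenerate")), label = m)
  }
  # constant envelope is degenerate for amplitude correlations
  const <- exp(1i * seq_len(n))
  for (m in c("envelope_correlation", "power_correlation")) {
    v <- get(m, asNamespace("ibsync"))(const, x)
    expect_identical(as.numeric(v), 0)
    expect_true(isTRUE(attr(v, "degenerate")), label = m)
  }
  # constant phase has zero circular variance
  v <- ccorr(Mod(x) + 0i, x)
  expect_identical(as.numeric(v), 0)
  expect_true(isTRUE(attr(v, "degenerate")))
})

test_that("worked 4-sample examples match hand-expanded sums", {
  x <- complex(real = c(1, 0.5, -0.2, 0.8), imaginary = c(0.3, -1, 0.7, 0.1))
  y <- complex(real = c(-0.4, 1.2, 0.6, -0.9), imaginary = c(0.8, 0.2, -0.5, 0.4))
  expect_equal(as.numeric(imaginary_coherence(x, y)),
               oracle_imaginary_coherence(x, y), tolerance = 1e-14)
  expect_equal(as.numeric(ccorr(x, y)), oracle_ccorr(x, y), tolerance = 1e-14)
  expect_equal(as.numeric(power_correlation(x, y)),
               oracle_power_correlation(x, y), tolerance = 1e-14)
})

test_that("null PLV of independent uniform phases follows the Rayleigh law", {
  set.seed(9)
  n <- 1000L
  reps <- 300L
  vals <- replicate(reps, {
    x <- exp(1i * runif(n, -pi, pi))
    y <- exp(1i * runif(n, -pi, pi))
    as.numeric(plv(x, y))
  })
  # E[PLV] = sqrt(pi) / (2 sqrt(N)) for independent phases
  expected <- sqrt(pi) / (2 * sqrt(n))
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - expected), 4 * se + 0.002)
})

test_that("null CCorr of independent uniform phases is centred on zero", {
  set.seed(10)
  n <- 1000L
  reps <- 300L
  vals <- replicate(reps, {
    x <- exp(1i * runif(n, -pi, pi))
    y <- exp(1i * runif(n, -pi, pi))
    as.numeric(ccorr(x, y))
  })
  expect_lt(abs(mean(vals)), 4 * sd(vals) / sqrt(reps))
})
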