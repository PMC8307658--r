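# Feature-level checks against independent closed-form / spectral oracles.

tukey_ref <- function(N, r) {
  n <- seq_len(N) - 1
  w <- rep(1, N)
  edge <- floor(r * (N - 1) / 2)
  idx <- 0:edge
  taper <- 0.5 * (1 + cos(pi * (2 * idx / (r * (N - 1)) - 1)))
  w[idx + 1] <- taper
  w[N - idx] <- taper
  w
}

test_that("AMSA matches the leakage-corrected single-tone closed form", {
  fs <- 250; N <- 1250; A <- 2; f0 <- 10
  x <- A * cos(2 * pi * f0 * (0:(N - 1)) / fs)
  got <- amsa(x, fs)
  # oracle: an on-bin tone's windowed DFT is the window spectrum imaged at
  # +-the tone bin, X_k = (A/2) (W[k-k0] + W[k+k0])
  w <- tukey_ref(N, 0.1)
  Wc <- fft(w)
  k0 <- f0 * N / fs
  fr <- (0:(N - 1)) * fs / N
  k <- 0:(N - 1)
  Xk <- (A / 2) * (Wc[((k - k0) %% N) + 1] + Wc[((k + k0) %% N) + 1])
  sel <- fr >= 2 & fr <= 30
  expected <- sum(fr[sel] * 2 * Mod(Xk[sel]) / sum(w))
  expect_equal(got, expected, tolerance = 1e-6)
  # the amplitude-sum window-gain constant is modest and positive
  expect_gt(got / (A * f0), 1); expect_lt(got / (A * f0), 3)
  expect_identical(amsa(numeric(N), fs), 0)
})

test_that("AMSA is additive over spectrally disjoint tones", {
  fs <- 250; N <- 1250; n <- 0:(N - 1)
  t1 <- 1.0 * cos(2 * pi * 5 * n / fs)
  t2 <- 0.5 * cos(2 * pi * 15 * n / fs)
  expect_equal(amsa(t1 + t2, fs), amsa(t1, fs) + amsa(t2, fs),
               tolerance = 0.01)
})

test_that("high-band power obeys Parseval on tones", {
  fs <- 250; N <- 1250; n <- 0:(N - 1)
  x25 <- 2 * cos(2 * pi * 25 * n / fs)
  expect_equal(high_power(x25, fs), 2^2 / 2, tolerance = 0.01)
  x5 <- 2 * cos(2 * pi * 5 * n / fs)
  expect_lt(high_power(x5, fs), 0.01 * 2^2 / 2)
  expect_identical(high_power(numeric(N), fs), 0)
})

test_that("fuzzy entropy ranks noise above a sinusoid and scales away", {
  set.seed(20)
  noise <- rnorm(1250)
  sine <- sqrt(2) * sin(2 * pi * 7 * (0:1249) / 250)  # unit variance
  expect_gt(fuzzen(noise), fuzzen(sine))
  expect_identical(fuzzen(rep(3.2, 1250)), 0)
  expect_equal(fuzzen(noise), fuzzen(50 * noise), tolerance = 1e-10)
})

test_that("smoothed nonlinear energy matches the Teager closed form", {
  A <- 1.5; nu <- 0.1
  x <- A * sin(2 * pi * nu * (0:1249))
  expect_equal(sneo(x, 250), A^2 * sin(2 * pi * nu)^2, tolerance = 0.02)
  expect_lt(abs(sneo(rep(2, 1250), 250)), 1e-12)
  set.seed(21)
  z <- rnorm(1250)
  expect_equal(sneo(2 * z, 250), 4 * sneo(z, 250), tolerance = 1e-12)
})

test_that("IQR uses the linear-interpolation convention", {
  expect_equal(iqr_feature(c(1, 2, 3, 4)), 1.5)
  expect_identical(iqr_feature(rep(7, 100)), 0)
  set.seed(22)
  x <- rnorm(100)
  expect_equal(iqr_feature(x + 10), iqr_feature(x), tolerance = 1e-12)
})

test_that("Burg noise variance identifies white noise and AR processes", {
  set.seed(23)
  s <- 0.7
  x <- rnorm(1250, 0, s)
  expect_equal(burg_noise_var(x, 4), s^2, tolerance = 0.15)
  # AR(2) with known innovation variance
  e_sd <- 0.3
  y <- as.numeric(stats::filter(rnorm(1250, 0, e_sd), c(1.2, -0.5),
                                method = "recursive"))
  expect_equal(burg_noise_var(y, 4), e_sd^2, tolerance = 0.15)
  # a noiseless line spectrum is absorbed by the AR poles
  tone <- sin(2 * pi * 12 * (0:1249) / 250)
  expect_lt(burg_noise_var(tone, 4), 0.01 * mean(tone^2))
  expect_error(burg_noise_var(1:3, 4), "order")
})

test_that("log power is the guarded log mean square", {
  expect_equal(log_power(numeric(100)), log(1e-12))
  A <- 3
  x <- A * cos(2 * pi * 10 * (0:1249) / 250)  # integer periods
  expect_equal(log_power(x), log(1e-12 + A^2 / 2), tolerance = 1e-9)
  expect_equal(log_power(10 * x) - log_power(x), log(100), tolerance = 1e-6)
})

test_that("cross power reduces to band power for identical tones", {
  fs <- 250; n <- 0:1249
  x <- cos(2 * pi * 4 * n / fs)
  expect_equal(cross_power(x, x, fs), 1 / 2, tolerance = 0.1)
  expect_identical(cross_power(x, numeric(1250), fs), 0)
  set.seed(24)
  e <- rnorm(1250); i <- rnorm(1250)
  expect_lt(cross_power(e, i, fs),
            0.4 * sqrt(cross_power(e, e, fs) * cross_power(i, i, fs)))
})

test_that("extract_features returns exactly 17 named, finite values", {
  seg <- simulate_pea_segment("faPEA", synth_params(), seed = 55)
  fv <- extract_features(seg)
  expect_length(fv, 17)
  expect_identical(names(fv), pea_feature_names())
  expect_identical(sum(startsWith(names(fv), "ecg_")), 9L)
  expect_identical(sum(startsWith(names(fv), "icc_")) +
                     sum(names(fv) == "cross_power"), 8L)
  expect_true(all(is.finite(fv)))
  expect_true(attr(fv, "icc_available"))
  # determinism
  expect_identical(fv, extract_features(seg))
})

test_that("features stay finite on degenerate segments", {
  # all-zero ECG: no beats, ICC unavailable, everything still finite
  seg0 <- pea_segment("z", numeric(1250), rnorm(1250) + 500, fs = 250)
  fv0 <- extract_features(seg0)
  expect_false(attr(fv0, "icc_available"))
  expect_true(all(fv0[10:17] == 0))
  expect_true(all(is.finite(fv0)))
  # pure-noise segment
  set.seed(26)
  segn <- pea_segment("n", rnorm(1250, 0, 0.05), rnorm(1250) + 500, fs = 250)
  expect_true(all(is.finite(extract_features(segn))))
})

test_that("metadata never leaks into the features", {
  set.seed(27)
  ecg <- rnorm(1250, 0, 0.2); ti <- rnorm(1250) + 800
  a <- extract_features(pea_segment("pA", ecg, ti, fs = 250,
                                    label = "faPEA", t_onset = 10))
  b <- extract_features(pea_segment("pB", ecg, ti, fs = 250,
                                    label = "unPEA", t_onset = 400))
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("class contrasts point the documented way on a synthetic cohort", {
  ft <- cohort_a_features()
  med <- function(f, l) median(ft[[f]][ft$label == l])
  for (f in c("ecg_amsa", "ecg_highpower", "icc_logpower", "cross_power"))
    expect_gt(med(f, "faPEA"), med(f, "unPEA"))
})
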