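test_that("the observation row matches its closed form", {
  expect_equal(build_observation_row(0.1, 0, 5),
               c(rep(1, 5), rep(0, 5)))
  expect_equal(build_observation_row(0.25, 1, 1), c(cos(pi / 2), sin(pi / 2)),
               tolerance = 1e-12)
  expect_equal(build_observation_row(0.125, 2, 2), c(0, -1, 1, 0),
               tolerance = 1e-12)
})

test_that("constant Fourier coefficients are recovered by the smoother", {
  set.seed(10)
  N <- 1250; f <- rep(0.004, N); n0 <- 0:(N - 1)
  ti <- 1 * cos(2 * pi * 0.004 * n0) + rnorm(N, 0, 0.01)
  fit <- kalman_rts_smooth(ti, f, K = 1)
  central <- 126:1125  # central 80%
  expect_true(all(fit$coeffs_a[central, 1] > 0.9))
  expect_true(all(fit$coeffs_a[central, 1] < 1.1))
  expect_lt(max(abs(fit$coeffs_b[central, 1])), 0.1)
  # convergence within a 1-s transient from an uninformative start
  after_1s <- 251:1250
  expect_true(all(abs(fit$coeffs_a[after_1s, 1] - 1) < 0.1))
})

test_that("zero input yields a zero circulation component", {
  fit <- kalman_rts_smooth(numeric(1250), rep(0.004, 1250), K = 3)
  expect_lt(max(abs(fit$icc)), 1e-6)
})

test_that("the smoother is linear in the observation at fixed gains", {
  set.seed(11)
  N <- 1250; f <- rep(0.005, N)
  ti <- cos(2 * pi * 0.005 * (0:(N - 1))) + rnorm(N, 0, 0.05)
  f1 <- kalman_rts_smooth(ti, f, K = 2, r_obs = 0.01, p0_scale = 1)
  f2 <- kalman_rts_smooth(2 * ti, f, K = 2, r_obs = 0.01, p0_scale = 1)
  expect_lt(max(abs(f2$icc - 2 * f1$icc)), 1e-9)
})

test_that("the RTS pass never inflates the state covariance", {
  set.seed(12)
  seg <- simulate_pea_segment("faPEA", synth_params(), seed = 33)
  ti_f <- bandpass_ti(seg$ti, 250)
  fit <- kalman_rts_smooth(ti_f, attr(seg, "f_true"))
  expect_true(all(fit$trace_smooth <= fit$trace_filter + 1e-9))
})

test_that("slowly varying harmonic components are reconstructed", {
  # small-scale version of the recovery study: AR(1)-modulated
  # coefficients with the pole matching the smoother prior, SNR 10 dB
  cors <- vapply(1:10, function(s) {
    seg <- simulate_pea_segment("faPEA", synth_params(noise_sd_ti = 0),
                                seed = 200 + s)
    icc <- attr(seg, "icc_true")
    noise_sd <- sqrt(mean(icc^2) / 10)
    ti <- icc + rnorm(length(icc), 0, noise_sd)
    fit <- kalman_rts_smooth(ti, attr(seg, "f_true"))
    cor(fit$icc, icc)
  }, 0)
  expect_gt(median(cors), 0.9)
})

test_that("undefined heart rate makes the ICC unavailable", {
  expect_error(kalman_rts_smooth(rnorm(100), rep(0, 100)),
               class = "pea_icc_unavailable")
})

test_that("ICC denoising keeps the circulation band and drops the rest", {
  fs <- 250; t <- (0:1249) / fs
  x4 <- sin(2 * pi * 4 * t)
  out4 <- denoise_icc(x4, fs)
  expect_gt(mean(out4^2) / mean(x4^2), 0.8)
  x20 <- sin(2 * pi * 20 * t)
  out20 <- denoise_icc(x20, fs)
  expect_lt(mean(out20^2) / mean(x20^2), 0.1)
  expect_identical(denoise_icc(numeric(1250), fs), numeric(1250))
})

test_that("icc_fit exposes fitted values and residuals", {
  set.seed(13)
  ti <- cos(2 * pi * 0.004 * (0:1249)) + rnorm(1250, 0, 0.05)
  fit <- kalman_rts_smooth(ti, rep(0.004, 1250), K = 1)
  expect_equal(fitted(fit) + residuals(fit), ti, tolerance = 1e-12)
})
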