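test_that("smooth_and_detrend: constant in, zero detrended out; cubic preserved", {
  sd0 <- smooth_and_detrend(rep(50, 400))
  expect_equal(sd0$detrended, rep(0, 400), tolerance = 1e-9)
  expect_equal(sd0$trend, rep(50, 400), tolerance = 1e-9)
  # Savitzky-Golay of order 3 reproduces a cubic exactly in the interior
  t <- seq(0, 1, length.out = 400)
  y <- 5 + 2 * t - 3 * t^2 + t^3
  f <- smooth_and_detrend(y, trend_sigma_s = 1e6)$filtered
  interior <- 41:360
  expect_equal(f[interior], y[interior], tolerance = 1e-8)
  expect_warning(smooth_and_detrend(rnorm(50) + 100), "shrunk")
})

test_that("a 5% relative sinusoid is recovered as ~5% mean amplitude", {
  t <- 0:1199                               # 10 cycles of a 120 s period
  area <- 40 * (1 + 0.05 * sin(2 * pi * t / 120))
  sdd <- smooth_and_detrend(area)
  r <- instantaneous_amplitude(sdd$detrended, sdd$trend)
  expect_lt(abs(r$mean_amplitude_pct - 5), 0.5)
  # scale invariance: doubling the area leaves the percentage unchanged
  sdd2 <- smooth_and_detrend(2 * area)
  r2 <- instantaneous_amplitude(sdd2$detrended, sdd2$trend)
  expect_equal(r2$mean_amplitude_pct, r$mean_amplitude_pct, tolerance = 1e-6)
  # zero detrended signal: zero amplitude
  r0 <- instantaneous_amplitude(rep(0, 300), rep(40, 300))
  expect_equal(r0$mean_amplitude_pct, 0)
  expect_error(instantaneous_amplitude(rnorm(100), rep(-1, 100)),
               class = "numeric_domain")
})

test_that("area_rate implements the normalized finite-difference formula", {
  expect_equal(area_rate(rep(100, 200), 1, 101), 0)
  a <- seq(100, 80, length.out = 101)
  expect_equal(area_rate(a, 1, 101), (-0.2) / 90, tolerance = 1e-12)
  # sign flips under time reversal
  expect_equal(area_rate(rev(a), 1, 101), -area_rate(a, 1, 101))
  expect_error(area_rate(a, 50, 50), class = "invalid_window")
})

test_that("ventral furrow summary normalizes to 100% at t=0 and averages rates", {
  n_fr <- 6.6 * 60 + 1
  const <- matrix(100, n_fr, 5)
  vf <- ventral_furrow_summary(const)
  expect_equal(vf$trajectory$mean_pct, rep(100, n_fr))
  expect_equal(vf$mean_rate_pct_per_min, 0)
  lin <- sapply(runif(8, 50, 200), function(a0) seq(a0, a0 / 2, length.out = n_fr))
  vf2 <- ventral_furrow_summary(lin)
  expect_equal(tail(vf2$trajectory$mean_pct, 1), 50, tolerance = 1e-9)
  expect_equal(vf2$mean_rate_pct_per_min, -50 / 6.6, tolerance = 1e-9)
  # hand-computed mean/SE on a mixed cohort
  set.seed(3)
  mix <- sapply(1:6, function(i) seq(100, 100 - 10 * i, length.out = n_fr))
  vf3 <- ventral_furrow_summary(mix)
  rates <- (mix[n_fr, ] / mix[1, ] * 100 - 100) / 6.6
  expect_equal(vf3$mean_rate_pct_per_min, mean(rates))
  expect_equal(vf3$se_rate_pct_per_min, sd(rates) / sqrt(6))
})

test_that("interface rate windows give pre/during/post contraction rates", {
  L <- rep(10, 300)
  L[101:151] <- seq(10, 9, length.out = 51)  # -1 um over 50 s
  L[152:300] <- 9
  r <- interface_rate_windows(L, 101, 151)
  expect_equal(r$rate_um_per_s[r$window == "pre"], 0)
  expect_equal(r$rate_um_per_s[r$window == "during"], -1 / 50, tolerance = 1e-9)
  expect_equal(r$rate_um_per_s[r$window == "post"], 0)
  expect_false(any(r$truncated))
  # interval at movie start: pre flagged truncated
  r2 <- interface_rate_windows(L, 10, 60)
  expect_true(r2$truncated[r2$window == "pre"])
  expect_error(interface_rate_windows(L, 0, 50), class = "invalid_interval")
  # formula check: 10 -> 8 um in 100 s
  L3 <- c(seq(10, 8, length.out = 101), rep(8, 50))
  r3 <- interface_rate_windows(L3, 1, 101)
  expect_equal(r3$rate_um_per_s[2], -0.02, tolerance = 1e-9)
})

test_that("amplitude is invariant to positive rescaling of the whole series", {
  set.seed(5)
  t <- 0:999
  area <- 30 * (1 + 0.08 * sin(2 * pi * t / 90 + 1)) + rnorm(1000, 0, 0.2)
  a1 <- oscillation_amplitudes(matrix(area, ncol = 1))$mean_amplitude_pct
  a2 <- oscillation_amplitudes(matrix(3.7 * area, ncol = 1))$mean_amplitude_pct
  expect_equal(a1, a2, tolerance = 1e-8)
})
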