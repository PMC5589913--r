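test_that("rolling gamma calibrates to 2 (ballistic), 1 (Brownian), <1 (stationary)", {
  set.seed(21)
  ball <- 10 - 0.05 * (0:499) + rnorm(500, 0, 0.01)
  expect_gte(median(rolling_gamma(ball), na.rm = TRUE), 1.8)
  bro <- cumsum(rnorm(500, 0, 0.1))
  expect_lt(abs(median(rolling_gamma(bro), na.rm = TRUE) - 1), 0.3)
  noi <- rnorm(500, 0, 0.05)
  expect_lte(median(rolling_gamma(noi), na.rm = TRUE), 0.5)
})

test_that("gamma is NA where no window fits and windows shrink gracefully", {
  x <- cumsum(rnorm(100))
  g <- rolling_gamma(x, windows = c(21, 41))
  expect_true(all(is.na(g[1:10])))
  expect_true(all(is.na(g[91:100])))
  expect_true(all(!is.na(g[21:80])))
  expect_error(rolling_gamma(rnorm(10), windows = 21), class = "invalid_input")
  expect_error(rolling_gamma(rnorm(50), windows = 20), class = "invalid_input")
})

test_that("staircase trajectories yield the designed steps with correct displacement", {
  s <- synth_trajectories(n = 1, N = 400, noise_sd = 0.05, C = 0.05,
                          runs = list(n_runs = 3, duration = 20, mode = "control"),
                          seed = 31)
  x <- s$trajectories[, 1]
  g <- rolling_gamma(x)
  ann <- detect_steps(x, g)
  expect_equal(nrow(ann$steps), 3)
  truth <- s$truth$runs[[1]]
  for (i in 1:3) {
    ov <- ann$steps$start <= truth$end[i] & ann$steps$end >= truth$start[i]
    expect_true(any(ov))
  }
  expect_lt(abs(sum(ann$steps$displacement_um) - sum(truth$displacement_um)), 0.6)
})

test_that("runs shorter than the minimum duration are never reported", {
  g <- rep(0, 200)
  g[50:59] <- 2.5        # 10-frame active run: below the 14-frame minimum
  ann <- detect_steps(rnorm(200, 10, 0.01), g)
  expect_equal(nrow(ann$steps), 0)
  g[100:113] <- 2.5      # exactly 14 frames: accepted
  ann2 <- detect_steps(rnorm(200, 10, 0.01), g)
  expect_equal(nrow(ann2$steps), 1)
  expect_equal(ann2$steps$duration_frames, 14)
  # with calibration off, the literal gamma > 1 rule applies
  g1 <- rep(0, 200); g1[20:40] <- 1.2
  expect_equal(nrow(detect_steps(rep(10, 200), g1, calibrate = FALSE)$steps), 1)
  expect_equal(nrow(detect_steps(rep(10, 200), g1, calibrate = TRUE)$steps), 0)
})

test_that("step detection is shift-invariant and sign-flips under negation", {
  s <- synth_trajectories(n = 1, N = 300, noise_sd = 0.03, C = 0.06,
                          runs = list(n_runs = 2, duration = 25), seed = 33)
  x <- s$trajectories[, 1]
  g <- rolling_gamma(x)
  a1 <- detect_steps(x, g)
  a2 <- detect_steps(x + 100, g)
  expect_equal(a1$steps$displacement_um, a2$steps$displacement_um)
  g_neg <- rolling_gamma(-x)
  a3 <- detect_steps(-x, g_neg)
  expect_equal(nrow(a3$steps), nrow(a1$steps))
  if (nrow(a3$steps) == nrow(a1$steps))
    expect_equal(a3$steps$displacement_um, -a1$steps$displacement_um,
                 tolerance = 0.2)
})

test_that("false-positive rate is low on diffusion; recall is high on strong runs", {
  set.seed(35)
  fp <- replicate(25, {
    s <- synth_trajectories(n = 1, N = 300, B = 1e-4, noise_sd = 0.05,
                            seed = sample.int(1e6, 1))
    x <- s$trajectories[, 1]
    mean(detect_steps(x, rolling_gamma(x))$active_mask)
  })
  expect_lte(mean(fp), 0.05)
  hits <- replicate(25, {
    s <- synth_trajectories(n = 1, N = 300, B = 1e-4, noise_sd = 0.05, C = 0.05,
                            runs = list(n_runs = 2, duration = 20),
                            seed = sample.int(1e6, 1))
    x <- s$trajectories[, 1]
    ann <- detect_steps(x, rolling_gamma(x))
    truth <- s$truth$runs[[1]]
    mean(vapply(seq_len(nrow(truth)), function(i)
      any(ann$steps$start <= truth$end[i] & ann$steps$end >= truth$start[i]),
      logical(1)))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("step metrics aggregate frequency, duration and net displacement", {
  # one 14-frame step in a 140-frame trajectory
  g <- rep(0, 140); g[30:43] <- 2.5
  x <- rep(10, 140)
  ann <- detect_steps(x, g)
  m <- step_metrics(list(ann))
  expect_equal(m$per_interface$n_steps, 1)
  expect_equal(m$per_interface$frequency_per_min, 1 / (140 / 60))
  expect_equal(m$per_interface$mean_duration_s, 14)
  # empty annotation: zero frequency, missing duration
  ann0 <- detect_steps(rep(10, 50), rep(0, 50))
  m0 <- step_metrics(list(ann0))
  expect_equal(m0$per_interface$frequency_per_min, 0)
  expect_true(is.na(m0$per_interface$mean_duration_s))
})

test_that("ratchet-off cohorts have near-zero net stepped displacement", {
  run_cohort <- function(mode, seed) {
    s <- synth_trajectories(n = 15, N = 400, noise_sd = 0.03, C = 0.05,
                            runs = list(n_runs = 4, duration = 20, mode = mode),
                            seed = seed)
    anns <- lapply(seq_len(ncol(s$trajectories)), function(j) {
      x <- s$trajectories[, j]
      detect_steps(x, rolling_gamma(x))
    })
    step_metrics(anns)
  }
  ctrl <- run_cohort("control", 41)
  roff <- run_cohort("ratchet_off", 42)
  expect_lt(abs(roff$summary$mean_net_displacement_um),
            0.2 * abs(ctrl$summary$mean_net_displacement_um))
  expect_lt(abs(roff$summary$mean_frequency_per_min -
                  ctrl$summary$mean_frequency_per_min) /
              ctrl$summary$mean_frequency_per_min, 0.25)
})
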