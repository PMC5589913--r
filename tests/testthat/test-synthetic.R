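test_that("generators are deterministic given the seed", {
  a <- synth_trajectories(n = 3, N = 100, A = 0.2, B = 0.001, noise_sd = 0.02,
                          seed = 7)
  b <- synth_trajectories(n = 3, N = 100, A = 0.2, B = 0.001, noise_sd = 0.02,
                          seed = 7)
  expect_identical(a, b)
  t1 <- synth_tissue("control", n_rows = 3, n_cols = 3, n_frames = 50,
                     n_steps = 1, seed = 5)
  t2 <- synth_tissue("control", n_rows = 3, n_cols = 3, n_frames = 50,
                     n_steps = 1, seed = 5)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$truth, t2$truth)
  s1 <- synth_spot_movie(5, 30, seed = 9)
  s2 <- synth_spot_movie(5, 30, seed = 9)
  expect_identical(s1$stack, s2$stack)
  # generators restore the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(synth_trajectories(n = 1, N = 50, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("trajectory generator honours its components", {
  z <- synth_trajectories(n = 2, N = 50, seed = 1)
  expect_true(all(z$trajectories == 10))
  # Brownian ensemble MSD slope ~ 2B
  B <- 0.002
  s <- synth_trajectories(n = 500, N = 60, B = B, seed = 2)
  disp2 <- colMeans(t(apply(s$trajectories, 2, function(x) (x - x[1])^2)))
  slope <- coef(lm(disp2[2:30] ~ 0 + I(1:29)))
  expect_lt(abs(slope - 2 * B) / (2 * B), 0.15)
  # runs are marked in truth and move at the prescribed speed
  r <- synth_trajectories(n = 1, N = 200, C = 0.05,
                          runs = list(n_runs = 2, duration = 20), seed = 3)
  tr <- r$truth$runs[[1]]
  expect_equal(nrow(tr), 2)
  expect_equal(tr$end - tr$start + 1, rep(20, 2))
  x <- r$trajectories[, 1]
  expect_equal(x[tr$end[1]] - x[tr$start[1]], tr$displacement_um[1],
               tolerance = 1e-9)
  # OU component has the prescribed stationary MSD plateau
  o <- synth_trajectories(n = 200, N = 300, A = 0.5, alpha = 0.1, seed = 4)
  msd_long <- mean(apply(o$trajectories, 2, function(x)
    mean((x[101:300] - x[1:200])^2)))
  expect_lt(abs(msd_long - 0.5) / 0.5, 0.15)
})

test_that("tissue generator truth matches its rendered movie", {
  tis <- synth_tissue("control", n_rows = 4, n_cols = 4, n_frames = 80,
                      n_steps = 1, amplitude_pct = 3, seed = 6)
  frames <- lapply(seq_along(tis$labels), function(t)
    frame_from_labels(tis$labels[[t]], tis$meta, t))
  tr <- track_cells(frames)
  # measured interior vertical interface lengths match truth within 1 px
  px_um <- tis$meta$pixel_size
  for (i in 2:3) for (j in 1:3) {
    id <- paste((i - 1) * 4 + j, (i - 1) * 4 + j + 1, sep = "|")
    truth <- tis$truth$length_series_um[, sprintf("v_r%d_c%d", i, j)]
    expect_lt(max(abs(truth - tr$length_series[, id]), na.rm = TRUE), px_um + 1e-9)
  }
  # measured areas match truth within a 1-px-wide boundary band
  cells <- tis$truth$area_series_um2
  id_map <- as.vector(outer(1:4, 1:4, function(i, j) (i - 1) * 4 + j))
  for (k in seq_len(ncol(cells))) {
    meas <- tr$area_series[, as.character(id_map[k])]
    per <- 4 * sqrt(cells[, k])          # generous boundary-band bound
    expect_lt(max(abs(cells[, k] - meas) / cells[, k]), 0.25)
  }
  # steps recorded in truth are real contractions of the truth series
  st <- tis$truth$steps
  expect_gt(nrow(st), 0)
  for (q in seq_len(min(5, nrow(st)))) {
    ser <- tis$truth$length_series_um[, st$interface_id[q]]
    expect_equal(ser[st$end[q]] - ser[st$start[q]], st$displacement_um[q],
                 tolerance = abs(st$displacement_um[q]) * 0.5 + 0.05)
  }
})

test_that("ratchet-off tissue has near-zero net stepped truth displacement", {
  roff <- synth_tissue("ratchet_off", n_rows = 4, n_cols = 4, n_frames = 200,
                       n_steps = 4, seed = 8)
  st <- roff$truth$steps
  net_per_iface <- tapply(st$displacement_um, st$interface_id, sum)
  ctrl <- synth_tissue("control", n_rows = 4, n_cols = 4, n_frames = 200,
                       n_steps = 4, seed = 8)
  net_ctrl <- tapply(ctrl$truth$steps$displacement_um,
                     ctrl$truth$steps$interface_id, sum)
  expect_lt(mean(abs(net_per_iface)), 0.2 * mean(abs(net_ctrl)))
})

test_that("spot movie truth honours placement, lifetimes and noiseless peaks", {
  sp <- synth_spot_movie(20, 60, lifetime_const_s = 30, snr = Inf, seed = 10)
  expect_true(all(sp$truth$lifetime_frames <= 30))
  expect_true(all(sp$truth$t_end <= 60))
  # noiseless single-spot movie: rendered peak is at the truth position
  sp1 <- synth_spot_movie(1, 40, lifetime_const_s = 20, snr = Inf, seed = 11)
  s1 <- sp1$truth[1, ]
  mid <- round((s1$t_start + s1$t_end) / 2)
  fr <- sp1$stack[[mid]]
  pk <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((pk[1] - s1$r)^2 + (pk[2] - s1$c)^2), 1.5)
  # polarity 1.0 on a lattice: all placements vertical
  tis <- synth_tissue("control", n_rows = 4, n_cols = 4, n_frames = 30,
                      n_steps = 0, seed = 2)
  spv <- synth_spot_movie(10, 30, lattice = tis, polarity_fraction = 1,
                          seed = 3)
  expect_true(all(spv$truth$placement == "vertical"))
})
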