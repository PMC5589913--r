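test_that("associate follows the three rules on hand-built geometry", {
  f <- frame_from_labels(three_cell_labels(), imaging_metadata(1))
  # near the 1|2 interface (vertical at col ~15.5, rows 2..15), mid-height
  a <- associate(c(8, 13), f)
  expect_equal(a$interface_id, "1|2")
  expect_equal(a$side, 1L)
  # > 10 px from every interface -> apical
  b <- associate(c(8, 4), f)
  expect_equal(b$interface_id, "APICAL")
  # centroid within the vertex-clearance zone -> apical
  vtx <- f$vertices[1, ]   # vertex at (1.5, 15.5)
  cl <- associate(c(2.2, 15.5), f)
  expect_equal(cl$interface_id, "APICAL")
  expect_error(associate(c(1, 1), f), class = "out_of_tissue")
})

test_that("associate agrees exactly with the brute-force oracle on random geometries", {
  set.seed(29)
  n_checked <- 0
  for (rep in 1:25) {
    lab <- brick_labels(sample(3:5, 1), sample(3:5, 1),
                        w = sample(10:14, 1), h = sample(8:12, 1))
    f <- frame_from_labels(lab, imaging_metadata(1))
    for (i in 1:40) {
      p <- c(runif(1, 2, nrow(lab) - 2), runif(1, 2, ncol(lab) - 2))
      if (lab[round(p[1]), round(p[2])] == 0) next
      got <- associate(p, f)$interface_id
      want <- associate_oracle(p, f)
      expect_identical(got, want)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 500)
})

test_that("interface classification uses the initial 90 s mean angle with the 15-degree rule", {
  mk_tracked <- function(angle) {
    ang <- matrix(angle, 100, 1, dimnames = list(NULL, "1|2"))
    structure(list(frames = list(), length_series = ang * NA,
                   area_series = matrix(numeric(0), 100, 0),
                   interface_angles = ang,
                   metadata = imaging_metadata()),
              class = "tracked_tissue")
  }
  expect_equal(classify_interfaces(mk_tracked(90))$class, "AP")
  expect_equal(classify_interfaces(mk_tracked(0))$class, "transverse")
  expect_equal(classify_interfaces(mk_tracked(74))$class, "transverse")
  expect_equal(classify_interfaces(mk_tracked(76))$class, "AP")
  expect_equal(classify_interfaces(mk_tracked(105))$class, "AP")
  expect_equal(classify_interfaces(mk_tracked(NA))$class, "unclassified")
})

test_that("density is compartments per interface per angle bin", {
  f <- frame_from_labels(brick_labels(4, 4), imaging_metadata(1))
  frames <- list(f)
  # take 3 vertical interfaces and mark compartments on them
  vert <- f$interfaces$interface_id[abs(f$interfaces$angle_deg - 90) < 1]
  assoc <- data.frame(track_id = 1:3, interface_id = vert[1:3],
                      side = 1L, t_start = 1L, t_end = 1L,
                      lifetime_frames = 1L, angle_deg = 90)
  dens <- density_profile(frames, assoc, bin_width = 15)
  bin90 <- which(dens$profile$bin_lo <= 90 & dens$profile$bin_hi > 90)
  n_vert_in_bin <- sum(!is.na(f$interfaces$angle_deg) &
                         f$interfaces$angle_deg >= 75 & f$interfaces$angle_deg < 90 |
                         f$interfaces$angle_deg == 90)
  expect_equal(dens$profile$density[bin90] *
                 sum(f$interfaces$angle_deg >= dens$profile$bin_lo[bin90] &
                       f$interfaces$angle_deg < dens$profile$bin_hi[bin90], na.rm = TRUE),
               3)
  expect_equal(dens$fraction_vertical, 1)
  # per-bin counts sum to total associated particles
  counts <- dens$per_frame[1, ] *
    vapply(seq_len(nrow(dens$profile)), function(b)
      sum(f$interfaces$angle_deg >= dens$profile$bin_lo[b] &
            f$interfaces$angle_deg < dens$profile$bin_hi[b], na.rm = TRUE),
      numeric(1))
  expect_equal(sum(counts, na.rm = TRUE), 3)
})

test_that("pairing analysis distinguishes paired, unpaired and multiple events", {
  assoc <- data.frame(
    track_id = 1:5,
    interface_id = c("1|2", "1|2", "3|4", "5|6", "5|6"),
    side = c(1L, 2L, 3L, 5L, 5L),
    t_start = c(1, 5, 1, 1, 3), t_end = c(10, 12, 8, 6, 9),
    lifetime_frames = c(10, 8, 8, 6, 7), angle_deg = 90)
  p <- pairing_analysis(assoc)
  ev <- p$events
  expect_true(ev$paired[ev$track_id == 1])   # opposite sides, overlapping
  expect_true(ev$paired[ev$track_id == 2])
  expect_false(ev$paired[ev$track_id == 3])  # alone on its interface
  expect_false(ev$paired[ev$track_id == 4])  # same side as 5
  expect_true(ev$multiple[ev$track_id == 4])
  expect_equal(p$fraction_paired, 2 / 5)
})

test_that("fixed colocalization applies the size and overlap rules", {
  A <- matrix(FALSE, 60, 60); B <- matrix(FALSE, 60, 60)
  # punctum 1: 3x3, fully overlapped (9 px > 4) -> colocalized
  A[5:7, 5:7] <- TRUE; B[5:7, 5:7] <- TRUE
  # punctum 2: 3x3, overlap 2x2 = 4 px, not > 4 -> not colocalized
  A[20:22, 20:22] <- TRUE; B[21:22, 21:22] <- TRUE
  # punctum 3: size 1 px -> outside 2..15 size range, ignored
  A[40, 40] <- TRUE
  r <- colocalize_fixed(A, B, imaging_metadata(1), grid_um = 60)
  expect_equal(r$n_puncta, 2)
  expect_equal(r$percent_colocalized, 50)
  expect_equal(colocalize_fixed(A, A, imaging_metadata(1),
                                grid_um = 60)$percent_colocalized, 100)
  expect_equal(colocalize_fixed(A, matrix(FALSE, 60, 60), imaging_metadata(1),
                                grid_um = 60)$percent_colocalized, 0)
})

test_that("live association requires > 1 px overlap for > 1 s", {
  mk_tracks <- function(frames, r, c, area = 9) {
    det <- data.frame(frame = frames, r = r, c = c, area_px = area,
                      intensity = 1)
    det$track_id <- 1L
    structure(list(detections = det,
                   tracks = data.frame(track_id = 1L, t_start = min(frames),
                                       t_end = max(frames),
                                       lifetime_frames = diff(range(frames)) + 1L,
                                       lifetime_s = diff(range(frames)) + 1,
                                       n_detections = length(frames),
                                       n_gaps_closed = 0L),
                   closed_gaps = data.frame()),
              class = "particle_tracks")
  }
  A <- mk_tracks(1:10, rep(20, 10), rep(20, 10))
  # B overlaps for exactly 1 frame (1 s): NOT associated (strict > 1 s)
  B1 <- mk_tracks(5, 20, 20)
  expect_false(associate_live(A, B1)$table$associated)
  # B overlaps frames 7..10 (4 s), late in A's life: associated, onset > 0.5
  B2 <- mk_tracks(7:10, rep(20, 4), rep(20, 4))
  r2 <- associate_live(A, B2)
  expect_true(r2$table$associated)
  expect_gt(r2$table$onset_fraction, 0.5)
})

test_that("opposing-cell area coupling reports pre/post rates around termination", {
  lab <- three_cell_labels()
  f <- frame_from_labels(lab, imaging_metadata(1))
  n_fr <- 120
  frames <- lapply(1:n_fr, function(t) { f$frame_index <- t; f })
  tr <- track_cells(frames)
  # impose contraction of cell 2 starting at frame 60 (termination time)
  a2 <- tr$area_series[, "2"]
  tr$area_series[, "2"] <- c(rep(a2[1], 60), a2[1] * (1 - 0.002 * (1:60)))
  assoc <- data.frame(track_id = 1L, interface_id = "1|2", side = 1L,
                      t_start = 40L, t_end = 60L, lifetime_frames = 21L,
                      angle_deg = 90)
  cp <- opposing_area_coupling(assoc, tr, window_s = 30)
  expect_equal(cp$opposing_cell, 2)
  expect_equal(cp$pre_rate, 0, tolerance = 1e-9)
  expect_lt(cp$post_rate, 0)
})
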