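test_that("interface length is the calibrated vertex-vertex distance", {
  m <- imaging_metadata(pixel_size = 1)
  expect_equal(interface_length(c(0, 0), c(0, 0), m), 0)
  expect_equal(interface_length(c(0, 0), c(3, 4), m), 5)
  m2 <- imaging_metadata(pixel_size = 0.164)
  expect_equal(interface_length(c(0, 0), c(0, 10), m2), 1.64)
  expect_error(interface_length(c(0, NA), c(1, 1), m), class = "invalid_input")
})

test_that("interface angle is folded to [0,180) and symmetric under vertex swap", {
  m <- imaging_metadata(1)
  expect_equal(interface_angle(c(0, 0), c(0, 10), m), 0)    # horizontal
  expect_equal(interface_angle(c(0, 0), c(10, 0), m), 90)   # vertical
  expect_equal(interface_angle(c(0, 0), c(1, 1), m), 45)
  expect_error(interface_angle(c(1, 1), c(1, 1), m), class = "degenerate_interface")
  set.seed(1)
  for (i in 1:50) {
    v1 <- runif(2, 0, 100); v2 <- runif(2, 0, 100)
    a1 <- interface_angle(v1, v2, m); a2 <- interface_angle(v2, v1, m)
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_true(a1 >= 0 && a1 < 180)
  }
})

test_that("skeletonization of three mutually adjacent cells gives 3 interfaces, 1 interior vertex", {
  f <- frame_from_labels(three_cell_labels(), imaging_metadata(1))
  expect_equal(nrow(f$cells), 3)
  expect_equal(nrow(f$interfaces), 3)
  # interior vertex: incident to all three interfaces
  n_inc <- vapply(f$vertices$interfaces, length, integer(1))
  expect_equal(sum(n_inc == 3), 1)
  # all cells mutually adjacent
  expect_setequal(f$cells$neighbors[[1]], c(2L, 3L))
})

test_that("cell areas partition the image and border flags are correct", {
  lab <- three_cell_labels()
  f <- frame_from_labels(lab, imaging_metadata(1))
  expect_equal(sum(f$cells$area_px) + sum(lab == 0), length(lab))
  expect_true(all(f$cells$touches_border))  # all three touch background ring
  lab2 <- brick_labels()
  f2 <- frame_from_labels(lab2, imaging_metadata(1))
  expect_equal(sum(f2$cells$area_px) + sum(lab2 == 0), length(lab2))
  interior <- f2$cells[!f2$cells$touches_border, ]
  expect_gt(nrow(interior), 0)
})

test_that("a 2x2 block of four cells yields a single 4-fold vertex", {
  lab <- matrix(0L, 20, 20)
  lab[2:10, 2:10] <- 1L; lab[2:10, 11:19] <- 2L
  lab[11:19, 2:10] <- 3L; lab[11:19, 11:19] <- 4L
  f <- frame_from_labels(lab, imaging_metadata(1))
  expect_equal(nrow(f$interfaces), 4)  # 1-2, 1-3, 2-4, 3-4 (no diagonal contact)
  n_inc <- vapply(f$vertices$interfaces, length, integer(1))
  expect_equal(sum(n_inc == 4), 1)     # central junction kept as one vertex
})

test_that("single-cell label image gives a no-interfaces result, not an error", {
  lab <- matrix(0L, 10, 10); lab[2:9, 2:9] <- 1L
  f <- frame_from_labels(lab, imaging_metadata(1))
  expect_equal(nrow(f$interfaces), 0)
  expect_equal(nrow(f$cells), 1)
})

test_that("validate_frame flags injected inconsistencies and passes clean frames", {
  f <- frame_from_labels(three_cell_labels(), imaging_metadata(1))
  expect_length(validate_frame(f), 0)
  f_bad <- f
  f_bad$cells$neighbors[[1]] <- setdiff(f_bad$cells$neighbors[[1]], 2L)
  expect_gt(length(validate_frame(f_bad)), 0)
  f_bad2 <- f
  f_bad2$interfaces$length_um[1] <- f_bad2$interfaces$length_um[1] + 5
  expect_gt(length(validate_frame(f_bad2)), 0)
})

test_that("tissue tables round-trip through CSV with identical measurements", {
  lab <- three_cell_labels()
  frames <- lapply(1:3, function(t) frame_from_labels(lab, imaging_metadata(), t))
  tr <- track_cells(frames)
  dir <- withr::local_tempdir()
  paths <- write_tissue_tables(tr, dir)
  ints <- read.csv(paths[["interfaces"]])
  back <- ints$length_um[ints$frame == 2]
  expect_equal(sort(back), sort(tr$frames[[2]]$interfaces$length_um))
  cells <- read.csv(paths[["cells"]])
  expect_equal(sort(cells$area_um2[cells$frame == 1]),
               sort(tr$frames[[1]]$cells$area_um2))
})
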