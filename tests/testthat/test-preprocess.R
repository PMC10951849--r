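test_that("segmentation cuts one 13-s epoch per marker and drops edge trials", {
  sf <- 100
  n <- 30 * sf
  set.seed(1)
  labels <- standard_montage_64()$label[1:3]
  mont <- standard_montage_64()[1:3, ]
  dat <- matrix(rnorm(3 * n), 3)
  ev <- data.frame(sample = c(6L * sf + 1L, 20L * sf), marker = c("S 12", "S 13"))
  rec <- eeg_continuous(dat, sf, labels, ev)
  ep <- segment_epochs(rec, montage = mont)
  expect_equal(dim(ep$data), c(3L, 13L * sf + 1L, 2L))
  # marker with exactly 6 s of data before it: epoch starts at sample 1
  expect_equal(ep$data[, 1, 1], dat[, 1])
  expect_equal(ep$condition, c("maintain", "reappraise"))

  # marker 5 s from the start is dropped with a warning
  ev2 <- data.frame(sample = c(5 * sf, 20 * sf), marker = c("S 12", "S 13"))
  rec2 <- eeg_continuous(dat, sf, labels, ev2)
  expect_warning(ep2 <- segment_epochs(rec2, montage = mont), "dropped")
  expect_equal(dim(ep2$data)[3], 1L)
  # no usable markers at all
  rec3 <- eeg_continuous(dat, sf, labels,
                         data.frame(sample = 10L, marker = "S 99"))
  expect_error(segment_epochs(rec3, montage = mont), "marker")
})

test_that("round trip simulator -> continuous -> segmentation recovers every trial", {
  ep <- fixture_participant()
  cont <- epochs_to_continuous(ep)
  ep2 <- segment_epochs(cont)
  expect_equal(dim(ep2$data)[3], dim(ep$data)[3])
  expect_identical(ep2$condition, ep$condition)
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
})

test_that("filter bank hits its band targets", {
  sf <- 250
  times <- seq(-6, 7, by = 1 / sf)
  mont <- standard_montage_64()[1:2, ]
  line <- sin(2 * pi * 50 * times)
  pass <- sin(2 * pi * 5 * times)
  dat <- array(0, c(2, length(times), 2))
  dat[1, , ] <- line
  dat[2, , ] <- pass
  ep <- eeg_epochs(dat, times, sf, c("maintain", "maintain"), mont)
  f <- filter_epochs(ep)
  mid <- abs(times) < 4 # avoid filter edge transients in the RMS measure
  expect_lt(sqrt(mean(f$data[1, mid, 1]^2)) / sqrt(mean(line[mid]^2)), 0.01)
  att <- sqrt(mean(f$data[2, mid, 1]^2)) / sqrt(mean(pass[mid]^2))
  expect_gt(att, 0.98)

  # DC offset is removed to numerical precision
  dat2 <- dat; dat2[1, , ] <- 100
  ep2 <- eeg_epochs(dat2, times, sf, c("maintain", "maintain"), mont)
  f2 <- filter_epochs(ep2)
  expect_lt(max(abs(rowMeans(f2$data[, , 1]))), 1e-8)
  expect_true("filtered" %in% f2$provenance)
  # non-finite input rejected
  dat3 <- dat; dat3[1, 5, 1] <- NA
  ep3 <- eeg_epochs(dat3, times, sf, c("maintain", "maintain"), mont)
  expect_error(filter_epochs(ep3), "non-finite")
})

test_that("spherical-spline interpolation reconstructs smooth topographies", {
  lf <- fixture_leadfield()
  hm <- lf$head_model
  mont <- standard_montage_64()
  # smooth spatial pattern: deep-source topography with a slow time course
  sf <- 50
  times <- seq(0, 2, by = 1 / sf)
  topo <- as.numeric(t(lf$gain[5, , ]) %*% c(0, 0, 1))
  dat <- array(outer(topo, sin(2 * pi * 3 * times)), c(64, length(times), 2))
  ep <- eeg_epochs(dat, times, sf, c("maintain", "maintain"), mont)

  for (bad in c("Cz", "F3", "PO8")) {
    i <- match(bad, mont$label)
    out <- interpolate_channels(ep, bad)
    expect_gt(cor(out$data[i, , 1], ep$data[i, , 1]), 0.95)
  }
  # duplicates are deduplicated; empty list is the identity
  out2 <- interpolate_channels(ep, c("Cz", "Cz"))
  expect_equal(out2$data, interpolate_channels(ep, "Cz")$data)
  out3 <- interpolate_channels(ep, character(0))
  expect_equal(out3$data, ep$data)
  expect_error(interpolate_channels(ep, "XX9"), "unknown")
})

test_that("z-score artifact rejection removes planted outliers only", {
  ep <- fixture_participant()
  d <- ep$data
  d[, , 5] <- d[, , 5] * 10
  spiked <- eeg_epochs(d, ep$times, ep$sfreq, ep$condition, ep$montage)
  r <- reject_artifact_trials(spiked)
  expect_equal(r$log$rejected, 5L)
  expect_equal(dim(r$epochs$data)[3], dim(d)[3] - 1L)
  # surviving trials' samples untouched
  expect_identical(r$epochs$data, d[, , -5])
  # homogeneous data: nothing removed; infinite threshold: identity
  r0 <- reject_artifact_trials(ep)
  expect_length(r0$log$rejected, 0)
  rInf <- reject_artifact_trials(spiked, z_threshold = Inf)
  expect_length(rInf$log$rejected, 0)
  expect_error(reject_artifact_trials(subset_trials(ep, 1)), "2 trials")
})

test_that("common-average reference zeroes channel means and is idempotent", {
  ep <- fixture_participant()
  r <- rereference_common_average(ep)
  expect_lt(max(abs(colMeans(r$data))), 1e-10)
  r2 <- rereference_common_average(r)
  expect_equal(r2$data, r$data, tolerance = 1e-12)
  # bipolar differences are reference-invariant
  expect_equal(r$data[3, , 1] - r$data[7, , 1],
               ep$data[3, , 1] - ep$data[7, , 1], tolerance = 1e-10)
})

test_that("re-referencing commutes with linear filtering", {
  ep <- subset_trials(fixture_participant(), 1:2)
  a <- suppressWarnings(rereference_common_average(filter_epochs(ep)))
  b <- suppressWarnings(filter_epochs(rereference_common_average(ep)))
  expect_lt(max(abs(a$data - b$data)) / max(abs(a$data)), 1e-8)
})

test_that("ICA cleanup removes a planted ocular artifact and spares clean data", {
  lf <- fixture_leadfield()
  cfg <- sim_config(n_blocks = 1L, trials_per_block = 12, sfreq = 50,
                    artifact_amplitude = 40, seed = 31)
  ep <- simulate_participant(cfg, "control", lf, seed = 32)
  artifact <- as.vector(attr(ep, "ground_truth")$artifact_course)
  ep <- rereference_common_average(ep)
  frontal <- grep("^Fp", ep$montage$label)
  before <- abs(cor(colMeans(matrix(ep$data[frontal, , ], nrow = 2)), artifact))
  res <- suppressWarnings(remove_ocular_components(ep, seed = 5))
  expect_gte(length(res$removed), 1)
  after <- abs(cor(colMeans(matrix(res$epochs$data[frontal, , ], nrow = 2)),
                   artifact))
  # correlation with the planted artifact time course drops by >= 80%
  expect_lt(after, 0.2 * before)

  # artifact-free recording: at most one component crosses the threshold and
  # untouched components leave the data intact
  cfg0 <- sim_config(n_blocks = 1L, trials_per_block = 12, sfreq = 50,
                     artifact_amplitude = 0, seed = 33)
  ep0 <- rereference_common_average(
    simulate_participant(cfg0, "control", lf, seed = 34))
  res0 <- suppressWarnings(remove_ocular_components(ep0, seed = 5))
  expect_lte(length(res0$removed), 1)
  if (length(res0$removed) == 0)
    expect_equal(res0$epochs$data, ep0$data, tolerance = 1e-9)
})
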