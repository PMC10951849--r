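make_tone_epochs <- function(A = 2, f0 = 6, sfreq = 100, n_trials = 6,
                             cond = "maintain", phase_locked = FALSE,
                             seed = 1) {
  set.seed(seed)
  times <- seq(-6, 7, by = 1 / sfreq)
  mont <- standard_montage_64()[1:2, ]
  dat <- array(0, c(2, length(times), n_trials))
  for (k in seq_len(n_trials)) {
    ph <- if (phase_locked) 0.4 else runif(1, 0, 2 * pi)
    dat[1, , k] <- A * sin(2 * pi * f0 * times + ph)
  }
  eeg_epochs(dat, times, sfreq, rep(cond, n_trials), mont)
}

test_that("ERP subtraction leaves zero-mean induced residuals", {
  ep <- fixture_participant()
  ind <- subtract_erp(ep)
  for (cond in unique(ind$condition)) {
    idx <- ind$condition == cond
    m <- rowMeans(ind$data[, , idx, drop = FALSE], dims = 2)
    expect_lt(max(abs(m)), 1e-10)
  }
  # identical trials within a condition -> all-zero residuals
  locked <- make_tone_epochs(phase_locked = TRUE)
  expect_lt(max(abs(subtract_erp(locked)$data)), 1e-12)
  # random-phase trials survive almost unchanged at moderate trial counts
  induced <- make_tone_epochs(n_trials = 40)
  res <- subtract_erp(induced)
  rms_in <- sqrt(mean(induced$data[1, , ]^2))
  rms_out <- sqrt(mean(res$data[1, , ]^2))
  expect_gt(rms_out / rms_in, 0.9)
  one <- subset_trials(ep, which(ep$condition == "maintain")[1])
  expect_error(subtract_erp(one), "fewer than 2")
})

test_that("single-tone power matches the analytic normalisation within 3%", {
  A <- 2.5
  ep <- make_tone_epochs(A = A)
  tf <- tfr_hanning(ep, freqs = c(5.5, 6, 6.5), centre_times = seq(-2, 2, 1))
  p6 <- tf$maintain$power[1, 2, ]
  expect_lt(max(abs(p6 - A^2 / 2)) / (A^2 / 2), 0.03)
  # energy linearity: doubling amplitude quadruples power
  ep2 <- make_tone_epochs(A = 2 * A)
  tf2 <- tfr_hanning(ep2, freqs = 6, centre_times = 0)
  tf1 <- tfr_hanning(ep, freqs = 6, centre_times = 0)
  expect_lt(abs(tf2$maintain$power[1, 1, 1] / tf1$maintain$power[1, 1, 1] - 4),
            1e-10)
  # zero signal -> zero power; frequencies beyond Nyquist rejected
  zed <- make_tone_epochs(A = 0)
  tfz <- tfr_hanning(zed, freqs = 6, centre_times = 0)
  expect_equal(max(tfz$maintain$power[1, , ]), 0)
  expect_error(tfr_hanning(ep, freqs = c(6, 80)), "Nyquist")
  expect_error(tfr_hanning(ep, freqs = 6.3), "grid")
})

test_that("white-noise power is flat across 10-25 Hz", {
  set.seed(4)
  sfreq <- 100
  times <- seq(-6, 7, by = 1 / sfreq)
  mont <- standard_montage_64()[1, , drop = FALSE]
  dat <- array(rnorm(length(times) * 60), c(1, length(times), 60))
  ep <- eeg_epochs(dat, times, sfreq, rep("maintain", 60), mont)
  tf <- tfr_hanning(ep, freqs = seq(10, 25, 0.5), centre_times = seq(-3, 3, 1))
  pw <- apply(tf$maintain$power[1, , ], 1, mean)
  fit <- lm(log(pw) ~ tf$maintain$freqs)
  expect_lt(abs(coef(fit)[2]), 0.02) # log-power slope per Hz
})

test_that("baseline subtraction zeroes the baseline and isolates bursts", {
  ep <- fixture_participant()
  tf <- tfr_hanning(subtract_erp(ep), freqs = seq(3.5, 8.5, 0.5),
                    centre_times = c(seq(-4.2, -3.2, 0.25), seq(1, 5, 0.5)))
  bs <- baseline_subtract(tf$reappraise)
  sel <- bs$times >= -4.2 & bs$times <= -3.2
  base_mean <- apply(bs$power[, , sel], c(1, 2), mean)
  expect_lt(max(abs(base_mean)), 1e-10)
  expect_equal(bs$baseline_state, "subtracted")
  expect_error(baseline_subtract(tfr_hanning(subtract_erp(ep), freqs = 6,
                                             centre_times = 2)$reappraise),
               "baseline")
  # the planted burst lives in the regulation window at the theta source
  # frequency: the largest positive values sit inside 1-5 s
  peak_t <- bs$times[which.max(apply(bs$power, 3, max))]
  expect_gte(peak_t, 1)
  expect_lte(peak_t, 5)
})

test_that("regulation contrast is an antisymmetric element-wise difference", {
  ep <- fixture_participant()
  tf <- tfr_hanning(subtract_erp(ep), freqs = seq(3.5, 8.5, 0.5),
                    centre_times = seq(1, 3, 0.5))
  a <- tf$reappraise; b <- tf$maintain
  expect_equal(regulation_contrast(a, a)$power, a$power * 0)
  ab <- regulation_contrast(a, b)
  ba <- regulation_contrast(b, a)
  expect_equal(ab$power, -ba$power)
  expect_equal(ab$label, "reappraisal-maintenance")
  b2 <- b; b2$times <- b2$times + 0.1
  expect_error(regulation_contrast(a, b2), "axes")
})

test_that("theta summary is the mean over the band-window box only", {
  freqs <- seq(3.5, 8.5, 0.5)
  times <- c(seq(-4.2, -3.2, 0.5), seq(0.5, 5.5, 0.5))
  nch <- 3
  pw <- array(0, c(nch, length(freqs), length(times)))
  inbox <- times >= 1 & times <= 5
  pw[, , inbox] <- 0.7
  pw[, , !inbox] <- 99 # values outside the box must not leak in
  tf <- thetareg:::new_tfr(pw, freqs, times, "subtracted", "contrast",
                           c("a", "b", "c"))
  s <- theta_summary(tf)
  expect_equal(unname(s), rep(0.7, nch))
})

test_that("planted group effect appears at effect-adjacent channels", {
  lf <- fixture_leadfield()
  hm <- lf$head_model
  cfg <- sim_config(n_blocks = 1L, trials_per_block = 24, sfreq = 50, seed = 77)
  ctl <- simulate_participant(cfg, "control", lf, seed = 78)
  bpd <- simulate_participant(cfg, "bpd", lf, seed = 79)
  s_ctl <- participant_theta_summary(ctl, slide_s = 0.25)
  s_bpd <- participant_theta_summary(bpd, slide_s = 0.25)
  adj <- effect_adjacent_channels(hm, attr(ctl, "ground_truth")$effect_voxel)
  expect_gt(mean(s_ctl[adj]), mean(s_bpd[adj]))
  # the contrast concentrates near the planted sources: effect-adjacent mean
  # beats the mean over remote channels by a wide margin
  remote <- setdiff(seq_len(64), unique(c(adj,
    effect_adjacent_channels(hm, attr(ctl, "ground_truth")$partner_voxel, 10),
    effect_adjacent_channels(hm, attr(ctl, "ground_truth")$effect_voxel, 10))))
  expect_gt(mean(s_ctl[adj]), 3 * abs(mean(s_ctl[remote])))
})
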