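test_that("sim_config validates the paradigm structure", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_blocks = 1L, trials_per_block = 25L), "divide")
  expect_error(sim_config(epoch_span = c(-2, 7)), "baseline")
  expect_error(sim_config(nonsense = 1), "unknown")
  cfg <- sim_config()
  expect_equal(cfg$n_per_group, 25L)
  expect_equal(cfg$n_blocks * cfg$trials_per_block, 150L)
  set.seed(1)
  expect_length(thetareg:::condition_sequence(cfg), 150L)
})

test_that("condition sequence balances conditions and bounds within-block repeats", {
  cfg <- sim_config()
  for (s in 1:5) {
    set.seed(s)
    seq_ <- thetareg:::condition_sequence(cfg)
    expect_equal(as.integer(table(seq_)), rep(50L, 3))
    # repeats are constrained within blocks (blocks are separated by breaks)
    for (b in 1:3) {
      blk <- seq_[((b - 1) * 50 + 1):(b * 50)]
      expect_lte(max(rle(blk)$lengths), 3)
    }
  }
})

test_that("participant simulation is reproducible and labelled", {
  lf <- fixture_leadfield()
  cfg <- sim_config(n_blocks = 1L, trials_per_block = 12, sfreq = 50, seed = 5)
  e1 <- simulate_participant(cfg, "bpd", lf, seed = 11)
  e2 <- simulate_participant(cfg, "bpd", lf, seed = 11)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$condition, e2$condition)
  expect_error(simulate_participant(cfg, "patient", lf, seed = 1), "group")
  expect_equal(dim(e1$data)[3], 12)
  expect_equal(length(e1$times), 13 * 50 + 1)
  expect_equal(e1$times[which.min(abs(e1$times))], 0)
})

test_that("sensor spectrum of a noise-only simulation has the configured 1/f slope", {
  lf <- fixture_leadfield()
  cfg <- sim_config(n_blocks = 1L, trials_per_block = 12, sfreq = 100,
                    theta_base_amp = 0,
                    theta_effect_size = c(control = 0, bpd = 0),
                    evoked_amplitude = 0, sensor_noise = 0.01,
                    noise_exponent = 1, seed = 2)
  ep <- simulate_participant(cfg, "control", lf, seed = 3)
  nt <- dim(ep$data)[2]
  freqs <- (seq_len(nt) - 1) / nt * ep$sfreq
  sel <- freqs > 2 & freqs < 30
  pows <- 0
  for (k in seq_len(dim(ep$data)[3]))
    pows <- pows + rowMeans(Mod(mvfft(t(ep$data[, , k])))^2)
  fit <- lm(log(pows[sel]) ~ log(freqs[sel]))
  expect_lt(abs(-coef(fit)[2] - cfg$noise_exponent), 0.2)
})

test_that("behavioural draws honour the configured group distributions", {
  cfg <- sim_config()
  # degenerate SDs: every BPD maintenance rating is exactly the group mean
  cfg0 <- cfg
  cfg0$behaviour$bpd$rating_sd[] <- 0
  cfg0$behaviour$bpd$erq_r_sd <- 0
  b <- simulate_behaviour(cfg0, "bpd", seed = 1)
  expect_true(all(b$rating_maintain == 58))
  expect_true(all(b$erq_reappraisal == 21))
  # bounds always respected
  cfgw <- cfg
  cfgw$behaviour$control$rating_sd[] <- 60
  bw <- simulate_behaviour(cfgw, "control", seed = 2)
  expect_true(all(bw$rating_maintain >= 0 & bw$rating_maintain <= 100))
  # pooled sample means within 3 SE of the truncated-normal means
  pool <- do.call(rbind, lapply(1:30, function(s)
    simulate_behaviour(cfg, "bpd", seed = 100 + s)))
  tmean <- function(mu, sd, a, b) {
    al <- (a - mu) / sd; be <- (b - mu) / sd
    mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  }
  n <- nrow(pool)
  m_exp <- tmean(58, 25, 0, 100)
  expect_lt(abs(mean(pool$rating_maintain) - m_exp), 3 * 25 / sqrt(n))
  m_exp_r <- tmean(42, 21, 0, 100)
  expect_lt(abs(mean(pool$rating_reappraise) - m_exp_r), 3 * 21 / sqrt(n))
  expect_lt(abs(mean(pool$erq_reappraisal) - tmean(21, 8, 10, 42)),
            3 * 8 / sqrt(n))
})

test_that("cohort bundles are deterministic with ground-truth bookkeeping", {
  lf <- fixture_leadfield()
  cfg <- sim_config(n_per_group = 2, n_blocks = 1L, trials_per_block = 6,
                    sfreq = 50, seed = 21)
  c1 <- generate_cohort(cfg, lf = lf)
  c2 <- generate_cohort(cfg, lf = lf)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$epochs[[1]]$data, c2$epochs[[1]]$data)
  expect_identical(c1$ground_truth$seeds, c2$ground_truth$seeds)
  expect_length(c1$ground_truth$effect_voxel, 1)
  expect_equal(nrow(c1$participants), 4)
  # ERQ-linked planted effect responds to the configured slope
  cfg2 <- sim_config(n_per_group = 2, n_blocks = 1L, trials_per_block = 6,
                     sfreq = 50, seed = 21, erq_theta_slope = 0.05)
  c3 <- generate_cohort(cfg2, lf = lf)
  incs <- vapply(c3$ground_truth$participant, `[[`, numeric(1),
                 "effect_increment")
  erqs <- c3$participants$erq_reappraisal
  base <- cfg2$theta_effect_size[c3$participants$group]
  mus <- vapply(c3$participants$group, function(g)
    cfg2$behaviour[[g]]$erq_r, numeric(1))
  expect_equal(unname(incs),
               pmax(0, unname(base) + 0.05 * (erqs - mus)), tolerance = 1e-12)
})
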