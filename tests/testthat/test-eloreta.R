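tone_epochs_64 <- function(f0 = 6, sfreq = 50, n_trials = 8, seed = 2) {
  set.seed(seed)
  times <- seq(-6, 7, by = 1 / sfreq)
  mont <- standard_montage_64()
  dat <- array(rnorm(64 * length(times) * n_trials, 0, 0.05),
               c(64, length(times), n_trials))
  for (k in seq_len(n_trials)) {
    ph <- runif(1, 0, 2 * pi)
    dat[1, , k] <- dat[1, , k] + sin(2 * pi * f0 * times + ph)
  }
  eeg_epochs(dat, times, sfreq, rep("maintain", n_trials), mont)
}

test_that("band Fourier coefficients concentrate a tone in its bin", {
  ep <- tone_epochs_64()
  sp <- band_fourier(ep, "regulation")
  expect_equal(sp$bins, seq(3.5, 8.5, 0.5))
  pw <- apply(Mod(sp$coef[1, , ])^2, 1, mean)
  expect_gt(pw[sp$bins == 6], 10 * max(pw[sp$bins != 6]))
  # zero signal -> zero coefficients
  zed <- ep; zed$data[] <- 0
  expect_equal(max(Mod(band_fourier(zed, "baseline")$coef)), 0)
  # off-grid bins rejected
  expect_error(band_fourier(ep, "regulation", band = c(3.6, 8.6)), "grid")
})

test_that("stationary noise has matched regulation and baseline densities", {
  set.seed(9)
  sfreq <- 50
  times <- seq(-6, 7, by = 1 / sfreq)
  mont <- standard_montage_64()[1, , drop = FALSE]
  ntr <- 300
  dat <- array(rnorm(length(times) * ntr), c(1, length(times), ntr))
  ep <- eeg_epochs(dat, times, sfreq, rep("maintain", ntr), mont)
  p_reg <- mean(Mod(band_fourier(ep, "regulation")$coef[1, , ])^2)
  p_base <- mean(Mod(band_fourier(ep, "baseline")$coef[1, , ])^2)
  # PSD scaling makes the two segment lengths comparable; Monte-Carlo
  # tolerance for 300 trials x 11 bins
  expect_lt(abs(log(p_reg / p_base)), 0.1)
})

test_that("eLORETA converges to its fixed point and is linear", {
  lf <- fixture_leadfield()
  op <- eloreta_inverse(lf, alpha_reg = 0.05)
  expect_lt(op$convergence$rel_change, 1e-6)
  expect_lte(op$convergence$iterations, 100)
  K <- leadfield_matrix(lf)
  x <- K[, 10]; y <- K[, 50]
  expect_lt(max(abs(op$T %*% (x + y) - (op$T %*% x + op$T %*% y))), 1e-10)
  expect_equal(op$T %*% (3 * x), 3 * (op$T %*% x), tolerance = 1e-12)
})

test_that("the symmetric pseudo-inverse agrees with MASS::ginv", {
  skip_if_not_installed("MASS")
  set.seed(12)
  A <- matrix(rnorm(64 * 5), 64)
  S <- A %*% t(A) # rank-5 psd
  P1 <- thetareg:::pinv_sym(S)
  P2 <- MASS::ginv(S)
  expect_lt(max(abs(P1 - P2)), 1e-8 * max(abs(P2)))
})

test_that("noiseless single dipoles localise exactly on a 60-voxel grid", {
  res <- run_localisation_study(n_voxels = 60, alpha_reg = 1e-10)
  expect_equal(res$n_correct, res$n_total)
})

test_that("source band power is non-negative and phase-invariant", {
  lf <- fixture_leadfield()
  op <- eloreta_inverse(lf, alpha_reg = 0.05)
  ep <- tone_epochs_64()
  sp <- band_fourier(ep, "regulation")
  p <- source_band_power(op, sp)
  expect_true(all(p >= 0))
  expect_length(p, lf$head_model$n_voxels)
  sp2 <- sp
  sp2$coef <- sp$coef * exp(1i * 1.1)
  expect_equal(source_band_power(op, sp2), p, tolerance = 1e-12)
  zed <- sp; zed$coef[] <- 0
  expect_equal(max(source_band_power(op, zed)), 0)
})

test_that("power-ratio contrast is near zero for stationary data and antisymmetric", {
  v <- 5
  p_reg <- runif(v, 1, 2)
  r <- power_ratio_contrast(p_reg, p_reg, p_reg, p_reg)
  expect_equal(r$contrast, rep(0, v))
  expect_equal(r$ratio_reappraise, rep(1, v))
  a_reg <- runif(v, 1, 2); a_base <- runif(v, 1, 2)
  b_reg <- runif(v, 1, 2); b_base <- runif(v, 1, 2)
  ab <- power_ratio_contrast(a_reg, a_base, b_reg, b_base)
  ba <- power_ratio_contrast(b_reg, b_base, a_reg, a_base)
  expect_equal(ab$contrast, -ba$contrast)
  expect_error(power_ratio_contrast(a_reg, c(0, a_base[-1]), b_reg, b_base),
               "voxel 1")
})

test_that("voxel permutation p-values are calibrated and match enumeration", {
  # uniformity under the null across 200 simulations (single voxel tracked)
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    a <- matrix(rnorm(5 * 4), 5)
    b <- matrix(rnorm(5 * 4), 5)
    voxel_permutation_test(a, b, n_perm = 500, seed = 1000 + s)$p_value[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # 4-vs-4: Monte-Carlo p within 3 SE of the exhaustive p over 70 assignments
  set.seed(5)
  a <- matrix(rnorm(4 * 3), 4); a[, 1] <- a[, 1] + 2
  b <- matrix(rnorm(4 * 3), 4)
  vt <- voxel_permutation_test(a, b, n_perm = 4000, seed = 6)
  X <- rbind(a, b)
  combs <- utils::combn(8, 4)
  obs <- colMeans(a) - colMeans(b)
  null <- apply(combs, 2, function(ix)
    colMeans(X[ix, , drop = FALSE]) - colMeans(X[-ix, , drop = FALSE]))
  for (vx in 1:3) {
    p_exact <- mean(abs(null[vx, ]) >= abs(obs[vx]) * (1 - 1e-9))
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(vt$p_value[vx] - p_exact), 3 * se + 1e-9)
  }
  expect_true(all(vt$p_value >= 1 / 4001))
  expect_error(voxel_permutation_test(a, b, n_perm = 50), "100")
})

test_that("one-sided option tests the directional hypothesis", {
  set.seed(11)
  a <- matrix(rnorm(6 * 4, 1), 6)
  b <- matrix(rnorm(6 * 4, 0), 6)
  one <- voxel_permutation_test(a, b, n_perm = 500, seed = 2, tails = "one")
  two <- voxel_permutation_test(a, b, n_perm = 500, seed = 2, tails = "two")
  expect_true(all(one$p_value <= two$p_value + 1e-12))
})
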