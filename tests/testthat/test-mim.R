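rand_herm3 <- function() {
  A <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
  (A %*% Conj(t(A))) / 3
}

test_that("MIM vanishes exactly for zero-lag (real) cross-spectra", {
  set.seed(1)
  Sii <- rand_herm3(); Sjj <- rand_herm3()
  S_real <- matrix(complex(real = rnorm(9), imaginary = 0), 3)
  expect_identical(mim_pair(Sii, Sjj, S_real), 0)
  # and for a full cross-spectrum of a real linear mixture: build S = M M^T
  # from a real mixing of independent sources (analytically real)
  M <- matrix(rnorm(18), 6)                # 6 source dims -> real mixing
  S <- (M %*% t(M)) + 0i
  cs <- structure(list(S = S, n_voxels = 2L, n_trials = 10, bins = 1,
                       per_bin = FALSE), class = "voxel_cross_spectrum")
  expect_equal(mim_voxel_to_whole_brain(cs), c(0, 0))
})

test_that("MIM is symmetric, non-negative and remix-invariant", {
  set.seed(2)
  for (i in 1:20) {
    Sii <- rand_herm3(); Sjj <- rand_herm3()
    Sij <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
    m <- mim_pair(Sii, Sjj, Sij)
    expect_gte(m, 0)
    expect_equal(mim_pair(Sjj, Sii, Conj(t(Sij))), m, tolerance = 1e-12)
    # rotation invariance (the property stated for source orientations)
    qa <- qr.Q(qr(matrix(rnorm(9), 3)))
    qb <- qr.Q(qr(matrix(rnorm(9), 3)))
    m_rot <- mim_pair(qa %*% Sii %*% t(qa), qb %*% Sjj %*% t(qb),
                      qa %*% Sij %*% t(qb))
    expect_lt(abs(m_rot - m) / m, 1e-10)
    # arbitrary invertible remixing (stronger property of the trace form)
    A <- matrix(rnorm(9), 3); B <- matrix(rnorm(9), 3)
    m_mix <- mim_pair(A %*% Sii %*% t(A), B %*% Sjj %*% t(B),
                      A %*% Sij %*% t(B))
    expect_lt(abs(m_mix - m) / m, 1e-8)
    # trace form equals the eigenvalue sum
    P <- solve(Re(Sii)) %*% Im(Sij) %*% solve(Re(Sjj)) %*% t(Im(Sij))
    expect_lt(abs(m - sum(Re(eigen(P)$values))) / m, 1e-12)
  }
  expect_error(mim_pair(matrix(1i, 3, 3) + diag(3), rand_herm3(),
                        matrix(0i, 3, 3)), "Hermitian")
})

test_that("MIM equals the scalar imaginary-coherence form for 1-D sources", {
  # two unidimensional sources with coherency c and phase lag embedded in 3-D
  set.seed(3)
  for (i in 1:10) {
    pw1 <- runif(1, 0.5, 3); pw2 <- runif(1, 0.5, 3)
    coh <- runif(1, 0, 0.95) * exp(1i * runif(1, -pi, pi))
    S11 <- diag(c(pw1, 1, 1)); S22 <- diag(c(pw2, 1, 1))
    S12 <- matrix(0 + 0i, 3, 3)
    S12[1, 1] <- coh * sqrt(pw1 * pw2)
    # independent scalar oracle: imaginary part of coherency, squared
    expect_equal(mim_pair(S11 + 0i, S22 + 0i, S12), Im(coh)^2,
                 tolerance = 1e-12)
  }
})

test_that("cross-spectral blocks are Hermitian and reduce correctly", {
  lf <- fixture_leadfield()
  op <- eloreta_inverse(lf, alpha_reg = 0.05)
  ep <- fixture_participant()
  sub <- subset_trials(ep, which(ep$condition == "maintain"))
  sp <- band_fourier(subtract_erp(ep), "regulation")
  cs <- voxel_cross_spectrum(op, sp)
  expect_lt(max(Mod(cs$S - Conj(t(cs$S)))), 1e-12)
  # two identical trials: S equals the single-trial outer product
  sp2 <- sp
  sp2$coef <- sp$coef[, , c(1, 1)]
  cs2 <- voxel_cross_spectrum(op, sp2)
  sc <- source_coefficients(op, sp)
  Sb <- 0
  for (f in seq_along(sp$bins)) {
    A <- sc[, f, 1, drop = TRUE]
    Sb <- Sb + A %*% Conj(t(A))
  }
  expect_equal(cs2$S, Sb / length(sp$bins), tolerance = 1e-10)
  sp1 <- sp; sp1$coef <- sp$coef[, , 1, drop = FALSE]
  expect_error(voxel_cross_spectrum(op, sp1), "2 trials")
})

test_that("whole-brain map on a 2-voxel grid equals the single pairwise MIM", {
  set.seed(4)
  A <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6)
  S <- (A %*% Conj(t(A))) / 6
  cs <- structure(list(S = S, n_voxels = 2L, n_trials = 10, bins = 1,
                       per_bin = FALSE), class = "voxel_cross_spectrum")
  mp <- mim_voxel_to_whole_brain(cs)
  m <- mim_pair(S[1:3, 1:3], S[4:6, 4:6], S[1:3, 4:6])
  expect_equal(mp, c(m, m), tolerance = 1e-12)
  expect_true(all(mp >= 0))
})

test_that("planted phase-lagged coupling peaks at the planted voxels", {
  lf <- fixture_leadfield()
  hm <- lf$head_model
  op <- eloreta_inverse(lf, alpha_reg = 0.05)
  cfg <- sim_config(n_blocks = 1L, trials_per_block = 24, sfreq = 50,
                    coupling_rel_amp = 1, seed = 51)
  ep <- simulate_participant(cfg, "control", lf, seed = 52)
  gt <- attr(ep, "ground_truth")
  maps <- participant_mim_maps(ep, op)
  vnb <- voxel_neighbors(hm)
  top <- order(-maps$reappraise)[1:6]
  near <- unique(c(gt$effect_voxel, gt$partner_voxel,
                   unlist(vnb[c(gt$effect_voxel, gt$partner_voxel)])))
  expect_true(any(top %in% near))
  # contrast of a condition with itself is exactly zero
  same <- list(list(reappraise = maps$maintain, maintain = maps$maintain),
               list(reappraise = maps$maintain, maintain = maps$maintain))
  ct <- mim_contrast_and_test(same, same, n_perm = 100, seed = 1)
  expect_equal(max(abs(ct$contrast_a)), 0)
})
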