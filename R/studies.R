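## Validation studies: self-contained simulation experiments that quantify
## the statistical properties of the pipeline (volume-conduction nullity,
## calibration, localisation, planted-effect recovery). Shared by the test
## suite and the acceptance script.

#' MIM volume-conduction nullity study
#'
#' Repeatedly simulates >= 20 independent sources mixed linearly to the
#' sensors (frequency-domain: independent complex Gaussian coefficients per
#' source, trial and bin), computes the voxel-to-whole-brain MIM map after
#' eLORETA inversion, and compares the map mean against the 95th percentile
#' of a trial-shuffled null (independent trial permutations per voxel
#' destroy cross-voxel phase consistency while keeping every marginal
#' spectrum).
#'
#' @param n_sims number of simulated datasets (50)
#' @param n_sources number of independent sources (20)
#' @param n_trials trials per dataset (200)
#' @param n_shuffles trial shuffles for the null (40)
#' @param n_voxels source-grid size (40)
#' @param seed master seed
#' @return list: `below_null_rate` (fraction of sims with map mean below the
#'   null 95th percentile), `map_means`, `null_q95s`
#' @export
run_mim_nullity_study <- function(n_sims = 50, n_sources = 20, n_trials = 200,
                                  n_shuffles = 40, n_voxels = 40, seed = 1) {
  hm <- head_model(n_voxels = n_voxels)
  lf <- generate_leadfield(hm)
  op <- eloreta_inverse(lf, alpha_reg = 0.05)
  nch <- length(hm$channel_labels)
  nb <- 11L
  below <- logical(n_sims)
  map_means <- numeric(n_sims)
  null_q95s <- numeric(n_sims)

  map_from_sc <- function(sc) {
    # sc: 3V x bins x trials source coefficients
    nbv <- dim(sc)[1]
    Sb <- matrix(0 + 0i, nbv, nbv)
    for (f in seq_len(dim(sc)[2])) {
      A <- matrix(sc[, f, ], nrow = nbv)
      Sb <- Sb + (A %*% Conj(t(A))) / dim(sc)[3]
    }
    cs <- structure(list(S = Sb / dim(sc)[2], n_voxels = nbv / 3L,
                         n_trials = dim(sc)[3], bins = seq_len(dim(sc)[2]),
                         per_bin = FALSE), class = "voxel_cross_spectrum")
    mim_voxel_to_whole_brain(cs)
  }

  for (s in seq_len(n_sims)) {
    set.seed(child_seed(seed, s))
    # independent sources at random voxels, random fixed orientations
    src_vox <- sample.int(n_voxels, n_sources, replace = FALSE)
    mix <- vapply(src_vox, function(vx) {
      ori <- rnorm(3); ori <- ori / sqrt(sum(ori^2))
      as.numeric(t(lf$gain[vx, , ]) %*% ori)
    }, numeric(nch))                                  # ch x sources
    coef <- array(complex(real = rnorm(n_sources * nb * n_trials),
                          imaginary = rnorm(n_sources * nb * n_trials)),
                  dim = c(n_sources, nb, n_trials))
    x <- array(mix %*% matrix(coef, n_sources), dim = c(nch, nb, n_trials))
    sc <- array(op$T %*% matrix(x, nch), dim = c(nrow(op$T), nb, n_trials))
    obs_map <- map_from_sc(sc)
    map_means[s] <- mean(obs_map)

    null_means <- numeric(n_shuffles)
    for (h in seq_len(n_shuffles)) {
      scs <- sc
      for (v in seq_len(n_voxels)) {
        perm <- sample.int(n_trials)
        idx <- (3 * (v - 1) + 1):(3 * v)
        scs[idx, , ] <- sc[idx, , perm]
      }
      null_means[h] <- mean(map_from_sc(scs))
    }
    null_q95s[s] <- quantile(null_means, 0.95, type = 1)
    below[s] <- map_means[s] < null_q95s[s]
    if (s == 1L) null_store <- matrix(NA_real_, n_sims, n_shuffles)
    null_store[s, ] <- null_means
  }
  # pooled check: the grand mean over simulations against the 95th
  # percentile of grand means formed from one shuffled null per simulation
  set.seed(child_seed(seed, 999999))
  grand_null <- replicate(400, mean(null_store[cbind(seq_len(n_sims),
                                    sample.int(n_shuffles, n_sims, TRUE))]))
  grand_mean <- mean(map_means)
  grand_q95 <- quantile(grand_null, 0.95, type = 1)
  list(below_null_rate = mean(below), map_means = map_means,
       null_q95s = null_q95s, grand_mean = grand_mean,
       grand_null_q95 = unname(grand_q95),
       grand_below = grand_mean < grand_q95)
}

#' MIM remixing-invariance study
#'
#' Applies random invertible 3 x 3 remixings within each voxel's source
#' space and records the relative MIM change, plus the agreement between
#' the trace form and the eigenvalue-sum form.
#'
#' @param n_remix number of random remixings (100)
#' @param seed RNG seed
#' @return list: `max_rel_change`, `max_trace_eig_diff`
#' @export
run_mim_invariance_study <- function(n_remix = 100, seed = 1) {
  set.seed(seed)
  rand_herm <- function() {
    A <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
    (A %*% Conj(t(A))) / 3
  }
  max_rel <- 0
  max_te <- 0
  for (i in seq_len(n_remix)) {
    Sii <- rand_herm(); Sjj <- rand_herm()
    Sij <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
    m0 <- mim_pair(Sii, Sjj, Sij)
    repeat {
      A <- matrix(rnorm(9), 3); B <- matrix(rnorm(9), 3)
      if (abs(det(A)) > 0.05 && abs(det(B)) > 0.05) break
    }
    m1 <- mim_pair(A %*% Sii %*% t(A), B %*% Sjj %*% t(B), A %*% Sij %*% t(B))
    max_rel <- max(max_rel, abs(m1 - m0) / m0)
    P <- solve(Re(Sii)) %*% Im(Sij) %*% solve(Re(Sjj)) %*% t(Im(Sij))
    max_te <- max(max_te, abs(m0 - sum(Re(eigen(P)$values))) / m0)
  }
  list(max_rel_change = max_rel, max_trace_eig_diff = max_te)
}

#' eLORETA exact-localisation study
#'
#' Noiseless single-dipole data from every voxel and orientation of a test
#' grid; counts how often the maximum source power lands on the true voxel.
#'
#' @param n_voxels grid size (100)
#' @param alpha_reg regularisation (near zero for the noiseless limit)
#' @return list: `n_correct`, `n_total`, `accuracy`
#' @export
run_localisation_study <- function(n_voxels = 100, alpha_reg = 1e-10) {
  hm <- head_model(n_voxels = n_voxels)
  lf <- generate_leadfield(hm)
  op <- eloreta_inverse(lf, alpha_reg = alpha_reg)
  K <- leadfield_matrix(lf)
  correct <- 0L; total <- 0L
  for (v in seq_len(n_voxels)) {
    for (o in 1:3) {
      x <- K[, 3 * (v - 1) + o]
      m <- op$T %*% x
      pw <- colSums(matrix(m^2, nrow = 3))
      total <- total + 1L
      if (which.max(pw) == v) correct <- correct + 1L
    }
  }
  list(n_correct = correct, n_total = total, accuracy = correct / total)
}

#' Cluster-permutation type-I calibration study
#'
#' Simulates null datasets (both groups from the same distribution) and
#' records the family-wise rejection rate: the fraction of datasets in which
#' any cluster reaches p < alpha.
#'
#' @param n_sims number of null datasets (500)
#' @param n_per_group participants per group (12)
#' @param n_perm permutations per test (500)
#' @param graph channel neighbour graph (default: Delaunay on the standard
#'   montage)
#' @param alpha nominal level
#' @param seed master seed
#' @return list: `fwer`, `n_sims`, binomial 95% interval bounds
#' @export
run_cluster_calibration_study <- function(n_sims = 500, n_per_group = 12,
                                          n_perm = 500, graph = NULL,
                                          alpha = 0.05, seed = 1) {
  if (is.null(graph)) graph <- build_neighbors(standard_montage_64())
  nch <- length(graph$labels)
  reject <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(child_seed(seed, s))
    a <- matrix(rnorm(n_per_group * nch), n_per_group)
    b <- matrix(rnorm(n_per_group * nch), n_per_group)
    r <- cluster_permutation_test(a, b, graph, n_perm = n_perm,
                                  seed = child_seed(seed, 10000 + s),
                                  alpha = alpha)
    ps <- vapply(r$clusters, `[[`, numeric(1), "p_value")
    reject[s] <- length(ps) > 0 && min(ps) < alpha
  }
  fwer <- mean(reject)
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_sims)
  list(fwer = fwer, n_sims = n_sims, lower = alpha - half, upper = alpha + half)
}

#' Monte-Carlo vs exhaustive permutation p (small-sample oracle check)
#'
#' On a 4-vs-4 dataset the group relabelling space has choose(8,4) = 70
#' assignments; the exact p of the largest observed cluster is compared with
#' the Monte-Carlo p from [cluster_permutation_test()].
#'
#' @param seed RNG seed for the toy data and the Monte-Carlo test
#' @param n_perm Monte-Carlo permutations
#' @return list: `p_mc`, `p_exact`, `se_mc`, `diff_in_se`
#' @export
run_enumeration_check <- function(seed = 1, n_perm = 2000) {
  set.seed(seed)
  nch <- 16
  mont <- standard_montage_64()[seq_len(nch), ]
  graph <- build_neighbors(mont)
  a <- matrix(rnorm(4 * nch), 4)
  a[, 1:3] <- a[, 1:3] + 2.2          # a moderate planted cluster
  b <- matrix(rnorm(4 * nch), 4)
  res <- cluster_permutation_test(a, b, graph, n_perm = n_perm,
                                  seed = seed + 1, alpha = 0.05)
  if (!length(res$clusters)) return(list(p_mc = NA, p_exact = NA))
  obs_mass <- abs(res$clusters[[1]]$mass)

  # exhaustive enumeration of all 70 assignments
  X <- rbind(a, b)
  combs <- utils::combn(8, 4)
  tcrit <- qt(1 - 0.05 / 2, 6)
  null <- apply(combs, 2, function(ix) {
    P <- matrix(0, 1, 8); P[1, ix] <- 1
    max_cluster_mass(X, P, 4, 4, tcrit, graph$adjacency)
  })
  p_exact <- sum(null >= obs_mass * (1 - 1e-9)) / 70 # obs labelling is one of the 70
  p_mc <- res$clusters[[1]]$p_value
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  list(p_mc = p_mc, p_exact = p_exact, se_mc = se,
       diff_in_se = abs(p_mc - p_exact) / se)
}

#' Planted-effect recovery study
#'
#' Runs the reduced-scale end-to-end pipeline over many seeded cohorts with
#' the default planted effects (control reappraisal-theta increment larger
#' than BPD) and records how often (i) the sensor cluster test's smallest-p
#' cluster contains a channel adjacent to a planted source, (ii) the
#' voxel-wise power-ratio test flags a planted voxel or one of its grid
#' neighbours, and (iii) the MIM-contrast test does the same.
#'
#' @param n_seeds number of independent cohorts (50)
#' @param seed master seed
#' @param n_per_group participants per group (8)
#' @param n_trials trials per participant (24; 8 per condition)
#' @param sfreq simulation sampling rate (50 Hz is ample for the theta band)
#' @param n_voxels source grid (48)
#' @param n_perm permutations per test (500)
#' @param slide_s sensor TFR slide (0.25 s)
#' @return list of recovery rates and per-seed indicators
#' @export
run_recovery_study <- function(n_seeds = 50, seed = 1, n_per_group = 8,
                               n_trials = 24, sfreq = 50, n_voxels = 48,
                               n_perm = 500, slide_s = 0.25) {
  hm <- head_model(n_voxels = n_voxels)
  lf <- generate_leadfield(hm)
  op <- eloreta_inverse(lf, alpha_reg = 0.05)
  graph <- build_neighbors(standard_montage_64())
  vnb <- voxel_neighbors(hm)

  sensor_hit <- logical(n_seeds)
  power_hit <- logical(n_seeds)
  mim_hit <- logical(n_seeds)

  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_per_group = n_per_group, n_blocks = 1L,
                      trials_per_block = n_trials, sfreq = sfreq,
                      seed = child_seed(seed, 333 + s))
    coh <- generate_cohort(cfg, lf = lf)
    gt <- coh$ground_truth
    planted <- c(gt$effect_voxel, gt$partner_voxel)
    planted_ext <- unique(c(planted, unlist(vnb[planted])))
    adj_ch <- unique(c(effect_adjacent_channels(hm, gt$effect_voxel),
                       effect_adjacent_channels(hm, gt$partner_voxel)))

    grp <- coh$participants$group
    ths <- t(vapply(coh$epochs, participant_theta_summary,
                    numeric(length(hm$channel_labels)), slide_s = slide_s))
    res <- cluster_permutation_test(ths[grp == "control", ], ths[grp == "bpd", ],
                                    graph, n_perm = max(n_perm, 100),
                                    seed = child_seed(seed, 444 + s))
    if (length(res$clusters)) {
      best <- res$clusters[[which.min(vapply(res$clusters, `[[`, numeric(1),
                                             "p_value"))]]
      sensor_hit[s] <- any(best$members %in% adj_ch)
    }

    src <- t(vapply(coh$epochs, function(ep)
      participant_source_contrast(ep, op)$contrast, numeric(n_voxels)))
    vt <- voxel_permutation_test(src[grp == "control", ], src[grp == "bpd", ],
                                 n_perm = max(n_perm, 100),
                                 seed = child_seed(seed, 555 + s),
                                 neighbors = vnb, hm = hm)
    power_hit[s] <- any(vt$significant[planted_ext])

    maps_ctl <- lapply(coh$epochs[grp == "control"], participant_mim_maps, op = op)
    maps_bpd <- lapply(coh$epochs[grp == "bpd"], participant_mim_maps, op = op)
    mt <- mim_contrast_and_test(maps_ctl, maps_bpd,
                                n_perm = max(n_perm, 100),
                                seed = child_seed(seed, 666 + s),
                                neighbors = vnb, hm = hm)
    mim_hit[s] <- any(mt$test$significant[planted_ext])
  }
  list(sensor_rate = mean(sensor_hit), power_rate = mean(power_hit),
       mim_rate = mean(mim_hit), sensor_hit = sensor_hit,
       power_hit = power_hit, mim_hit = mim_hit, n_seeds = n_seeds)
}

#' Induced-pathway specificity check
#'
#' Evoked-only simulation (no induced theta): after ERP subtraction the
#' theta summaries should be a small fraction of the planted-effect scale.
#' Also verifies the analytic single-tone Hanning gain of the TFR.
#'
#' @param seed RNG seed
#' @param sfreq sampling rate for the check (100)
#' @return list: `max_abs_summary`, `effect_scale`, `leakage_fraction`,
#'   `tone_rel_error`
#' @export
run_induced_specificity_check <- function(seed = 1, sfreq = 100) {
  hm <- head_model(n_voxels = 60)
  lf <- generate_leadfield(hm)

  # evoked-only: induced amplitude zero in every condition/group; the trial
  # count matches the study paradigm (150 trials, 50 per condition)
  cfg0 <- sim_config(n_per_group = 2, n_blocks = 1L, trials_per_block = 150,
                     sfreq = sfreq, theta_base_amp = 0,
                     theta_effect_size = c(control = 0, bpd = 0),
                     evoked_amplitude = 2, seed = seed)
  ep0 <- simulate_participant(cfg0, "control", lf, seed = child_seed(seed, 1))
  s0 <- participant_theta_summary(ep0, slide_s = 0.25)

  # reference scale: the default planted effect at the same trial count
  cfg1 <- sim_config(n_per_group = 2, n_blocks = 1L, trials_per_block = 150,
                     sfreq = sfreq, seed = seed)
  ep1 <- simulate_participant(cfg1, "control", lf, seed = child_seed(seed, 2))
  s1 <- participant_theta_summary(ep1, slide_s = 0.25)
  effect_scale <- max(abs(s1))

  # analytic single-tone check: amplitude A tone -> power A^2/2
  set.seed(child_seed(seed, 3))
  A <- 2.5; f0 <- 6
  times <- seq(-6, 7, by = 1 / sfreq)
  mont <- standard_montage_64()[1:2, ]
  dat <- array(0, c(2, length(times), 6))
  for (k in 1:6) {
    ph <- runif(1, 0, 2 * pi)
    dat[1, , k] <- A * sin(2 * pi * f0 * times + ph)
    dat[2, , k] <- rnorm(length(times), 0, 0.01)
  }
  epo <- eeg_epochs(dat, times, sfreq, rep("maintain", 6), mont)
  tf <- tfr_hanning(epo, freqs = f0, centre_times = seq(1, 5, 0.5))
  tone_power <- mean(tf$maintain$power[1, 1, ])
  tone_rel_error <- abs(tone_power - A^2 / 2) / (A^2 / 2)

  list(max_abs_summary = max(abs(s0)), effect_scale = effect_scale,
       leakage_fraction = max(abs(s0)) / effect_scale,
       tone_rel_error = tone_rel_error)
}

#' Regression and ANOVA recovery check
#'
#' (i) A synthetic cohort with a planted ERQ-R -> theta slope of 0.02 and
#' vanishing residual noise must recover the coefficient; (ii) the split-plot
#' ANOVA is run on the default behavioural cohort and its condition effect
#' reported.
#'
#' @param seed RNG seed
#' @param slope planted slope (0.02 microvolt^2 per ERQ-R unit)
#' @param noise_sd residual SD (1e-6; the sigma -> 0 limit)
#' @return list: `slope_recovered`, `slope_planted`, `anova` (anova_result on
#'   the simulated ratings), `behaviour` (the behavioural table used)
#' @export
run_behaviour_recovery_check <- function(seed = 1, slope = 0.02,
                                         noise_sd = 1e-6) {
  cfg <- sim_config(seed = seed)
  beh <- rbind(simulate_behaviour(cfg, "bpd", child_seed(seed, 1)),
               simulate_behaviour(cfg, "control", child_seed(seed, 2)))
  set.seed(child_seed(seed, 3))
  bpd <- beh[beh$group == "bpd", ]
  theta <- slope * bpd$erq_reappraisal + rnorm(nrow(bpd), 0, noise_sd)
  reg <- theta_regression(theta, bpd$erq_reappraisal, bpd$erq_suppression,
                          bpd$rating_reappraise - bpd$rating_maintain)
  est <- reg$coefficients$estimate[reg$coefficients$term == "erq_r"]

  long <- data.frame(
    participant = rep(beh$participant_id, 2),
    group = rep(beh$group, 2),
    condition = rep(c("maintain", "reappraise"), each = nrow(beh)),
    value = c(beh$rating_maintain, beh$rating_reappraise))
  av <- mixed_anova_2x2(long)
  list(slope_recovered = est, slope_planted = slope, regression = reg,
       anova = av, behaviour = beh)
}
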