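## Synthetic cohort generator.
##
## Emulates the study conditions: two groups (BPD, control) of 25
## participants, three blocks of 50 trials in three conditions
## (neutral / maintain / reappraise, equal counts overall), 13-s epochs from
## -6 to +7 s around the regulation instruction with picture onset at -3 s.
## Each trial is the leadfield projection of (i) spatially distributed 1/f
## background sources, (ii) phase-locked evoked transients after picture and
## instruction onset (identical across trials within a condition), (iii) a
## random-phase induced theta source at a right-frontal voxel whose amplitude
## in the regulation window rises by a group-specific increment in the
## reappraisal condition only, and (iv) a second theta source phase-lagged to
## the first (planting genuine, non-zero-lag connectivity), plus uncorrelated
## sensor noise.

#' Simulation configuration
#'
#' Returns the full set of generator parameters with defaults emulating the
#' study conditions; any field can be overridden by name.
#'
#' @param ... named overrides of the defaults listed below
#' @return object of class `sim_config` (a validated list)
#'
#' @section Fields:
#' \describe{
#'   \item{n_per_group, n_blocks, trials_per_block}{cohort sizes: 25, 3, 50}
#'   \item{sfreq}{sampling rate, Hz (250)}
#'   \item{epoch_span}{c(-6, 7) seconds around the instruction}
#'   \item{picture_onset}{-3 s}
#'   \item{regulation_window}{c(1, 5) s; baseline_window c(-4.2, -3.2) s}
#'   \item{theta_freq}{6 Hz induced oscillation}
#'   \item{theta_base_amp}{source amplitude of the induced theta oscillator
#'     in the regulation window, all conditions (1.0)}
#'   \item{theta_effect_size}{named vector: reappraisal-only amplitude
#'     increment per group (control 1.0, bpd 0.4)}
#'   \item{coupling_rel_amp}{amplitude of the phase-lagged partner source
#'     relative to the primary (0.8)}
#'   \item{coupling_lag}{phase lag of the partner in radians (pi/2)}
#'   \item{effect_target, partner_target}{voxel site labels or coordinates
#'     ("right_frontal", "central")}
#'   \item{n_noise_sources, noise_amp, noise_exponent}{12 pink-noise sources,
#'     source amplitude 1.2, 1/f exponent 1}
#'   \item{sensor_noise}{white sensor noise SD in microvolts (0.5)}
#'   \item{evoked_amplitude}{scale of the phase-locked transients (1.0)}
#'   \item{artifact_amplitude}{frontal low-frequency drift amplitude
#'     (0 = off; used to exercise ICA cleanup)}
#'   \item{subject_jitter}{relative SD of per-participant amplitude scaling
#'     (0.1)}
#'   \item{erq_theta_slope}{optional linear dependence of the planted theta
#'     increment on the participant's ERQ Reappraisal score (0 = off)}
#'   \item{behaviour}{group means/SDs for ratings and ERQ facets (see
#'     [simulate_behaviour()])}
#'   \item{seed}{master seed}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_per_group = 25L,
    n_blocks = 3L,
    trials_per_block = 50L,
    sfreq = 250,
    epoch_span = c(-6, 7),
    picture_onset = -3,
    regulation_window = c(1, 5),
    baseline_window = c(-4.2, -3.2),
    theta_freq = 6,
    theta_base_amp = 1.0,
    theta_effect_size = c(control = 1.0, bpd = 0.4),
    coupling_rel_amp = 0.8,
    coupling_lag = pi / 2,
    effect_target = "right_frontal",
    partner_target = "central",
    n_noise_sources = 12L,
    noise_amp = 1.2,
    noise_exponent = 1,
    sensor_noise = 0.5,
    evoked_amplitude = 1.0,
    artifact_amplitude = 0,
    subject_jitter = 0.1,
    erq_theta_slope = 0,
    behaviour = list(
      bpd = list(rating = c(neutral = 15, maintain = 58, reappraise = 42),
                 rating_sd = c(neutral = 10, maintain = 25, reappraise = 21),
                 erq_r = 21, erq_r_sd = 8, erq_s = 15, erq_s_sd = 5),
      control = list(rating = c(neutral = 15, maintain = 56, reappraise = 35),
                     rating_sd = c(neutral = 10, maintain = 21, reappraise = 19),
                     erq_r = 27, erq_r_sd = 7, erq_s = 12, erq_s_sd = 5)),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 1, cfg$n_blocks >= 1, cfg$trials_per_block >= 1,
            cfg$sfreq > 0, length(cfg$epoch_span) == 2,
            cfg$epoch_span[1] < cfg$epoch_span[2])
  total <- cfg$n_blocks * cfg$trials_per_block
  if (total %% 3L != 0L)
    stop("total trial count must divide into the three conditions ",
         "(2:1 negative:neutral pictures, negatives split between maintain ",
         "and reappraise)")
  if (cfg$epoch_span[1] > cfg$baseline_window[1] ||
      cfg$epoch_span[2] < cfg$regulation_window[2] + 1)
    stop("epoch_span must cover the baseline window and the regulation ",
         "window with a 1-s margin")
  if (!all(c("control", "bpd") %in% names(cfg$theta_effect_size)))
    stop("theta_effect_size needs named entries for both groups")
  if (is.null(cfg$seed)) stop("sim_config: seed must be set")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_per_group, " per group, ", x$n_blocks, " x ",
      x$trials_per_block, " trials @ ", x$sfreq, " Hz, effect ",
      paste(sprintf("%s=%.2f", names(x$theta_effect_size), x$theta_effect_size),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Pseudo-randomised condition sequence
#'
#' Equal numbers of neutral / maintain / reappraise trials per experiment,
#' spread evenly over blocks, shuffled within block under the constraint of
#' no more than three consecutive repeats of the same condition.
#'
#' @param cfg sim_config
#' @return character vector of length n_blocks * trials_per_block
#' @keywords internal
condition_sequence <- function(cfg) {
  total <- cfg$n_blocks * cfg$trials_per_block
  per_cond <- total / 3L
  conds <- c("neutral", "maintain", "reappraise")
  pool <- rep(conds, each = per_cond)
  pool <- pool[sample.int(total)]
  out <- character(0)
  for (b in seq_len(cfg$n_blocks)) {
    blk <- pool[((b - 1) * cfg$trials_per_block + 1):(b * cfg$trials_per_block)]
    for (try in 1:200) {
      cand <- blk[sample.int(length(blk))]
      runs <- rle(cand)$lengths
      if (max(runs) <= 3) { blk <- cand; break }
    }
    out <- c(out, blk)
  }
  out
}

## raised-cosine on/off envelope over [t0, t1] with ramp `r` seconds
window_envelope <- function(times, t0, t1, r = 0.25) {
  env <- numeric(length(times))
  inside <- times >= t0 & times <= t1
  env[inside] <- 1
  up <- times >= t0 & times < t0 + r
  env[up] <- 0.5 - 0.5 * cos(pi * (times[up] - t0) / r)
  dn <- times > t1 - r & times <= t1
  env[dn] <- 0.5 - 0.5 * cos(pi * (t1 - times[dn]) / r)
  env
}

## fixed evoked waveform: damped 5-Hz transient starting at `onset`
evoked_waveform <- function(times, onset, amp) {
  tt <- times - onset
  w <- numeric(length(times))
  on <- tt >= 0 & tt <= 1
  w[on] <- amp * exp(-tt[on] / 0.2) * sin(2 * pi * 5 * tt[on])
  w
}

#' Simulate one participant's epoched EEG
#'
#' @param cfg sim_config
#' @param group "control" or "bpd"
#' @param lf leadfield (shared ground truth with the inverse solver)
#' @param seed integer seed for this participant
#' @param effect_increment optional override of the reappraisal theta
#'   increment (used to couple the planted effect to ERQ scores)
#' @return `eeg_epochs` with attribute `ground_truth` (planted sites,
#'   amplitudes, per-condition source power of the effect oscillator)
#' @export
simulate_participant <- function(cfg, group, lf, seed,
                                 effect_increment = NULL) {
  if (!group %in% c("control", "bpd")) stop("unknown group label: ", group)
  validate_sim_config(cfg)
  hm <- lf$head_model
  set.seed(seed)

  nch <- nrow(hm$channel_positions)
  times <- seq(cfg$epoch_span[1], cfg$epoch_span[2], by = 1 / cfg$sfreq)
  nt <- length(times)
  conds <- condition_sequence(cfg)
  ntr <- length(conds)

  effect_voxel <- nearest_voxel(hm, cfg$effect_target)
  partner_voxel <- nearest_voxel(hm, cfg$partner_target)
  posterior_voxel <- nearest_voxel(hm, "posterior")
  central_voxel <- nearest_voxel(hm, "central")

  radial_topo <- function(vx) {
    ori <- hm$voxel_positions[vx, ]
    ori <- ori / sqrt(sum(ori^2))
    as.numeric(t(lf$gain[vx, , ]) %*% ori)
  }
  topo_eff <- radial_topo(effect_voxel)
  topo_par <- radial_topo(partner_voxel)
  topo_pic <- radial_topo(posterior_voxel)
  topo_ins <- radial_topo(central_voxel)

  # fixed background-source sites and random orientations for this participant
  noise_vox <- sample.int(hm$n_voxels, cfg$n_noise_sources)
  noise_topo <- vapply(noise_vox, function(vx) {
    ori <- rnorm(3); ori <- ori / sqrt(sum(ori^2))
    as.numeric(t(lf$gain[vx, , ]) %*% ori)
  }, numeric(nch))

  subj_scale <- max(0.2, 1 + rnorm(1, 0, cfg$subject_jitter))
  inc <- effect_increment %||% unname(cfg$theta_effect_size[[group]])

  env <- window_envelope(times, cfg$regulation_window[1], cfg$regulation_window[2])
  ev_pic <- evoked_waveform(times, cfg$picture_onset, cfg$evoked_amplitude)
  ev_ins <- evoked_waveform(times, 0, cfg$evoked_amplitude)

  frontal <- grepl("^(Fp|AF)", hm$channel_labels)
  art_topo <- as.numeric(frontal) + 0.3 * grepl("^F[0-9z]", hm$channel_labels)
  # ocular artifact: sparse blink-like pulses (300-ms raised-cosine bumps)
  blink_course <- function() {
    w <- numeric(nt)
    n_blinks <- rpois(1, 4) + 1
    width <- round(0.3 * cfg$sfreq)
    for (b in seq_len(n_blinks)) {
      at <- sample.int(nt - width, 1)
      w[at:(at + width - 1)] <- w[at:(at + width - 1)] +
        (0.5 - 0.5 * cos(2 * pi * seq_len(width) / width))
    }
    w
  }
  artifact_course <- if (cfg$artifact_amplitude > 0)
    matrix(0, nt, ntr) else NULL

  data <- array(0, dim = c(nch, nt, ntr))
  theta_amp_cond <- c(neutral = cfg$theta_base_amp, maintain = cfg$theta_base_amp,
                      reappraise = cfg$theta_base_amp + inc)
  det_topo <- cbind(topo_pic, topo_ins, topo_eff, topo_par) # fixed topographies
  for (k in seq_len(ntr)) {
    cond <- conds[k]
    # (i) background 1/f sources, new realisation each trial
    src <- pink_noise_matrix(nt, cfg$n_noise_sources, cfg$noise_exponent, cfg$sfreq)
    # (ii) evoked transients, identical within condition (negative pictures
    # evoke a slightly larger response than neutral ones); (iii) induced
    # theta at the effect voxel, random phase per trial; (iv) phase-lagged
    # partner source (plants MIM connectivity)
    pic_scale <- if (cond == "neutral") 1 else 1.2
    phi <- runif(1, 0, 2 * pi)
    amp <- theta_amp_cond[[cond]] * subj_scale
    waves <- rbind(ev_pic * pic_scale,
                   ev_ins,
                   amp * sin(2 * pi * cfg$theta_freq * times + phi) * env,
                   cfg$coupling_rel_amp * amp *
                     sin(2 * pi * cfg$theta_freq * times + phi + cfg$coupling_lag) * env)
    x <- noise_topo %*% (t(src) * cfg$noise_amp) + det_topo %*% waves +
      matrix(rnorm(nch * nt, 0, cfg$sensor_noise), nch, nt)
    if (cfg$artifact_amplitude > 0) {
      ac <- cfg$artifact_amplitude * blink_course()
      artifact_course[, k] <- ac
      x <- x + outer(art_topo, ac)
    }
    data[, , k] <- x
  }

  ep <- eeg_epochs(data, times, cfg$sfreq, conds, hm_montage(hm),
                   provenance = "simulated")
  attr(ep, "ground_truth") <- list(
    effect_voxel = effect_voxel, partner_voxel = partner_voxel,
    noise_voxels = noise_vox, group = group,
    theta_amp_by_condition = theta_amp_cond * subj_scale,
    effect_increment = inc, subject_scale = subj_scale, seed = seed,
    artifact_course = artifact_course)
  ep
}

#' @keywords internal
hm_montage <- function(hm) {
  data.frame(label = hm$channel_labels,
             x = hm$channel_positions[, 1],
             y = hm$channel_positions[, 2],
             z = hm$channel_positions[, 3],
             stringsAsFactors = FALSE)
}

#' Simulate behavioural ratings and ERQ scores
#'
#' Condition-mean emotion ratings (0-100 scale) and ERQ facet scores drawn
#' from truncated normal distributions with the group means/SDs of the study
#' population (BPD: reappraisal 42 +/- 21, maintenance 58 +/- 25, ERQ-R
#' 21 +/- 8, ERQ-S 15 +/- 5; controls 35 +/- 19, 56 +/- 21, 27 +/- 7,
#' 12 +/- 5).
#'
#' @param cfg sim_config
#' @param group "control" or "bpd"
#' @param seed integer seed
#' @param n number of participants to draw (default cfg$n_per_group)
#' @return data.frame: participant_id, group, rating_neutral,
#'   rating_maintain, rating_reappraise, erq_reappraisal, erq_suppression
#' @export
simulate_behaviour <- function(cfg, group, seed, n = cfg$n_per_group) {
  if (!group %in% c("control", "bpd")) stop("unknown group label: ", group)
  set.seed(seed)
  par <- cfg$behaviour[[group]]
  ratings <- sapply(c("neutral", "maintain", "reappraise"), function(cd)
    rtruncnorm(n, par$rating[[cd]], par$rating_sd[[cd]], 0, 100))
  ratings <- matrix(ratings, nrow = n)
  data.frame(
    participant_id = sprintf("%s%02d", substr(group, 1, 3), seq_len(n)),
    group = group,
    rating_neutral = ratings[, 1],
    rating_maintain = ratings[, 2],
    rating_reappraise = ratings[, 3],
    erq_reappraisal = rtruncnorm(n, par$erq_r, par$erq_r_sd, 10, 42),
    erq_suppression = rtruncnorm(n, par$erq_s, par$erq_s_sd, 4, 28),
    stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Behavioural table plus epoched EEG for every participant, with a
#' ground-truth record of the planted effects. Deterministic given
#' `cfg$seed`. With `out_dir` set, each participant's epochs are written to
#' `<out_dir>/<id>_epochs.rds` and the returned `epochs` field holds paths
#' instead of objects (full-scale cohorts do not fit in memory).
#'
#' @param cfg sim_config
#' @param lf leadfield (default: generated from `head_model(n_voxels)`)
#' @param n_voxels voxel count when `lf` is NULL
#' @param out_dir optional directory for per-participant RDS files
#' @return list: `participants` (behavioural table), `epochs` (named list of
#'   eeg_epochs or file paths), `ground_truth`, `config`
#' @export
generate_cohort <- function(cfg, lf = NULL, n_voxels = 400, out_dir = NULL) {
  validate_sim_config(cfg)
  if (is.null(lf)) lf <- generate_leadfield(head_model(n_voxels = n_voxels))
  beh <- rbind(simulate_behaviour(cfg, "bpd", child_seed(cfg$seed, 1)),
               simulate_behaviour(cfg, "control", child_seed(cfg$seed, 2)))
  n_all <- nrow(beh)
  seeds <- vapply(seq_len(n_all), function(i) child_seed(cfg$seed, 100 + i),
                  integer(1))

  epochs <- vector("list", n_all)
  names(epochs) <- beh$participant_id
  gt_part <- vector("list", n_all)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  for (i in seq_len(n_all)) {
    g <- beh$group[i]
    inc <- unname(cfg$theta_effect_size[[g]])
    if (cfg$erq_theta_slope != 0) {
      mu <- cfg$behaviour[[g]]$erq_r
      inc <- inc + cfg$erq_theta_slope * (beh$erq_reappraisal[i] - mu)
      inc <- max(0, inc)
    }
    ep <- simulate_participant(cfg, g, lf, seeds[i], effect_increment = inc)
    gt_part[[i]] <- attr(ep, "ground_truth")
    if (is.null(out_dir)) {
      epochs[[i]] <- ep
    } else {
      path <- file.path(out_dir, paste0(beh$participant_id[i], "_epochs.rds"))
      saveRDS(ep, path)
      epochs[[i]] <- path
    }
  }
  gt <- list(effect_voxel = gt_part[[1]]$effect_voxel,
             partner_voxel = gt_part[[1]]$partner_voxel,
             theta_effect_size = cfg$theta_effect_size,
             participant = setNames(gt_part, beh$participant_id),
             seeds = setNames(seeds, beh$participant_id))
  list(participants = beh, epochs = epochs, ground_truth = gt, config = cfg,
       leadfield = lf)
}
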