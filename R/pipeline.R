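## End-to-end orchestration: simulate -> preprocess -> sensor TFR + cluster
## test -> eLORETA source power -> MIM connectivity -> behavioural
## statistics, with every stage seeded and all artifacts written to a run
## directory.

#' Pipeline run configuration
#'
#' @param sim [sim_config()] for the cohort generator
#' @param n_voxels source-grid size
#' @param out_dir run directory (created if missing)
#' @param tfr_slide_s sensor TFR slide in seconds
#' @param n_perm_sensor,n_perm_voxel permutation counts
#' @param tails voxel-test sidedness ("two" or "one")
#' @param z_threshold artifact-rejection threshold (z units)
#' @param do_filter run the Butterworth filter bank (the simulator output is
#'   already band-limited and detrended, so this mainly costs time on
#'   synthetic runs; required for data read from disk)
#' @param do_ica run ocular ICA cleanup (only useful when the simulation
#'   plants a frontal drift, `artifact_amplitude > 0`)
#' @param seeds named list of stage seeds (cluster, voxel, mim); derived
#'   from `sim$seed` when omitted
#' @return object of class `run_config`
#' @export
run_config <- function(sim = sim_config(), n_voxels = 400, out_dir = tempfile("run"),
                       tfr_slide_s = 0.05, n_perm_sensor = 10000,
                       n_perm_voxel = 10000, tails = "two", z_threshold = 4,
                       do_filter = FALSE, do_ica = FALSE, seeds = NULL) {
  validate_sim_config(sim)
  if (is.null(seeds))
    seeds <- list(cluster = child_seed(sim$seed, 71),
                  voxel = child_seed(sim$seed, 72),
                  mim = child_seed(sim$seed, 73))
  if (!all(c("cluster", "voxel", "mim") %in% names(seeds)))
    stop("seeds must name every stochastic stage: cluster, voxel, mim")
  cfg <- list(sim = sim, n_voxels = n_voxels, out_dir = out_dir,
              tfr_slide_s = tfr_slide_s, n_perm_sensor = n_perm_sensor,
              n_perm_voxel = n_perm_voxel, tails = tails,
              z_threshold = z_threshold, do_filter = do_filter,
              do_ica = do_ica, seeds = seeds)
  class(cfg) <- "run_config"
  cfg
}

#' Serialise / restore a run configuration (YAML)
#' @param cfg run_config
#' @param path output file
#' @return `write_run_config` the path; `read_run_config` a run_config
#' @export
write_run_config <- function(cfg, path) {
  # yaml writes named atomic vectors as plain sequences; convert them to
  # maps so names survive the round trip
  listify <- function(x) {
    if (is.list(x)) return(lapply(x, listify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  x <- lapply(unclass(cfg), listify)
  x$sim <- lapply(unclass(cfg$sim), listify)
  yaml::write_yaml(x, path, precision = 15L)
  path
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- x$sim
  sim$theta_effect_size <- unlist(sim$theta_effect_size)
  for (f in c("epoch_span", "regulation_window", "baseline_window"))
    sim[[f]] <- as.numeric(unlist(sim[[f]]))
  sim$behaviour <- lapply(sim$behaviour, function(g) {
    g$rating <- unlist(g$rating); g$rating_sd <- unlist(g$rating_sd); g
  })
  simcfg <- do.call(sim_config, sim)
  x$sim <- NULL
  do.call(run_config, c(list(sim = simcfg), x))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a freshly simulated cohort and writes the
#' artifacts to the run directory: `participants.csv`, `results.json`,
#' `run_config.yaml`, `log.txt` plus RDS intermediates (theta summaries,
#' source contrasts, MIM maps) with MD5 checksums in the log. Re-running
#' with the same configuration reproduces all statistics exactly.
#'
#' @param cfg run_config
#' @return list with the main results (cluster test, voxel power test, MIM
#'   test, behavioural ANOVAs, regression) and `paths` of written artifacts
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t_start <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), " ", ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("run started; R ", R.version.string)
  write_run_config(cfg, file.path(cfg$out_dir, "run_config.yaml"))

  stage <- function(name, expr) {
    logf("stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " [artifacts in ", cfg$out_dir, "]", call. = FALSE))
  }

  hm <- head_model(n_voxels = cfg$n_voxels)
  lf <- generate_leadfield(hm)

  coh <- stage("simulate", generate_cohort(cfg$sim, lf = lf))
  utils::write.csv(coh$participants,
                   file.path(cfg$out_dir, "participants.csv"), row.names = FALSE)
  grp <- coh$participants$group

  rejection_logs <- list()
  coh$epochs <- stage("preprocess", lapply(setNames(names(coh$epochs),
                                                    names(coh$epochs)),
    function(id) {
    ep <- coh$epochs[[id]]
    if (cfg$do_filter) ep <- filter_epochs(ep)
    rej <- reject_artifact_trials(ep, z_threshold = cfg$z_threshold)
    rejection_logs[[id]] <<- rej$log
    ep <- rereference_common_average(rej$epochs)
    if (cfg$do_ica) ep <- remove_ocular_components(ep)$epochs
    ep
  }))
  logf("trial rejection: ",
       paste(vapply(rejection_logs, function(l) length(l$rejected),
                    integer(1)), collapse = " "))

  # sensor level
  graph <- build_neighbors(standard_montage_64())
  ths <- stage("sensor_tfr", t(vapply(coh$epochs, participant_theta_summary,
                                      numeric(length(hm$channel_labels)),
                                      slide_s = cfg$tfr_slide_s)))
  cluster <- stage("sensor_stats",
    cluster_permutation_test(ths[grp == "control", ], ths[grp == "bpd", ],
                             graph, n_perm = cfg$n_perm_sensor,
                             seed = cfg$seeds$cluster))

  # source level
  op <- stage("eloreta", eloreta_inverse(lf))
  logf("eLORETA converged in ", op$convergence$iterations, " iterations")
  vnb <- voxel_neighbors(hm)
  src <- stage("source_power", t(vapply(coh$epochs, function(ep)
    participant_source_contrast(ep, op)$contrast, numeric(cfg$n_voxels))))
  voxel <- stage("source_stats",
    voxel_permutation_test(src[grp == "control", ], src[grp == "bpd", ],
                           n_perm = cfg$n_perm_voxel, seed = cfg$seeds$voxel,
                           tails = cfg$tails, neighbors = vnb, hm = hm))

  # connectivity
  maps <- stage("mim", lapply(coh$epochs, participant_mim_maps, op = op))
  mim <- stage("mim_stats",
    mim_contrast_and_test(maps[grp == "control"], maps[grp == "bpd"],
                          n_perm = cfg$n_perm_voxel, seed = cfg$seeds$mim,
                          tails = cfg$tails, neighbors = vnb, hm = hm))

  # behaviour
  beh <- coh$participants
  long <- data.frame(participant = rep(beh$participant_id, 2),
                     group = rep(beh$group, 2),
                     condition = rep(c("maintain", "reappraise"),
                                     each = nrow(beh)),
                     value = c(beh$rating_maintain, beh$rating_reappraise))
  anova_ratings <- stage("behaviour_anova", mixed_anova_2x2(long))

  cluster_channels <- if (length(cluster$clusters))
    cluster$clusters[[which.min(vapply(cluster$clusters, `[[`, numeric(1),
                                       "p_value"))]]$members
  else effect_adjacent_channels(hm, coh$ground_truth$effect_voxel)
  theta_cluster_mean <- rowMeans(ths[, cluster_channels, drop = FALSE])
  bpd_idx <- grp == "bpd"
  regression <- stage("behaviour_regression",
    theta_regression(theta_cluster_mean[bpd_idx],
                     beh$erq_reappraisal[bpd_idx],
                     beh$erq_suppression[bpd_idx],
                     beh$rating_reappraise[bpd_idx] -
                       beh$rating_maintain[bpd_idx]))

  # artifacts
  saveRDS(list(theta_summaries = ths, source_contrasts = src, mim_maps = maps,
               ground_truth = coh$ground_truth),
          file.path(cfg$out_dir, "intermediates.rds"))
  results <- list(
    sensor_clusters = lapply(cluster$clusters, function(cl)
      list(channels = cl$labels, mass = cl$mass, p = cl$p_value)),
    voxel_power = list(n_significant = sum(voxel$significant),
                       clusters = lapply(voxel$clusters, function(cl)
                         list(size = cl$size,
                              centroid_mm = round(cl$centroid_mm, 1),
                              mean_difference = cl$mean_difference))),
    mim = list(n_significant = sum(mim$test$significant),
               clusters = lapply(mim$test$clusters, function(cl)
                 list(size = cl$size, centroid_mm = round(cl$centroid_mm, 1),
                      mean_difference = cl$mean_difference))),
    anova_ratings = anova_ratings$table,
    anova_simple_effects = anova_ratings$simple_effects,
    regression = list(F = regression$F, df1 = regression$df1,
                      df2 = regression$df2, p = regression$p,
                      r_squared = regression$r_squared,
                      coefficients = regression$coefficients),
    seeds = cfg$seeds)
  json_path <- file.path(cfg$out_dir, "results.json")
  jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  for (f in c("participants.csv", "results.json", "intermediates.rds"))
    logf("checksum ", f, " ", unname(tools::md5sum(file.path(cfg$out_dir, f))))
  logf("run finished in ",
       round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 1), " s")

  list(cluster = cluster, voxel = voxel, mim = mim,
       anova_ratings = anova_ratings, regression = regression,
       theta_summaries = ths, source_contrasts = src,
       ground_truth = coh$ground_truth, participants = beh,
       paths = list(dir = cfg$out_dir, results = json_path, log = log_path))
}
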