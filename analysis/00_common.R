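# Shared settings for the analysis workflow: desk-scale study dimensions
# (the methods vignette documents why these sizes) and the run directory.
# Each numbered script can be run on its own; later scripts load the
# artifacts written by earlier ones from results/run/.

library(thetareg)

RUN_DIR <- file.path("results", "run")
dir.create(RUN_DIR, showWarnings = FALSE, recursive = TRUE)

MASTER_SEED <- 20240304L

analysis_sim_config <- function() {
  sim_config(
    n_per_group = 8L,        # desk-scale cohort (full study: 25 per group)
    n_blocks = 3L,
    trials_per_block = 12L,  # 36 trials, 12 per condition (full study: 150)
    sfreq = 100,             # ample for the 1-30 Hz analysis band
    seed = MASTER_SEED)
}

N_VOXELS <- 100              # source grid (full cortical mapping: 2839)
N_PERM <- 2000               # permutations (publication scale: 100000)

load_run <- function(name) {
  path <- file.path(RUN_DIR, paste0(name, ".rds"))
  if (!file.exists(path))
    stop("missing artifact '", name, "'; run the earlier scripts first")
  readRDS(path)
}

save_run <- function(object, name) {
  saveRDS(object, file.path(RUN_DIR, paste0(name, ".rds")))
}
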