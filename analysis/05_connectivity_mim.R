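# Functional connectivity: theta-band voxel-to-whole-brain MIM per
# participant and condition, the reappraise-minus-maintain contrast, and
# the voxel-wise group comparison (same permutation machinery as for source
# power).
#
# Writes: results/mim_voxel_table.csv, results/run/mim.rds

source(file.path("analysis", "00_common.R"))

cohort <- load_run("cohort_clean")
lf <- load_run("leadfield")
hm <- lf$head_model
grp <- cohort$participants$group

op <- eloreta_inverse(lf)
cat("Computing MIM maps (", hm$n_voxels, " voxels, ",
    hm$n_voxels * (hm$n_voxels - 1) / 2, " pairs per participant/condition)...\n",
    sep = "")
maps <- lapply(cohort$epochs, participant_mim_maps, op = op)

vnb <- voxel_neighbors(hm)
mt <- mim_contrast_and_test(maps[grp == "control"], maps[grp == "bpd"],
                            n_perm = N_PERM, seed = MASTER_SEED + 3,
                            neighbors = vnb, hm = hm)
save_run(list(maps = maps, test = mt$test), "mim")

tab <- data.frame(voxel = seq_len(hm$n_voxels),
                  x_mm = round(hm$voxel_mm[, 1], 1),
                  y_mm = round(hm$voxel_mm[, 2], 1),
                  z_mm = round(hm$voxel_mm[, 3], 1),
                  mim_contrast_diff = signif(mt$test$difference, 5),
                  p = mt$test$p_value, significant = mt$test$significant)
write.csv(tab, file.path("results", "mim_voxel_table.csv"), row.names = FALSE)

print(mt$test)
gt <- cohort$ground_truth
cat(sprintf("\nPlanted coupling pair (%d, %d): p = %.4f and %.4f\n",
            gt$effect_voxel, gt$partner_voxel,
            mt$test$p_value[gt$effect_voxel], mt$test$p_value[gt$partner_voxel]))
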