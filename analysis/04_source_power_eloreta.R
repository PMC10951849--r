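# Source-level analysis: eLORETA inverse solution, theta power of the
# regulation segment normalised by the pre-picture baseline (power ratio),
# reappraise-minus-maintain contrast per participant, and the voxel-wise
# permutation comparison between groups.
#
# Writes: results/source_voxel_table.csv, results/run/source.rds

source(file.path("analysis", "00_common.R"))

cohort <- load_run("cohort_clean")
lf <- load_run("leadfield")
hm <- lf$head_model
grp <- cohort$participants$group

op <- eloreta_inverse(lf)
cat("eLORETA operator:", op$convergence$iterations, "iterations, rel change",
    signif(op$convergence$rel_change, 3), "\n")

src <- t(vapply(cohort$epochs, function(ep)
  participant_source_contrast(ep, op)$contrast, numeric(hm$n_voxels)))

vnb <- voxel_neighbors(hm)
vt <- voxel_permutation_test(src[grp == "control", ], src[grp == "bpd", ],
                             n_perm = N_PERM, seed = MASTER_SEED + 2,
                             tails = "two", neighbors = vnb, hm = hm)
save_run(list(operator_convergence = op$convergence, contrasts = src,
              test = vt), "source")

tab <- data.frame(voxel = seq_len(hm$n_voxels),
                  x_mm = round(hm$voxel_mm[, 1], 1),
                  y_mm = round(hm$voxel_mm[, 2], 1),
                  z_mm = round(hm$voxel_mm[, 3], 1),
                  mean_contrast_diff = round(vt$difference, 5),
                  p = vt$p_value, significant = vt$significant)
write.csv(tab, file.path("results", "source_voxel_table.csv"),
          row.names = FALSE)

print(vt)
gt <- cohort$ground_truth
cat(sprintf("\nPlanted voxel %d: group difference %.3f, p = %.4f\n",
            gt$effect_voxel, vt$difference[gt$effect_voxel],
            vt$p_value[gt$effect_voxel]))
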