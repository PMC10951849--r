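# Behavioural statistics: mixed (split-plot) ANOVA of the emotion ratings
# (group x condition) with Bonferroni simple effects, the analogous ANOVA of
# the ERQ facets, and the multiple regression predicting the theta-cluster
# contrast in the BPD group from ERQ scores and rating differences.
#
# Writes: results/behaviour_report.txt, results/behaviour.json

source(file.path("analysis", "00_common.R"))

cohort <- load_run("cohort_clean")
sensor <- load_run("sensor")
beh <- cohort$participants

long_ratings <- data.frame(
  participant = rep(beh$participant_id, 2),
  group = rep(beh$group, 2),
  condition = rep(c("maintain", "reappraise"), each = nrow(beh)),
  value = c(beh$rating_maintain, beh$rating_reappraise))
av_ratings <- mixed_anova_2x2(long_ratings)

long_erq <- data.frame(
  participant = rep(beh$participant_id, 2),
  group = rep(beh$group, 2),
  condition = rep(c("reappraisal", "suppression"), each = nrow(beh)),
  value = c(beh$erq_reappraisal, beh$erq_suppression))
av_erq <- mixed_anova_2x2(long_erq)

# cluster-mean theta contrast for the BPD group, using the smallest-p
# sensor cluster (the planted-effect site when significant)
cl <- sensor$cluster$clusters
ch <- if (length(cl)) {
  cl[[which.min(vapply(cl, `[[`, numeric(1), "p_value"))]]$members
} else {
  seq_len(64)
}
theta_mean <- rowMeans(sensor$theta_summaries[, ch, drop = FALSE])
bpd <- beh$group == "bpd"
reg <- theta_regression(theta_mean[bpd], beh$erq_reappraisal[bpd],
                        beh$erq_suppression[bpd],
                        beh$rating_reappraise[bpd] - beh$rating_maintain[bpd])

rep_path <- file.path("results", "behaviour_report.txt")
sink(rep_path)
cat("Emotion ratings: mixed 2x2 ANOVA (group x condition)\n")
print(av_ratings)
cat("\nERQ facets: mixed 2x2 ANOVA (group x facet)\n")
print(av_erq)
cat("\nRegression: BPD theta cluster contrast ~ ERQ-R + ERQ-S + rating diff\n")
print(reg)
sink()
cat(readLines(rep_path), sep = "\n")

jsonlite::write_json(list(
  ratings_anova = av_ratings$table,
  ratings_simple_effects = av_ratings$simple_effects,
  erq_anova = av_erq$table,
  erq_simple_effects = av_erq$simple_effects,
  regression = list(F = reg$F, df1 = reg$df1, df2 = reg$df2, p = reg$p,
                    r_squared = reg$r_squared,
                    coefficients = reg$coefficients)),
  file.path("results", "behaviour.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
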