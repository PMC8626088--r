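# Stage 5: group-level statistics over the output profiles.
#
# Pearson correlation matrix between samples, per-region one-way ANOVA with
# Tukey HSD across the two groups, and average-linkage hierarchical
# clustering on correlation distance with multiscale bootstrap support
# (1000 replicates per scale).

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
run_stage("stats", cfg)

R <- as.matrix(read.csv(file.path(RESULTS_DIR, "correlation.csv"),
                        row.names = 1))
cat("Sample correlation matrix:\n")
print(round(R, 3))
at <- read.csv(file.path(RESULTS_DIR, "anova_tukey.csv"))
sig <- at$region[at$p < 0.05]
cat("Regions with p < 0.05 (one-way ANOVA):",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
cl <- jsonlite::fromJSON(file.path(RESULTS_DIR, "cluster.json"))
for (i in seq_along(cl$bp))
  cat(sprintf("  node {%s}: BP %.2f AU %.2f\n",
              paste(cl$node_sets[[i]], collapse = ","), cl$bp[i], cl$au[i]))
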