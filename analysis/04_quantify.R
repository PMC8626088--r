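# Stage 4: per-region connectivity quantification.
#
# Outputs: validated signal voxels per analysis region, normalized with the
# injection mask excluded from numerator and denominator. Inputs: somata
# detected in the retrograde volumes, region-assigned, injection-site somata
# excluded. Also writes the per-group output/input ratio table with the
# 0.25 / 4 reciprocity categories.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
run_stage("quantify", cfg)

prof <- read.csv(file.path(RESULTS_DIR, "profiles.csv"))
cat("Profiles written for", length(unique(prof$sample)), "samples;",
    "all sums:", paste(round(tapply(prof$proportion,
      interaction(prof$sample, prof$modality), sum), 6), collapse = " "), "\n")
for (g in c("g1", "g2")) {
  rr <- read.csv(file.path(RESULTS_DIR, paste0("ratio_", g, ".csv")))
  cat(sprintf("  %s ratio categories: %s\n", g,
              paste(names(table(rr$category)), table(rr$category),
                    collapse = " ", sep = "=")))
}
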