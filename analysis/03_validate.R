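# Stage 3: path validation of detected projection signal.
#
# The detection mask is pooled into 10 um signal-density cells; an eikonal
# arrival-time field is marched from the injection site (speed = density +
# 1e-3), every signal-bearing cell is back-tracked down the gradient, and
# cells that fail to reach the injection site, or whose path spends less
# than 80% of its points in foreground (density > 0.05) cells, are cleared.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
run_stage("validate", cfg)

sheet <- read.csv(file.path(RESULTS_DIR, "samples.csv"))
for (s in sheet$sample) {
  rep <- read.csv(file.path(RESULTS_DIR, paste0(s, "_validation_report.csv")))
  cat(sprintf("  %s: %d/%d signal cells removed (%d voxels cleared)\n",
              s, sum(rep$removed), nrow(rep), sum(rep$removed_voxels)))
}
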