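# Stage 1: generate the synthetic study data.
#
# Builds the toy atlas (ellipsoid brain, 6 Voronoi regions, central
# injection region), then for every sample simulates an anterograde volume
# (axon tubes toward group-specific target regions) and a retrograde volume
# (somata scattered per region), adds the background gradient and sensor
# noise, and writes volumes, injection masks, and ground truth.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
run_stage("simulate", cfg)

sheet <- read.csv(file.path(RESULTS_DIR, "samples.csv"))
cat("Simulated", nrow(sheet), "samples across",
    length(unique(sheet$group)), "groups into", RESULTS_DIR, "\n")
for (s in sheet$sample) {
  tr <- jsonlite::fromJSON(file.path(RESULTS_DIR, paste0(s, "_truth.json")))
  cat(sprintf("  %s planted output fractions: %s\n", s,
              paste(sprintf("%s=%.2f", names(tr), unlist(tr)), collapse = " ")))
}
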