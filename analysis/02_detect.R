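# Stage 2: per-coronal-section signal detection.
#
# Every volume is processed section by section: background estimation (min
# with the section median, ten 9x9 mean convolutions), subtraction, 5x5
# Gaussian filtering, Yen thresholding clipped to the study's predetermined
# range (floor 100 gray units), and binarization against
# max(4 x background, threshold).

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
run_stage("detect", cfg)

sheet <- read.csv(file.path(RESULTS_DIR, "samples.csv"))
for (s in sheet$sample) {
  thr <- read.csv(file.path(RESULTS_DIR, paste0(s, "_output_thresholds.csv")))
  m <- as_mask(read_volume(file.path(RESULTS_DIR, paste0(s, "_output_mask.nrrd"))))
  cat(sprintf("  %s: %d foreground voxels, clipped thresholds %.1f-%.1f\n",
              s, sum(m$data), min(thr$clipped), max(thr$clipped)))
}
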