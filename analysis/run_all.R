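# Runs the full workflow (stages 1-5) and writes the reproducibility
# manifest. Equivalent to sourcing 01..05 in order.
source(file.path("analysis", "00_config.R"))
manifest <- run_pipeline(study_config())
cat("Pipeline finished in", round(manifest$total_seconds, 1), "s;",
    length(manifest$artifacts), "artifacts under", RESULTS_DIR, "\n")
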