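# Shared configuration for the analysis workflow.
#
# The study: a synthetic two-group tracing experiment (two "neuron groups"
# with rotated projection-target preferences), two brains per group and per
# tracing direction, on a 60^3 voxel toy brain with 6 regions. Every
# downstream script is a thin driver over the package's pipeline stages and
# reads/writes results/run/.

library(tracemapr)

RESULTS_DIR <- file.path("results", "run")
ROOT_SEED <- 20260919L

study_config <- function() {
  pipeline_config(list(
    out_dir = RESULTS_DIR,
    seed = ROOT_SEED,
    shape = c(60L, 60L, 60L),
    n_regions = 6L,
    groups = list(g1 = NULL, g2 = NULL),  # rotated default target splits
    samples_per_group = 2L,
    sim = list(n_axons = 60L, somata_per_region = 4L, soma_radius = 2,
               terminal_mode = "region", shape = c(60L, 60L, 60L)),
    detection = list(yen_clip_min = 100),
    stats = list(n_boot = 1000L)))
}
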