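# Shared fixtures. Expensive synthetic-recovery runs are computed once per
# session and memoized here; every value is a pure function of the seeds
# fixed below.

fixture_cache <- new.env(parent = emptyenv())

# the synthetic study's predetermined Yen clip range: floor at half the
# nominal label amplitude (200), well above the background + noise ceiling
study_detection_params <- function() detection_params(yen_clip_min = 100)

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, expr, envir = fixture_cache)
  get(key, envir = fixture_cache)
}

small_atlas <- function() memo("small_atlas", make_toy_atlas(c(40, 40, 40), 4, seed = 7))

recovery_atlas <- function() memo("recovery_atlas",
                                  make_toy_atlas(c(100, 100, 100), 8, seed = 101))

# full output-side recovery for one seed: axons + isolated noise blobs ->
# detection -> path validation -> quantification, with ground truth
run_output_recovery <- function(seed, with_blobs = TRUE) {
  memo(paste0("outrec_", seed, "_", with_blobs), {
    atlas <- recovery_atlas()
    cfg <- simulation_config(seed = seed)
    ax <- simulate_axons(atlas, cfg)
    vol <- ax$volume
    blob_mask <- NULL
    if (with_blobs) {
      avoid <- ax$truth$planted_signal_mask
      avoid$data <- avoid$data | ax$truth$injection_mask$data
      nb <- plant_noise_blobs(vol, avoid, 100, seed = seed + 200L)
      vol <- nb$volume
      blob_mask <- nb$blob_mask
    }
    noisy <- add_background_and_noise(vol, cfg, seed + 50L)
    mask <- detect_volume(noisy, study_detection_params())
    val <- validate_signal(mask, ax$truth$injection_mask)
    prof <- quantify_outputs(val, atlas$annotation, atlas$table,
                             ax$truth$injection_mask)
    truth <- ax$truth$true_output_fraction
    est <- prof$proportion[match(as.integer(names(truth)), prof$region)]
    est <- est / sum(est)   # renormalize over non-injection regions
    planted <- ax$truth$planted_signal_mask$data
    list(atlas = atlas, cfg = cfg, truth = ax$truth, mask = mask, val = val,
         profile = prof, est = est, true_frac = truth,
         blob_mask = blob_mask,
         tube_retention = sum(val$data & planted) / sum(planted),
         noise_removed = if (with_blobs)
           1 - sum(val$data & blob_mask$data) / sum(mask$data & blob_mask$data)
         else NA_real_)
  })
}

# soma-side recovery for one seed: spheres -> detection -> soma extraction
run_input_recovery <- function(seed) {
  memo(paste0("inrec_", seed), {
    atlas <- recovery_atlas()
    cfg <- simulation_config(seed = seed, somata_per_region = 7L)
    so <- simulate_somata(atlas, cfg)
    noisy <- add_background_and_noise(so$volume, cfg, seed + 70L)
    mask <- detect_volume(noisy, study_detection_params())
    det <- detect_somata(noisy, mask)
    det <- assign_somata(det, atlas$annotation, atlas$table,
                         so$truth$injection_mask)
    truth_xy <- do.call(rbind, so$truth$soma_coordinates_um)
    matched <- match_coordinates(truth_xy,
                                 as.matrix(det[, c("x_um", "y_um", "z_um")]),
                                 radius = cfg$soma_radius)
    planted_counts <- vapply(so$truth$soma_coordinates_um, nrow, 1L)
    prof <- quantify_inputs(det, atlas$table)
    est <- prof$proportion[match(as.integer(names(planted_counts)),
                                 prof$region)]
    list(truth = so$truth, detected = det,
         recall = matched / nrow(truth_xy),
         precision = matched / nrow(det),
         planted_prop = planted_counts / sum(planted_counts),
         est_prop = est)
  })
}

# sample-by-region matrix with two planted clusters of profiles
two_cluster_matrix <- function(p = 200, within_sd = 0.3, seed = 5) {
  set.seed(seed)
  base1 <- rnorm(p); base2 <- rnorm(p)
  M <- rbind(t(sapply(1:4, function(i) base1 + rnorm(p, sd = within_sd))),
             t(sapply(1:4, function(i) base2 + rnorm(p, sd = within_sd))))
  rownames(M) <- paste0("s", 1:8)
  M
}

toy_region_df <- function() {
  data.frame(
    id = c(1L, 2L, 3L, 4L, 5L),
    acronym = c("ROOT", "A", "A1", "B", "C"),
    parent_id = c(NA, 1L, 2L, 1L, 1L),
    in_analysis_set = c(FALSE, TRUE, FALSE, TRUE, FALSE),
    is_injection_region = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}
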