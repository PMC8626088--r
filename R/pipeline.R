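## ---------------------------------------------------------------------------
## Config-driven end-to-end execution: synthetic generation -> detection ->
## path validation -> quantification -> statistics, with per-stage artifact
## files, parameter echo, and a reproducibility manifest. All randomness
## flows from one root seed, split deterministically per stage and sample.
## ---------------------------------------------------------------------------

#' Build and validate a pipeline configuration
#'
#' @param config a named list, or a path to a YAML/JSON file holding one.
#'   Fields (all but `out_dir` and `seed` optional):
#'   `out_dir`, `seed`, `shape`, `n_regions`, `groups` (named list: group
#'   label -> target-fraction vector named by region id, or `NULL` for the
#'   default split), `samples_per_group`, `sim` (overrides for
#'   [simulation_config()]), `detection` (arguments of
#'   [detection_params()]), `validation` (arguments of
#'   [validation_params()]), `stats` (`n_boot`, `scales`, `alpha`).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(sub(".*\\.", "", config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::fromJSON(config, simplifyVector = TRUE),
      stop("pipeline_config: expected a .yaml/.yml/.json path"))
  }
  defaults <- list(shape = c(60L, 60L, 60L), n_regions = 6L,
                   groups = list(g1 = NULL, g2 = NULL),
                   samples_per_group = 2L, sim = list(),
                   detection = list(), validation = list(),
                   stats = list(n_boot = 200L, scales = seq(0.5, 1.4, 0.1),
                                alpha = 0.05))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$out_dir)) stop("pipeline_config: out_dir is required")
  stochastic <- TRUE  # simulation and bootstrap stages are stochastic
  if (stochastic && is.null(config$seed))
    stop("pipeline_config: seed is required (stochastic stages configured)")
  config$seed <- as.integer(config$seed)
  config$stats <- utils::modifyList(defaults$stats, as.list(config$stats))
  # parameter objects validate their own invariants now, not mid-run
  do.call(detection_params, config$detection)
  do.call(validation_params, config$validation)
  structure(config, class = "pipeline_config")
}

#' Demo pipeline configuration
#'
#' A small two-group, two-samples-per-group synthetic study (60^3 voxel toy
#' brain, 6 regions) that exercises every stage in about a minute.
#'
#' @param out_dir output directory.
#' @param seed root seed.
#' @return a `pipeline_config`.
#' @export
demo_pipeline_config <- function(out_dir, seed = 1L) {
  pipeline_config(list(
    out_dir = out_dir, seed = seed,
    shape = c(60L, 60L, 60L), n_regions = 6L,
    groups = list(g1 = NULL, g2 = NULL),
    samples_per_group = 2L,
    sim = list(n_axons = 60L, somata_per_region = 4L, soma_radius = 2,
               terminal_mode = "region", shape = c(60L, 60L, 60L)),
    detection = list(yen_clip_min = 100),
    stats = list(n_boot = 200L)))
}

sample_sheet <- function(config) {
  groups <- names(config$groups)
  do.call(rbind, lapply(seq_along(groups), function(gi) {
    data.frame(sample = sprintf("%s_s%d", groups[gi],
                                seq_len(config$samples_per_group)),
               group = groups[gi],
               idx = (gi - 1) * config$samples_per_group +
                     seq_len(config$samples_per_group),
               stringsAsFactors = FALSE)
  }))
}

## group-specific default target fractions: rotate the default split so
## groups differ in their projection pattern
group_fractions <- function(config, table, gi) {
  fr <- config$groups[[gi]]
  if (!is.null(fr)) {
    v <- as.numeric(fr)
    names(v) <- names(fr)
    return(v / sum(v))
  }
  base <- default_target_fractions(table)
  k <- (gi - 1) %% length(base)
  stats::setNames(base[((seq_along(base) - 1 + k) %% length(base)) + 1],
                  names(base))
}

art <- function(config, ...) file.path(config$out_dir, paste0(...))

require_artifacts <- function(config, files, producer) {
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("run_stage: missing upstream artifact(s) ",
         paste(basename(missing), collapse = ", "),
         "; run stage '", producer, "' first")
  invisible(TRUE)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

stage_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- make_toy_atlas(config$shape, config$n_regions,
                          seed = config$seed + 11L)
  write_volume(atlas$annotation, art(config, "annotation.nrrd"))
  write_region_table(atlas$table, art(config, "regions.csv"))
  sheet <- sample_sheet(config)
  utils::write.csv(sheet, art(config, "samples.csv"), row.names = FALSE)
  groups <- names(config$groups)
  log_stage("simulate", "atlas ", paste(config$shape, collapse = "x"),
            ", ", config$n_regions, " regions, ",
            nrow(sheet), " samples")
  for (i in seq_len(nrow(sheet))) {
    gi <- match(sheet$group[i], groups)
    fr <- group_fractions(config, atlas$table, gi)
    sim <- do.call(simulation_config, utils::modifyList(
      list(shape = config$shape, target_fractions = fr,
           seed = config$seed + 97L * sheet$idx[i]),
      config$sim[setdiff(names(config$sim), c("shape", "target_fractions",
                                              "seed"))]))
    sim$shape <- config$shape
    ax <- simulate_axons(atlas, sim)
    so <- simulate_somata(atlas, sim)
    axv <- add_background_and_noise(ax$volume, sim, sim$seed + 1L)
    sov <- add_background_and_noise(so$volume, sim, sim$seed + 2L)
    s <- sheet$sample[i]
    write_volume(axv, art(config, s, "_output_vol.nrrd"), dtype = "double")
    write_volume(sov, art(config, s, "_input_vol.nrrd"), dtype = "double")
    write_volume(ax$truth$injection_mask, art(config, s, "_injection.nrrd"))
    jsonlite::write_json(as.list(ax$truth$true_output_fraction),
                         art(config, s, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    truth_somata <- do.call(rbind, lapply(names(so$truth$soma_coordinates_um),
      function(id) {
        m <- so$truth$soma_coordinates_um[[id]]
        data.frame(region = as.integer(id), x_um = m[, 1], y_um = m[, 2],
                   z_um = m[, 3])
      }))
    utils::write.csv(truth_somata, art(config, s, "_truth_somata.csv"),
                     row.names = FALSE)
  }
  invisible(TRUE)
}

stage_detect <- function(config) {
  sheet_file <- art(config, "samples.csv")
  require_artifacts(config, sheet_file, "simulate")
  sheet <- utils::read.csv(sheet_file, stringsAsFactors = FALSE)
  dp <- do.call(detection_params, config$detection)
  log_stage("detect", "params: kernel ", dp$background_kernel, "x",
            dp$background_kernel, " x", dp$background_iterations,
            ", gaussian ", dp$gaussian_kernel, " sigma ", dp$gaussian_sigma,
            ", multiplier ", dp$background_multiplier)
  for (s in sheet$sample) {
    require_artifacts(config, art(config, s, "_output_vol.nrrd"), "simulate")
    for (mod in c("output", "input")) {
      vol <- read_volume(art(config, s, "_", mod, "_vol.nrrd"))
      mask <- detect_volume(vol, dp)
      write_volume(mask, art(config, s, "_", mod, "_mask.nrrd"))
      utils::write.csv(attr(mask, "thresholds"),
                       art(config, s, "_", mod, "_thresholds.csv"),
                       row.names = FALSE)
    }
  }
  invisible(TRUE)
}

stage_validate <- function(config) {
  sheet_file <- art(config, "samples.csv")
  require_artifacts(config, sheet_file, "simulate")
  sheet <- utils::read.csv(sheet_file, stringsAsFactors = FALSE)
  vp <- do.call(validation_params, config$validation)
  log_stage("validate", "density threshold ",
            vp$foreground_density_threshold, ", confidence cutoff ",
            vp$confidence_cutoff, ", speed floor ", vp$speed_floor)
  for (s in sheet$sample) {
    require_artifacts(config, art(config, s, "_output_mask.nrrd"), "detect")
    mask <- as_mask(read_volume(art(config, s, "_output_mask.nrrd")))
    inj <- as_mask(read_volume(art(config, s, "_injection.nrrd")))
    val <- validate_signal(mask, inj, vp)
    write_volume(val, art(config, s, "_output_valid.nrrd"))
    utils::write.csv(attr(val, "report"),
                     art(config, s, "_validation_report.csv"),
                     row.names = FALSE)
  }
  invisible(TRUE)
}

stage_quantify <- function(config) {
  sheet_file <- art(config, "samples.csv")
  require_artifacts(config, sheet_file, "simulate")
  sheet <- utils::read.csv(sheet_file, stringsAsFactors = FALSE)
  ann <- read_volume(art(config, "annotation.nrrd"))
  tab <- load_region_table(art(config, "regions.csv"))
  out_profiles <- list()
  in_profiles <- list()
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$sample[i]
    require_artifacts(config, art(config, s, "_output_valid.nrrd"), "validate")
    val <- as_mask(read_volume(art(config, s, "_output_valid.nrrd")))
    inj <- as_mask(read_volume(art(config, s, "_injection.nrrd")))
    out_profiles[[s]] <- quantify_outputs(val, ann, tab, inj,
                                          sample = s, group = sheet$group[i])
    imask <- as_mask(read_volume(art(config, s, "_input_mask.nrrd")))
    ivol <- read_volume(art(config, s, "_input_vol.nrrd"))
    somata <- detect_somata(ivol, imask)
    somata <- assign_somata(somata, ann, tab, inj)
    write_soma_csv(somata, art(config, s, "_somata.csv"))
    in_profiles[[s]] <- quantify_inputs(somata, tab, sample = s,
                                        group = sheet$group[i])
  }
  write_profiles_csv(c(out_profiles, in_profiles),
                     art(config, "profiles.csv"))
  # per-group mean ratio table
  for (g in unique(sheet$group)) {
    sel <- sheet$sample[sheet$group == g]
    om <- Reduce(`+`, lapply(out_profiles[sel], `[[`, "proportion")) / length(sel)
    im <- Reduce(`+`, lapply(in_profiles[sel], `[[`, "proportion")) / length(sel)
    op <- out_profiles[[sel[1]]]; op$proportion <- om
    ip <- in_profiles[[sel[1]]];  ip$proportion <- im
    utils::write.csv(output_input_ratio(op, ip),
                     art(config, "ratio_", g, ".csv"), row.names = FALSE)
  }
  log_stage("quantify", nrow(sheet), " samples quantified")
  invisible(TRUE)
}

stage_stats <- function(config) {
  require_artifacts(config, art(config, "profiles.csv"), "quantify")
  prof <- utils::read.csv(art(config, "profiles.csv"),
                          stringsAsFactors = FALSE)
  sheet <- utils::read.csv(art(config, "samples.csv"),
                           stringsAsFactors = FALSE)
  mk <- function(modality) {
    lapply(sheet$sample, function(s) {
      df <- prof[prof$sample == s & prof$modality == modality, ]
      class(df) <- c("connectivity_profile", "data.frame")
      df
    })
  }
  M <- group_matrix(mk("output"))
  utils::write.csv(correlation_matrix(M), art(config, "correlation.csv"))
  utils::write.csv(anova_tukey_table(M, alpha = config$stats$alpha),
                   art(config, "anova_tukey.csv"), row.names = FALSE)
  tree <- bootstrap_support(M, n_boot = config$stats$n_boot,
                            scales = config$stats$scales,
                            seed = config$seed + 7919L)
  write_cluster_json(tree, art(config, "cluster.json"))
  log_stage("stats", "n_boot ", config$stats$n_boot, ", ",
            nrow(M), " samples x ", ncol(M), " regions")
  invisible(TRUE)
}

pipeline_stages <- c("simulate", "detect", "validate", "quantify", "stats")

#' Run one pipeline stage
#'
#' @param stage one of `"simulate"`, `"detect"`, `"validate"`,
#'   `"quantify"`, `"stats"`.
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @return `TRUE` invisibly; artifacts appear under `config$out_dir`.
#' @export
run_stage <- function(stage, config) {
  config <- if (inherits(config, "pipeline_config")) config
            else pipeline_config(config)
  stage <- match.arg(stage, pipeline_stages)
  switch(stage,
         simulate = stage_simulate(config),
         detect = stage_detect(config),
         validate = stage_validate(config),
         quantify = stage_quantify(config),
         stats = stage_stats(config))
}

#' Run the full pipeline
#'
#' Executes simulate, detect, validate, quantify, and stats in order and
#' writes `manifest.json` (inputs, parameter echo, package version,
#' per-artifact MD5 checksums, wall-clock). Re-running with an identical
#' config reproduces identical CSV outputs.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- if (inherits(config, "pipeline_config")) config
            else pipeline_config(config)
  t0 <- Sys.time()
  timings <- list()
  for (stage in pipeline_stages) {
    ts <- Sys.time()
    tryCatch(run_stage(stage, config),
             error = function(e)
               stop("pipeline failed at stage '", stage, "': ",
                    conditionMessage(e), call. = FALSE))
    timings[[stage]] <- as.numeric(difftime(Sys.time(), ts, units = "secs"))
  }
  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("tracemapr")),
    config = unclass(config),
    seed = config$seed,
    artifacts = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))),
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, art(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
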