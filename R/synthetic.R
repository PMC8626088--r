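## ---------------------------------------------------------------------------
## Synthetic data: toy atlases and labeled volumes with planted ground truth.
## Emulates, at desk scale, what the real pipeline consumes: an annotation
## volume registered to the intensity data, tubular axon tracts leaving an
## injection site (anterograde labeling), spherical somata scattered per
## region (retrograde labeling), a smooth additive background, and Gaussian
## sensor noise.
## ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration with study-condition defaults
#'
#' Defaults define the synthetic study conditions used throughout the tests:
#' a 100^3 voxel brain at 1 um isotropic with 8 regions, 200 axons of tube
#' radius 3 voxels and tortuosity 0.15, signal amplitude 200 gray units over
#' a background gradient of amplitude 20 and Gaussian noise sigma 10
#' (signal-to-noise ratio 20), somata of radius 3 voxels placed at least
#' 3 radii apart, and a spherical injection mask of radius 6 um.
#'
#' @param ... overrides for any default field.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    shape = c(100L, 100L, 100L),
    voxel_size_um = c(1, 1, 1),
    n_regions = 8L,
    target_fractions = NULL,     # named by region id; NULL = default split
    axon_radius = 3,             # voxels
    tortuosity = 0.15,           # step-direction jitter in [0, 1]
    n_axons = 200L,
    axon_step = 1.5,             # voxels per walk step
    terminal_mode = "centroid",  # "centroid": compact bundles; "region":
                                 # terminals drawn uniformly in the target
    somata_per_region = 6L,      # scalar or named by region id
    soma_radius = 3,             # voxels
    soma_separation_factor = 3,  # min center distance = factor * radius
    background_gradient = 20,    # gray units across one section
    noise_sigma = 10,            # gray units
    signal_amplitude = 200,      # gray units
    injection_radius_um = 6,
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("simulation_config: unknown field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  if (any(c(cfg$axon_radius, cfg$soma_radius) < 1))
    stop("simulation_config: radii must be >= 1 voxel")
  if (!is.null(cfg$target_fractions) && any(cfg$target_fractions < 0))
    stop("simulation_config: target fractions must be non-negative")
  if (cfg$tortuosity < 0 || cfg$tortuosity > 1)
    stop("simulation_config: tortuosity must be in [0, 1]")
  if (cfg$noise_sigma < 0) stop("simulation_config: noise_sigma must be >= 0")
  structure(cfg, class = "simulation_config")
}

#' Generate a toy brain atlas
#'
#' The brain is an ellipsoid (semi-axes 0.45 of each extent) of nonzero
#' labels inside the given shape; its interior is partitioned into
#' `n_regions` contiguous cells by seeded Voronoi sites chosen by
#' farthest-point sampling (Voronoi cells of a convex body are convex, hence
#' connected, and farthest-point sites give comparably sized regions). The region whose site lies
#' nearest the brain centroid is flagged as the injection region; all
#' regions are flagged for analysis. Label 0 fills the outside.
#'
#' @param shape three integers >= 20.
#' @param n_regions integer >= 2.
#' @param seed RNG seed; the same seed reproduces the identical atlas.
#' @param voxel_size_um voxel size (default 1 um isotropic).
#' @return list with `annotation` ([volume3d()] of integer labels) and
#'   `table` (a [region_table()]).
#' @export
make_toy_atlas <- function(shape, n_regions, seed, voxel_size_um = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 20))
    stop("make_toy_atlas: shape must be 3 integers >= 20")
  if (n_regions < 2) stop("make_toy_atlas: n_regions must be >= 2")
  ctr <- (shape - 1) / 2
  semi <- 0.45 * shape
  d1 <- ((seq_len(shape[1]) - 1 - ctr[1]) / semi[1])^2
  d2 <- ((seq_len(shape[2]) - 1 - ctr[2]) / semi[2])^2
  d3 <- ((seq_len(shape[3]) - 1 - ctr[3]) / semi[3])^2
  rad2 <- outer(outer(d1, d2, "+"), d3, "+")
  inside <- rad2 <= 1
  nin <- sum(inside)
  if (n_regions > nin)
    stop("make_toy_atlas: n_regions exceeds interior voxel count")
  idx <- which(inside)
  coords <- arrayInd(idx, shape) - 1L   # 0-based voxel indices
  # farthest-point site selection over a seeded candidate pool: regions come
  # out comparably sized and chunky, so every region can host somata
  sites <- with_seed(seed, {
    ncand <- min(nin, max(256L, 32L * n_regions))
    cand <- coords[sample.int(nin, ncand), , drop = FALSE]
    d2ctr <- rowSums(sweep(cand, 2, ctr, "-")^2)
    chosen <- which.min(d2ctr)          # first site: center of the brain
    mind2 <- rowSums(sweep(cand, 2, cand[chosen, ], "-")^2)
    while (length(chosen) < n_regions) {
      nxt <- which.max(mind2)
      chosen <- c(chosen, nxt)
      mind2 <- pmin(mind2, rowSums(sweep(cand, 2, cand[nxt, ], "-")^2))
    }
    cand[chosen, , drop = FALSE]
  })
  best <- rep(Inf, nin)
  lab <- integer(nin)
  for (r in seq_len(n_regions)) {
    d2r <- (coords[, 1] - sites[r, 1])^2 + (coords[, 2] - sites[r, 2])^2 +
           (coords[, 3] - sites[r, 3])^2
    take <- d2r < best
    best[take] <- d2r[take]
    lab[take] <- r
  }
  labels <- array(0L, dim = shape)
  labels[idx] <- lab
  site_to_ctr <- rowSums(sweep(sites, 2, ctr, "-")^2)
  inj <- which.min(site_to_ctr)
  tab <- region_table(data.frame(
    id = seq_len(n_regions),
    acronym = sprintf("R%02d", seq_len(n_regions)),
    parent_id = NA_integer_,
    in_analysis_set = TRUE,
    is_injection_region = seq_len(n_regions) == inj,
    stringsAsFactors = FALSE))
  list(annotation = volume3d(labels, voxel_size_um = voxel_size_um),
       table = tab)
}

region_centroid_vox <- function(annotation, id) {
  idx <- which(annotation$data == id)
  colMeans(arrayInd(idx, dim(annotation$data)) - 1L)
}

injection_region_id <- function(table) {
  id <- table$regions$id[table$regions$is_injection_region]
  if (length(id) != 1) stop("atlas must flag exactly one injection region")
  id
}

make_injection_mask <- function(annotation, center_vox, radius_um) {
  s <- annotation$voxel_size_um
  shape <- dim(annotation$data)
  r_vox <- radius_um / s
  box <- lapply(1:3, function(a)
    max(0, floor(center_vox[a] - r_vox[a])):min(shape[a] - 1, ceiling(center_vox[a] + r_vox[a])))
  g <- as.matrix(expand.grid(box[[1]], box[[2]], box[[3]]))
  d2 <- ((g[, 1] - center_vox[1]) / r_vox[1])^2 +
        ((g[, 2] - center_vox[2]) / r_vox[2])^2 +
        ((g[, 3] - center_vox[3]) / r_vox[3])^2
  m <- array(FALSE, dim = shape)
  m[g[d2 <= 1, , drop = FALSE] + 1L] <- TRUE
  volume3d(m, voxel_size_um = s, origin_um = annotation$origin_um)
}

default_target_fractions <- function(table) {
  inj <- injection_region_id(table)
  ids <- setdiff(sort(table$regions$id), inj)
  take <- ids[seq_len(min(4, length(ids)))]
  fr <- c(0.4, 0.3, 0.2, 0.1)[seq_along(take)]
  stats::setNames(fr / sum(fr), take)
}

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Simulate anterogradely labeled axon tracts
#'
#' Each axon is a biased random walk from the injection-region centroid
#' toward a terminal point drawn uniformly inside a target region sampled
#' proportional to the configured target fractions; the per-step direction
#' mixes the homing direction with an isotropic random unit vector with
#' weight `tortuosity`. Walks are rasterized as tubes of the configured
#' radius at the signal amplitude.
#'
#' Ground-truth output fractions are recomputed from the planted tube voxels
#' per region, excluding the injection region and non-annotated space, and
#' renormalized; this is the quantity the detection + validation +
#' quantification chain is later asked to recover.
#'
#' @param atlas list with `annotation` and `table` (see [make_toy_atlas()]).
#' @param config a [simulation_config()].
#' @return list with `volume` (signal-only [volume3d()], background-free)
#'   and `truth` (fields `true_output_fraction`, `injection_mask`,
#'   `planted_signal_mask`, `polylines`, `seed`).
#' @export
simulate_axons <- function(atlas, config) {
  ann <- atlas$annotation
  tab <- atlas$table
  shape <- dim(ann$data)
  inj <- injection_region_id(tab)
  fr <- config$target_fractions
  if (is.null(fr)) fr <- default_target_fractions(tab)
  fr <- fr / sum(fr)
  targets <- as.integer(names(fr))
  if (!length(setdiff(targets, inj)))
    stop("simulate_axons: target fractions must cover a non-injection region")
  # "centroid" terminals collapse each region's axons into one compact
  # bundle (sparse corridor network); "region" terminals are drawn
  # uniformly inside the target region, so axons fan out and deposited
  # tube volume stays roughly proportional to axon count
  region_vox <- lapply(stats::setNames(targets, targets), function(id)
    which(ann$data == id))
  cen <- lapply(stats::setNames(targets, targets),
                function(id) region_centroid_vox(ann, id))
  start <- region_centroid_vox(ann, inj)
  step <- config$axon_step
  budget <- as.integer(4 * sum(shape) / step)

  polys <- with_seed(config$seed, {
    pick <- targets[sample.int(length(targets), config$n_axons,
                                 replace = TRUE, prob = fr)]
    out <- vector("list", config$n_axons)
    for (a in seq_len(config$n_axons)) {
      if (identical(config$terminal_mode, "region")) {
        vx <- region_vox[[as.character(pick[a])]]
        tgt <- as.numeric(arrayInd(vx[sample.int(length(vx), 1L)], shape)) - 1
      } else {
        tgt <- cen[[as.character(pick[a])]]
      }
      p <- start
      pts <- matrix(p, ncol = 3)
      for (s in seq_len(budget)) {
        base <- tgt - p
        nb <- sqrt(sum(base^2))
        if (nb < 2) break
        base <- base / nb
        u <- random_unit_vectors(1)[1, ]
        dirv <- (1 - config$tortuosity) * base + config$tortuosity * u
        dirv <- dirv / sqrt(sum(dirv^2))
        p2 <- p + step * dirv
        if (any(p2 < 0) || any(p2 > shape - 1)) break
        p <- p2
        pts <- rbind(pts, p)
      }
      out[[a]] <- pts
    }
    out
  })

  sep <- matrix(NA_real_, 1, 3)
  allpts <- do.call(rbind, lapply(polys, function(p) rbind(p, sep)))
  tube <- cpp_rasterize_tube(array(0, dim = shape), shape, allpts,
                             config$axon_radius, 1)
  planted <- tube > 0
  vol <- tube * config$signal_amplitude
  inj_mask <- make_injection_mask(ann, start, config$injection_radius_um)

  lab <- collapse_to_analysis(ann$data[planted], tab)
  keep <- lab != inj & lab != NON_ANNOTATED_ID & lab != OTHERS_ID
  if (!any(keep))
    stop("simulate_axons: no tube voxel left the injection region within budget")
  counts <- table(factor(lab[keep], levels = sort(setdiff(
    analysis_region_ids(tab, sentinels = FALSE), inj))))
  frac <- as.numeric(counts) / sum(counts)
  names(frac) <- names(counts)

  truth <- list(
    true_output_fraction = frac,
    injection_region = inj,
    injection_mask = inj_mask,
    planted_signal_mask = volume3d(planted, voxel_size_um = ann$voxel_size_um,
                                   origin_um = ann$origin_um),
    polylines = polys,
    seed = config$seed)
  list(volume = volume3d(vol, voxel_size_um = ann$voxel_size_um,
                         origin_um = ann$origin_um),
       truth = truth)
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Simulate retrogradely labeled input-neuron somata
#'
#' Spheres of the configured radius and amplitude are placed uniformly at
#' random inside each requested region, rejecting candidates whose sphere
#' would cross the region boundary or whose center comes closer than
#' `soma_separation_factor * soma_radius` to an accepted soma.
#'
#' @param atlas list with `annotation` and `table`.
#' @param config a [simulation_config()]; `somata_per_region` is a scalar
#'   (applied to every non-injection analysis region) or a vector named by
#'   region id.
#' @return list with `volume` (signal-only [volume3d()]) and `truth`
#'   (fields `soma_coordinates_um` — named list of n x 3 matrices per region
#'   — `injection_mask`, `planted_signal_mask`, `seed`).
#' @export
simulate_somata <- function(atlas, config) {
  ann <- atlas$annotation
  tab <- atlas$table
  shape <- dim(ann$data)
  inj <- injection_region_id(tab)
  req <- config$somata_per_region
  if (is.null(names(req))) {
    ids <- setdiff(sort(analysis_region_ids(tab, sentinels = FALSE)), inj)
    req <- stats::setNames(rep(as.integer(req), length(ids)), ids)
  }
  req <- req[req > 0]
  r <- config$soma_radius
  min_sep <- config$soma_separation_factor * r
  guard <- ball_offsets(r + 1)
  fill <- ball_offsets(r)

  vol <- array(0, dim = shape)
  accepted <- matrix(numeric(0), ncol = 3)
  coords <- list()
  with_seed(config$seed + 1L, {
    for (id in names(req)) {
      rid <- as.integer(id)
      cand <- which(ann$data == rid)
      if (!length(cand)) stop("simulate_somata: region ", id, " is empty")
      got <- matrix(numeric(0), ncol = 3)
      for (k in seq_len(req[[id]])) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
          c0 <- arrayInd(sample(cand, 1L), shape) - 1L
          pts <- sweep(guard, 2, as.numeric(c0), "+")
          if (any(pts < 0) || any(sweep(pts, 2, shape - 1, ">"))) next
          if (!all(ann$data[pts + 1L] == rid)) next
          if (nrow(accepted) &&
              min(sqrt(rowSums(sweep(accepted, 2, as.numeric(c0), "-")^2))) < min_sep)
            next
          ok <- TRUE
          break
        }
        if (!ok)
          stop("simulate_somata: could not place soma ", k, " in region ", id,
               " (capacity exceeded)")
        accepted <- rbind(accepted, as.numeric(c0))
        got <- rbind(got, as.numeric(c0))
        vox <- sweep(fill, 2, as.numeric(c0), "+")
        vox <- vox[!(rowSums(vox < 0) > 0) &
                   !(rowSums(sweep(vox, 2, shape - 1, ">")) > 0), , drop = FALSE]
        vol[vox + 1L] <- config$signal_amplitude
      }
      coords[[id]] <- got
    }
  })

  volv <- volume3d(vol, voxel_size_um = ann$voxel_size_um,
                   origin_um = ann$origin_um)
  coords_um <- lapply(coords, function(m) voxel_center_um(volv, m))
  start <- region_centroid_vox(ann, inj)
  truth <- list(
    soma_coordinates_um = coords_um,
    injection_region = inj,
    injection_mask = make_injection_mask(ann, start, config$injection_radius_um),
    planted_signal_mask = volume3d(vol > 0, voxel_size_um = ann$voxel_size_um,
                                   origin_um = ann$origin_um),
    seed = config$seed)
  list(volume = volv, truth = truth)
}

#' Add smooth background and sensor noise to a signal volume
#'
#' Adds a per-section linear gradient of the configured amplitude along the
#' left-right axis plus i.i.d. Gaussian noise, clipped at zero. Deterministic
#' given the seed.
#'
#' @param volume a [volume3d()] (typically the signal-only output of
#'   [simulate_axons()] or [simulate_somata()]).
#' @param config a [simulation_config()] (`background_gradient`,
#'   `noise_sigma`).
#' @param seed RNG seed for the noise field.
#' @return a [volume3d()] with background and noise added.
#' @export
add_background_and_noise <- function(volume, config, seed) {
  d <- dim(volume$data)
  g <- config$background_gradient
  grad <- if (d[3] > 1) g * (seq_len(d[3]) - 1) / (d[3] - 1) else rep(0, d[3])
  out <- volume$data + rep(grad, each = d[1] * d[2])
  if (config$noise_sigma > 0)
    out <- out + with_seed(seed, array(stats::rnorm(prod(d), 0, config$noise_sigma), dim = d))
  out[out < 0] <- 0
  volume3d(array(out, dim = d), voxel_size_um = volume$voxel_size_um,
           origin_um = volume$origin_um)
}

#' Plant isolated noise blobs into a signal volume
#'
#' Scatters small bright spheres ("confusing noise") across the brain,
#' keeping every blob at least `clearance_vox` voxels (Chebyshev) away from
#' existing signal and from other blobs so blobs stay isolated at the
#' density-grid scale instead of forming chains of foreground cells.
#'
#' @param volume signal-only [volume3d()] (e.g. from [simulate_axons()]).
#' @param avoid_mask logical [volume3d()] of voxels blobs must keep clear
#'   of (planted signal plus injection site).
#' @param n number of blobs requested.
#' @param radius blob radius in voxels (default 1.2, small enough that
#'   a detection-dilated blob cannot make its cell foreground).
#' @param amplitude blob brightness (defaults to the volume's max).
#' @param clearance_vox minimum Chebyshev distance to existing signal
#'   (default 12, i.e. beyond the adjacent 10 um cell).
#' @param blob_clearance_vox minimum Chebyshev distance between blobs
#'   (default 10: guarantees distinct density-grid cells).
#' @param seed RNG seed.
#' @return list with `volume` (blobs added) and `blob_mask` (logical
#'   [volume3d()] of planted blob voxels); fewer than `n` blobs are placed
#'   (with a warning) if space runs out.
#' @export
plant_noise_blobs <- function(volume, avoid_mask, n, radius = 1.2,
                              amplitude = NULL, clearance_vox = 12L,
                              blob_clearance_vox = 10L, seed = 1L) {
  shape <- dim(volume$data)
  if (is.null(amplitude)) amplitude <- max(volume$data)
  fill <- ball_offsets(radius)
  blob <- array(FALSE, dim = shape)
  occupied <- avoid_mask$data
  lo <- clearance_vox + 2L
  placed <- 0L
  with_seed(seed, {
    cand_order <- sample.int(200000L)
    tries <- 0L
    while (placed < n && tries < length(cand_order)) {
      tries <- tries + 1L
      c0 <- floor(stats::runif(3, lo, shape - lo))
      g <- clearance_vox
      if (any(occupied[(c0[1] - g):(c0[1] + g) + 1L,
                       (c0[2] - g):(c0[2] + g) + 1L,
                       (c0[3] - g):(c0[3] + g) + 1L])) next
      b <- blob_clearance_vox
      if (any(blob[(c0[1] - b):(c0[1] + b) + 1L,
                   (c0[2] - b):(c0[2] + b) + 1L,
                   (c0[3] - b):(c0[3] + b) + 1L])) next
      vox <- sweep(fill, 2, c0, "+")
      blob[vox + 1L] <- TRUE
      placed <- placed + 1L
    }
  })
  if (placed < n)
    warning("plant_noise_blobs: placed only ", placed, " of ", n, " blobs")
  out <- volume
  out$data[blob] <- amplitude
  list(volume = out,
       blob_mask = volume3d(blob, voxel_size_um = volume$voxel_size_um,
                            origin_um = volume$origin_um))
}
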