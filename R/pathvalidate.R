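## ---------------------------------------------------------------------------
## Connectivity validation of detected signal: the detection mask is coarsed
## to a signal-density grid (default 10 um cells), an eikonal arrival-time
## field is marched from the injection site with speed increasing in signal
## density, every signal-bearing cell is back-tracked down the arrival-time
## gradient, and cells whose path misses the injection site or spends too
## little of its length in dense-signal cells are cleared as unconnected
## noise.
## ---------------------------------------------------------------------------

#' Validation parameters
#'
#' @param foreground_density_threshold a grid cell is "foreground" when its
#'   signal density exceeds this (default 0.05).
#' @param confidence_cutoff minimum fraction of back-track points in
#'   foreground cells for a cell's signal to be retained (default 0.8).
#' @param speed_floor additive floor epsilon of the speed law
#'   `F = density + epsilon`, keeping empty space traversable (default 1e-3).
#' @param step_size back-tracking step in grid cells (default 0.5).
#' @param max_steps back-track step budget; default 10x the grid diagonal.
#' @param cell_size_um density-grid cell size (default 10 um isotropic).
#' @return a `validation_params` list.
#' @export
validation_params <- function(foreground_density_threshold = 0.05,
                              confidence_cutoff = 0.8,
                              speed_floor = 1e-3,
                              step_size = 0.5,
                              max_steps = NULL,
                              cell_size_um = c(10, 10, 10)) {
  if (foreground_density_threshold <= 0 || foreground_density_threshold >= 1)
    stop("validation_params: foreground_density_threshold must be in (0,1)")
  if (confidence_cutoff <= 0 || confidence_cutoff > 1)
    stop("validation_params: confidence_cutoff must be in (0,1]")
  if (speed_floor <= 0) stop("validation_params: speed_floor must be > 0")
  structure(list(foreground_density_threshold = foreground_density_threshold,
                 confidence_cutoff = confidence_cutoff,
                 speed_floor = speed_floor,
                 step_size = step_size,
                 max_steps = max_steps,
                 cell_size_um = cell_size_um),
            class = "validation_params")
}

voxel_cell_index <- function(shape, m) {
  ## 0-based density-grid cell id for every voxel, in array order
  g <- ceiling(shape / m)
  ci1 <- (seq_len(shape[1]) - 1L) %/% m[1]
  ci2 <- (seq_len(shape[2]) - 1L) %/% m[2]
  ci3 <- (seq_len(shape[3]) - 1L) %/% m[3]
  a1 <- rep(ci1, times = shape[2] * shape[3])
  a2 <- rep(rep(ci2, each = shape[1]), times = shape[3])
  a3 <- rep(ci3, each = shape[1] * shape[2])
  list(cell = a1 + g[1] * (a2 + g[2] * a3), gdim = as.integer(g))
}

#' Signal-density grid of a binary mask
#'
#' Density of a cell = detected voxels in the cell / total voxels in the
#' cell; boundary cells use their actual (possibly smaller) voxel count.
#' The cell size must be a whole number of voxels per axis.
#'
#' @param mask logical [volume3d()].
#' @param cell_size_um length-3 cell size in micrometres (default 10).
#' @return a `density_grid`: fields `density` (3D array in \[0,1\]),
#'   `cell_size_um`, `cells_per_axis`, `voxel_geometry`.
#' @export
compute_density_grid <- function(mask, cell_size_um = c(10, 10, 10)) {
  stopifnot(is_volume3d(mask), is.logical(mask$data))
  m <- cell_size_um / mask$voxel_size_um
  if (any(abs(m - round(m)) > 1e-9))
    stop("compute_density_grid: cell size must be a whole number of voxels")
  m <- as.integer(round(m))
  shape <- dim(mask$data)
  ci <- voxel_cell_index(shape, m)
  ncell <- prod(ci$gdim)
  tot <- tabulate(ci$cell + 1L, nbins = ncell)
  fg <- tabulate(ci$cell[as.vector(mask$data)] + 1L, nbins = ncell)
  structure(list(density = array(fg / tot, dim = ci$gdim),
                 cell_size_um = cell_size_um,
                 cells_per_axis = m,
                 voxel_geometry = list(shape = shape,
                                       voxel_size_um = mask$voxel_size_um,
                                       origin_um = mask$origin_um)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s cells of %s um, mean density %.4g\n",
              paste(dim(x$density), collapse = "x"),
              paste(x$cell_size_um, collapse = "x"), mean(x$density)))
  invisible(x)
}

#' Speed field from a density grid
#'
#' Affine speed law `F = density + epsilon`: marching prefers dense-signal
#' corridors while every cell stays reachable in finite time.
#'
#' @param grid a [compute_density_grid()] result.
#' @param params a [validation_params()] (uses `speed_floor`).
#' @return 3D array of positive speeds.
#' @export
density_to_speed <- function(grid, params = validation_params()) {
  grid$density + params$speed_floor
}

#' Eikonal arrival-time field by multistencils fast marching
#'
#' Solves `|grad T| * F = 1` with `T = 0` on the seed cells, using
#' second-order upwind differences on axis-aligned plus in-plane diagonal
#' stencils, with first-order fallback where second-order neighbors are not
#' yet finalized. Cells with `F <= 0` are obstacles (`T = Inf`).
#'
#' @param speed 3D array of speeds (grid-cell units).
#' @param seeds n x 3 matrix of 0-based seed cell indices.
#' @param second_order use second-order differences (default TRUE).
#' @return 3D array of arrival times.
#' @export
msfm_time_field <- function(speed, seeds, second_order = TRUE) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  if (!nrow(seeds)) stop("msfm_time_field: empty seed set")
  gdim <- dim(speed)
  lin <- as.integer(seeds[, 1] + gdim[1] * (seeds[, 2] + gdim[2] * seeds[, 3]))
  T <- cpp_msfm(as.vector(speed), as.integer(gdim), lin,
                second_order = second_order, cross_stencils = TRUE)
  array(T, dim = gdim)
}

#' Back-track one cell to the seed set down the arrival-time gradient
#'
#' Descends the trilinearly interpolated negative gradient of `T` with a
#' fixed step until a seed cell is entered, the step budget is exhausted, or
#' no downhill progress remains. Failure is encoded in `reached_seed`.
#'
#' @param T arrival-time array from [msfm_time_field()].
#' @param start length-3 0-based cell index (or continuous cell coordinate).
#' @param seed_mask logical array marking seed cells.
#' @param params a [validation_params()].
#' @return a `path_trace`: `points` (n x 3, continuous 0-based cell
#'   coordinates), `reached_seed`.
#' @export
backtrack_path <- function(T, start, seed_mask, params = validation_params()) {
  gdim <- dim(T)
  max_steps <- params$max_steps
  if (is.null(max_steps))
    max_steps <- as.integer(ceiling(10 * sqrt(sum(gdim^2)) / params$step_size))
  res <- cpp_backtrack(as.vector(T), as.integer(gdim), as.vector(seed_mask),
                       as.numeric(start), params$step_size, max_steps)
  structure(list(points = res$points, reached_seed = res$reached_seed),
            class = "path_trace")
}

#' Confidence of a back-tracked path
#'
#' The fraction of path points lying in foreground cells, a foreground cell
#' being one whose signal density exceeds the configured threshold.
#' Points inside seed (injection) cells count as foreground: the injection
#' site is the densest labeled tissue, and a path is only penalized for the
#' empty space it crosses, not for arriving.
#'
#' @param path a `path_trace` from [backtrack_path()].
#' @param grid the [compute_density_grid()] the path was traced over.
#' @param params a [validation_params()].
#' @param seed_mask optional logical array over grid cells; points in seed
#'   cells are counted as foreground.
#' @return numeric in \[0, 1\].
#' @export
path_confidence <- function(path, grid, params = validation_params(),
                            seed_mask = NULL) {
  pts <- path$points
  if (!nrow(pts)) stop("path_confidence: empty path")
  cells <- round(pts)
  fg <- grid$density[cells + 1L] > params$foreground_density_threshold
  if (!is.null(seed_mask)) fg <- fg | seed_mask[cells + 1L]
  mean(fg)
}

#' Remove signal not path-connected to the injection site
#'
#' Builds the density grid, marches arrival times from the cells overlapping
#' the injection mask, back-tracks every signal-bearing cell, and clears all
#' mask voxels inside cells that fail to reach a seed or whose path
#' confidence falls below the cutoff. An optional manual-override mask is
#' cleared last.
#'
#' @param mask logical [volume3d()] of detected signal.
#' @param injection logical [volume3d()] of the injection site.
#' @param params a [validation_params()].
#' @param override_mask optional logical [volume3d()] of voxels to clear
#'   unconditionally (stand-in for manual inspection).
#' @return the validated logical [volume3d()] (a subset of `mask`) with
#'   attribute `report`: one row per signal-bearing cell with
#'   `reached_seed`, `confidence`, `removed`, `removed_voxels`.
#' @export
validate_signal <- function(mask, injection, params = validation_params(),
                            override_mask = NULL) {
  stopifnot_same_geometry(mask, injection)
  if (!any(injection$data)) stop("validate_signal: empty injection mask")
  grid <- compute_density_grid(mask, params$cell_size_um)
  gdim <- dim(grid$density)
  ncell <- prod(gdim)
  ci <- voxel_cell_index(dim(mask$data), grid$cells_per_axis)

  seed_cells <- unique(ci$cell[as.vector(injection$data)])
  seed_mask <- array(FALSE, dim = gdim)
  seed_mask[seed_cells + 1L] <- TRUE
  seeds0 <- arrayInd(seed_cells + 1L, gdim) - 1L

  speed <- density_to_speed(grid, params)
  T <- msfm_time_field(speed, seeds0)

  fg_cells <- which(array(tabulate(ci$cell[as.vector(mask$data)] + 1L,
                                   nbins = ncell) > 0, dim = gdim))
  cells0 <- arrayInd(fg_cells, gdim) - 1L
  n <- nrow(cells0)
  reached <- logical(n)
  conf <- numeric(n)
  for (i in seq_len(n)) {
    tr <- backtrack_path(T, cells0[i, ], seed_mask, params)
    reached[i] <- tr$reached_seed
    conf[i] <- path_confidence(tr, grid, params, seed_mask)
  }
  removed <- !reached | conf < params$confidence_cutoff

  out <- mask$data
  if (any(removed)) {
    bad <- logical(ncell)
    bad[fg_cells[removed]] <- TRUE
    out[bad[ci$cell + 1L] & out] <- FALSE
  }
  if (!is.null(override_mask)) {
    stopifnot_same_geometry(mask, override_mask)
    out[override_mask$data] <- FALSE
  }
  removed_voxels <- tabulate(ci$cell[as.vector(mask$data & !out)] + 1L,
                             nbins = ncell)[fg_cells]
  res <- volume3d(out, voxel_size_um = mask$voxel_size_um,
                  origin_um = mask$origin_um)
  attr(res, "report") <- data.frame(
    cell1 = cells0[, 1], cell2 = cells0[, 2], cell3 = cells0[, 3],
    reached_seed = reached, confidence = conf, removed = removed,
    removed_voxels = removed_voxels)
  res
}
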