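## ---------------------------------------------------------------------------
## Soma localization: a parameterized stand-in for dedicated sphere-fitting
## soma detectors. 26-connected components of the detection mask are
## size-filtered; oversized components are split by a local-maxima-seeded
## watershed on intensity; accepted components yield intensity-weighted
## centroids, merged by a minimum-separation rule (brighter soma kept).
## ---------------------------------------------------------------------------

soma_list <- function(df) {
  need <- c("x_um", "y_um", "z_um", "volume_voxels", "peak", "region_id",
            "excluded")
  for (col in setdiff(need, names(df))) df[[col]] <- NA
  class(df) <- c("soma_list", "data.frame")
  df
}

empty_soma_list <- function() {
  soma_list(data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                       volume_voxels = integer(0), peak = numeric(0),
                       region_id = integer(0), excluded = logical(0)))
}

## local maxima of `intensity` restricted to component voxels (0-based coords)
component_maxima <- function(intensity, coords0, shape) {
  box_lo <- pmax(apply(coords0, 2, min) - 1L, 0L)
  box_hi <- pmin(apply(coords0, 2, max) + 1L, shape - 1L)
  bd <- box_hi - box_lo + 1L
  loc <- array(-Inf, dim = bd)
  rel <- sweep(coords0, 2, box_lo, "-") + 1L
  loc[rel] <- intensity[coords0 + 1L]
  is_max <- array(TRUE, dim = bd)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    shifted <- array(-Inf, dim = bd)
    src1 <- max(1, 1 - di):min(bd[1], bd[1] - di)
    src2 <- max(1, 1 - dj):min(bd[2], bd[2] - dj)
    src3 <- max(1, 1 - dk):min(bd[3], bd[3] - dk)
    shifted[src1 + di, src2 + dj, src3 + dk] <- loc[src1, src2, src3]
    is_max <- is_max & (loc >= shifted)
  }
  cand <- rel[is_max[rel] & is.finite(loc[rel]), , drop = FALSE]
  if (!nrow(cand)) cand <- rel[which.max(loc[rel]), , drop = FALSE]
  sweep(cand, 2, box_lo, "+") - 1L
}

greedy_separate <- function(coords0, score, min_sep_vox) {
  ord <- order(-score, coords0[, 1], coords0[, 2], coords0[, 3])
  kept <- integer(0)
  for (i in ord) {
    if (length(kept)) {
      d <- sqrt(rowSums(sweep(coords0[kept, , drop = FALSE], 2,
                              coords0[i, ], "-")^2))
      if (min(d) < min_sep_vox) next
    }
    kept <- c(kept, i)
  }
  kept
}

#' Detect somata in a 3D intensity volume
#'
#' @param intensity a [volume3d()] of gray values.
#' @param mask logical [volume3d()] of detected signal (e.g. from
#'   [detect_volume()]).
#' @param soma_radius_um nominal soma radius; sets the default size band
#'   `[0.2, 5] * (4/3) pi r^3` voxels and the default separation `2 r`.
#' @param min_voxels,max_voxels component size band (voxels); oversized
#'   components are watershed-split.
#' @param min_separation_um centroids closer than this are merged, keeping
#'   the brighter one.
#' @return a `soma_list` data.frame: `x_um, y_um, z_um, volume_voxels,
#'   peak, region_id, excluded` (region/excluded filled by
#'   [assign_somata()]).
#' @export
detect_somata <- function(intensity, mask, soma_radius_um = 3,
                          min_voxels = NULL, max_voxels = NULL,
                          min_separation_um = NULL) {
  stopifnot_same_geometry(intensity, mask)
  vox_um <- prod(intensity$voxel_size_um)
  sphere_vox <- (4 / 3) * pi * soma_radius_um^3 / vox_um
  if (is.null(min_voxels)) min_voxels <- max(1, round(0.2 * sphere_vox))
  if (is.null(max_voxels)) max_voxels <- round(5 * sphere_vox)
  if (is.null(min_separation_um)) min_separation_um <- 2 * soma_radius_um
  if (min_voxels < 1) stop("detect_somata: min_voxels must be >= 1")
  shape <- dim(mask$data)
  mean_vox <- mean(intensity$voxel_size_um)
  lab <- cpp_label26(as.vector(mask$data), shape)
  ncomp <- max(lab)
  if (ncomp == 0) return(empty_soma_list())
  sizes <- tabulate(lab, nbins = ncomp)
  vox_by_comp <- split(which(lab > 0), lab[lab > 0])

  centers <- matrix(numeric(0), ncol = 3)
  vols <- integer(0)
  peaks <- numeric(0)
  for (ci in seq_len(ncomp)) {
    if (sizes[ci] < min_voxels) next
    vox <- vox_by_comp[[as.character(ci)]]
    coords0 <- arrayInd(vox, shape) - 1L
    ints <- intensity$data[vox]
    if (sizes[ci] <= max_voxels) {
      parts <- list(seq_along(vox))
    } else {
      mx <- component_maxima(intensity$data, coords0, shape)
      kept <- greedy_separate(mx, intensity$data[mx + 1L],
                              min_separation_um / mean_vox)
      seeds <- mx[kept, , drop = FALSE]
      if (nrow(seeds) <= 1) {
        parts <- list(seq_along(vox))
      } else {
        seed_lin <- seeds[, 1] + shape[1] * (seeds[, 2] + shape[2] * seeds[, 3])
        assign <- cpp_watershed_flood(as.vector(intensity$data), shape,
                                      vox - 1L, as.integer(seed_lin))
        parts <- split(seq_along(vox), assign)
        parts <- parts[vapply(parts, length, 1L) >= min_voxels]
      }
    }
    for (p in parts) {
      w <- ints[p]
      ctr <- colSums(coords0[p, , drop = FALSE] * w) / sum(w)
      centers <- rbind(centers, ctr)
      vols <- c(vols, length(p))
      peaks <- c(peaks, max(w))
    }
  }
  if (!nrow(centers)) return(empty_soma_list())
  keep <- greedy_separate(centers, peaks + 1e-9 * vols,
                          min_separation_um / mean_vox)
  keep <- sort(keep)
  ctr_um <- sweep(sweep(centers[keep, , drop = FALSE] + 0.5, 2,
                        intensity$voxel_size_um, "*"),
                  2, intensity$origin_um, "+")
  soma_list(data.frame(x_um = ctr_um[, 1], y_um = ctr_um[, 2],
                       z_um = ctr_um[, 3],
                       volume_voxels = vols[keep], peak = peaks[keep],
                       region_id = NA_integer_, excluded = FALSE))
}

#' Assign somata to analysis regions and flag injection-site somata
#'
#' @param somata a `soma_list` from [detect_somata()] or loaded from CSV.
#' @param annotation label [volume3d()].
#' @param table a [region_table()].
#' @param injection_mask optional logical [volume3d()]; somata inside it are
#'   flagged `excluded` (they are dropped from input quantification).
#' @return the `soma_list` with `region_id` and `excluded` filled.
#' @export
assign_somata <- function(somata, annotation, table, injection_mask = NULL) {
  if (!nrow(somata)) return(somata)
  coords <- as.matrix(somata[, c("x_um", "y_um", "z_um")])
  somata$region_id <- region_of_point(coords, annotation, table)
  if (!is.null(injection_mask)) {
    idx0 <- um_to_voxel(injection_mask, coords)
    somata$excluded <- injection_mask$data[idx0 + 1L]
  } else {
    somata$excluded <- FALSE
  }
  somata
}

#' Apply a 3x4 affine transform to coordinates
#'
#' `c' = A c + t` with `A` the left 3x3 block and `t` the fourth column.
#'
#' @param coordinates n x 3 matrix (or length-3 vector) of coordinates.
#' @param matrix 3 x 4 numeric affine matrix.
#' @param inverse apply the inverse transform instead.
#' @return transformed n x 3 matrix.
#' @export
apply_affine <- function(coordinates, matrix, inverse = FALSE) {
  if (is.null(dim(coordinates))) coordinates <- rbind(coordinates)
  if (!all(dim(matrix) == c(3, 4)) || any(!is.finite(matrix)))
    stop("apply_affine: matrix must be a finite 3x4 affine")
  A <- matrix[, 1:3]
  t <- matrix[, 4]
  if (inverse) {
    if (abs(det(A)) < 1e-12)
      stop("apply_affine: singular linear part, cannot invert")
    Ai <- solve(A)
    sweep(coordinates, 2, t, "-") %*% t(Ai)
  } else {
    sweep(coordinates %*% t(A), 2, t, "+")
  }
}

#' Write / read a soma list as CSV
#' @param somata a `soma_list`.
#' @param path CSV path.
#' @export
write_soma_csv <- function(somata, path) {
  utils::write.csv(as.data.frame(somata), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_soma_csv
#' @export
read_soma_csv <- function(path) {
  soma_list(utils::read.csv(path, stringsAsFactors = FALSE))
}
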