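#' Build and validate a region hierarchy table
#'
#' The parcellation is a forest of regions: each region has a unique positive
#' integer id and an optional parent. A subset of regions is flagged as the
#' analysis set; quantification collapses every label upward to its first
#' ancestor (or self) in that set. Regions whose lineage never meets the
#' analysis set are pooled into "Others" ([OTHERS_ID]); voxels labeled 0 are
#' outside the annotated atlas ([NON_ANNOTATED_ID]).
#'
#' @param df data.frame with columns `id`, `acronym`, `parent_id`
#'   (NA or 0 for roots), `in_analysis_set`, and optionally
#'   `is_injection_region`.
#' @return a `region_table`: the validated data.frame plus a precomputed
#'   label-to-analysis-region map.
#' @export
region_table <- function(df) {
  need <- c("id", "acronym", "parent_id", "in_analysis_set")
  if (!all(need %in% names(df)))
    stop("region_table: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$id <- as.integer(df$id)
  df$parent_id <- as.integer(df$parent_id)
  df$parent_id[!is.na(df$parent_id) & df$parent_id == 0L] <- NA_integer_
  df$in_analysis_set <- as.logical(df$in_analysis_set)
  if (is.null(df$is_injection_region)) df$is_injection_region <- FALSE
  df$is_injection_region <- as.logical(df$is_injection_region)
  if (anyDuplicated(df$id)) stop("region_table: duplicate region id")
  if (any(df$id <= 0)) stop("region_table: ids must be positive")
  if (any(!is.na(df$parent_id) & !(df$parent_id %in% df$id)))
    stop("region_table: parent_id refers to unknown region")

  # cycle check + collapse map in one upward walk per region
  parent <- stats::setNames(df$parent_id, df$id)
  flagged <- stats::setNames(df$in_analysis_set, df$id)
  nreg <- nrow(df)
  collapse <- stats::setNames(rep(NA_integer_, nreg), df$id)
  for (r in df$id) {
    cur <- r
    seen <- character(0)
    repeat {
      key <- as.character(cur)
      if (key %in% seen) stop("region_table: cycle in parent links at id ", r)
      seen <- c(seen, key)
      if (isTRUE(flagged[[key]])) { collapse[[as.character(r)]] <- cur; break }
      nxt <- parent[[key]]
      if (is.na(nxt)) { collapse[[as.character(r)]] <- OTHERS_ID; break }
      cur <- nxt
    }
  }
  structure(list(regions = df, collapse_map = collapse), class = "region_table")
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("<region_table> %d regions, %d in analysis set\n",
              nrow(x$regions), sum(x$regions$in_analysis_set)))
  invisible(x)
}

#' Load a region hierarchy table from CSV or JSON
#'
#' CSV header: `id,acronym,parent_id,in_analysis_set,is_injection_region`
#' (injection flag optional); JSON: an array of objects with the same keys.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return a validated [region_table()].
#' @export
load_region_table <- function(path) {
  if (!file.exists(path)) stop("load_region_table: file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    stop("load_region_table: expected .csv or .json"))
  region_table(df)
}

#' Write a region table to CSV
#' @param table a [region_table()].
#' @param path output CSV path.
#' @export
write_region_table <- function(table, path) {
  utils::write.csv(table$regions, path, row.names = FALSE)
  invisible(path)
}

#' Collapse raw atlas labels to analysis regions
#'
#' Walks parent links upward from each label until a region flagged
#' `in_analysis_set` is met (an analysis region collapses to itself). Labels
#' with no flagged ancestor map to [OTHERS_ID]; label 0 maps to
#' [NON_ANNOTATED_ID]. Vectorized.
#'
#' @param region_id integer vector of raw labels (0 allowed).
#' @param table a [region_table()].
#' @return integer vector of analysis region ids.
#' @export
collapse_to_analysis <- function(region_id, table) {
  stopifnot(inherits(table, "region_table"))
  region_id <- as.integer(region_id)
  out <- rep(NA_integer_, length(region_id))
  out[region_id == 0L] <- NON_ANNOTATED_ID
  nz <- which(region_id != 0L)
  if (length(nz)) {
    key <- as.character(region_id[nz])
    mapped <- table$collapse_map[key]
    if (any(is.na(names(mapped)) | is.na(mapped)))
      stop("collapse_to_analysis: unknown region id(s): ",
           paste(unique(region_id[nz][is.na(mapped)]), collapse = ", "))
    out[nz] <- unname(mapped)
  }
  out
}

#' Ids of the analysis set (plus sentinels)
#' @param table a [region_table()].
#' @param sentinels include [OTHERS_ID] and [NON_ANNOTATED_ID].
#' @return integer vector of analysis region ids.
#' @export
analysis_region_ids <- function(table, sentinels = TRUE) {
  ids <- table$regions$id[table$regions$in_analysis_set]
  if (sentinels) ids <- c(ids, OTHERS_ID, NON_ANNOTATED_ID)
  ids
}

#' Acronyms for analysis region ids (sentinels included)
#' @param ids integer vector of analysis region ids.
#' @param table a [region_table()].
#' @return character vector.
#' @export
region_acronyms <- function(ids, table) {
  acr <- stats::setNames(table$regions$acronym, table$regions$id)
  out <- acr[as.character(ids)]
  out[ids == OTHERS_ID] <- "Others"
  out[ids == NON_ANNOTATED_ID] <- "NA-area"
  unname(out)
}

#' Analysis region containing a physical point
#'
#' Converts micrometre coordinates to voxel indices under the half-open
#' voxel-box convention, looks up the raw label, and collapses it to the
#' analysis set.
#'
#' @param coordinate_um numeric matrix (n x 3) or length-3 vector.
#' @param annotation a [volume3d()] of integer labels (0 outside the brain).
#' @param table a [region_table()].
#' @return integer vector of analysis region ids.
#' @export
region_of_point <- function(coordinate_um, annotation, table) {
  idx0 <- um_to_voxel(annotation, coordinate_um)
  d <- dim(annotation$data)
  bad <- idx0[, 1] < 0 | idx0[, 2] < 0 | idx0[, 3] < 0 |
         idx0[, 1] >= d[1] | idx0[, 2] >= d[2] | idx0[, 3] >= d[3]
  if (any(bad))
    stop("region_of_point: ", sum(bad), " coordinate(s) out of volume bounds")
  lab <- annotation$data[idx0 + 1L]
  collapse_to_analysis(lab, table)
}
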