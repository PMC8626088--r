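## ---------------------------------------------------------------------------
## Per-region connectivity quantification. Outputs: validated projection
## signal volume per region, normalized over the whole brain with the
## injection site excluded from numerator and denominator. Inputs: counts of
## region-assigned somata, with injection-site somata excluded. Both emit a
## normalized connectivity profile over the analysis regions plus the
## "Others" and non-annotated pools.
## ---------------------------------------------------------------------------

connectivity_profile <- function(df, sample = "sample1", group = NA_character_,
                                 modality = c("output", "input")) {
  modality <- match.arg(modality)
  df$sample <- sample
  df$group <- group
  df$modality <- modality
  df <- df[, c("sample", "group", "modality", "region", "acronym", "raw",
               "proportion")]
  class(df) <- c("connectivity_profile", "data.frame")
  df
}

profile_skeleton <- function(table) {
  ids <- sort(analysis_region_ids(table, sentinels = FALSE))
  ids <- c(ids, OTHERS_ID, NON_ANNOTATED_ID)
  data.frame(region = ids, acronym = region_acronyms(ids, table),
             raw = 0, proportion = 0, stringsAsFactors = FALSE)
}

#' Quantify whole-brain outputs from a validated signal mask
#'
#' Per analysis region, the raw value is the count of validated foreground
#' voxels whose collapsed label is that region (at 1 um isotropic this count
#' is the signal volume in um^3), excluding voxels inside the injection
#' mask; proportions normalize the raw values to sum to one.
#'
#' @param validated_mask logical [volume3d()] from [validate_signal()].
#' @param annotation label [volume3d()].
#' @param table a [region_table()].
#' @param injection_mask logical [volume3d()]; voxels inside are excluded
#'   from numerator and denominator.
#' @param sample,group identifiers carried into the profile.
#' @return a `connectivity_profile` data.frame (`sample, group, modality,
#'   region, acronym, raw, proportion`).
#' @export
quantify_outputs <- function(validated_mask, annotation, table,
                             injection_mask = NULL,
                             sample = "sample1", group = NA_character_) {
  stopifnot_same_geometry(validated_mask, annotation)
  keep <- validated_mask$data
  if (!is.null(injection_mask)) {
    stopifnot_same_geometry(validated_mask, injection_mask)
    keep <- keep & !injection_mask$data
  }
  lab <- collapse_to_analysis(annotation$data[keep], table)
  skel <- profile_skeleton(table)
  counts <- table(factor(lab, levels = skel$region))
  skel$raw <- as.numeric(counts)
  total <- sum(skel$raw)
  if (total == 0)
    stop("quantify_outputs: no validated signal outside the injection site ",
         "(degenerate profile)")
  skel$proportion <- skel$raw / total
  connectivity_profile(skel, sample, group, "output")
}

#' Quantify whole-brain inputs from a region-assigned soma list
#'
#' Somata flagged `excluded` (inside the injection site) are dropped; per
#' region the proportion is its soma count over all remaining somata.
#'
#' @param somata a region-assigned `soma_list` (see [assign_somata()]).
#' @param table a [region_table()].
#' @param sample,group identifiers carried into the profile.
#' @return a `connectivity_profile` data.frame.
#' @export
quantify_inputs <- function(somata, table, sample = "sample1",
                            group = NA_character_) {
  if (any(is.na(somata$region_id)))
    stop("quantify_inputs: somata are not region-assigned")
  kept <- somata[!somata$excluded, , drop = FALSE]
  if (!nrow(kept))
    stop("quantify_inputs: no somata outside the injection site ",
         "(degenerate profile)")
  skel <- profile_skeleton(table)
  counts <- table(factor(kept$region_id, levels = skel$region))
  skel$raw <- as.numeric(counts)
  skel$proportion <- skel$raw / sum(skel$raw)
  connectivity_profile(skel, sample, group, "input")
}

#' Output-to-input ratio per region, with reciprocity categories
#'
#' Ratio = output proportion / input proportion. Zero input with positive
#' output gives `Inf` (output-biased); both zero gives `NaN` (undefined).
#' Categories: ratio < 0.25 input-biased, 0.25 <= ratio <= 4 balanced
#' (boundaries inclusive), ratio > 4 output-biased.
#'
#' @param output_profile,input_profile `connectivity_profile`s over the
#'   same region set.
#' @return data.frame `region, acronym, output, input, ratio, category`.
#' @export
output_input_ratio <- function(output_profile, input_profile) {
  if (!identical(sort(output_profile$region), sort(input_profile$region)))
    stop("output_input_ratio: profiles cover different region sets")
  o <- output_profile[order(output_profile$region), ]
  i <- input_profile[order(input_profile$region), ]
  ratio <- ifelse(i$proportion > 0, o$proportion / i$proportion,
                  ifelse(o$proportion > 0, Inf, NaN))
  category <- rep("undefined", length(ratio))
  category[!is.nan(ratio) & ratio < 0.25] <- "input-biased"
  category[!is.nan(ratio) & ratio >= 0.25 & ratio <= 4] <- "balanced"
  category[!is.nan(ratio) & ratio > 4] <- "output-biased"
  data.frame(region = o$region, acronym = o$acronym,
             output = o$proportion, input = i$proportion,
             ratio = ratio, category = category, stringsAsFactors = FALSE)
}

#' Pearson similarity of two connectivity profiles
#'
#' @param p,q `connectivity_profile`s (or plain numeric vectors) over the
#'   same region set with at least 3 regions.
#' @return Pearson correlation coefficient.
#' @export
profile_similarity <- function(p, q) {
  pv <- if (is.data.frame(p)) p$proportion[order(p$region)] else p
  qv <- if (is.data.frame(q)) q$proportion[order(q$region)] else q
  if (length(pv) != length(qv) || length(pv) < 3)
    stop("profile_similarity: need matched profiles over >= 3 regions")
  if (stats::sd(pv) == 0 || stats::sd(qv) == 0)
    stop("profile_similarity: zero variance, correlation undefined")
  stats::cor(pv, qv)
}

#' Write profiles to long-format CSV
#' @param profiles a `connectivity_profile` or list of them.
#' @param path CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  utils::write.csv(do.call(rbind, lapply(profiles, as.data.frame)), path,
                   row.names = FALSE)
  invisible(path)
}
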