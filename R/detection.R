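## ---------------------------------------------------------------------------
## Per-coronal-section projection-signal detection: background estimation
## (min with a robust scalar estimate, then repeated uniform-mean smoothing),
## background subtraction, Gaussian filtering, Yen thresholding clipped to a
## configured range, and binarization against both the global threshold and
## a multiple of the local background.
## ---------------------------------------------------------------------------

#' Detection parameters
#'
#' @param background_iterations number of sequential mean-filter passes used
#'   to smooth the background estimate (default 10).
#' @param background_kernel odd side length of the uniform averaging
#'   template (default 9).
#' @param gaussian_kernel odd side length of the Gaussian filter (default 5).
#' @param gaussian_sigma Gaussian standard deviation in pixels (default 1).
#' @param background_multiplier a pixel must exceed this multiple of the
#'   local background estimate to be foreground (default 4).
#' @param yen_clip_min,yen_clip_max gray-unit bounds the Yen threshold is
#'   clipped to. `NA` for `yen_clip_min` means "95th percentile of the
#'   filtered section" (computed per section); `NA` for `yen_clip_max`
#'   means unbounded above.
#' @param yen_bins histogram bins for float data (default 256).
#' @return a `detection_params` list.
#' @export
detection_params <- function(background_iterations = 10L,
                             background_kernel = 9L,
                             gaussian_kernel = 5L,
                             gaussian_sigma = 1.0,
                             background_multiplier = 4,
                             yen_clip_min = NA_real_,
                             yen_clip_max = NA_real_,
                             yen_bins = 256L) {
  if (background_kernel %% 2 == 0 || background_kernel < 3 ||
      gaussian_kernel %% 2 == 0 || gaussian_kernel < 3)
    stop("detection_params: kernels must be odd and >= 3")
  if (background_multiplier <= 0)
    stop("detection_params: background_multiplier must be > 0")
  if (!is.na(yen_clip_min) && !is.na(yen_clip_max) && yen_clip_min > yen_clip_max)
    stop("detection_params: yen_clip_min must be <= yen_clip_max")
  structure(list(background_iterations = as.integer(background_iterations),
                 background_kernel = as.integer(background_kernel),
                 gaussian_kernel = as.integer(gaussian_kernel),
                 gaussian_sigma = gaussian_sigma,
                 background_multiplier = background_multiplier,
                 yen_clip_min = yen_clip_min,
                 yen_clip_max = yen_clip_max,
                 yen_bins = as.integer(yen_bins)),
            class = "detection_params")
}

#' Estimate the smooth background of one coronal section
#'
#' The initial estimate is the per-section median gray level (robust to
#' sparse bright signal); the section is clipped to it from above
#' (elementwise min), then smoothed by `background_iterations` sequential
#' convolutions with the uniform `background_kernel` x `background_kernel`
#' averaging template, reflecting at borders.
#'
#' @param section 2D numeric matrix.
#' @param params a [detection_params()].
#' @return 2D background field, same shape as `section`.
#' @export
estimate_background <- function(section, params = detection_params()) {
  if (!is.matrix(section) || !length(section))
    stop("estimate_background: section must be a nonempty matrix")
  if (all(is.na(section))) stop("estimate_background: all-NA section")
  b0 <- stats::median(section)
  b <- pmin(section, b0)
  k <- rep(1 / params$background_kernel, params$background_kernel)
  for (i in seq_len(params$background_iterations))
    b <- cpp_conv2_sep(b, k)
  b
}

#' Subtract a background field, flooring at zero
#' @param section,background 2D matrices of identical shape.
#' @return `pmax(section - background, 0)`.
#' @export
subtract_background <- function(section, background) {
  if (!identical(dim(section), dim(background)))
    stop("subtract_background: shape mismatch")
  pmax(section - background, 0)
}

gaussian_kernel_1d <- function(size, sigma) {
  h <- (size - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian-filter one section
#'
#' Convolution with a truncated, renormalized `gaussian_kernel` x
#' `gaussian_kernel` Gaussian of the configured sigma, reflecting at
#' borders. The kernel sums to one, so constant sections are unchanged.
#'
#' @param section 2D numeric matrix.
#' @param params a [detection_params()].
#' @return filtered 2D matrix.
#' @export
gaussian_filter <- function(section, params = detection_params()) {
  cpp_conv2_sep(section, gaussian_kernel_1d(params$gaussian_kernel,
                                            params$gaussian_sigma))
}

#' Yen threshold of a gray-level histogram, clipped to a range
#'
#' Maximizes Yen's maximum-correlation criterion over all candidate splits;
#' ties break toward the lower gray level. The raw threshold is then clipped
#' into `[clip_min, clip_max]`.
#'
#' @param counts non-negative histogram counts.
#' @param levels gray levels (bin centers), same length as `counts`,
#'   increasing.
#' @param clip_min,clip_max clipping bounds (`NA` = unbounded).
#' @return list with `raw`, `clipped`, and `degenerate` (TRUE when fewer
#'   than two bins are occupied, in which case `raw` is the single occupied
#'   level).
#' @export
yen_threshold <- function(counts, levels = seq_along(counts) - 1,
                          clip_min = NA_real_, clip_max = NA_real_) {
  if (length(counts) != length(levels))
    stop("yen_threshold: counts and levels differ in length")
  if (sum(counts) <= 0) stop("yen_threshold: empty histogram")
  occupied <- which(counts > 0)
  if (length(occupied) < 2) {
    raw <- levels[occupied]
    degenerate <- TRUE
  } else {
    p <- counts / sum(counts)
    P1 <- cumsum(p)
    P1sq <- cumsum(p^2)
    P2sq <- sum(p^2) - P1sq
    n <- length(p)
    t <- seq_len(n - 1)
    crit <- rep(-Inf, n - 1)
    valid <- P1[t] > 0 & P1[t] < 1 & P1sq[t] > 0 & P2sq[t] > 0
    crit[valid] <- -log(P1sq[t][valid] * P2sq[t][valid]) +
      2 * log(P1[t][valid] * (1 - P1[t][valid]))
    raw <- levels[which.max(crit)]
    degenerate <- FALSE
  }
  clipped <- raw
  if (!is.na(clip_min)) clipped <- max(clipped, clip_min)
  if (!is.na(clip_max)) clipped <- min(clipped, clip_max)
  list(raw = raw, clipped = clipped, degenerate = degenerate)
}

#' Binarize a filtered section
#'
#' The per-pixel threshold is `max(background_multiplier * background,
#' clipped_threshold)`: a pixel is foreground only if it exceeds both the
#' global clipped Yen value and a multiple of its local background.
#'
#' @param filtered,background 2D matrices of identical shape.
#' @param clipped_threshold scalar gray-unit threshold.
#' @param params a [detection_params()].
#' @return 2D logical mask.
#' @export
binarize <- function(filtered, background, clipped_threshold,
                     params = detection_params()) {
  if (!identical(dim(filtered), dim(background)))
    stop("binarize: shape mismatch")
  filtered > pmax(params$background_multiplier * background, clipped_threshold)
}

#' Run the full detection pipeline on one section
#' @param section 2D numeric matrix.
#' @param params a [detection_params()].
#' @return list with `background`, `filtered`, `yen_threshold_raw`,
#'   `yen_threshold_clipped`, `degenerate`, `mask`.
#' @export
detect_section <- function(section, params = detection_params()) {
  bg <- estimate_background(section, params)
  sub <- subtract_background(section, bg)
  fil <- gaussian_filter(sub, params)
  clip_min <- params$yen_clip_min
  if (is.na(clip_min)) clip_min <- stats::quantile(fil, 0.95, names = FALSE)
  rng <- range(fil)
  if (rng[1] == rng[2]) {
    yt <- list(raw = rng[1], clipped = max(rng[1], clip_min), degenerate = TRUE)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = params$yen_bins + 1)
    counts <- tabulate(pmin(findInterval(fil, breaks, rightmost.closed = TRUE),
                            params$yen_bins), nbins = params$yen_bins)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    yt <- yen_threshold(counts, centers, clip_min, params$yen_clip_max)
  }
  mask <- binarize(fil, bg, yt$clipped, params)
  list(background = bg, filtered = fil, yen_threshold_raw = yt$raw,
       yen_threshold_clipped = yt$clipped, degenerate = yt$degenerate,
       mask = mask)
}

#' Detect labeled signal across a whole volume
#'
#' Applies the section pipeline independently to every coronal section
#' (first array axis) and stacks the binary masks. The per-section raw and
#' clipped thresholds are attached as attribute `thresholds` (a data.frame
#' with one row per section) for logging.
#'
#' @param volume a [volume3d()], assumed resampled to isotropic spacing
#'   upstream.
#' @param params a [detection_params()].
#' @return a logical [volume3d()] mask with attribute `thresholds`.
#' @export
detect_volume <- function(volume, params = detection_params()) {
  stopifnot(is_volume3d(volume))
  d <- dim(volume$data)
  mask <- array(FALSE, dim = d)
  thr <- data.frame(section = seq_len(d[1]), raw = NA_real_, clipped = NA_real_,
                    degenerate = FALSE)
  for (s in seq_len(d[1])) {
    res <- detect_section(matrix(volume$data[s, , ], d[2], d[3]), params)
    mask[s, , ] <- res$mask
    thr$raw[s] <- res$yen_threshold_raw
    thr$clipped[s] <- res$yen_threshold_clipped
    thr$degenerate[s] <- res$degenerate
  }
  out <- volume3d(mask, voxel_size_um = volume$voxel_size_um,
                  origin_um = volume$origin_um)
  attr(out, "thresholds") <- thr
  out
}
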