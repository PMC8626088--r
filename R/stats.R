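## ---------------------------------------------------------------------------
## Group-level comparisons over connectivity profiles: sample x region
## matrices, Pearson correlation matrices, per-region one-way ANOVA with
## Tukey HSD, and average-linkage hierarchical clustering on correlation
## distance with multiscale bootstrap support (BP and approximately
## unbiased AU values).
## ---------------------------------------------------------------------------

#' Assemble connectivity profiles into a sample-by-region matrix
#'
#' @param profiles list of `connectivity_profile`s (one per sample).
#' @return numeric matrix, rows = samples (named), columns = regions
#'   (named by acronym), with attribute `groups` (character per row) and
#'   `region_ids`.
#' @export
group_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]][order(profiles[[1]]$region), ]
  M <- t(vapply(profiles, function(p) {
    p <- p[order(p$region), ]
    if (!identical(p$region, ref$region))
      stop("group_matrix: profiles cover different region sets")
    p$proportion
  }, numeric(nrow(ref))))
  rownames(M) <- vapply(profiles, function(p) p$sample[1], character(1))
  colnames(M) <- ref$acronym
  attr(M, "groups") <- vapply(profiles, function(p) as.character(p$group[1]),
                              character(1))
  attr(M, "region_ids") <- ref$region
  M
}

#' Pearson correlation matrix between samples
#'
#' @param M sample-by-region matrix (rows are correlated pairwise).
#' @return symmetric matrix with unit diagonal; rows with zero variance
#'   produce `NA` entries (flagged with a warning).
#' @export
correlation_matrix <- function(M) {
  if (ncol(M) < 3) stop("correlation_matrix: need >= 3 regions")
  degenerate <- apply(M, 1, stats::sd) == 0
  R <- suppressWarnings(stats::cor(t(M)))
  if (any(degenerate)) {
    warning("correlation_matrix: zero-variance row(s): ",
            paste(rownames(M)[degenerate], collapse = ", "))
    R[degenerate, ] <- NA
    R[, degenerate] <- NA
  }
  diag(R) <- 1
  R
}

#' One-way ANOVA with Tukey HSD for one region
#'
#' Classic one-way ANOVA (`F = MS_between / MS_within` on `k - 1`, `N - k`
#' degrees of freedom) followed by Tukey's honestly-significant-difference
#' multiple comparisons with Tukey-Kramer standard errors for unbalanced
#' designs. When both between- and within-group variance vanish the test is
#' degenerate and reported as `F = 0, p = 1`.
#'
#' @param M sample-by-region matrix from [group_matrix()].
#' @param region column name or index.
#' @param groups character vector of group labels per row (defaults to the
#'   matrix's `groups` attribute).
#' @param alpha significance level for the Tukey flags (default 0.05).
#' @return list: `region`, `group_means`, `group_sem`, `F`, `p`, `df`,
#'   `tukey` (data.frame `pair, diff, p_adj, significant`), `degenerate`.
#' @export
anova_tukey <- function(M, region, groups = attr(M, "groups"), alpha = 0.05) {
  y <- M[, region]
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("anova_tukey: need >= 2 groups with >= 2 samples each")
  means <- tapply(y, g, mean)
  sems <- tapply(y, g, function(v) stats::sd(v) / sqrt(length(v)))
  pairs <- utils::combn(levels(g), 2)
  pair_names <- paste(pairs[2, ], pairs[1, ], sep = "-")
  if (stats::var(y) == 0) {
    tk <- data.frame(pair = pair_names, diff = 0, p_adj = 1,
                     significant = FALSE, stringsAsFactors = FALSE)
    return(list(region = region, group_means = means, group_sem = sems,
                F = 0, p = 1, df = c(nlevels(g) - 1L, length(y) - nlevels(g)),
                tukey = tk, degenerate = TRUE))
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  pv <- s[["Pr(>F)"]][1]
  th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  th <- th[pair_names, , drop = FALSE]
  tk <- data.frame(pair = pair_names, diff = th[, "diff"],
                   p_adj = th[, "p adj"],
                   significant = th[, "p adj"] < alpha,
                   stringsAsFactors = FALSE, row.names = NULL)
  list(region = region, group_means = means, group_sem = sems,
       F = Fv, p = pv, df = c(s$Df[1], s$Df[2]), tukey = tk,
       degenerate = FALSE)
}

#' Per-region ANOVA/Tukey table over all regions
#' @param M sample-by-region matrix.
#' @param groups group labels per row.
#' @param alpha significance level.
#' @return data.frame with one row per region: `region, F, p` plus one
#'   adjusted-p column per group pair.
#' @export
anova_tukey_table <- function(M, groups = attr(M, "groups"), alpha = 0.05) {
  res <- lapply(colnames(M), function(r) anova_tukey(M, r, groups, alpha))
  pair_names <- res[[1]]$tukey$pair
  tab <- data.frame(region = colnames(M),
                    F = vapply(res, `[[`, numeric(1), "F"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  for (pn in pair_names)
    tab[[paste0("p_adj.", pn)]] <-
      vapply(res, function(x) x$tukey$p_adj[x$tukey$pair == pn], numeric(1))
  tab
}

correlation_distance <- function(M) {
  R <- suppressWarnings(stats::cor(t(M)))
  if (any(is.na(R)))
    stop("hcluster: zero-variance item, correlation distance undefined")
  stats::as.dist(1 - R)
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Distance `d(x, y) = 1 - Pearson r(x, y)` between rows, agglomerated with
#' average (UPGMA) linkage.
#'
#' @param M sample-by-region matrix; rows are the clustered items.
#' @return a `cluster_tree`: fields `hclust` (a [stats::hclust()] object),
#'   `labels`, `node_sets` (per internal node, the sorted item labels it
#'   spans), and optionally `bp` / `au` after [bootstrap_support()].
#' @export
hcluster <- function(M) {
  if (nrow(M) < 3) stop("hcluster: need >= 3 items")
  hc <- stats::hclust(correlation_distance(M), method = "average")
  structure(list(hclust = hc, labels = rownames(M),
                 node_sets = hclust_node_sets(hc, rownames(M))),
            class = "cluster_tree")
}

## per internal node, the sorted set of leaf labels it spans
hclust_node_sets <- function(hc, labels) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    members <- unlist(lapply(hc$merge[i, ], function(m)
      if (m < 0) labels[-m] else sets[[m]]))
    sets[[i]] <- sort(members)
  }
  sets
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d items, %d internal nodes%s\n",
              length(x$labels), length(x$node_sets),
              if (!is.null(x$bp)) ", with bootstrap support" else ""))
  invisible(x)
}

#' Multiscale bootstrap support for a cluster tree
#'
#' Columns (regions) are resampled with replacement at sizes `round(r * p)`
#' for each scale `r`; each replicate is reclustered and every node of the
#' reference tree is checked for appearance (same spanned item set). BP is
#' the appearance fraction at scale 1. AU comes from the multiscale probit
#' fit: `qnorm(1 - BP(r))` is regressed on `(sqrt(r), 1/sqrt(r))` and
#' `AU = 1 - pnorm(v - c)` where `v, c` are the fitted coefficients
#' (signed distance and curvature).
#'
#' @param M sample-by-region matrix; rows are the clustered items.
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param scales relative resampling sizes; must include 1
#'   (default `seq(0.5, 1.4, 0.1)`).
#' @param seed RNG seed (mandatory; the procedure is deterministic given
#'   it).
#' @return the `cluster_tree` for `M` with fields `bp`, `au`,
#'   `au_flagged` (nodes never observed, AU reported as 0), `bp_table`
#'   (nodes x scales appearance fractions).
#' @export
bootstrap_support <- function(M, n_boot = 1000L, scales = seq(0.5, 1.4, 0.1),
                              seed) {
  if (missing(seed)) stop("bootstrap_support: seed is mandatory")
  if (n_boot < 100) stop("bootstrap_support: n_boot must be >= 100")
  if (!any(abs(scales - 1) < 1e-9))
    stop("bootstrap_support: scales must include 1")
  tree <- hcluster(M)
  keys <- vapply(tree$node_sets, paste, character(1), collapse = "\r")
  p <- ncol(M)
  counts <- matrix(0L, nrow = length(keys), ncol = length(scales),
                   dimnames = list(NULL, paste0("r", scales)))
  with_seed(seed, {
    for (si in seq_along(scales)) {
      m <- max(3L, as.integer(round(scales[si] * p)))
      for (b in seq_len(n_boot)) {
        cols <- sample.int(p, m, replace = TRUE)
        Mb <- M[, cols, drop = FALSE]
        if (any(apply(Mb, 1, stats::sd) == 0)) next
        hb <- stats::hclust(correlation_distance(Mb), method = "average")
        kb <- vapply(hclust_node_sets(hb, rownames(M)), paste, character(1),
                     collapse = "\r")
        counts[, si] <- counts[, si] + as.integer(keys %in% kb)
      }
    }
  })
  bp_table <- counts / n_boot
  bp <- bp_table[, which(abs(scales - 1) < 1e-9)[1]]
  au <- numeric(length(keys))
  flagged <- logical(length(keys))
  for (i in seq_along(keys)) {
    if (all(counts[i, ] == 0)) { au[i] <- 0; flagged[i] <- TRUE; next }
    if (all(counts[i, ] == n_boot)) { au[i] <- 1; next }
    bpc <- pmin(pmax(bp_table[i, ], 0.5 / n_boot), 1 - 0.5 / n_boot)
    z <- stats::qnorm(1 - bpc)
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    beta <- stats::lm.fit(X, z)$coefficients
    au[i] <- 1 - stats::pnorm(beta[1] - beta[2])
  }
  tree$bp <- unname(bp)
  tree$au <- unname(au)
  tree$au_flagged <- flagged
  tree$bp_table <- bp_table
  tree
}

#' Serialize a cluster tree (with support values) to JSON
#' @param tree a `cluster_tree`.
#' @param path output path.
#' @export
write_cluster_json <- function(tree, path) {
  obj <- list(labels = tree$labels,
              merge = tree$hclust$merge,
              height = tree$hclust$height,
              node_sets = tree$node_sets,
              bp = tree$bp, au = tree$au, au_flagged = tree$au_flagged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
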