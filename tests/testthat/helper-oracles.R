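# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each operation so they share no code path
# with the implementation they check.

# literal sliding-window 2D convolution with reflect (edge-repeating) borders
slow_conv2 <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  kh <- (nrow(kernel) - 1) / 2; kw <- (ncol(kernel) - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in -kh:kh) for (b in -kw:kw)
      s <- s + kernel[a + kh + 1, b + kw + 1] * x[refl(i + a, nr), refl(j + b, nc)]
    out[i, j] <- s
  }
  out
}

# literal background estimate: min with median, then n explicit mean filters
slow_background <- function(section, iterations = 10, k = 9) {
  b <- pmin(section, median(section))
  kern <- matrix(1 / (k * k), k, k)
  for (i in seq_len(iterations)) b <- slow_conv2(b, kern)
  b
}

# exhaustive scan of Yen's maximum-correlation criterion
slow_yen <- function(counts, levels) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf; best_t <- NA
  for (t in seq_len(n - 1)) {
    p1 <- sum(p[1:t]); s1 <- sum(p[1:t]^2); s2 <- sum(p[(t + 1):n]^2)
    if (p1 <= 0 || p1 >= 1 || s1 <= 0 || s2 <= 0) next
    crit <- -log(s1 * s2 / (p1^2 * (1 - p1)^2))
    if (crit > best) { best <- crit; best_t <- levels[t] }  # ties: lower level
  }
  best_t
}

# triple-loop density grid counting
slow_density_grid <- function(mask_arr, m) {
  shape <- dim(mask_arr)
  g <- ceiling(shape / m)
  dens <- array(NA_real_, dim = g)
  for (a in seq_len(g[1])) for (b in seq_len(g[2])) for (c in seq_len(g[3])) {
    i <- ((a - 1) * m[1] + 1):min(a * m[1], shape[1])
    j <- ((b - 1) * m[2] + 1):min(b * m[2], shape[2])
    k <- ((c - 1) * m[3] + 1):min(c * m[3], shape[3])
    block <- mask_arr[i, j, k]
    dens[a, b, c] <- sum(block) / length(block)
  }
  dens
}

# 26-neighbor Dijkstra with edge cost = length / harmonic-mean speed
slow_dijkstra26 <- function(F, seed_idx1) {
  g <- dim(F); n <- prod(g)
  idx <- arrayInd(seq_len(n), g)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lens <- sqrt(rowSums(offs^2))
  Td <- rep(Inf, n); Td[seed_idx1] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, Td))
    if (!is.finite(Td[u])) break
    done[u] <- TRUE
    for (r in seq_len(nrow(offs))) {
      v <- idx[u, ] + offs[r, ]
      if (any(v < 1) || any(v > g)) next
      vl <- v[1] + g[1] * ((v[2] - 1) + g[2] * (v[3] - 1))
      cost <- lens[r] * 0.5 * (1 / F[u] + 1 / F[vl])
      if (Td[u] + cost < Td[vl]) Td[vl] <- Td[u] + cost
    }
  }
  Td
}

# textbook Pearson correlation
slow_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# one-way ANOVA + Tukey from first principles
slow_anova_tukey <- function(y, groups) {
  g <- factor(groups)
  k <- nlevels(g); N <- length(y)
  means <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (means - mean(y))^2)
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  Fv <- msb / msw
  p <- 1 - pf(Fv, k - 1, N - k)
  pairs <- combn(levels(g), 2)
  p_adj <- apply(pairs, 2, function(pr) {
    ns <- tapply(y, g, length)[pr]
    se <- sqrt(msw / 2 * (1 / ns[1] + 1 / ns[2]))
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    1 - ptukey(q, k, N - k)
  })
  names(p_adj) <- paste(pairs[2, ], pairs[1, ], sep = "-")
  list(F = Fv, p = p, p_adj = p_adj)
}

# greedy one-to-one matching of detected to planted coordinates
match_coordinates <- function(truth, detected, radius) {
  if (!nrow(detected) || !nrow(truth)) return(0L)
  D <- as.matrix(dist(rbind(truth, detected)))
  D <- D[seq_len(nrow(truth)), nrow(truth) + seq_len(nrow(detected)),
         drop = FALSE]
  matched <- 0L
  used <- rep(FALSE, ncol(D))
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (D[i, j] <= radius) { matched <- matched + 1L; used[j] <- TRUE }
  }
  matched
}
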