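test_that("density grid counts match trivial cases and the triple-loop oracle", {
  full <- volume3d(array(TRUE, dim = c(10, 10, 10)))
  g <- compute_density_grid(full)
  expect_equal(dim(g$density), c(1L, 1L, 1L))
  expect_equal(as.numeric(g$density), 1)

  quarter <- array(FALSE, dim = c(10, 10, 10))
  quarter[1:5, 1:5, 1:10] <- TRUE  # 250 of 1000
  expect_equal(as.numeric(compute_density_grid(volume3d(quarter))$density),
               0.25)

  set.seed(41)
  m <- array(runif(24 * 30 * 17) < 0.3, dim = c(24, 30, 17))  # ragged edges
  got <- compute_density_grid(volume3d(m))
  expect_equal(got$density, slow_density_grid(m, c(10, 10, 10)))
})

test_that("the speed law is affine in density with a positive floor", {
  g <- compute_density_grid(volume3d(array(FALSE, dim = c(20, 20, 20))))
  p <- validation_params()
  expect_equal(as.numeric(density_to_speed(g, p)),
               rep(p$speed_floor, 8))
  g$density[] <- 1
  expect_equal(as.numeric(density_to_speed(g, p)), rep(1 + p$speed_floor, 8))
  d1 <- g; d1$density[] <- 0.7
  d2 <- g; d2$density[] <- 0.2
  expect_true(all(density_to_speed(d1, p) > density_to_speed(d2, p)))
})

test_that("arrival times track Euclidean distance under uniform speed", {
  g <- c(21L, 21L, 21L)
  T <- msfm_time_field(array(1, dim = g), matrix(c(10, 10, 10), ncol = 3))
  idx <- arrayInd(seq_len(prod(g)), g) - 1L
  dist <- sqrt(rowSums(sweep(idx, 2, c(10, 10, 10), "-")^2))
  sel <- dist >= 5
  expect_lt(max(abs(as.vector(T)[sel] - dist[sel]) / dist[sel]), 0.03)
  expect_equal(T[11, 11, 11], 0)
  expect_true(all(T >= 0))
  expect_error(msfm_time_field(array(1, dim = g),
                               matrix(numeric(0), ncol = 3)), "empty")
})

test_that("zero-speed pockets stay unreachable and are reported as such", {
  g <- c(15L, 15L, 15L)
  F <- array(1, dim = g)
  F[10:15, 10:15, 10:15] <- 0
  F[12, 12, 12] <- 1  # a live cell sealed inside an obstacle
  T <- msfm_time_field(F, matrix(c(2, 2, 2), ncol = 3))
  expect_true(is.infinite(T[12, 12, 12]))
  seed_mask <- array(FALSE, g); seed_mask[3, 3, 3] <- TRUE
  tr <- backtrack_path(T, c(11, 11, 11), seed_mask)
  expect_false(tr$reached_seed)
})

test_that("back-tracking from a seed cell is a single-point success", {
  g <- c(11L, 11L, 11L)
  T <- msfm_time_field(array(1, dim = g), matrix(c(5, 5, 5), ncol = 3))
  seed_mask <- array(FALSE, g); seed_mask[6, 6, 6] <- TRUE
  tr <- backtrack_path(T, c(5, 5, 5), seed_mask)
  expect_true(tr$reached_seed)
  expect_equal(nrow(tr$points), 1)
})

test_that("paths through a uniform corridor are near-straight", {
  g <- c(31L, 11L, 11L)
  T <- msfm_time_field(array(1, dim = g), matrix(c(1, 5, 5), ncol = 3))
  seed_mask <- array(FALSE, g); seed_mask[2, 6, 6] <- TRUE
  p <- validation_params()
  tr <- backtrack_path(T, c(28, 5, 5), seed_mask, p)
  expect_true(tr$reached_seed)
  steps <- diff(tr$points)
  path_len <- sum(sqrt(rowSums(steps^2)))
  straight <- sqrt(sum((c(28, 5, 5) - c(1, 5, 5))^2))
  expect_lt(path_len / straight, 1.05)
})

test_that("path confidence equals a per-point recount", {
  g <- compute_density_grid(volume3d(array(FALSE, dim = c(50, 50, 50))))
  set.seed(42)
  g$density[] <- runif(length(g$density))
  pts <- cbind(runif(100, 0, 4), runif(100, 0, 4), runif(100, 0, 4))
  path <- structure(list(points = pts, reached_seed = TRUE),
                    class = "path_trace")
  p <- validation_params(foreground_density_threshold = 0.4)
  got <- path_confidence(path, g, p)
  oracle <- mean(vapply(seq_len(100), function(i) {
    cell <- round(pts[i, ]) + 1
    g$density[cell[1], cell[2], cell[3]] > 0.4
  }, logical(1)))
  expect_equal(got, oracle)
  # all-foreground and half-foreground cases
  g$density[] <- 1
  expect_equal(path_confidence(path, g, p), 1)
  empty <- structure(list(points = pts[0, , drop = FALSE],
                          reached_seed = FALSE), class = "path_trace")
  expect_error(path_confidence(empty, g, p), "empty")
})

test_that("a tube touching the injection survives; an isolated blob does not", {
  shape <- c(60, 60, 60)
  mask <- array(FALSE, dim = shape)
  mask[21:30, 21:30, 1:30] <- TRUE          # density-1 corridor into the center
  blob <- array(FALSE, dim = shape)
  blob[50:52, 50:52, 50:52] <- TRUE         # isolated noise blob
  inj <- array(FALSE, dim = shape)
  inj[21:30, 21:30, 21:30] <- TRUE
  v <- function(a) volume3d(a)
  val <- validate_signal(v(mask | blob), v(inj))
  expect_true(all(val$data[mask]))
  expect_false(any(val$data[blob]))
})

test_that("validation conserves, is idempotent, and clears by cell", {
  rec <- run_output_recovery(1)
  # conservation: output is a subset of the input mask
  expect_false(any(rec$val$data & !rec$mask$data))
  # idempotence on the validated mask
  again <- validate_signal(rec$val, rec$truth$injection_mask)
  expect_identical(again$data, rec$val$data)
  # the manual-override mask is applied last
  ov <- rec$val; ov$data[] <- FALSE
  ov$data[which(rec$val$data)[1:10]] <- TRUE
  cleared <- validate_signal(rec$mask, rec$truth$injection_mask,
                             override_mask = ov)
  expect_false(any(cleared$data[ov$data]))
  expect_error(validate_signal(rec$mask,
                               volume3d(array(FALSE, dim = dim(rec$mask$data)))),
               "empty injection")
})

test_that("validated per-region signal tracks the planted ground truth", {
  rec <- run_output_recovery(1)
  expect_gte(rec$tube_retention, 0.9)
  expect_gte(rec$noise_removed, 0.95)
  expect_gte(cor(rec$true_frac, rec$est), 0.95)
})
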