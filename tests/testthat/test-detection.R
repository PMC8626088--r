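test_that("background estimation clips bright pixels and matches brute force", {
  p <- detection_params()
  # constant section: mean filtering a constant returns it
  cst <- matrix(17, 20, 20)
  expect_equal(estimate_background(cst, p), cst)
  # flat background with one bright pixel: the min step removes it entirely
  flat <- matrix(10, 30, 30); spot <- flat; spot[15, 15] <- 5000
  expect_equal(estimate_background(spot, p), flat)
  # random section equals the literal min + ten 9x9 sliding-window means
  set.seed(21)
  sec <- matrix(runif(64 * 64, 0, 100), 64, 64)
  expect_equal(estimate_background(sec, p), slow_background(sec),
               tolerance = 1e-9)
  expect_error(estimate_background(matrix(NA_real_, 3, 3), p), "NA")
})

test_that("background subtraction floors at zero", {
  I <- matrix(c(100, 10, 30), 1, 3)
  B <- matrix(30, 1, 3)
  expect_equal(subtract_background(I, B), matrix(c(70, 0, 0), 1, 3))
  expect_equal(subtract_background(B, B), matrix(0, 1, 3))
  expect_error(subtract_background(I, matrix(0, 2, 2)), "mismatch")
})

test_that("Gaussian filter is normalized, impulse-preserving, oracle-exact", {
  p <- detection_params()
  cst <- matrix(3.5, 15, 15)
  expect_equal(gaussian_filter(cst, p), cst)
  # delta impulse reproduces the kernel; total mass preserved
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- gaussian_filter(imp, p)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  k1 <- tracemapr:::gaussian_kernel_1d(5, 1.0)
  expect_equal(out[6:10, 6:10], outer(k1, k1), tolerance = 1e-12)
  set.seed(22)
  sec <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(gaussian_filter(sec, p), slow_conv2(sec, outer(k1, k1)),
               tolerance = 1e-9)
})

test_that("Yen threshold equals exhaustive criterion maximization", {
  # two equal-mass deltas: threshold strictly between them
  counts <- rep(0, 256); counts[11] <- 500; counts[201] <- 500
  got <- yen_threshold(counts, 0:255)
  expect_equal(got$raw, slow_yen(counts, 0:255))
  # foreground is the strict > side, so the split lies between the modes
  expect_gte(got$raw, 10); expect_lt(got$raw, 200)
  # random histograms, exact agreement with the brute-force scan
  set.seed(23)
  for (i in 1:25) {
    counts <- rpois(64, lambda = runif(1, 0.5, 20))
    if (sum(counts > 0) < 2) next
    expect_identical(yen_threshold(counts, 0:63)$raw, slow_yen(counts, 0:63))
  }
})

test_that("Yen clipping and degenerate histograms are handled", {
  counts <- rep(0, 256); counts[11] <- 500; counts[201] <- 500
  raw <- yen_threshold(counts, 0:255)$raw
  expect_equal(yen_threshold(counts, 0:255, clip_min = raw + 50)$clipped,
               raw + 50)
  expect_equal(yen_threshold(counts, 0:255, clip_max = raw - 50)$clipped,
               raw - 50)
  single <- rep(0, 10); single[4] <- 100
  got <- yen_threshold(single, 0:9)
  expect_true(got$degenerate)
  expect_equal(got$raw, 3)
  expect_error(yen_threshold(rep(0, 5)), "empty")
})

test_that("binarization requires exceeding both local and global thresholds", {
  p <- detection_params()  # multiplier 4
  fil <- matrix(c(51, 100, 40), 1, 3)
  bg0 <- matrix(0, 1, 3)
  expect_equal(binarize(fil, bg0, 50, p)[1, ], c(TRUE, TRUE, FALSE))
  bg30 <- matrix(30, 1, 3)  # 4*30 = 120 dominates the clipped threshold 50
  expect_equal(binarize(fil, bg30, 50, p)[1, ], c(FALSE, FALSE, FALSE))
  expect_error(binarize(fil, matrix(0, 2, 2), 50, p), "mismatch")
})

test_that("a blank noise-free section yields an empty mask", {
  res <- detect_section(matrix(0, 30, 30))
  expect_true(res$degenerate)
  expect_false(any(res$mask))
})

test_that("raising the Yen clip floor never adds foreground", {
  set.seed(24)
  vol <- volume3d(array(pmax(rnorm(30^3, 20, 10), 0), dim = c(30, 30, 30)))
  vol$data[10:20, 10:20, 10:20] <- 200
  n_prev <- Inf
  for (clip in c(10, 50, 100, 150)) {
    m <- detect_volume(vol, detection_params(yen_clip_min = clip))
    expect_lte(sum(m$data), n_prev)
    n_prev <- sum(m$data)
  }
})

test_that("a blank noisy volume with a high clip floor stays almost empty", {
  set.seed(25)
  cfg <- simulation_config()
  blank <- add_background_and_noise(volume3d(array(0, dim = c(40, 40, 40))),
                                    cfg, seed = 31)
  m <- detect_volume(blank, detection_params(yen_clip_min = 100))
  expect_lt(mean(m$data), 0.001)
})

test_that("volume detection is deterministic and recovers planted tubes", {
  rec <- run_output_recovery(1)
  m2 <- detect_volume(add_background_and_noise({
    atlas <- recovery_atlas()
    cfg <- simulation_config(seed = 1)
    ax <- simulate_axons(atlas, cfg)
    nbav <- ax$truth$planted_signal_mask
    nbav$data <- nbav$data | ax$truth$injection_mask$data
    plant_noise_blobs(ax$volume, nbav, 100, seed = 201)$volume
  }, simulation_config(seed = 1), 51), study_detection_params())
  expect_identical(m2$data, rec$mask$data)
  # voxel-level F1 against the planted tubes (noise blobs are separate
  # plants, not tube error; they are excluded from the false positives)
  planted <- rec$truth$planted_signal_mask$data
  blobs <- rec$blob_mask$data
  tp <- sum(rec$mask$data & planted)
  f1 <- 2 * tp / (2 * tp + sum(rec$mask$data & !planted & !blobs) +
                    sum(!rec$mask$data & planted))
  expect_gte(f1, 0.8)
})
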