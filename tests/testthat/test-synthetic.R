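test_that("toy atlases partition an ellipsoid into contiguous labeled regions", {
  atlas <- make_toy_atlas(c(40, 40, 40), 2, seed = 3)
  ann <- atlas$annotation$data
  expect_setequal(unique(as.vector(ann)), c(0L, 1L, 2L))
  expect_true(all(table(ann[ann > 0]) > 0))
  # same seed twice -> identical volume and table
  atlas2 <- make_toy_atlas(c(40, 40, 40), 2, seed = 3)
  expect_identical(atlas2$annotation$data, ann)
  # contiguity under 26-connectivity for a finer partition
  fine <- make_toy_atlas(c(60, 60, 60), 8, seed = 9)
  for (id in 1:8) {
    lab <- tracemapr:::cpp_label26(as.vector(fine$annotation$data == id),
                                   dim(fine$annotation$data))
    expect_equal(max(lab), 1, info = paste("region", id))
  }
  expect_error(make_toy_atlas(c(20, 20, 20), 100000, seed = 1), "exceeds")
  expect_equal(sum(fine$table$regions$is_injection_region), 1)
})

test_that("axon walks home onto a single target with zero tortuosity", {
  atlas <- small_atlas()
  inj <- atlas$table$regions$id[atlas$table$regions$is_injection_region]
  target <- setdiff(atlas$table$regions$id, inj)[1]
  cfg <- simulation_config(shape = c(40, 40, 40), tortuosity = 0,
                           n_axons = 20L, axon_radius = 1,
                           target_fractions = setNames(1, target), seed = 2)
  ax <- simulate_axons(atlas, cfg)
  lab <- collapse_to_analysis(
    atlas$annotation$data[ax$truth$planted_signal_mask$data], atlas$table)
  outside <- lab[lab != inj & lab != NON_ANNOTATED_ID]
  expect_gte(mean(outside == target), 0.99)
})

test_that("planted output fractions are recomputed from the planted mask", {
  atlas <- recovery_atlas()
  inj <- atlas$table$regions$id[atlas$table$regions$is_injection_region]
  # pick the two targets most equidistant from the injection centroid, so
  # tube length (voxels per axon) weights both targets about equally
  start <- tracemapr:::region_centroid_vox(atlas$annotation, inj)
  cand <- setdiff(sort(atlas$table$regions$id), inj)
  dists <- vapply(cand, function(id) sqrt(sum(
    (tracemapr:::region_centroid_vox(atlas$annotation, id) - start)^2)),
    numeric(1))
  ord <- order(dists)
  pick <- which.min(diff(dists[ord]))
  targets <- cand[ord][pick:(pick + 1)]
  # thin tubes fanning out across the whole target region: deposited volume
  # stays proportional to axon count instead of saturating one bundle
  cfg <- simulation_config(target_fractions = setNames(c(0.7, 0.3), targets),
                           axon_radius = 1, terminal_mode = "region",
                           seed = 4)
  ax <- simulate_axons(atlas, cfg)
  # oracle: recount the planted mask voxels per region
  lab <- collapse_to_analysis(
    atlas$annotation$data[ax$truth$planted_signal_mask$data], atlas$table)
  keep <- lab != inj & lab != NON_ANNOTATED_ID & lab != OTHERS_ID
  counts <- table(factor(lab[keep], levels = names(ax$truth$true_output_fraction)))
  expect_equal(unname(ax$truth$true_output_fraction),
               as.numeric(counts) / sum(counts))
  expect_equal(sum(ax$truth$true_output_fraction), 1, tolerance = 1e-9)
  # realized fractions over the two targets land near the requested split
  # (walks also deposit signal in regions they cross on the way)
  fr <- ax$truth$true_output_fraction[as.character(targets)]
  fr <- fr / sum(fr)
  expect_lt(max(abs(fr - c(0.7, 0.3))), 0.1)
})

test_that("zero amplitude yields a background-only volume", {
  atlas <- small_atlas()
  cfg <- simulation_config(shape = c(40, 40, 40), signal_amplitude = 0,
                           n_axons = 10L, seed = 2)
  ax <- simulate_axons(atlas, cfg)
  expect_true(all(ax$volume$data == 0))
})

test_that("somata are planted inside their regions, well separated", {
  atlas <- recovery_atlas()
  cfg <- simulation_config(somata_per_region = 5L, seed = 8)
  so <- simulate_somata(atlas, cfg)
  coords <- so$truth$soma_coordinates_um
  for (id in names(coords)) {
    expect_equal(nrow(coords[[id]]), 5)
    got <- region_of_point(coords[[id]], atlas$annotation, atlas$table)
    expect_true(all(got == as.integer(id)), info = paste("region", id))
  }
  all_xyz <- do.call(rbind, coords)
  dmat <- as.matrix(dist(all_xyz))
  expect_gte(min(dmat[upper.tri(dmat)]), 2 * cfg$soma_radius)
  # planted somata never touch non-annotated space
  expect_true(all(atlas$annotation$data[so$truth$planted_signal_mask$data] > 0))
})

test_that("zero requested somata gives a blank volume", {
  atlas <- small_atlas()
  cfg <- simulation_config(shape = c(40, 40, 40), somata_per_region = 0L,
                           seed = 2)
  so <- simulate_somata(atlas, cfg)
  expect_true(all(so$volume$data == 0))
  expect_length(so$truth$soma_coordinates_um, 0)
})

test_that("background gradient and noise behave as configured", {
  v <- volume3d(array(0, dim = c(6, 10, 20)))
  cfg <- simulation_config(background_gradient = 40, noise_sigma = 0)
  out <- add_background_and_noise(v, cfg, seed = 1)
  for (s in 1:6)
    expect_equal(max(out$data[s, , ]) - min(out$data[s, , ]), 40)
  # sigma 0, gradient 0 -> identity
  cfg0 <- simulation_config(background_gradient = 0, noise_sigma = 0)
  expect_equal(add_background_and_noise(v, cfg0, seed = 1)$data, v$data)
  # same seed -> identical noise; different seed -> different
  cfgn <- simulation_config(noise_sigma = 5)
  a <- add_background_and_noise(v, cfgn, seed = 9)
  b <- add_background_and_noise(v, cfgn, seed = 9)
  c <- add_background_and_noise(v, cfgn, seed = 10)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  expect_true(all(a$data >= 0))
})

test_that("generators are pure functions of config and seed", {
  atlas <- small_atlas()
  cfg <- simulation_config(shape = c(40, 40, 40), n_axons = 15L,
                           somata_per_region = 2L, soma_radius = 2, seed = 6)
  expect_identical(simulate_axons(atlas, cfg)$volume$data,
                   simulate_axons(atlas, cfg)$volume$data)
  expect_identical(simulate_somata(atlas, cfg)$truth$soma_coordinates_um,
                   simulate_somata(atlas, cfg)$truth$soma_coordinates_um)
})

test_that("noise blobs stay clear of signal and of each other", {
  atlas <- recovery_atlas()
  cfg <- simulation_config(seed = 2)
  ax <- simulate_axons(atlas, cfg)
  avoid <- ax$truth$planted_signal_mask
  avoid$data <- avoid$data | ax$truth$injection_mask$data
  nb <- plant_noise_blobs(ax$volume, avoid, 100, seed = 3)
  blob <- which(nb$blob_mask$data, arr.ind = TRUE)
  expect_gte(nrow(blob), 100 * 5)  # 100 blobs of >= 5 voxels each
  sig <- which(avoid$data, arr.ind = TRUE)
  cheb <- function(a, b) max(abs(a - b))
  set.seed(4)
  for (i in sample(nrow(blob), 20)) {
    d <- apply(sig, 1, function(s) cheb(blob[i, ], s))
    expect_gte(min(d), 12 - 2 * 1.2)  # clearance minus blob extent
  }
})
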