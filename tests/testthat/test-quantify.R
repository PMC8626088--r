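two_region_setup <- function() {
  ann <- array(0L, dim = c(10, 10, 10))
  ann[1:5, , ] <- 1L; ann[6:10, , ] <- 2L
  tab <- region_table(data.frame(
    id = 1:2, acronym = c("A", "B"), parent_id = NA_integer_,
    in_analysis_set = TRUE, is_injection_region = c(TRUE, FALSE)))
  list(ann = volume3d(ann), tab = tab)
}

test_that("output proportions normalize validated voxel counts per region", {
  s <- two_region_setup()
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[1:3, 1, 1] <- TRUE   # 3 voxels in A
  mask[6, 1:5, 1] <- TRUE   # 5 voxels... make it 1 voxel rows
  mask[6, , ] <- FALSE
  mask[6, 1, 1] <- TRUE     # 1 voxel in B
  p <- quantify_outputs(volume3d(mask), s$ann, s$tab)
  expect_equal(p$proportion[p$region == 1], 0.75)
  expect_equal(p$proportion[p$region == 2], 0.25)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-9)

  # all signal in one region
  only <- array(FALSE, dim = c(10, 10, 10)); only[7:9, 1, 1] <- TRUE
  p1 <- quantify_outputs(volume3d(only), s$ann, s$tab)
  expect_equal(p1$proportion[p1$region == 2], 1)
})

test_that("injection-mask voxels never influence output proportions", {
  s <- two_region_setup()
  inj <- array(FALSE, dim = c(10, 10, 10)); inj[1:2, , ] <- TRUE
  base <- array(FALSE, dim = c(10, 10, 10))
  base[4, 1:4, 1] <- TRUE; base[7, 1:6, 1] <- TRUE
  more <- base; more[1, 1:9, 1:9] <- TRUE  # extra signal strictly inside inj
  pb <- quantify_outputs(volume3d(base), s$ann, s$tab, volume3d(inj))
  pm <- quantify_outputs(volume3d(more), s$ann, s$tab, volume3d(inj))
  expect_equal(pb$proportion, pm$proportion)
  expect_error(quantify_outputs(volume3d(inj & FALSE), s$ann, s$tab),
               "degenerate")
})

test_that("input proportions drop excluded somata and renormalize", {
  s <- two_region_setup()
  sl <- tracemapr:::soma_list(data.frame(
    x_um = 0, y_um = 0, z_um = 0,
    volume_voxels = 10L, peak = 1,
    region_id = c(rep(1L, 30), rep(2L, 70), rep(1L, 50)),
    excluded = c(rep(FALSE, 100), rep(TRUE, 50))))
  p <- quantify_inputs(sl, s$tab)
  expect_equal(p$proportion[p$region == 1], 0.3)
  expect_equal(p$proportion[p$region == 2], 0.7)
  expect_equal(sum(p$raw), 100)
  all_ex <- sl; all_ex$excluded <- TRUE
  expect_error(quantify_inputs(all_ex, s$tab), "degenerate")
  unassigned <- sl; unassigned$region_id <- NA_integer_
  expect_error(quantify_inputs(unassigned, s$tab), "not region-assigned")
})

test_that("output/input ratios reproduce the published worked example", {
  s <- two_region_setup()
  skel <- tracemapr:::profile_skeleton(s$tab)
  mk <- function(props, modality) {
    df <- skel; df$proportion <- props; df$raw <- props * 1000
    tracemapr:::connectivity_profile(df, modality = modality)
  }
  # region B mirrors the interpeduncular nucleus: 2.5% of inputs, 29.9% of
  # outputs -> ratio 11.96, an output-biased region
  out <- mk(c(0.701, 0.299, 0, 0), "output")
  inp <- mk(c(0.975, 0.025, 0, 0), "input")
  rr <- output_input_ratio(out, inp)
  b <- rr[rr$region == 2, ]
  expect_equal(b$ratio, 29.9 / 2.5, tolerance = 1e-12)
  expect_equal(b$ratio, 11.96)
  expect_equal(b$category, "output-biased")
})

test_that("ratio categories partition regions with inclusive boundaries", {
  s <- two_region_setup()
  skel <- tracemapr:::profile_skeleton(s$tab)
  # craft profiles covering every category including exact boundaries
  out <- skel; out$proportion <- c(0.25, 0.4, 0.1, 0.25)
  inp <- skel; inp$proportion <- c(1.00, 0.1, 1.0, 0)
  op <- tracemapr:::connectivity_profile(out, modality = "output")
  ip <- tracemapr:::connectivity_profile(inp, modality = "input")
  rr <- output_input_ratio(op, ip)
  expect_equal(rr$category[rr$region == 1], "balanced")        # exactly 0.25
  expect_equal(rr$category[rr$region == 2], "balanced")        # 4.0 exactly
  expect_equal(rr$category[rr$region == OTHERS_ID], "input-biased")  # 0.1
  expect_equal(rr$category[rr$region == NON_ANNOTATED_ID], "output-biased")
  # Inf
  # every region falls in exactly one category
  expect_true(all(table(rr$region) == 1))
  expect_true(all(rr$category %in% c("input-biased", "balanced",
                                     "output-biased", "undefined")))
  # both zero -> undefined
  z_out <- op; z_out$proportion[z_out$region == 1] <- 0
  z_in <- ip; z_in$proportion[z_in$region == 1] <- 0
  zr <- output_input_ratio(z_out, z_in)
  expect_equal(zr$category[zr$region == 1], "undefined")
})

test_that("profile similarity is Pearson r with its invariances", {
  set.seed(51)
  p <- runif(71); p <- p / sum(p)
  q <- runif(71); q <- q / sum(q)
  expect_equal(profile_similarity(p, p), 1)
  expect_equal(profile_similarity(p, 3 * p + 0.01), 1)
  expect_equal(profile_similarity(p, q), slow_pearson(p, q),
               tolerance = 1e-12)
  expect_error(profile_similarity(rep(0.5, 10), q[1:10]), "zero variance")
  expect_error(profile_similarity(p[1:2], q[1:2]), ">= 3")
})

test_that("recovered profiles match planted fractions on synthetic data", {
  rec <- run_output_recovery(1)
  expect_lt(max(abs(rec$true_frac - rec$est)), 0.05)
  expect_equal(sum(rec$profile$proportion), 1, tolerance = 1e-9)
  inp <- run_input_recovery(1)
  expect_lt(max(abs(inp$planted_prop - inp$est_prop)), 0.02)
})
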