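test_that("config validation enforces the band/level geometry", {
  expect_error(phantom_config(background_level = 39000), "narrow")
  expect_error(phantom_config(edge_level = 37700), "medium")
  expect_error(phantom_config(axis_level = 43000), "band")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(clearance_nm = 50), "voxel diagonal")
  expect_silent(invisible(phantom_config()))
})

test_that("chromosome solids are calibrated to the reference DNA volume", {
  ref <- load_reference()
  cfg <- phantom_config(noise_sd = 0, seed = 1)
  set.seed(2)
  sol <- make_chromosome_solid(ref[ref$chrom_id == "1", ], cfg)
  # 248.9 Mbp x 5.80 nm^3/bp
  expect_equal(sol$target_volume_nm3, 1.44362e9, tolerance = 1e-4)
  expect_lte(sol$p_len_nm, sol$q_len_nm)
  # realized short-arm fraction tracks the canonical centromere index
  expect_lt(abs(sol$ci_percent / 48.4 - 1), 0.05)
  set.seed(3)
  acro <- make_chromosome_solid(ref[ref$chrom_id == "13", ], cfg)
  expect_lt(abs(acro$ci_percent / 17.5 - 1), 0.05)
})

test_that("a metacentric solid has equal arms and a straight solid is straight", {
  ref <- load_reference()
  meta <- ref[ref$chrom_id == "1", ]
  meta$canonical_ci <- 50
  cfg <- phantom_config(noise_sd = 0, bend_deg = 0, seed = 1)
  set.seed(4)
  sol <- make_chromosome_solid(meta, cfg)
  expect_lt(abs(sol$p_len_nm - sol$q_len_nm), max(cfg$voxel_nm))
  # bend 0: end-to-end distance equals centerline path length within 1%
  pts <- sol$centerline
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  expect_lt(abs(arc / chord - 1), 0.01)
})

test_that("oversized chromosomes are rejected", {
  ref <- load_reference()
  cfg <- phantom_config(noise_sd = 0, seed = 1, nucleus_diameter_nm = 2000)
  set.seed(1)
  expect_error(make_chromosome_solid(ref[ref$chrom_id == "1", ], cfg),
               "too large")
})

test_that("rendered medium-envelope volume matches the DNA calibration", {
  ph <- small_phantom()
  lab <- small_labels()
  ref <- load_reference()
  # labels are ordered by size; truth rows are ordered by size as well
  for (i in seq_len(nrow(ph$truth))) {
    target <- ref$mbp[ref$chrom_id == ph$truth$chrom_id[i]] * 1e6 * 5.80
    measured <- sum(lab == i) * prod(ph$stack$voxel_nm)
    expect_lt(abs(measured / target - 1), 0.10)
  }
})

test_that("phantom generation is bit-reproducible and respects the truth table", {
  cfg <- phantom_config(noise_sd = 120, seed = 31)
  k <- c("19", "21", "X")
  p1 <- generate_phantom(cfg, karyotype = k)
  p2 <- generate_phantom(cfg, karyotype = k)
  expect_identical(p1$stack$data, p2$stack$data)
  expect_identical(as.integer(p1$labels), as.integer(p2$labels))
  expect_identical(p1$truth, p2$truth)
  expect_equal(nrow(p1$truth), 3L)
  expect_true(all(p1$truth$true_p_len_nm <= p1$truth$true_q_len_nm))
  expect_true(all(p1$truth$true_ci_percent > 0 & p1$truth$true_ci_percent <= 50))
})

test_that("an empty karyotype yields an all-background phantom", {
  ph <- generate_phantom(phantom_config(noise_sd = 0, seed = 3),
                         karyotype = character(0))
  expect_equal(nrow(ph$truth), 0L)
  expect_true(all(ph$labels == 0L))
  expect_true(all(ph$stack$data == 33000))
})

test_that("objects are disjoint, connected, and fit in the nuclear sphere", {
  ph <- small_phantom()
  sizes <- tabulate(ph$labels[ph$labels > 0])
  # volumes bookkeeping: truth volume equals labeled voxel volume exactly
  expect_equal(ph$truth$true_volume_nm3,
               sizes[ph$truth$object_id] * prod(ph$stack$voxel_nm))
  expect_lte(sum(ph$truth$true_volume_nm3),
             (4 / 3) * pi * (ph$config$nucleus_diameter_nm / 2)^3)
  # every object is one 26-connected component
  for (id in ph$truth$object_id) {
    comp <- label_components(ph$labels == id, 26, min_voxels = 1,
                             voxel_nm = ph$stack$voxel_nm)
    expect_equal(attr(comp, "n_objects"), 1L)
  }
  expect_true(all(ph$truth$true_radius_nm <
                    ph$config$nucleus_diameter_nm / 2))
})

test_that("the three bands carve nested envelopes on the noiseless phantom", {
  ph <- small_phantom()
  narrow <- threshold_band(ph$stack, "narrow")
  medium <- threshold_band(ph$stack, "medium")
  wide <- threshold_band(ph$stack, "wide")
  expect_true(all(medium[narrow]))
  for (id in ph$truth$object_id) {
    obj <- ph$labels == id
    expect_lt(sum(narrow & obj), sum(medium & obj))
    expect_lte(sum(medium & obj), sum(wide & obj))
  }
})

test_that("gene-density radial bias places gene-rich chromosomes inward", {
  expect_gte(radial_bias_negative_count(), 9L)
})
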