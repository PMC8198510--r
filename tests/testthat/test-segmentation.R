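test_that("band presets match the published contrast levels", {
  narrow <- segmentation_band("narrow")
  medium <- segmentation_band("medium")
  wide <- segmentation_band("wide")
  expect_equal(c(narrow$min_intensity, narrow$max_intensity), c(38445, 41264))
  expect_equal(c(medium$min_intensity, medium$max_intensity), c(37596, 43832))
  expect_equal(c(wide$min_intensity, wide$max_intensity), c(37498, 41346))
  expect_error(segmentation_band("custom"), "explicit")
  expect_error(segmentation_band("custom", 10, 5), "exceed")
})

test_that("thresholding is inclusive on both band ends", {
  vals <- c(37500, 38444, 38445, 40000, 41264, 41265)
  stack <- image_stack(array(vals, dim = c(length(vals), 1, 1)),
                       c(44, 44, 100))
  mask <- threshold_band(stack, "narrow")
  expect_equal(as.vector(mask), c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("narrow mask is a subset of the medium mask on any stack", {
  set.seed(11)
  stack <- image_stack(array(sample(30000:48000, 4000, replace = TRUE),
                             dim = c(20, 20, 10)), c(44, 44, 100))
  narrow <- threshold_band(stack, "narrow")
  medium <- threshold_band(stack, "medium")
  expect_true(all(medium[narrow]))
  ph <- small_phantom()
  n2 <- threshold_band(ph$stack, "narrow")
  m2 <- threshold_band(ph$stack, "medium")
  expect_true(all(m2[n2]))
  expect_lt(sum(n2), sum(m2))
})

test_that("component labeling counts, filters and orders objects", {
  mask <- array(FALSE, dim = c(20, 10, 10))
  mask[2:6, 2:6, 2:6] <- TRUE       # 125 voxels
  mask[12:18, 2:6, 2:6] <- TRUE     # 175 voxels
  mask[10, 9, 9] <- TRUE            # speck
  lab <- label_components(mask, 26, min_voxels = 50, voxel_nm = c(44, 44, 100))
  expect_equal(attr(lab, "n_objects"), 2L)
  # labels ordered by descending size
  expect_equal(sum(lab == 1), 175L)
  expect_equal(sum(lab == 2), 125L)
  # the speck survives only without the size filter
  lab2 <- label_components(mask, 26, min_voxels = 1, voxel_nm = c(44, 44, 100))
  expect_equal(attr(lab2, "n_objects"), 3L)
  lab3 <- label_components(mask, 26, min_voxels = 1000,
                           voxel_nm = c(44, 44, 100))
  expect_equal(attr(lab3, "n_objects"), 0L)
})

test_that("component labeling matches a brute-force flood fill", {
  set.seed(5)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      mask <- array(runif(15^3) < 0.35, dim = c(15, 15, 15))
      got <- label_components(mask, conn, min_voxels = 1,
                              voxel_nm = c(10, 10, 10))
      want <- flood_fill_oracle(mask, conn)
      # identical partitions up to relabeling: components keyed by their
      # smallest member voxel must coincide
      key <- function(lab) {
        comps <- lapply(split(which(lab > 0), lab[lab > 0]), sort)
        comps[order(vapply(comps, min, 0))]
      }
      expect_equal(unname(key(got)), unname(key(want)))
    }
  }
})

test_that("enlarging a band never shrinks the retained mask", {
  set.seed(21)
  stack <- image_stack(array(sample(36000:45000, 6000, replace = TRUE),
                             dim = c(20, 20, 15)), c(44, 44, 100))
  small <- threshold_band(stack, segmentation_band("custom", 39000, 41000))
  big <- threshold_band(stack, segmentation_band("custom", 38500, 42000))
  expect_true(all(big[small]))
  lab_s <- label_components(small, 26, min_voxels = 1)
  lab_b <- label_components(big, 26, min_voxels = 1)
  expect_true(all(lab_b[lab_s > 0] > 0))
})

test_that("segmentation is deterministic", {
  ph <- small_phantom()
  l1 <- segment_stack(ph$stack, "medium", expected_objects = NA)
  l2 <- segment_stack(ph$stack, "medium", expected_objects = NA)
  expect_identical(as.integer(l1), as.integer(l2))
})

test_that("in-plane bilateral denoising preserves shape and reduces noise", {
  ph <- small_phantom()
  expect_identical(denoise_inplane(ph$stack, spatial_radius = 0), ph$stack)

  flat <- image_stack(array(40000L, dim = c(12, 12, 4)), c(44, 44, 100))
  den <- denoise_inplane(flat, spatial_radius = 2, range_sd = 300)
  expect_equal(den$data, flat$data)

  noisy <- generate_phantom(phantom_config(noise_sd = 150, seed = 7),
                            karyotype = small_karyotype)
  den <- denoise_inplane(noisy$stack, spatial_radius = 2, range_sd = 300)
  inner <- noisy$labels > 0
  sd_before <- sd(noisy$stack$data[inner])
  sd_after <- sd(den$data[inner])
  expect_lt(sd_after, sd_before)
  expect_equal(dim(den$data), dim(noisy$stack$data))
})

test_that("medium-band segmentation of the small phantom recovers all objects", {
  lab <- small_labels()
  expect_equal(attr(lab, "n_objects"), length(small_karyotype))
})
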