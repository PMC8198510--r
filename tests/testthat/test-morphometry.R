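test_that("DNA conversion applies exactly 5.80 nm^3 per bp", {
  expect_identical(dna_from_volume(5.80e6), 1)
  expect_identical(dna_from_volume(0), 0)
  # chromosome-1 sizing arithmetic, checked by independent multiplication
  v1 <- 248.9 * 1e6 * 5.80
  expect_equal(dna_from_volume(v1), 248.9)
  expect_error(dna_from_volume(-1), "non-negative")
})

test_that("DNA conversion round-trips to machine precision", {
  v <- c(1, 2.71e8, 1.44362e9, 5.80e6)
  expect_equal(dna_from_volume(v) * 5.80 * 1e6, v, tolerance = 1e-14)
})

test_that("voxel-count volume arithmetic is exact", {
  lab <- array(0L, dim = c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L  # 10^3 voxels
  attr(lab, "voxel_nm") <- c(11, 11, 25)
  m <- measure_chromosome(lab, 1)
  expect_equal(m$volume_nm3, 1000 * 11 * 11 * 25)
})

test_that("skeleton length and diameter recover an analytic cylinder", {
  sp <- c(11, 11, 25)
  a <- c(300, 500, 500)
  b <- c(2300, 500, 500)  # axis length 2000, radius 300
  lab <- voxel_cylinder(a, b, 300, c(240, 92, 42), sp)
  sk <- skeleton_longest_path(lab, 1)
  expect_lt(abs(sk$length_nm - 2000), sqrt(sum(sp^2)))
  m <- measure_chromosome(lab, 1)
  expect_lt(abs(m$mean_diameter_nm - 600), sqrt(sum(sp^2)))
  # a uniform cylinder has no constriction
  expect_false(m$ci_reliable)
})

test_that("a single-voxel object has zero length", {
  lab <- array(0L, dim = c(5, 5, 5))
  lab[3, 3, 3] <- 1L
  attr(lab, "voxel_nm") <- c(44, 44, 100)
  sk <- skeleton_longest_path(lab, 1)
  expect_equal(sk$length_nm, 0)
})

test_that("missing objects are reported", {
  lab <- array(0L, dim = c(5, 5, 5))
  lab[2, 2, 2] <- 1L
  attr(lab, "voxel_nm") <- c(44, 44, 100)
  expect_error(measure_chromosome(lab, 3), "not present")
})

test_that("centromere localisation finds a symmetric dumbbell waist", {
  # two thick rods joined by a thin central bridge, axis along x
  sp <- c(20, 20, 20)
  dims <- c(120, 40, 40)
  lab1 <- voxel_cylinder(c(100, 400, 400), c(1050, 400, 400), 250, dims, sp)
  lab2 <- voxel_cylinder(c(1350, 400, 400), c(2300, 400, 400), 250, dims, sp)
  bridge <- voxel_cylinder(c(1000, 400, 400), c(1400, 400, 400), 110, dims, sp)
  lab <- array(pmin(1L, lab1 + lab2 + bridge), dim = dims)
  attr(lab, "voxel_nm") <- check_spacing_for_test(sp)
  m <- measure_chromosome(lab, 1)
  expect_true(m$ci_reliable)
  expect_lt(abs(m$ci_len_percent - 50), 5)
  expect_lte(m$p_len_nm, m$q_len_nm)
})

test_that("flat profiles fall back to the canonical prior when supplied", {
  prof <- rep(200, 50)
  arc <- seq(0, 2000, length.out = 50)
  res <- locate_centromere(prof, arc)
  expect_false(res$reliable)
  res2 <- locate_centromere(prof, arc, fallback_ci = 30)
  expect_false(res2$reliable)
  expect_equal(res2$ci_percent, 30, tolerance = 1e-6)
})

test_that("morphometry is equivariant under voxel-spacing rescaling", {
  lab <- voxel_capsule(c(300, 400, 400), c(1700, 500, 400), 200,
                       c(60, 30, 20), c(40, 40, 50))
  m1 <- measure_chromosome(lab, 1)
  s <- 2
  lab2 <- lab
  attr(lab2, "voxel_nm") <- attr(lab, "voxel_nm") * s
  m2 <- measure_chromosome(lab2, 1)
  expect_equal(m2$volume_nm3, m1$volume_nm3 * s^3, tolerance = 1e-12)
  expect_equal(m2$total_len_nm, m1$total_len_nm * s, tolerance = 1e-9)
  expect_equal(m2$mean_diameter_nm, m1$mean_diameter_nm * s, tolerance = 1e-9)
  expect_equal(m2$ci_len_percent, m1$ci_len_percent, tolerance = 1e-9)
})

test_that("genome percentages sum to 100 and behave on trivial cases", {
  morph <- data.frame(total_len_nm = c(1000, 1000), volume_nm3 = c(2e8, 6e8))
  out <- genome_percentages(morph)
  expect_equal(out$len_percent_of_genome, c(50, 50))
  expect_equal(out$vol_percent_of_genome, c(25, 75))
  one <- genome_percentages(data.frame(total_len_nm = 5, volume_nm3 = 5))
  expect_equal(one$len_percent_of_genome, 100)
  expect_error(genome_percentages(data.frame(total_len_nm = 0,
                                             volume_nm3 = 0)), "zero")
  full <- small_morph()
  expect_equal(sum(full$len_percent_of_genome), 100, tolerance = 1e-6)
  expect_equal(sum(full$vol_percent_of_genome), 100, tolerance = 1e-6)
})

test_that("phantom morphometry recovers the ground truth", {
  morph <- small_morph()
  tr <- match_truth(morph, small_phantom()$truth)
  vol_err <- morph$volume_nm3 / tr$true_volume_nm3 - 1
  len_err <- morph$total_len_nm / (tr$true_p_len_nm + tr$true_q_len_nm) - 1
  ci_err <- morph$ci_len_percent - tr$true_ci_percent
  expect_true(all(abs(vol_err) <= 0.10))
  expect_true(all(abs(len_err) <= 0.10))
  expect_true(all(abs(ci_err) <= 5))
  expect_true(all(morph$p_len_nm <= morph$q_len_nm))
  expect_equal(morph$total_len_nm, morph$p_len_nm + morph$q_len_nm)
  expect_true(all(morph$ci_len_percent > 0 & morph$ci_len_percent <= 50))
  # chromosome 1 carries the largest volume share
  big <- tr$chrom_id[which.max(morph$vol_percent_of_genome)]
  expect_equal(big, "1")
})
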