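test_that("noiseless phantom identification is exact up to homolog swap", {
  asg <- full_assignment()
  tr <- match_truth(full_morph(), full_phantom()$truth)
  expect_true(attr(asg, "is_complete"))
  expect_equal(asg$chrom_id, tr$chrom_id)
  expect_equal(asg$group, group_of(tr$chrom_id))
  expect_equal(sort(unique(asg$group)), LETTERS[1:8])
})

test_that("homolog 'a' is the larger of each pair", {
  asg <- full_assignment()
  morph <- full_morph()
  for (chrom in as.character(1:22)) {
    rows <- which(asg$chrom_id == chrom)
    expect_length(rows, 2L)
    va <- morph$volume_nm3[rows[asg$homolog[rows] == "a"]]
    vb <- morph$volume_nm3[rows[asg$homolog[rows] == "b"]]
    expect_gte(va, vb)
  }
})

test_that("assignment is invariant to the order of the input records", {
  morph <- full_morph()
  set.seed(9)
  perm <- sample.int(nrow(morph))
  shuffled <- morph[perm, ]
  asg1 <- full_assignment()
  asg2 <- assign_karyotype(shuffled)
  m <- match(asg1$object_id, asg2$object_id)
  expect_equal(asg1$chrom_id, asg2$chrom_id[m])
  expect_equal(asg1$homolog, asg2$homolog[m])
})

test_that("wrong record counts error unless partial assignment is requested", {
  morph <- full_morph()
  expect_error(assign_karyotype(morph[1:10, ]), "46.*10")
  part <- assign_karyotype(morph[1:10, ], allow_partial = TRUE)
  expect_false(attr(part, "is_complete"))
  expect_true(all(!is.na(part$chrom_id)))
})

test_that("matching ties break deterministically", {
  cost <- matrix(1, 2, 2)
  a1 <- karyo3d:::hungarian_cpp(cost)
  a2 <- karyo3d:::hungarian_cpp(cost)
  expect_identical(a1, a2)
  expect_setequal(a1, 1:2)
})

test_that("group classification survives 5% volume noise", {
  morph <- full_morph()
  tr <- match_truth(morph, full_phantom()$truth)
  group_hits <- integer(0)
  chrom_hits <- integer(0)
  for (sd in 1:10) {
    set.seed(100 + sd)
    noisy <- morph
    noisy$volume_nm3 <- noisy$volume_nm3 * (1 + rnorm(nrow(noisy), 0, 0.05))
    noisy$vol_percent_of_genome <-
      100 * noisy$volume_nm3 / sum(noisy$volume_nm3)
    asg <- assign_karyotype(noisy)
    group_hits <- c(group_hits, sum(asg$group == group_of(tr$chrom_id)))
    chrom_hits <- c(chrom_hits, sum(asg$chrom_id == tr$chrom_id))
  }
  # group-level calls stay essentially perfect even when within-group-C
  # numbering permutes under noise
  expect_true(all(group_hits >= 44))
  expect_gte(median(group_hits), 46)
  expect_true(all(chrom_hits >= 40))
})

test_that("volume validates against reference DNA content", {
  asg <- full_assignment()
  morph <- full_morph()
  val <- validate_assignment(asg, morph)
  expect_gt(val$r_squared, 0.99)
  expect_lt(abs(val$slope / 5.80e6 - 1), 0.10)
  expect_length(val$outliers, 0L)

  # measured volumes exactly proportional to Mbp give a perfect fit
  ref <- load_reference()
  fake <- morph
  fake$volume_nm3 <- ref$mbp[match(asg$chrom_id, ref$chrom_id)] * 5.80e6
  val2 <- validate_assignment(asg, fake)
  expect_equal(val2$r_squared, 1, tolerance = 1e-12)
  expect_equal(val2$slope, 5.80e6, tolerance = 1e-6)

  # chromosome 21 carries the least reference DNA, below chromosome 22
  mbp <- ref$mbp[match(asg$chrom_id, ref$chrom_id)]
  expect_equal(unique(asg$chrom_id[mbp == min(mbp)]), "21")
  expect_lt(ref$mbp[ref$chrom_id == "21"], ref$mbp[ref$chrom_id == "22"])
})

test_that("degenerate references are rejected", {
  asg <- full_assignment()
  morph <- full_morph()
  ref <- load_reference()
  ref$mbp <- 100
  expect_error(validate_assignment(asg, morph, ref), "degenerate")
})
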