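test_that("packaged reference karyotype carries the published sizes", {
  ref <- load_reference()
  expect_equal(nrow(ref), 24L)
  lookup <- function(chrom) ref$mbp[ref$chrom_id == chrom]
  expect_equal(lookup("1"), 248.9)
  expect_equal(lookup("21"), 46.7)
  expect_equal(lookup("22"), 50.8)
  expect_equal(lookup("19"), 58.6)
  expect_equal(lookup("20"), 64.4)
  expect_equal(ref$chrom_id[which.max(ref$mbp)], "1")
  expect_equal(ref$chrom_id[which.min(ref$mbp)], "21")
})

test_that("reference table satisfies genome-scale and gene-density ordering", {
  ref <- load_reference()
  autosomes <- ref$mbp[ref$chrom_id %in% as.character(1:22)]
  diploid <- 2 * sum(autosomes) + ref$mbp[ref$chrom_id == "X"] +
    ref$mbp[ref$chrom_id == "Y"]
  expect_lt(abs(diploid - 6.2e3) / 6.2e3, 0.05)
  expect_equal(ref$chrom_id[which.max(ref$gene_density)], "19")
  med <- median(ref$gene_density)
  expect_lt(ref$gene_density[ref$chrom_id == "18"], med)
  expect_lt(ref$gene_density[ref$chrom_id == "Y"], med)
  acro <- c("13", "14", "15", "21", "22", "Y")
  expect_true(all(ref$canonical_ci[ref$chrom_id %in% acro] < 20))
  expect_true(all(ref$canonical_ci > 0 & ref$canonical_ci <= 50))
})

test_that("group lookup follows the cytogenetic grouping", {
  expect_equal(group_of("2"), "A")
  expect_equal(group_of("14"), "D")
  expect_equal(group_of("X"), "H")
  expect_equal(group_of(as.character(6:12)), rep("C", 7))
  expect_error(group_of("chr1"), "unknown chromosome")
})

test_that("malformed reference tables are rejected with the offending row", {
  ref <- load_reference()
  tmp <- withr::local_tempfile(fileext = ".csv")

  dup <- rbind(ref, ref[ref$chrom_id == "5", ])
  write.csv(dup, tmp, row.names = FALSE)
  expect_error(load_reference(tmp), "duplicate.*5")

  missing <- ref[ref$chrom_id != "17", ]
  write.csv(missing, tmp, row.names = FALSE)
  expect_error(load_reference(tmp), "missing chromosome.*17")

  wrong_group <- ref
  wrong_group$group[wrong_group$chrom_id == "4"] <- "A"
  write.csv(wrong_group, tmp, row.names = FALSE)
  expect_error(load_reference(tmp), "group label.*4")

  bad_ci <- ref
  bad_ci$canonical_ci[bad_ci$chrom_id == "13"] <- 35
  write.csv(bad_ci, tmp, row.names = FALSE)
  expect_error(load_reference(tmp), "acrocentric")
})

test_that("karyotype templates expand to 46 slots", {
  xy <- karyotype_slots("XY")
  expect_length(xy, 46L)
  expect_equal(sum(xy == "7"), 2L)
  expect_equal(sum(xy == "Y"), 1L)
  xx <- karyotype_slots("XX")
  expect_equal(sum(xx == "X"), 2L)
  expect_false("Y" %in% xx)
})
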