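test_that("nucleus center and radii handle symmetric inputs", {
  lab <- array(0L, dim = c(21, 21, 21))
  lab[9:13, 9:13, 9:13] <- 1L  # centered cube
  attr(lab, "voxel_nm") <- c(10, 10, 10)
  cr <- nucleus_center_and_radii(lab)
  expect_equal(cr$radii$radius_nm, 0, tolerance = 1e-9)

  lab2 <- array(0L, dim = c(21, 11, 11))
  lab2[2:4, 5:7, 5:7] <- 1L
  lab2[18:20, 5:7, 5:7] <- 2L
  attr(lab2, "voxel_nm") <- c(10, 10, 10)
  cr2 <- nucleus_center_and_radii(lab2)
  expect_equal(cr2$radii$radius_nm[1], cr2$radii$radius_nm[2],
               tolerance = 1e-9)
})

test_that("phantom radii match the truth table", {
  ph <- small_phantom()
  cr <- nucleus_center_and_radii(small_labels())
  tr <- ph$truth
  # order objects by matching centroids
  m <- vapply(seq_len(nrow(cr$radii)), function(i) {
    which.min((tr$centroid_x_nm - cr$radii$centroid_x_nm[i])^2 +
                (tr$centroid_y_nm - cr$radii$centroid_y_nm[i])^2 +
                (tr$centroid_z_nm - cr$radii$centroid_z_nm[i])^2)
  }, integer(1))
  # truth radii use the geometric nucleus center; measured radii the chromatin
  # centroid -- they agree within the center offset plus a voxel diagonal
  offset <- sqrt(sum((cr$center_nm -
                        ph$nucleus_center_nm)^2))
  tol <- offset + sqrt(sum(ph$stack$voxel_nm^2))
  expect_true(all(abs(cr$radii$radius_nm - tr$true_radius_nm[m]) <= tol))
})

test_that("radial bins partition [0, max] into five equal regions", {
  expect_equal(as.character(radial_bins(c(0, 3600))),
               c("center", "periphery"))
  r <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(as.character(radial_bins(r)),
               c("center", "center-intermediate", "intermediate",
                 "periphery-intermediate", "periphery"))
  expect_equal(as.character(radial_bins(c(0, 0, 0))), rep("center", 3))
  expect_error(radial_bins(c(-1, 2)), "non-negative")
  expect_equal(levels(radial_bins(1)),
               c("center", "center-intermediate", "intermediate",
                 "periphery-intermediate", "periphery"))
})

test_that("radial regression recovers exact fits and rejects degenerate input", {
  x <- 1:10
  fit <- radial_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- radial_regression(x, rep(5, 10))
  expect_equal(flat$r_squared, 0)
  expect_error(radial_regression(rep(1, 5), 1:5), "constant")
  expect_error(radial_regression(1:2, 1:2), "at least 3")
})

test_that("neighbor detection respects touching and distant objects", {
  lab <- array(0L, dim = c(30, 12, 12))
  lab[2:6, 2:6, 2:6] <- 1L
  lab[7:11, 2:6, 2:6] <- 2L    # touching cube
  lab[25:29, 2:6, 2:6] <- 3L   # far cube
  attr(lab, "voxel_nm") <- c(100, 100, 100)
  nm <- neighbor_map(lab, cutoff_nm = 0)
  expect_true(nm$matrix["1", "2"])
  expect_false(nm$matrix["1", "3"])
  # cubes 2 and 3: 13 empty voxels = 1400 nm gap (center to center)
  nm2 <- neighbor_map(lab, cutoff_nm = 200)
  expect_false(nm2$matrix["2", "3"])
  expect_true(isSymmetric(nm$matrix))
  expect_true(all(!diag(nm$matrix)))
})

test_that("neighbor matrix agrees with a brute-force pairwise oracle", {
  ph <- small_phantom()
  lab <- small_labels()
  sp <- ph$stack$voxel_nm
  for (cutoff in c(250, 600)) {
    nm <- neighbor_map(lab, cutoff_nm = cutoff)
    k <- attr(lab, "n_objects")
    d <- dim(lab)
    coords <- lapply(seq_len(k), function(id) {
      w0 <- which(lab == id) - 1L
      cbind((w0 %% d[1] + 0.5) * sp[1],
            ((w0 %/% d[1]) %% d[2] + 0.5) * sp[2],
            (w0 %/% (d[1] * d[2]) + 0.5) * sp[3])
    })
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dmin <- sqrt(min(outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2),
                               "+") - 2 * tcrossprod(coords[[i]], coords[[j]])))
        expect_equal(unname(nm$matrix[i, j]),
                     dmin <= cutoff + sqrt(sum(sp^2)))
      }
    }
  }
})

test_that("neighbor maps are monotone in the cutoff", {
  lab <- small_labels()
  n1 <- neighbor_map(lab, cutoff_nm = 150)
  n2 <- neighbor_map(lab, cutoff_nm = 500)
  expect_true(all(n2$matrix[n1$matrix]))
})

test_that("spatial quantities are invariant under rigid translation", {
  lab <- array(0L, dim = c(40, 30, 20))
  lab[3:8, 3:8, 3:6] <- 1L
  lab[15:22, 10:14, 8:12] <- 2L
  lab[30:34, 20:24, 14:17] <- 3L
  attr(lab, "voxel_nm") <- c(50, 50, 80)
  shift <- c(4L, 3L, 2L)
  lab2 <- array(0L, dim = dim(lab))
  lab2[(1:40) > shift[1], (1:30) > shift[2], (1:20) > shift[3]] <-
    lab[1:(40 - shift[1]), 1:(30 - shift[2]), 1:(20 - shift[3])]
  attr(lab2, "voxel_nm") <- attr(lab, "voxel_nm")
  cr1 <- nucleus_center_and_radii(lab)
  cr2 <- nucleus_center_and_radii(lab2)
  expect_equal(cr1$radii$radius_nm, cr2$radii$radius_nm, tolerance = 1e-9)
  n1 <- neighbor_map(lab, cutoff_nm = 300)
  n2 <- neighbor_map(lab2, cutoff_nm = 300)
  expect_equal(unname(n1$matrix), unname(n2$matrix))
})

test_that("the spatial report binds radii, regions, regressions and neighbors", {
  rep <- spatial_report(full_labels(), full_morph(), full_assignment(),
                        cutoff_nm = 250)
  tab <- rep$chromosomes
  expect_equal(nrow(tab), 46L)
  # heat-map order follows the karyotype: 1a, 1b, ..., 22b, X, Y
  expect_equal(tab$name[1:4], c("1a", "1b", "2a", "2b"))
  expect_equal(tail(tab$name, 2), c("X", "Y"))
  expect_equal(rownames(rep$neighbor_map$matrix), tab$name)
  expect_true(isSymmetric(rep$neighbor_map$matrix))
  expect_true(all(table(tab$region) >= 0))
  expect_true(all(!is.na(tab$region)))
  expect_true(is.finite(rep$regressions$volume$r_squared))
  expect_true(is.finite(rep$regressions$gene_density$r_squared))
})
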