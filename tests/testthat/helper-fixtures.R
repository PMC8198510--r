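# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, fast phantom: eight chromosome types spanning the size range,
# noiseless, fixed seed.
small_karyotype <- c("1", "4", "13", "19", "20", "21", "22", "X", "Y")

small_phantom <- function() {
  cached("small_phantom", function() {
    generate_phantom(phantom_config(noise_sd = 0, seed = 7),
                     karyotype = small_karyotype)
  })
}

small_labels <- function() {
  cached("small_labels", function() {
    segment_stack(small_phantom()$stack, "medium",
                  expected_objects = length(small_karyotype))
  })
}

small_morph <- function() {
  cached("small_morph", function() measure_chromosomes(small_labels()))
}

# The full 46,XY noiseless phantom used by the karyotype-scale checks.
full_phantom <- function() {
  cached("full_phantom", function() {
    generate_phantom(phantom_config(noise_sd = 0, seed = 42))
  })
}

full_labels <- function() {
  cached("full_labels", function() segment_stack(full_phantom()$stack, "medium"))
}

full_morph <- function() {
  cached("full_morph", function() measure_chromosomes(full_labels()))
}

full_assignment <- function() {
  cached("full_assignment", function() assign_karyotype(full_morph()))
}

# Number of seeds (out of 10) for which a strongly biased phantom yields a
# negative gene-density ~ radius regression slope; shared by two test files
# because the ten placements are the most expensive fixture.
radial_bias_negative_count <- function() {
  cached("radial_bias_neg", function() {
    ref <- load_reference()
    slots <- karyotype_slots("XY")
    cfg <- phantom_config(noise_sd = 0, radial_bias = 4, seed = 1)
    negative <- 0L
    for (sd in 1:10) {
      set.seed(sd)
      sol <- karyo3d:::place_karyotype(cfg, ref, slots)
      stopifnot(!is.null(sol))
      rad <- vapply(sol, function(s) sqrt(sum(s$position^2)), numeric(1))
      gd <- ref$gene_density[match(vapply(sol, `[[`, "", "chrom_id"),
                                   ref$chrom_id)]
      if (radial_regression(gd, rad)$slope < 0) negative <- negative + 1L
    }
    negative
  })
}

# Match measured objects to truth rows by centroid (labels are renumbered by
# size during segmentation, so object ids need not line up with truth ids).
match_truth <- function(morph, truth) {
  idx <- vapply(seq_len(nrow(morph)), function(i) {
    which.min((truth$centroid_x_nm - morph$centroid_x_nm[i])^2 +
                (truth$centroid_y_nm - morph$centroid_y_nm[i])^2 +
                (truth$centroid_z_nm - morph$centroid_z_nm[i])^2)
  }, integer(1))
  truth[idx, , drop = FALSE]
}

# Analytic voxelized solids for oracle tests -----------------------------

# A solid of all voxels within `radius` of the segment [a, b] (nm).
voxel_capsule <- function(a, b, radius, dims, voxel_nm) {
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  P <- cbind((idx[, 1] - 0.5) * voxel_nm[1],
             (idx[, 2] - 0.5) * voxel_nm[2],
             (idx[, 3] - 0.5) * voxel_nm[3])
  ab <- b - a
  tt <- pmin(1, pmax(0, ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
                           (P[, 3] - a[3]) * ab[3]) / sum(ab^2)))
  d2 <- (P[, 1] - a[1] - tt * ab[1])^2 + (P[, 2] - a[2] - tt * ab[2])^2 +
    (P[, 3] - a[3] - tt * ab[3])^2
  lab <- array(0L, dims)
  lab[d2 <= radius^2] <- 1L
  attr(lab, "voxel_nm") <- check_spacing_for_test(voxel_nm)
  lab
}

# A flat-ended cylinder (no end caps) along the segment [a, b].
voxel_cylinder <- function(a, b, radius, dims, voxel_nm) {
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  P <- cbind((idx[, 1] - 0.5) * voxel_nm[1],
             (idx[, 2] - 0.5) * voxel_nm[2],
             (idx[, 3] - 0.5) * voxel_nm[3])
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
           (P[, 3] - a[3]) * ab[3]) / len2
  d2 <- (P[, 1] - a[1] - tt * ab[1])^2 + (P[, 2] - a[2] - tt * ab[2])^2 +
    (P[, 3] - a[3] - tt * ab[3])^2
  lab <- array(0L, dims)
  lab[tt >= 0 & tt <= 1 & d2 <= radius^2] <- 1L
  attr(lab, "voxel_nm") <- check_spacing_for_test(voxel_nm)
  lab
}

check_spacing_for_test <- function(voxel_nm) {
  stats::setNames(rep_len(as.numeric(voxel_nm), 3), c("x", "y", "z"))
}

# Brute-force flood fill (pure R) as the independent connected-components
# oracle for small grids.
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  touch <- rowSums(off != 0)
  off <- off[touch > 0 & switch(as.character(connectivity),
                                "6" = touch == 1,
                                "18" = touch <= 2,
                                "26" = touch <= 3), , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      w0 <- cur - 1L
      cx <- w0 %% d[1] + 1L
      cy <- (w0 %/% d[1]) %% d[2] + 1L
      cz <- w0 %/% (d[1] * d[2]) + 1L
      for (k in seq_len(nrow(off))) {
        x <- cx + off[k, 1]; y <- cy + off[k, 2]; z <- cz + off[k, 3]
        if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) next
        j <- x + d[1] * ((y - 1L) + d[2] * (z - 1L))
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}
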