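# Radial organisation and neighborhood mapping: per-chromosome radius from
# the nuclear center of mass, five equal radial regions, volume/gene-density
# regressions, and the symmetric neighbor matrix.

.RADIAL_LEVELS <- c("center", "center-intermediate", "intermediate",
                    "periphery-intermediate", "periphery")

#' Nuclear center of mass and per-object radii
#'
#' The nucleus center is the voxel-count-weighted centroid of all chromosome
#' voxels (in physical nm); each object's radius is the Euclidean distance
#' from its own centroid to that center.
#'
#' @param labels Integer label volume.
#' @param voxel_nm Spacing; default from the labels.
#' @param object_ids Objects to include (default all).
#' @return A list: `center_nm` (length 3) and `radii` (`data.frame` with
#'   `object_id`, `radius_nm`, centroid columns).
#' @export
nucleus_center_and_radii <- function(labels, voxel_nm = NULL,
                                     object_ids = NULL) {
  voxel_nm <- resolve_spacing(labels, voxel_nm)
  if (is.null(object_ids)) object_ids <- sort(unique(labels[labels > 0]))
  if (!length(object_ids)) stop("label volume contains no objects")
  cent <- object_centroids(labels, voxel_nm, object_ids)
  sizes <- vapply(object_ids, function(id) sum(labels == id), 0)
  center <- colSums(cent * sizes) / sum(sizes)
  radii <- sqrt(rowSums(sweep(cent, 2, center)^2))
  list(center_nm = center,
       radii = data.frame(object_id = object_ids, radius_nm = radii,
                          centroid_x_nm = cent[, 1], centroid_y_nm = cent[, 2],
                          centroid_z_nm = cent[, 3]))
}

#' Bin radii into five equal radial regions
#'
#' Partitions `[0, max(radius)]` into `n_bins` equal-width bins, half-open
#' `[lo, hi)` except the outermost which is closed, labeled from `center`
#' (smallest radii) to `periphery` (largest).
#'
#' @param radii Non-negative radii in nm.
#' @param n_bins Number of regions (default 5, the named regions).
#' @return Factor of region labels, levels ordered center to periphery.
#' @export
radial_bins <- function(radii, n_bins = 5) {
  if (any(radii < 0)) stop("radii must be non-negative")
  lv <- if (n_bins == 5) .RADIAL_LEVELS else paste0("region_", seq_len(n_bins))
  rmax <- max(radii)
  if (rmax == 0) {
    return(factor(rep(lv[1], length(radii)), levels = lv))
  }
  idx <- pmin(n_bins, floor(radii / rmax * n_bins) + 1L)
  factor(lv[idx], levels = lv)
}

#' Regression of radial position on a chromosome property
#'
#' Ordinary least squares of radius on volume or gene density;
#' `r_squared` is the squared Pearson correlation (0 when the response or
#' predictor has no variance to explain).
#'
#' @param x Per-chromosome predictor (volume in nm^3, or genes/Mbp).
#' @param y Radii in nm.
#' @return A list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
radial_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("predictor x is constant")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x))
}

# boundary voxels (those with a 6-neighbor outside the object) in physical nm
boundary_points <- function(labels, object_id, voxel_nm) {
  d <- dim(labels)
  w0 <- object_voxels(labels, object_id) - 1L
  x <- w0 %% d[1]
  y <- (w0 %/% d[1]) %% d[2]
  z <- w0 %/% (d[1] * d[2])
  inside <- array(FALSE, dim = d)
  inside[w0 + 1L] <- TRUE
  on_boundary <- logical(length(w0))
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
    off_grid <- xx < 0 | yy < 0 | zz < 0 | xx >= d[1] | yy >= d[2] | zz >= d[3]
    nb <- !off_grid
    flat <- xx[nb] + d[1] * (yy[nb] + d[2] * zz[nb]) + 1L
    out_nb <- logical(length(w0))
    out_nb[nb] <- !inside[flat]
    on_boundary <- on_boundary | off_grid | out_nb
  }
  cbind((x[on_boundary] + 0.5) * voxel_nm[1],
        (y[on_boundary] + 0.5) * voxel_nm[2],
        (z[on_boundary] + 0.5) * voxel_nm[3])
}

#' Chromosome neighborhood map
#'
#' Two chromosomes are spatial neighbors when the minimum surface-to-surface
#' distance is at most `cutoff_nm`. Surfaces are represented by boundary
#' voxel centers, which sit up to one voxel inside the true surface, so the
#' test allows one voxel diagonal on top of the cutoff: objects whose
#' boundary voxel centers are within `cutoff_nm + voxel diagonal` are
#' neighbors (touching objects are neighbors at any cutoff >= 0). The matrix
#' is symmetric with an all-`FALSE` diagonal and monotone in the cutoff.
#' Bounding boxes prune far pairs before the exact point-set distance test.
#'
#' @param labels Integer label volume.
#' @param voxel_nm Spacing; default from the labels.
#' @param cutoff_nm Neighbor distance threshold in nm (default 250).
#' @param names Optional per-object names (e.g. `"1a"`, row order of the
#'   karyotype) used as dimnames.
#' @return A list of class `neighbor_map`: `matrix` (logical, symmetric),
#'   `neighbors` (named list), `cutoff_nm`.
#' @export
neighbor_map <- function(labels, voxel_nm = NULL, cutoff_nm = 250,
                         names = NULL) {
  if (cutoff_nm < 0) stop("cutoff_nm must be >= 0")
  voxel_nm <- resolve_spacing(labels, voxel_nm)
  ids <- sort(unique(labels[labels > 0]))
  k <- length(ids)
  eff <- cutoff_nm + sqrt(sum(voxel_nm^2))
  mat <- matrix(FALSE, k, k)
  if (k > 1) {
    pts <- lapply(ids, boundary_points, labels = labels, voxel_nm = voxel_nm)
    bb_lo <- t(vapply(pts, function(p) apply(p, 2, min), numeric(3)))
    bb_hi <- t(vapply(pts, function(p) apply(p, 2, max), numeric(3)))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        gap <- pmax(bb_lo[j, ] - bb_hi[i, ], bb_lo[i, ] - bb_hi[j, ], 0)
        if (sqrt(sum(gap^2)) > eff) next
        d2 <- min_pairdist_sq_cpp(pts[[i]], pts[[j]], eff^2)
        if (d2 <= eff^2) mat[i, j] <- mat[j, i] <- TRUE
      }
    }
  }
  nm <- if (is.null(names)) as.character(ids) else names
  dimnames(mat) <- list(nm, nm)
  neighbors <- stats::setNames(lapply(seq_len(k), function(i) nm[mat[i, ]]), nm)
  structure(list(matrix = mat, neighbors = neighbors, cutoff_nm = cutoff_nm,
                 object_ids = ids),
            class = "neighbor_map")
}

#' @export
print.neighbor_map <- function(x, ...) {
  cat(sprintf("neighbor_map: %d objects, cutoff %g nm, %d neighbor pair(s)\n",
              nrow(x$matrix), x$cutoff_nm, sum(x$matrix) / 2))
  invisible(x)
}

#' Plot a neighbor map as a heat map
#'
#' @param x A [neighbor_map()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.neighbor_map <- function(x, ...) {
  m <- x$matrix[, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m * 1,
                  col = c("white", "firebrick"), axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("Chromosome neighbors (cutoff %g nm)",
                                 x$cutoff_nm), ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.5)
  graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Full spatial report for an identified nucleus
#'
#' Combines radii, radial regions, the two radial regressions (on volume and
#' on gene density, when an assignment and reference are available), and the
#' neighbor matrix in karyotype row order (1a, 1b, ..., 22b, X, Y).
#'
#' @param labels Integer label volume.
#' @param morph A [measure_chromosomes()] table.
#' @param assignment Optional [assign_karyotype()] result; enables the
#'   gene-density regression and karyotype-ordered output.
#' @param reference A [load_reference()] table.
#' @param voxel_nm Spacing; default from the labels.
#' @param cutoff_nm Neighbor cutoff in nm.
#' @return A list of class `spatial_report`: `center_nm`, `chromosomes`
#'   (radius, region, per-object names), `regressions`, `neighbor_map`.
#' @export
spatial_report <- function(labels, morph, assignment = NULL,
                           reference = load_reference(), voxel_nm = NULL,
                           cutoff_nm = 250) {
  voxel_nm <- resolve_spacing(labels, voxel_nm)
  cr <- nucleus_center_and_radii(labels, voxel_nm)
  tab <- cr$radii
  tab$region <- radial_bins(tab$radius_nm)

  ord <- seq_len(nrow(tab))
  if (!is.null(assignment)) {
    m <- match(tab$object_id, assignment$object_id)
    tab$chrom_id <- assignment$chrom_id[m]
    tab$homolog <- assignment$homolog[m]
    tab$name <- paste0(tab$chrom_id, ifelse(is.na(tab$homolog), "",
                                            tab$homolog))
    ord <- order(match(tab$chrom_id, .CHROM_LEVELS), tab$homolog)
    tab <- tab[ord, ]
  } else {
    tab$name <- as.character(tab$object_id)
  }

  vol <- morph$volume_nm3[match(tab$object_id, morph$object_id)]
  regressions <- list(volume = radial_regression(vol, tab$radius_nm))
  if (!is.null(assignment)) {
    gd <- reference$gene_density[match(tab$chrom_id, reference$chrom_id)]
    regressions$gene_density <- radial_regression(gd, tab$radius_nm)
  }

  nmap <- neighbor_map(labels, voxel_nm, cutoff_nm)
  perm <- match(tab$object_id, nmap$object_ids)
  nmap$matrix <- nmap$matrix[perm, perm, drop = FALSE]
  dimnames(nmap$matrix) <- list(tab$name, tab$name)
  nmap$neighbors <- stats::setNames(
    lapply(seq_len(nrow(nmap$matrix)), function(i) tab$name[nmap$matrix[i, ]]),
    tab$name)
  nmap$object_ids <- tab$object_id

  structure(list(center_nm = cr$center_nm, chromosomes = tab,
                 regressions = regressions, neighbor_map = nmap,
                 cutoff_nm = cutoff_nm),
            class = "spatial_report")
}

#' @export
print.spatial_report <- function(x, ...) {
  cat(sprintf("spatial_report: %d chromosomes, nucleus center (%.0f, %.0f, %.0f) nm\n",
              nrow(x$chromosomes), x$center_nm[1], x$center_nm[2],
              x$center_nm[3]))
  cat(sprintf("  radius ~ volume:       R^2 = %.3f (slope %.3g)\n",
              x$regressions$volume$r_squared, x$regressions$volume$slope))
  if (!is.null(x$regressions$gene_density)) {
    cat(sprintf("  radius ~ gene density: R^2 = %.3f (slope %.3g)\n",
                x$regressions$gene_density$r_squared,
                x$regressions$gene_density$slope))
  }
  print(table(x$chromosomes$region))
  invisible(x)
}
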