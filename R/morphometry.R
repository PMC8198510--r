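# Per-object morphometry: volume, geodesic centerline arm lengths,
# centromere localisation, centromere index, diameter, DNA content and
# genome-percentage normalisations.

#' Convert chromosome volume to DNA content
#'
#' Divides the volume by 5.80 nm^3 per base pair (the packing density of the
#' chromosomal protein--DNA complex) and by 1e6 to express the result in Mbp.
#'
#' @param volume_nm3 Non-negative volume(s) in nm^3.
#' @return DNA content in Mbp.
#' @examples
#' dna_from_volume(5.80e6)  # exactly 1 Mbp
#' @export
dna_from_volume <- function(volume_nm3) {
  if (any(!is.finite(volume_nm3)) || any(volume_nm3 < 0)) {
    stop("volume_nm3 must be finite and non-negative")
  }
  volume_nm3 / NM3_PER_BP / 1e6
}

object_voxels <- function(labels, object_id) {
  w <- which(labels == object_id)
  if (!length(w)) stop("object ", object_id, " not present in label volume")
  w
}

resolve_spacing <- function(labels, voxel_nm) {
  if (is.null(voxel_nm)) voxel_nm <- attr(labels, "voxel_nm")
  check_spacing(voxel_nm)
}

# Crop an object to its padded bounding box; returns local mask, offset and
# dims for kernel calls.
crop_object <- function(labels, object_id) {
  d <- dim(labels)
  w0 <- object_voxels(labels, object_id) - 1L
  x <- w0 %% d[1]
  y <- (w0 %/% d[1]) %% d[2]
  z <- w0 %/% (d[1] * d[2])
  lo <- c(max(min(x) - 1L, 0L), max(min(y) - 1L, 0L), max(min(z) - 1L, 0L))
  hi <- c(min(max(x) + 1L, d[1] - 1L), min(max(y) + 1L, d[2] - 1L),
          min(max(z) + 1L, d[3] - 1L))
  cd <- hi - lo + 1L
  mask <- logical(prod(cd))
  lx <- x - lo[1]; ly <- y - lo[2]; lz <- z - lo[3]
  flat <- lx + cd[1] * (ly + cd[2] * lz) + 1L
  mask[flat] <- TRUE
  list(mask = mask, dims = cd, offset = lo, flat = flat)
}

#' Chromosome axis (skeleton) and tip-to-tip length of one object
#'
#' Extracts the central axis of a labeled object as a smooth principal
#' curve: the voxel cloud is rotated into its principal-component frame, the
#' two transverse coordinates are regressed on the axial one with quadratic
#' polynomials (capturing the gentle bow of a bent chromosome), and the
#' fitted curve is sampled densely. Every voxel's axial arc position is the
#' cumulative arc length of the curve at its own axial coordinate, so the
#' tip-to-tip length -- the arc spanned by the extreme voxels -- is
#' insensitive to the lateral width of the object and to how the two merged
#' sister chromatids wrap the common axis. Suited to the gently curved
#' rod-shaped chromosomes in scope; not to strongly folded shapes.
#'
#' @param labels Integer label volume.
#' @param object_id Object to trace.
#' @param voxel_nm Spacing (x, y, z) in nm; default from the labels.
#' @param degree Degree of the transverse drift polynomials (default 2).
#' @return A list: `polyline_nm` (curve vertices, nm), `arc_nm` (arc position
#'   of each vertex, 0 at the first tip), `radius_nm` (local object radius
#'   from the distance transform at the nearest voxel to each vertex),
#'   `length_nm` (tip-to-tip arc length), `voxel_arc_nm` (axial arc position
#'   of every object voxel, in `[0, length_nm]`).
#' @export
skeleton_longest_path <- function(labels, object_id, voxel_nm = NULL,
                                  degree = 2) {
  voxel_nm <- resolve_spacing(labels, voxel_nm)
  cr <- crop_object(labels, object_id)
  edt <- edt_sq_cpp(cr$mask, cr$dims, voxel_nm)
  radius <- sqrt(edt[cr$flat])

  w0 <- cr$flat - 1L
  V <- cbind(
    ((w0 %% cr$dims[1]) + cr$offset[1] + 0.5) * voxel_nm[1],
    (((w0 %/% cr$dims[1]) %% cr$dims[2]) + cr$offset[2] + 0.5) * voxel_nm[2],
    ((w0 %/% (cr$dims[1] * cr$dims[2])) + cr$offset[3] + 0.5) * voxel_nm[3]
  )
  n <- nrow(V)
  if (n < 2) {
    return(list(polyline_nm = V, arc_nm = 0, radius_nm = radius,
                length_nm = 0, voxel_arc_nm = rep(0, n)))
  }

  ctr <- colMeans(V)
  X <- sweep(V, 2, ctr)
  rot <- svd(X, nu = 0, nv = 3)$v
  s <- drop(X %*% rot[, 1])
  span <- diff(range(s))
  if (span <= 0) {
    return(list(polyline_nm = V[1, , drop = FALSE], arc_nm = 0,
                radius_nm = radius[1], length_nm = 0,
                voxel_arc_nm = rep(0, n)))
  }

  # transverse drift of the axis as low-order polynomials of s
  deg <- min(degree, n - 1)
  B <- stats::poly(s, deg, raw = TRUE)
  f2 <- stats::lm.fit(cbind(1, B), drop(X %*% rot[, 2]))$coefficients
  f3 <- stats::lm.fit(cbind(1, B), drop(X %*% rot[, 3]))$coefficients
  f2[is.na(f2)] <- 0
  f3[is.na(f3)] <- 0

  ns <- max(11L, as.integer(ceiling(span / max(voxel_nm))))
  s_g <- seq(min(s), max(s), length.out = ns)
  Bg <- cbind(1, stats::poly(s_g, deg, raw = TRUE))
  curve <- sweep(outer(s_g, rot[, 1]) +
                   outer(drop(Bg %*% f2), rot[, 2]) +
                   outer(drop(Bg %*% f3), rot[, 3]), 2, ctr, "+")

  arc_c <- c(0, cumsum(sqrt(rowSums(diff(curve)^2))))
  voxel_arc <- stats::approx(s_g, arc_c, xout = s, rule = 2)$y

  # local radius at each curve vertex = distance transform at nearest voxel
  rad_c <- vapply(seq_len(nrow(curve)), function(i) {
    d2 <- (V[, 1] - curve[i, 1])^2 + (V[, 2] - curve[i, 2])^2 +
      (V[, 3] - curve[i, 3])^2
    radius[which.min(d2)]
  }, numeric(1))

  list(polyline_nm = curve, arc_nm = arc_c, radius_nm = rad_c,
       length_nm = arc_c[length(arc_c)], voxel_arc_nm = voxel_arc)
}

#' Locate the centromere on a skeleton radius profile
#'
#' The centromere is the constriction separating the two arms: the minimum
#' of the (smoothed) local-radius profile sampled along the skeleton,
#' restricted to the central portion of the arc so telomeric taper is not
#' mistaken for a constriction. Ties go to the position nearer the skeleton
#' midpoint. A profile without a constriction deeper than `min_depth`
#' (relative) is flagged unreliable; if `fallback_ci` is supplied the
#' canonical centromere index is used instead.
#'
#' @param radius_nm Local radius along the skeleton (from
#'   [skeleton_longest_path()]).
#' @param arc_nm Cumulative arc length, same length as `radius_nm`.
#' @param window Arc-length fraction window searched (default central
#'   14--86%: wide enough to reach acrocentric centromeres, whose canonical
#'   index lies below 20, while still excluding the telomeric taper of the
#'   rounded chromatid ends).
#' @param smooth_k Moving-average window (samples) applied before the search.
#' @param min_depth Minimum relative depth `(max - min) / max` of the
#'   constriction inside the window for a reliable call.
#' @param fallback_ci Canonical centromere index (percent) used when the
#'   profile is flat.
#' @return A list: `arc_position_nm`, `p_len_nm`, `q_len_nm`, `ci_percent`,
#'   `reliable`.
#' @export
locate_centromere <- function(radius_nm, arc_nm, window = c(0.14, 0.86),
                              smooth_k = 3, min_depth = 0.08,
                              fallback_ci = NULL) {
  n <- length(radius_nm)
  L <- arc_nm[n]
  if (n < 3 || L <= 0) {
    return(list(arc_position_nm = NA_real_, p_len_nm = 0, q_len_nm = L,
                ci_percent = NA_real_, reliable = FALSE))
  }
  sm <- stats::filter(radius_nm, rep(1 / smooth_k, smooth_k), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- radius_nm[is.na(sm)]
  frac <- arc_nm / L
  inside <- which(frac >= window[1] & frac <= window[2])
  if (!length(inside)) inside <- seq_len(n)
  depth <- (max(sm[inside]) - min(sm[inside])) / max(sm[inside])
  reliable <- is.finite(depth) && depth >= min_depth
  if (!reliable && !is.null(fallback_ci)) {
    s_c <- fallback_ci / 100 * L
  } else {
    cand <- inside[sm[inside] <= min(sm[inside]) + 1e-9]
    i_min <- cand[which.min(abs(arc_nm[cand] - L / 2))]
    s_c <- arc_nm[i_min]
    if ((i_min - 1L) %in% inside && (i_min + 1L) %in% inside) {
      # parabolic sub-sample refinement of the constriction position
      y0 <- sm[i_min - 1]; y1 <- sm[i_min]; y2 <- sm[i_min + 1]
      denom <- y0 - 2 * y1 + y2
      if (is.finite(denom) && denom > 0) {
        delta <- max(-1, min(1, 0.5 * (y0 - y2) / denom))
        step <- (arc_nm[min(n, i_min + 1)] - arc_nm[max(1, i_min - 1)]) / 2
        s_c <- s_c + delta * step
      }
    }
  }
  p <- min(s_c, L - s_c)
  q <- L - p
  list(arc_position_nm = s_c, p_len_nm = p, q_len_nm = q,
       ci_percent = 100 * p / L, reliable = reliable)
}

#' Measure one labeled chromosome object
#'
#' Computes volume (voxel count times voxel volume), the geodesic-centerline
#' tip-to-tip length split into p (shorter) and q (longer) arms at the
#' centromere, centromere index by length and by volume, mean diameter
#' (twice the mean distance-transform radius along the skeleton), DNA
#' content and centroid.
#'
#' The centromere is localised on the object's cross-section profile: every
#' voxel is assigned its axial arc coordinate on the principal-curve skeleton
#' (see [skeleton_longest_path()]), the per-arc cross-section area (voxel
#' volume per unit arc) is converted to an equivalent-circle radius, and
#' [locate_centromere()] finds the constriction on that profile. The axial
#' coordinate makes the constriction search insensitive to how the two
#' merged sister chromatids wrap the common axis. The same coordinate
#' partitions voxels into p-arm and q-arm volumes (a curvature-aware version
#' of cutting with a plane orthogonal to the local tangent at the
#' centromere).
#'
#' @inheritParams skeleton_longest_path
#' @param expected_ci Optional canonical centromere index used as a fallback
#'   when no constriction is detectable.
#' @return A one-row `data.frame` with the `chromosome_morphometry` columns.
#' @export
measure_chromosome <- function(labels, object_id, voxel_nm = NULL,
                               expected_ci = NULL) {
  voxel_nm <- resolve_spacing(labels, voxel_nm)
  vox <- object_voxels(labels, object_id)
  vol <- length(vox) * prod(voxel_nm)
  skel <- skeleton_longest_path(labels, object_id, voxel_nm)

  d <- dim(labels)
  w0 <- vox - 1L
  vx <- ((w0 %% d[1]) + 0.5) * voxel_nm[1]
  vy <- (((w0 %/% d[1]) %% d[2]) + 0.5) * voxel_nm[2]
  vz <- ((w0 %/% (d[1] * d[2])) + 0.5) * voxel_nm[3]

  np <- nrow(skel$polyline_nm)
  if (np >= 3 && skel$length_nm > 0) {
    # cross-section area profile over the axial arc coordinate, estimated
    # with a Gaussian kernel so the profile is not quantised to voxel planes
    L <- skel$length_nm
    s_vox <- skel$voxel_arc_nm
    h <- 0.75 * max(voxel_nm)
    grid <- seq(0, L, length.out = max(11L, as.integer(2 * L / max(voxel_nm))))
    area <- vapply(grid, function(g)
      sum(stats::dnorm(s_vox, g, h)) * prod(voxel_nm), numeric(1))
    r_eff <- sqrt(area / pi)
    cen <- locate_centromere(r_eff, grid, smooth_k = 1,
                             fallback_ci = expected_ci)
    if (!is.na(cen$arc_position_nm)) {
      # p/q by length over the full [0, L] arc (bin centers span slightly less)
      s_c <- cen$arc_position_nm
      cen$p_len_nm <- min(s_c, L - s_c)
      cen$q_len_nm <- L - cen$p_len_nm
      cen$ci_percent <- 100 * cen$p_len_nm / L
    }
  } else {
    cen <- locate_centromere(skel$radius_nm, skel$arc_nm,
                             fallback_ci = expected_ci)
    s_vox <- NULL
  }

  if (!is.na(cen$arc_position_nm) && !is.null(s_vox)) {
    start_vol <- sum(s_vox <= cen$arc_position_nm) * prod(voxel_nm)
    p_is_start <- cen$arc_position_nm <= skel$length_nm / 2
    p_vol <- if (p_is_start) start_vol else vol - start_vol
    q_vol <- vol - p_vol
  } else {
    p_vol <- NA_real_; q_vol <- NA_real_
  }

  data.frame(
    object_id = object_id,
    volume_nm3 = vol,
    p_len_nm = cen$p_len_nm,
    q_len_nm = cen$q_len_nm,
    total_len_nm = cen$p_len_nm + cen$q_len_nm,
    ci_len_percent = cen$ci_percent,
    p_vol_nm3 = p_vol,
    q_vol_nm3 = q_vol,
    ci_vol_percent = if (is.na(p_vol)) NA_real_ else 100 * p_vol / vol,
    ci_reliable = cen$reliable || !is.null(expected_ci),
    dna_mbp = dna_from_volume(vol),
    mean_diameter_nm = mean_diameter(skel),
    centroid_x_nm = mean(vx),
    centroid_y_nm = mean(vy),
    centroid_z_nm = mean(vz),
    stringsAsFactors = FALSE
  )
}

# Twice the mean distance-transform radius along the central 20--80% of the
# skeleton arc (the telomeric taper would bias a full-arc mean downward).
mean_diameter <- function(skel) {
  arc <- skel$arc_nm
  L <- max(arc)
  sel <- arc >= 0.2 * L & arc <= 0.8 * L
  if (sum(sel) < 3) sel <- rep(TRUE, length(arc))
  2 * mean(skel$radius_nm[sel])
}

#' Measure every object in a label volume
#'
#' Runs [measure_chromosome()] on each labeled object and appends the
#' genome-percentage normalisations.
#'
#' @inheritParams skeleton_longest_path
#' @param object_ids Objects to measure (default: all).
#' @return A `data.frame` of class `chromosome_morphometry`, one row per
#'   object, with `len_percent_of_genome` and `vol_percent_of_genome` each
#'   summing to 100.
#' @export
measure_chromosomes <- function(labels, voxel_nm = NULL, object_ids = NULL) {
  voxel_nm <- resolve_spacing(labels, voxel_nm)
  if (is.null(object_ids)) {
    object_ids <- sort(unique(labels[labels > 0]))
  }
  if (!length(object_ids)) stop("label volume contains no objects")
  rows <- lapply(object_ids, function(id)
    measure_chromosome(labels, id, voxel_nm))
  morph <- do.call(rbind, rows)
  morph <- genome_percentages(morph)
  attr(morph, "voxel_nm") <- voxel_nm
  class(morph) <- c("chromosome_morphometry", "data.frame")
  morph
}

#' Genome-percentage normalisations
#'
#' Expresses each chromosome's length and volume as a percentage of the
#' summed length/volume of all chromosomes in the nucleus; each column sums
#' to exactly 100.
#'
#' @param morph A morphometry `data.frame` with `total_len_nm` and
#'   `volume_nm3`.
#' @return The input with `len_percent_of_genome` and
#'   `vol_percent_of_genome` columns filled in.
#' @export
genome_percentages <- function(morph) {
  if (nrow(morph) < 1) stop("need at least one measured chromosome")
  tot_len <- sum(morph$total_len_nm)
  tot_vol <- sum(morph$volume_nm3)
  if (tot_len <= 0 || tot_vol <= 0) {
    stop("total length/volume is zero; cannot normalise")
  }
  morph$len_percent_of_genome <- 100 * morph$total_len_nm / tot_len
  morph$vol_percent_of_genome <- 100 * morph$volume_nm3 / tot_vol
  morph
}

#' @export
print.chromosome_morphometry <- function(x, ...) {
  cat(sprintf(
    "chromosome_morphometry: %d object(s), total volume %.3g nm^3 (%.1f Mbp)\n",
    nrow(x), sum(x$volume_nm3), sum(x$dna_mbp)))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
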