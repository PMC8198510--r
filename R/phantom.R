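# Synthetic prophase-nucleus phantom: 46 paired-chromatid chromosome solids
# inside a 7.2 um sphere, rendered as a 16-bit stack whose three contrast
# bands carve nested envelopes, with a full ground-truth table.

NM3_PER_BP <- 5.80

#' Phantom generator configuration
#'
#' Defaults emulate the acquisition geometry of a serial block-face EM stack
#' of a single prophase lymphocyte nucleus: a 7.2 um spherical nucleus,
#' anisotropic voxels, a bright chromatid axis (intensity 41000) falling off
#' quadratically to the chromatid edge (37550) and a nucleoplasm background
#' (33000), so that the narrow/medium/wide band presets select nested
#' envelopes. The default grid is the coarse 44 x 44 x 100 nm one (a phantom
#' builds in seconds); the acquisition-resolution 11 x 11 x 25 nm grid is
#' selected via `voxel_nm`.
#'
#' @param voxel_nm Voxel spacing (x, y, z) in nm. Default `c(44, 44, 100)`;
#'   full resolution is `c(11, 11, 25)`.
#' @param nucleus_diameter_nm Nuclear sphere diameter (default 7200).
#' @param volume_scale Unitless multiplier on reference chromosome volumes.
#' @param axis_level,edge_level,background_level 16-bit intensities of the
#'   chromatid axis, chromatid surface, and nucleoplasm.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units); 0 gives a noiseless phantom.
#' @param radial_bias Strength `beta >= 0` of gene-density-dependent interior
#'   placement; 0 (default) places chromosomes uniformly.
#' @param bend_deg Maximum total arc curvature of a chromosome centerline in
#'   degrees.
#' @param seed RNG seed; the whole phantom is a pure function of
#'   (config, seed).
#' @param chromatid_radius_nm Radius of one chromatid capsule (default 230,
#'   giving a ~0.83 um chromosome width across the partially merged pair).
#' @param chromatid_separation_nm Distance between the two sister-chromatid
#'   axes; the default `1.5 * chromatid_radius_nm` merges the capsules over a
#'   wide contact zone (condensed prophase chromatids touch along their
#'   length rather than at a tangent line), which also keeps the object
#'   robustly 26-connected after thresholding.
#' @param constriction_factor Radius multiplier at the centromeric waist.
#' @param constriction_rel_width Waist half-width as a fraction of the
#'   chromatid centerline length (capped at 250 nm).
#' @param clearance_nm Minimum surface-to-surface distance enforced between
#'   different chromosomes (must exceed one voxel diagonal so segmentation is
#'   well posed).
#' @param wall_clearance_nm Minimum clearance to the nuclear envelope.
#' @param karyotype `"XY"` (default) or `"XX"`.
#' @param max_sweeps Relaxation sweep budget for one packing attempt.
#' @param max_restarts Re-seeded packing restarts before giving up.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(voxel_nm = c(44, 44, 100),
                           nucleus_diameter_nm = 7200,
                           volume_scale = 1.0,
                           axis_level = 41000,
                           edge_level = 37550,
                           background_level = 33000,
                           noise_sd = 150,
                           radial_bias = 0,
                           bend_deg = 20,
                           seed = 42L,
                           chromatid_radius_nm = 230,
                           chromatid_separation_nm = NULL,
                           constriction_factor = 0.7,
                           constriction_rel_width = 0.18,
                           clearance_nm = 135,
                           wall_clearance_nm = 60,
                           karyotype = c("XY", "XX"),
                           max_sweeps = 12000L,
                           max_restarts = 20L) {
  cfg <- list(
    voxel_nm = check_spacing(voxel_nm),
    nucleus_diameter_nm = nucleus_diameter_nm,
    volume_scale = volume_scale,
    axis_level = axis_level,
    edge_level = edge_level,
    background_level = background_level,
    noise_sd = noise_sd,
    radial_bias = radial_bias,
    bend_deg = bend_deg,
    seed = as.integer(seed),
    chromatid_radius_nm = chromatid_radius_nm,
    chromatid_separation_nm = if (is.null(chromatid_separation_nm))
      1.5 * chromatid_radius_nm else chromatid_separation_nm,
    constriction_factor = constriction_factor,
    constriction_rel_width = constriction_rel_width,
    clearance_nm = clearance_nm,
    wall_clearance_nm = wall_clearance_nm,
    karyotype = match.arg(karyotype),
    max_sweeps = as.integer(max_sweeps),
    max_restarts = as.integer(max_restarts)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  bands <- band_presets()
  if (cfg$background_level >= bands$narrow[1]) {
    stop("background_level must lie below the narrow-band minimum")
  }
  if (cfg$edge_level >= bands$medium[1]) {
    stop("edge_level must lie below the medium-band minimum")
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (cfg$axis_level < b[1] || cfg$axis_level > b[2]) {
      stop("axis_level must fall inside the ", nm, " band preset")
    }
  }
  if (cfg$axis_level <= cfg$edge_level ||
      cfg$edge_level <= cfg$background_level) {
    stop("intensity levels must satisfy background < edge < axis")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$radial_bias < 0) stop("radial_bias must be >= 0")
  if (cfg$bend_deg < 0 || cfg$bend_deg >= 180) {
    stop("bend_deg must lie in [0, 180)")
  }
  diag_nm <- sqrt(sum(cfg$voxel_nm^2))
  if (cfg$clearance_nm <= diag_nm) {
    stop(sprintf(
      "clearance_nm (%g) must exceed one voxel diagonal (%.1f nm) so that ",
      cfg$clearance_nm, diag_nm),
      "distinct chromosomes cannot touch under 26-connectivity")
  }
  if (cfg$nucleus_diameter_nm <= 6 * cfg$chromatid_radius_nm) {
    stop("nucleus too small for the configured chromatid radius")
  }
  if (cfg$chromatid_separation_nm <= 0 ||
      cfg$chromatid_separation_nm > 2 * cfg$chromatid_radius_nm) {
    stop("chromatid_separation_nm must lie in (0, 2 * chromatid_radius_nm] ",
         "so the sister chromatids stay merged")
  }
  invisible(TRUE)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Cross-section area of two merged circles of radius r, centers d apart.
pair_cross_section <- function(r, d) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# Union volume of the two hemispherical cap pairs at both chromatid ends.
pair_cap_volume <- function(r, d) {
  if (d >= 2 * r) return(2 * (4 / 3) * pi * r^3)
  lens3 <- pi * (4 * r + d) * (2 * r - d)^2 / 12  # sphere-sphere lens
  2 * (4 / 3) * pi * r^3 - lens3
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "phantom_config: nucleus %.1f um, voxel (%g, %g, %g) nm, %s karyotype\n",
    x$nucleus_diameter_nm / 1000, x$voxel_nm[1], x$voxel_nm[2], x$voxel_nm[3],
    x$karyotype))
  cat(sprintf(
    "  levels axis/edge/background = %g/%g/%g, noise_sd = %g, beta = %g, seed = %d\n",
    x$axis_level, x$edge_level, x$background_level, x$noise_sd,
    x$radial_bias, x$seed))
  invisible(x)
}

# Run `expr` under a private RNG stream, restoring the caller's state.
with_phantom_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Radius multiplier along the tip-to-tip arc: a Gaussian waist of depth
# (1 - constriction_factor) at the centromere.
constriction_profile <- function(s, s_c, w, factor) {
  1 - (1 - factor) * exp(-((s - s_c) / w)^2)
}

#' Build one paired-chromatid chromosome solid
#'
#' Constructs the geometry of a single prophase chromosome: two parallel,
#' touching capsule-shaped sister chromatids sharing a common (optionally
#' gently curved) centerline direction, with a radius constriction at the
#' centromere placed so that the short-arm fraction of the tip-to-tip length
#' equals the canonical centromere index. The chromatid centerline length is
#' calibrated so the rendered solid's volume equals
#' `volume_scale * mbp * 1e6 * 5.80` nm^3 (the DNA-to-volume conversion), with
#' analytic correction for the end caps and the centromeric waist.
#'
#' Geometry is built in a random orientation about the origin; consumes RNG.
#'
#' @param entry One row of a [load_reference()] table.
#' @param config A [phantom_config()].
#' @param volume_factor Extra multiplier (homolog jitter).
#' @return A list with `segments` (matrices `p1`, `p2` and radii `r1`, `r2`
#'   describing both chromatids), the shared `centerline` polyline, tip-to-tip
#'   `length_nm`, arm lengths `p_len_nm`/`q_len_nm`, `ci_percent`,
#'   `radius_nm`, and the analytic `target_volume_nm3`.
#' @export
make_chromosome_solid <- function(entry, config, volume_factor = 1) {
  r <- config$chromatid_radius_nm
  sep <- config$chromatid_separation_nm
  V <- config$volume_scale * entry$mbp * 1e6 * NM3_PER_BP * volume_factor
  a <- 1 - config$constriction_factor
  A <- pair_cross_section(r, sep)
  caps <- pair_cap_volume(r, sep)

  Lc <- (V - caps) / A
  if (!is.finite(Lc) || Lc <= 0) {
    stop("chromosome ", entry$chrom_id,
         " is too small to form a chromatid rod at this volume scale")
  }
  for (i in 1:3) {  # waist width depends on Lc; fixed point in 2-3 steps
    w <- min(250, config$constriction_rel_width * Lc)
    deficit <- A * a * w * (2 * sqrt(pi) - a * sqrt(pi / 2))
    Lc <- (V - caps + deficit) / A
  }
  L <- Lc + 2 * r  # nominal tip-to-tip extent including hemispherical caps

  max_len <- config$nucleus_diameter_nm -
    2 * (r + config$wall_clearance_nm)
  if (L > max_len) {
    stop("chromosome ", entry$chrom_id,
         " is too large for the nucleus at the configured scale (extent ",
         round(L), " nm > ", round(max_len), " nm)")
  }

  ci <- entry$canonical_ci
  # Waist arc position: the waist's Gaussian tail shrinks the p-side end-cap
  # radius (and with it the true tip position), so solve for the position
  # whose realized short-arm fraction equals the canonical index.
  s_c <- ci / 100 * L
  for (i in 1:4) {
    m1 <- constriction_profile(r + 0, s_c, w, config$constriction_factor)
    mN <- constriction_profile(r + Lc, s_c, w, config$constriction_factor)
    L_tmp <- Lc + r * (m1 + mN)
    s_c <- ci / 100 * L_tmp + r - r * m1
  }

  # centerline: circular arc with total turning angle theta in a random plane
  theta <- runif(1, 0, config$bend_deg) * pi / 180
  n_pts <- max(12L, ceiling(Lc / (2 * r)) * 4L)
  s_axis <- seq(0, Lc, length.out = n_pts)
  if (theta < 1e-6) {
    pts <- cbind(s_axis, 0, 0)
  } else {
    Ra <- Lc / theta
    ang <- s_axis / Ra
    pts <- cbind(Ra * sin(ang), Ra * (1 - cos(ang)), 0)
  }
  rot <- random_rotation()
  pts <- pts %*% t(rot)
  normal <- c(rot[1, 3], rot[2, 3], rot[3, 3])  # bend-plane normal

  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)

  # per-point radius from the constriction profile (arc includes the cap)
  s_pt <- r + s_axis
  rho <- r * constriction_profile(s_pt, s_c, w, config$constriction_factor)

  # the renderer caps each chain end with a sphere of the local radius, so
  # the exact rendered extent (and the truth lengths) use those end radii
  L_true <- Lc + rho[1] + rho[n_pts]
  p_true <- s_c - r + rho[1]

  offs <- normal * sep
  chromatid_a <- pts
  chromatid_b <- sweep(pts, 2, offs, "+")
  seg_from <- seq_len(n_pts - 1L)
  p1 <- rbind(chromatid_a[seg_from, , drop = FALSE],
              chromatid_b[seg_from, , drop = FALSE])
  p2 <- rbind(chromatid_a[seg_from + 1L, , drop = FALSE],
              chromatid_b[seg_from + 1L, , drop = FALSE])
  r1 <- c(rho[seg_from], rho[seg_from])
  r2 <- c(rho[seg_from + 1L], rho[seg_from + 1L])

  list(
    segments = list(p1 = p1, p2 = p2, r1 = r1, r2 = r2),
    centerline = pts,
    chromatid_offset = offs,
    length_nm = L_true,
    p_len_nm = min(p_true, L_true - p_true),
    q_len_nm = max(p_true, L_true - p_true),
    ci_percent = 100 * min(p_true, L_true - p_true) / L_true,
    radius_nm = r,
    target_volume_nm3 = V
  )
}

# Placement of all karyotype slots inside the nuclear sphere: seeded random
# initial positions (largest chromosome first, gene-density radial bias
# applied at this stage) followed by pairwise repulsive relaxation over the
# exact chromatid-centerline segment geometry. The enforced centerline
# separation is annealed upward in stages (inflation); any two chromosomes
# closer than the current target are translated -- and torqued -- apart along
# their minimum-distance vector, and chromosomes poking through the nuclear
# wall are pushed back inside, until no violations remain at the full
# threshold 2 * chromatid_radius + clearance. Returns NULL on failure
# (caller restarts with a fresh substream).
place_karyotype <- function(config, reference, karyotype,
                            max_sweeps = config$max_sweeps) {
  if (length(karyotype) == 0L) return(list())
  idx <- match(karyotype, reference$chrom_id)
  if (anyNA(idx)) {
    stop("karyotype contains unknown chromosome(s): ",
         paste(unique(karyotype[is.na(idx)]), collapse = ", "))
  }
  ord <- order(-reference$mbp[idx], karyotype)
  slots <- karyotype[ord]
  n <- length(slots)

  R_nuc <- config$nucleus_diameter_nm / 2
  r <- config$chromatid_radius_nm
  g_max <- max(reference$gene_density)
  thr <- 2 * r + config$clearance_nm
  r_allow <- R_nuc - r - config$wall_clearance_nm

  # homolog bookkeeping per slot: first slot of each pair is 'a' and carries
  # the larger half of the pair's volume jitter delta ~ U(0.005, 0.03)
  homolog <- character(n)
  vf <- numeric(n)
  for (chrom in unique(slots)) {
    w <- which(slots == chrom)
    delta <- runif(1, 0.005, 0.03)
    homolog[w[1]] <- "a"
    vf[w[1]] <- 1 + delta / 2
    if (length(w) > 1) {
      homolog[w[2]] <- "b"
      vf[w[2]] <- 1 - delta / 2
    }
  }

  solids <- vector("list", n)
  seg1 <- vector("list", n)  # global segment endpoints, both chromatids
  seg2 <- vector("list", n)

  sample_position <- function(g_norm) {
    repeat {
      pos <- runif(3, -R_nuc, R_nuc)
      if (sum(pos^2) > R_nuc^2) next
      if (config$radial_bias > 0) {
        p_acc <- exp(-config$radial_bias * g_norm *
                       sqrt(sum(pos^2)) / R_nuc)
        if (runif(1) > p_acc) next
      }
      return(pos)
    }
  }

  init_slot <- function(i) {
    chrom <- slots[i]
    entry <- reference[reference$chrom_id == chrom, ]
    solid <- make_chromosome_solid(entry, config, volume_factor = vf[i])
    pos <- sample_position(entry$gene_density / g_max)
    solid$position <- pos
    solid$chrom_id <- chrom
    solid$homolog <- homolog[i]
    solid$rot_extra <- diag(3)
    solids[[i]] <<- solid
    seg1[[i]] <<- sweep(solid$segments$p1, 2, pos, "+")
    seg2[[i]] <<- sweep(solid$segments$p2, 2, pos, "+")
  }

  shift_slot <- function(i, v) {
    seg1[[i]] <<- sweep(seg1[[i]], 2, v, "+")
    seg2[[i]] <<- sweep(seg2[[i]], 2, v, "+")
    solids[[i]]$position <<- solids[[i]]$position + v
  }

  # small rigid rotation about the solid's centroid (Rodrigues formula);
  # rotations are accumulated and applied to the geometry at render time
  rotate_slot <- function(i, axis, angle) {
    nrm <- sqrt(sum(axis^2))
    if (nrm < 1e-12 || abs(angle) < 1e-6) return(invisible())
    k <- axis / nrm
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
    ctr <- solids[[i]]$position
    seg1[[i]] <<- sweep(sweep(seg1[[i]], 2, ctr) %*% t(R), 2, ctr, "+")
    seg2[[i]] <<- sweep(sweep(seg2[[i]], 2, ctr) %*% t(R), 2, ctr, "+")
    solids[[i]]$rot_extra <<- R %*% solids[[i]]$rot_extra
  }

  fix_wall <- function(i) {
    rad2 <- pmax(rowSums(seg1[[i]]^2), rowSums(seg2[[i]]^2))
    m <- sqrt(max(rad2))
    if (m > r_allow) {
      # push back to a strictly interior position (hysteresis) so pair
      # pushes and the wall do not trade the same violation forever
      w <- which.max(rad2)
      pt <- if (sum(seg1[[i]][w, ]^2) >= sum(seg2[[i]][w, ]^2))
        seg1[[i]][w, ] else seg2[[i]][w, ]
      shift_slot(i, -pt / m * (m - (r_allow - 40)))
      TRUE
    } else FALSE
  }

  for (i in seq_len(n)) init_slot(i)

  # inflation annealing: enforce a gradually growing separation target, each
  # time pushing violating pairs slightly past it (hysteresis), so the
  # packing decompresses smoothly instead of oscillating at full density
  viol_count <- integer(n)
  stages <- c(0.55, 0.7, 0.8, 0.87, 0.92, 0.96, 1.0, 1.04)
  sweeps_used <- 0L
  for (m in stages) {
    target <- m * thr
    target2 <- target^2
    settle <- target * 1.04
    stage_sweeps <- 0L
    repeat {
      sweeps_used <- sweeps_used + 1L
      stage_sweeps <- stage_sweeps + 1L
      if (sweeps_used > max_sweeps) {
        attr(solids, "failed_chrom") <- slots[which.max(viol_count)]
        return(NULL)
      }
      moved <- FALSE
      if (config$radial_bias > 0 && m < 1) {
        # gene-density-dependent centripetal drift (sedimentation): gene-rich
        # chromosomes settle inward while collisions are being resolved; off
        # in the final stages so the packing can converge
        for (i in seq_len(n)) {
          pos <- solids[[i]]$position
          pr <- sqrt(sum(pos^2))
          if (pr < 1) next
          g_i <- reference$gene_density[reference$chrom_id == slots[i]] / g_max
          shift_slot(i, -pos / pr * min(3 * config$radial_bias * g_i, 25))
        }
      }
      for (i in seq_len(n)) if (fix_wall(i)) moved <- TRUE
      bb_lo <- t(vapply(seq_len(n), function(i)
        pmin(c(min(seg1[[i]][, 1]), min(seg1[[i]][, 2]), min(seg1[[i]][, 3])),
             c(min(seg2[[i]][, 1]), min(seg2[[i]][, 2]), min(seg2[[i]][, 3]))),
        numeric(3)))
      bb_hi <- t(vapply(seq_len(n), function(i)
        pmax(c(max(seg1[[i]][, 1]), max(seg1[[i]][, 2]), max(seg1[[i]][, 3])),
             c(max(seg2[[i]][, 1]), max(seg2[[i]][, 2]), max(seg2[[i]][, 3]))),
        numeric(3)))
      viol_count[] <- 0L
      # randomized pair order: avoids deterministic limit cycles
      scan <- sample.int(n)
      for (ii in seq_len(n - 1L)) {
        for (jj in (ii + 1L):n) {
          i <- min(scan[ii], scan[jj])
          j <- max(scan[ii], scan[jj])
          gap <- pmax(bb_lo[j, ] - bb_hi[i, ], bb_lo[i, ] - bb_hi[j, ], 0)
          if (sum(gap^2) > target2) next
          res <- min_segdist_arg_cpp(seg1[[i]], seg2[[i]],
                                     seg1[[j]], seg2[[j]])
          d <- sqrt(res[1])
          if (d >= target) next
          pa <- res[2:4]
          pb <- res[5:7]
          u <- pb - pa
          if (d < 1e-9) {
            u <- stats::rnorm(3)
            u <- u / sqrt(sum(u^2))
          } else {
            u <- u / d
          }
          push <- (settle - d) / 2
          # torque response: rotate each rod away about its centroid, scaled
          # by the contact lever arm over the squared gyration radius
          la <- pa - solids[[i]]$position
          lb <- pb - solids[[j]]$position
          rg2_i <- mean(rowSums(sweep(seg1[[i]], 2, solids[[i]]$position)^2))
          rg2_j <- mean(rowSums(sweep(seg1[[j]], 2, solids[[j]]$position)^2))
          rotate_slot(i, pracma_cross(la, -u),
                      min(0.08, push * sqrt(sum(la^2)) / (rg2_i + 1)))
          rotate_slot(j, pracma_cross(lb, u),
                      min(0.08, push * sqrt(sum(lb^2)) / (rg2_j + 1)))
          shift_slot(i, -u * push)
          shift_slot(j, u * push)
          # keep the bounding boxes coherent after the move
          bb_lo[i, ] <- bb_lo[i, ] - u * push
          bb_hi[i, ] <- bb_hi[i, ] - u * push
          bb_lo[j, ] <- bb_lo[j, ] + u * push
          bb_hi[j, ] <- bb_hi[j, ] + u * push
          viol_count[i] <- viol_count[i] + 1L
          viol_count[j] <- viol_count[j] + 1L
          moved <- TRUE
        }
      }
      if (!moved) break
      # non-final stages are heuristics: cap their effort (the final stages
      # at the full threshold are the ones that must converge exactly)
      if (m < 1 && stage_sweeps >= 150L) break
      if (stage_sweeps %% 80L == 0L) {
        # jostle every chromosome a little to break residual limit cycles
        for (i in seq_len(n)) shift_slot(i, stats::rnorm(3, 0, 15))
      }
      if (m < 0.9 && stage_sweeps %% 500L == 0L) {
        # deep jam early in the schedule: re-sample the most entangled
        # chromosome entirely (resets its geometry and position)
        init_slot(which.max(viol_count))
      }
    }
  }
  solids
}

#' Generate a ground-truthed synthetic nucleus phantom
#'
#' Places the full karyotype (46,XY by default) of paired-chromatid
#' chromosome solids inside the nuclear sphere by seeded rejection sampling
#' (largest first, automatic re-seeded restarts if a packing dead-ends),
#' renders the 16-bit intensity stack with a quadratic axis-to-edge falloff
#' plus optional Gaussian noise, and returns the voxel-exact label volume and
#' per-object ground truth. Identical `(config, seed)` give bit-identical
#' output.
#'
#' @param config A [phantom_config()].
#' @param reference A [load_reference()] table.
#' @param karyotype Optional character vector of chromosome slots (defaults
#'   to the 46 slots of `config$karyotype`); an empty vector yields an
#'   all-background phantom with an empty truth table.
#' @return A list of class `nucleus_phantom` with elements `stack`
#'   ([image_stack()]), `labels` (integer array, `voxel_nm` attribute),
#'   `truth` (one row per object) and `config`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_config(noise_sd = 0, seed = 1),
#'                        karyotype = c("19", "21", "Y"))
#' nrow(ph$truth)  # 3
#' }
#' @export
generate_phantom <- function(config = phantom_config(),
                             reference = load_reference(),
                             karyotype = NULL) {
  if (is.null(karyotype)) karyotype <- karyotype_slots(config$karyotype)

  sp <- config$voxel_nm
  margin <- 3L
  dims <- as.integer(ceiling(config$nucleus_diameter_nm / sp) + 2L * margin)
  center <- dims * sp / 2

  placed <- NULL
  failed <- NULL
  for (restart in 0:config$max_restarts) {
    placed <- with_phantom_rng(config$seed + restart * 1009L,
                               place_karyotype(config, reference, karyotype))
    if (!is.null(placed)) break
    failed <- attr(placed, "failed_chrom")
  }
  if (is.null(placed) && length(karyotype)) {
    stop("phantom placement failed after ", config$max_restarts,
         " restarts; nucleus too crowded while placing chromosome ",
         if (is.null(failed)) "?" else failed)
  }

  n_vox <- prod(dims)
  img <- rep(as.numeric(config$background_level), n_vox)
  lab <- integer(n_vox)
  counts <- integer(length(placed))
  for (i in seq_along(placed)) {
    s <- placed[[i]]
    shift <- s$position + center
    rot <- if (is.null(s$rot_extra)) diag(3) else s$rot_extra
    counts[i] <- render_capsule_chain_cpp(
      img, lab, dims, sp,
      sweep(s$segments$p1 %*% t(rot), 2, shift, "+"),
      sweep(s$segments$p2 %*% t(rot), 2, shift, "+"),
      s$segments$r1, s$segments$r2, i,
      config$axis_level, config$edge_level, config$background_level)
  }

  if (config$noise_sd > 0) {
    img <- with_phantom_rng(config$seed + 500009L,
                            img + rnorm(n_vox, 0, config$noise_sd))
  }
  img <- round(pmin(65535, pmax(0, img)))
  stack <- image_stack(array(as.integer(img), dim = dims), sp)
  labels <- array(lab, dim = dims)
  attr(labels, "voxel_nm") <- sp

  vox_vol <- prod(sp)
  if (length(placed)) {
    cent <- object_centroids(labels, sp, seq_along(placed))
    truth <- data.frame(
      object_id = seq_along(placed),
      chrom_id = vapply(placed, `[[`, "", "chrom_id"),
      homolog = vapply(placed, `[[`, "", "homolog"),
      true_volume_nm3 = counts * vox_vol,
      true_p_len_nm = vapply(placed, `[[`, 0, "p_len_nm"),
      true_q_len_nm = vapply(placed, `[[`, 0, "q_len_nm"),
      true_ci_percent = vapply(placed, `[[`, 0, "ci_percent"),
      centroid_x_nm = cent[, 1],
      centroid_y_nm = cent[, 2],
      centroid_z_nm = cent[, 3],
      stringsAsFactors = FALSE
    )
    truth$true_radius_nm <-
      sqrt((truth$centroid_x_nm - center[1])^2 +
           (truth$centroid_y_nm - center[2])^2 +
           (truth$centroid_z_nm - center[3])^2)
  } else {
    truth <- data.frame(
      object_id = integer(0), chrom_id = character(0), homolog = character(0),
      true_volume_nm3 = numeric(0), true_p_len_nm = numeric(0),
      true_q_len_nm = numeric(0), true_ci_percent = numeric(0),
      centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
      centroid_z_nm = numeric(0), true_radius_nm = numeric(0),
      stringsAsFactors = FALSE
    )
  }

  structure(list(stack = stack, labels = labels, truth = truth,
                 config = config, nucleus_center_nm = center),
            class = "nucleus_phantom")
}

# Voxel centroids (physical nm) for the given object ids.
object_centroids <- function(labels, voxel_nm, ids) {
  out <- matrix(NA_real_, nrow = length(ids), ncol = 3)
  d <- dim(labels)
  for (i in seq_along(ids)) {
    w <- which(labels == ids[i])
    if (!length(w)) next
    w0 <- w - 1L
    x <- w0 %% d[1]
    y <- (w0 %/% d[1]) %% d[2]
    z <- w0 %/% (d[1] * d[2])
    out[i, ] <- c(mean(x + 0.5) * voxel_nm[1],
                  mean(y + 0.5) * voxel_nm[2],
                  mean(z + 0.5) * voxel_nm[3])
  }
  out
}

#' @export
print.nucleus_phantom <- function(x, ...) {
  cat(sprintf("nucleus_phantom: %d chromosome objects, seed %d\n",
              nrow(x$truth), x$config$seed))
  print(x$stack)
  invisible(x)
}

#' Write all phantom artifacts to a directory
#'
#' Writes `stack.tif`, `labels.tif` (both 16-bit multi-page TIFF with JSON
#' spacing sidecars), `truth.csv`, and `phantom_config.json`.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(phantom$stack, file.path(dir, "stack.tif"))
  write_labels(phantom$labels, file.path(dir, "labels.tif"))
  utils::write.csv(phantom$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- phantom$config
  cfg$voxel_nm <- unname(cfg$voxel_nm)
  jsonlite::write_json(unclass(cfg), file.path(dir, "phantom_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
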