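# Identification: globally optimal assignment of measured objects onto the
# 46-slot reference karyotype, cytogenetic grouping, and validation of
# measured volumes against reference DNA content.

#' Assign measured objects to the reference karyotype
#'
#' Formalises scatter-plot karyotyping (volume and length versus centromere
#' index) as a linear-assignment problem: each measured object is matched to
#' one of the 46 template slots (two per autosome, one X and one Y for a
#' 46,XY template) minimising the summed cost
#' \deqn{w_v |vol\% - ref\%| + w_l |len\% - ref\%| + w_c |ci - ci_{canon}|}
#' with every feature standardised to zero mean and unit variance on its own
#' side, so affine differences between measured geometry and reference Mbp do
#' not bias the matching. The optimum is found exactly with the Hungarian
#' algorithm; ties are broken deterministically by (object order, slot
#' order). Within each autosome pair the larger-volume object is homolog
#' `a` (ties to the lower `object_id`).
#'
#' @param morph A [measure_chromosomes()] table (46 rows for a complete
#'   nucleus).
#' @param reference A [load_reference()] table.
#' @param weights Named numeric: `volume`, `length`, `ci` (defaults 1, 1,
#'   0.5 -- the centromere index is the noisiest feature).
#' @param sex `"XY"` or `"XX"` template.
#' @param allow_partial Permit fewer/more objects than 46 (unmatched slots or
#'   objects are left unassigned); otherwise a count mismatch is an error.
#' @return A `data.frame` of class `karyotype_assignment`: per object
#'   `chrom_id`, `homolog`, `group`, `assignment_cost`; attributes
#'   `total_cost` and `is_complete`.
#' @export
assign_karyotype <- function(morph, reference = load_reference(),
                             weights = c(volume = 1, length = 1, ci = 0.5),
                             sex = c("XY", "XX"), allow_partial = FALSE) {
  sex <- match.arg(sex)
  slots <- karyotype_slots(sex)
  n_obj <- nrow(morph)
  n_slot <- length(slots)
  if (n_obj != n_slot && !allow_partial) {
    stop("expected ", n_slot, " measured objects, got ", n_obj,
         " (set allow_partial = TRUE for incomplete nuclei)")
  }

  ridx <- match(slots, reference$chrom_id)
  slot_mbp <- reference$mbp[ridx]
  slot_ci <- reference$canonical_ci[ridx]
  ref_pct <- 100 * slot_mbp / sum(slot_mbp)

  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  mz_vol <- zscore(morph$vol_percent_of_genome)
  mz_len <- zscore(morph$len_percent_of_genome)
  ci_meas <- ifelse(is.na(morph$ci_len_percent),
                    mean(morph$ci_len_percent, na.rm = TRUE),
                    morph$ci_len_percent)
  mz_ci <- zscore(ci_meas)
  sz_pct <- zscore(ref_pct)
  sz_ci <- zscore(slot_ci)

  n <- max(n_obj, n_slot)
  cost <- matrix(0, n, n)
  base <- weights[["volume"]] * abs(outer(mz_vol, sz_pct, "-")) +
    weights[["length"]] * abs(outer(mz_len, sz_pct, "-")) +
    weights[["ci"]] * abs(outer(mz_ci, sz_ci, "-"))
  # deterministic tie-break: infinitesimal preference for low (object, slot)
  tie <- 1e-9 * outer(seq_len(n_obj) / n_obj, seq_len(n_slot) / n_slot^2, "+")
  cost[seq_len(n_obj), seq_len(n_slot)] <- base + tie

  row_to_col <- hungarian_cpp(cost)

  out <- data.frame(
    object_id = morph$object_id,
    chrom_id = NA_character_,
    homolog = NA_character_,
    group = NA_character_,
    assignment_cost = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_obj)) {
    j <- row_to_col[i]
    if (j <= n_slot) {
      out$chrom_id[i] <- slots[j]
      out$assignment_cost[i] <- base[i, j]
    }
  }
  out$group[!is.na(out$chrom_id)] <- group_of(out$chrom_id[!is.na(out$chrom_id)])

  # homolog labels: 'a' = larger measured volume within each pair
  for (chrom in unique(out$chrom_id[!is.na(out$chrom_id)])) {
    rows <- which(out$chrom_id == chrom)
    if (length(rows) == 1L) {
      out$homolog[rows] <- ""   # unpaired sex chromosome: no homolog suffix
    } else {
      vols <- morph$volume_nm3[rows]
      ord <- order(-vols, morph$object_id[rows])
      out$homolog[rows[ord]] <- c("a", "b")[seq_along(rows)]
    }
  }

  assigned <- !is.na(out$chrom_id)
  counts <- table(out$chrom_id[assigned])
  complete <- n_obj == n_slot && all(assigned) &&
    identical(sort(out$chrom_id[assigned]), sort(slots))
  attr(out, "total_cost") <- sum(out$assignment_cost[assigned])
  attr(out, "is_complete") <- complete
  attr(out, "sex") <- sex
  attr(out, "weights") <- weights
  class(out) <- c("karyotype_assignment", "data.frame")
  out
}

#' @export
print.karyotype_assignment <- function(x, ...) {
  cat(sprintf(
    "karyotype_assignment: %d object(s), %s, total cost %.3f, groups: %s\n",
    nrow(x), if (attr(x, "is_complete")) "complete" else "incomplete",
    attr(x, "total_cost"),
    paste(sort(unique(x$group[!is.na(x$group)])), collapse = "")))
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Validate an assignment against reference DNA content
#'
#' Ordinary least-squares regression of measured chromosome volume on the
#' reference Mbp of the assigned slot. On correctly segmented data the slope
#' recovers the DNA packing density (5.80e6 nm^3 per Mbp) and the fit is
#' nearly perfect; objects whose volume deviates from the fitted line by more
#' than 25% (relative) are flagged as outliers.
#'
#' @param assignment A [assign_karyotype()] result.
#' @param morph The morphometry table it was computed from.
#' @param reference A [load_reference()] table.
#' @param outlier_threshold Relative deviation flag level (default 0.25).
#' @return A list of class `karyotype_validation`: `slope`, `intercept`,
#'   `r_squared`, and per-object `relative_volume_error` and `outliers`.
#' @export
validate_assignment <- function(assignment, morph,
                                reference = load_reference(),
                                outlier_threshold = 0.25) {
  ok <- !is.na(assignment$chrom_id)
  if (!any(ok)) stop("assignment contains no assigned objects")
  mbp <- reference$mbp[match(assignment$chrom_id[ok], reference$chrom_id)]
  vol <- morph$volume_nm3[match(assignment$object_id[ok], morph$object_id)]
  if (length(unique(mbp)) < 2) {
    stop("degenerate reference: all assigned Mbp values are equal")
  }
  fit <- stats::lm(vol ~ mbp)
  fitted <- stats::fitted(fit)
  rel_err <- (vol - fitted) / fitted
  r2 <- if (stats::var(vol) == 0) 1 else stats::cor(vol, mbp)^2
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    object_id = assignment$object_id[ok],
    chrom_id = assignment$chrom_id[ok],
    relative_volume_error = unname(rel_err),
    outliers = assignment$object_id[ok][abs(rel_err) > outlier_threshold],
    outlier_threshold = outlier_threshold
  ), class = "karyotype_validation")
}

#' @export
print.karyotype_validation <- function(x, ...) {
  cat(sprintf(
    "volume ~ Mbp: slope %.3g nm^3/Mbp, intercept %.3g, R^2 = %.4f\n",
    x$slope, x$intercept, x$r_squared))
  if (length(x$outliers)) {
    cat("outliers (|rel err| > ", x$outlier_threshold, "): object(s) ",
        paste(x$outliers, collapse = ", "), "\n", sep = "")
  } else {
    cat("no volume outliers\n")
  }
  invisible(x)
}
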