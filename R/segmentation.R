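# Band thresholding at the three published contrast levels, in-plane
# bilateral denoising, and 3D connected-component labeling.

band_presets <- function() {
  list(narrow = c(38445, 41264),
       medium = c(37596, 43832),
       wide   = c(37498, 41346))
}

#' Segmentation band (contrast threshold interval)
#'
#' The three presets are the published 16-bit contrast levels for prophase
#' chromosome segmentation: narrow (38445--41264, the bright axial core),
#' medium (37596--43832, the envelope whose volume tracks DNA content) and
#' wide (37498--41346). Bounds are inclusive on both ends. Note the wide
#' preset is not an interval superset of medium (its maximum is lower);
#' nesting is only guaranteed for narrow within medium.
#'
#' @param name `"narrow"`, `"medium"`, `"wide"`, or `"custom"`.
#' @param min_intensity,max_intensity Required for `"custom"`; override the
#'   preset bounds otherwise.
#' @return An object of class `segmentation_band`.
#' @examples
#' segmentation_band("medium")
#' segmentation_band("custom", 40000, 42000)
#' @export
segmentation_band <- function(name = c("medium", "narrow", "wide", "custom"),
                              min_intensity = NULL, max_intensity = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(min_intensity) || is.null(max_intensity)) {
      stop("custom bands need explicit min_intensity and max_intensity")
    }
  } else {
    preset <- band_presets()[[name]]
    if (is.null(min_intensity)) min_intensity <- preset[1]
    if (is.null(max_intensity)) max_intensity <- preset[2]
  }
  if (min_intensity > max_intensity) {
    stop("min_intensity must not exceed max_intensity")
  }
  structure(list(name = name, min_intensity = min_intensity,
                 max_intensity = max_intensity),
            class = "segmentation_band")
}

#' @export
print.segmentation_band <- function(x, ...) {
  cat(sprintf("segmentation_band '%s': [%g, %g]\n",
              x$name, x$min_intensity, x$max_intensity))
  invisible(x)
}

#' Edge-preserving in-plane denoising
#'
#' Applies a bilateral filter independently to every x-y slice (noise in
#' block-face stacks is per-slice; filtering within slices avoids mixing
#' across the coarser sectioning axis). A `spatial_radius` of 0 returns the
#' input unchanged.
#'
#' @param stack An [image_stack()].
#' @param spatial_radius Window radius in voxels.
#' @param range_sd Intensity-domain Gaussian sd; edges with contrast well
#'   above this are preserved.
#' @param spatial_sd Spatial Gaussian sd in voxels (default `radius / 2`).
#' @return A denoised [image_stack()] of identical shape and spacing.
#' @export
denoise_inplane <- function(stack, spatial_radius = 2, range_sd = 300,
                            spatial_sd = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (spatial_radius < 0) stop("spatial_radius must be >= 0")
  if (spatial_radius == 0) return(stack)
  if (is.null(spatial_sd)) spatial_sd <- spatial_radius / 2
  d <- dim(stack$data)
  out <- bilateral_xy_cpp(as.numeric(stack$data), d,
                          as.integer(spatial_radius), spatial_sd, range_sd)
  image_stack(array(round(out), dim = d), stack$voxel_nm)
}

#' Threshold a stack with a segmentation band
#'
#' A voxel is selected iff `min_intensity <= intensity <= max_intensity`
#' (inclusive on both ends).
#'
#' @param stack An [image_stack()].
#' @param band A [segmentation_band()] or a preset name.
#' @return Logical 3D array with a `voxel_nm` attribute.
#' @export
threshold_band <- function(stack, band = "medium") {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(band)) band <- segmentation_band(band)
  stopifnot(inherits(band, "segmentation_band"))
  mask <- stack$data >= band$min_intensity & stack$data <= band$max_intensity
  attr(mask, "voxel_nm") <- stack$voxel_nm
  mask
}

default_min_voxels <- function(voxel_nm) {
  # volume of a 0.2 um diameter sphere in current voxel units: far below the
  # smallest chromosome at any supported resolution, far above noise specks
  max(1L, as.integer(round((4 / 3) * pi * 100^3 / prod(voxel_nm))))
}

#' Label connected components of a binary mask
#'
#' 3D connected components under 6/18/26-connectivity; components smaller
#' than `min_voxels` are removed and the survivors renumbered `1..K` by
#' descending voxel count (ties broken by first occurrence in scan order).
#' The default connectivity of 26 keeps diagonally touching sister chromatids
#' in one object on anisotropic grids.
#'
#' @param mask Logical 3D array (e.g. from [threshold_band()]).
#' @param connectivity 6, 18 or 26.
#' @param min_voxels Minimum component size kept; default is the voxel volume
#'   of a 0.2 um sphere at the mask's spacing.
#' @param voxel_nm Spacing; taken from `attr(mask, "voxel_nm")` when absent.
#' @return Integer 3D array of labels (`0` = background) of class
#'   `label_volume`, with attributes `voxel_nm` and `n_objects`.
#' @export
label_components <- function(mask, connectivity = 26, min_voxels = NULL,
                             voxel_nm = NULL) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  if (is.null(voxel_nm)) voxel_nm <- attr(mask, "voxel_nm")
  if (is.null(min_voxels)) {
    if (is.null(voxel_nm)) {
      stop("min_voxels or voxel spacing required to size the default filter")
    }
    min_voxels <- default_min_voxels(check_spacing(voxel_nm))
  }
  d <- dim(mask)
  raw <- cc_label_cpp(as.logical(mask), d, as.integer(connectivity))
  out <- integer(length(raw))
  if (any(raw > 0L)) {
    sizes <- tabulate(raw)
    keep <- which(sizes >= min_voxels)
    if (length(keep)) {
      ord <- keep[order(-sizes[keep], keep)]
      remap <- integer(length(sizes))
      remap[ord] <- seq_along(ord)
      pos <- raw > 0L
      out[pos] <- remap[raw[pos]]
    }
  }
  lab <- array(out, dim = d)
  if (!is.null(voxel_nm)) attr(lab, "voxel_nm") <- check_spacing(voxel_nm)
  attr(lab, "n_objects") <- max(lab)
  class(lab) <- c("label_volume", class(lab))
  lab
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels, %d object(s)\n",
              paste(dim(x), collapse = " x "), attr(x, "n_objects")))
  invisible(x)
}

#' Segment a stack end to end
#'
#' Convenience wrapper: optional in-plane denoising, band thresholding and
#' connected-component labeling. Warns when the object count differs from
#' the expected karyotype size.
#'
#' @inheritParams threshold_band
#' @inheritParams label_components
#' @param denoise Apply [denoise_inplane()] first?
#' @param expected_objects Emit a warning when the labeled object count
#'   differs (default 46); `NA` disables the check.
#' @param ... Passed to [denoise_inplane()].
#' @return A `label_volume`.
#' @export
segment_stack <- function(stack, band = "medium", denoise = FALSE,
                          connectivity = 26, min_voxels = NULL,
                          expected_objects = 46L, ...) {
  if (denoise) stack <- denoise_inplane(stack, ...)
  mask <- threshold_band(stack, band)
  lab <- label_components(mask, connectivity, min_voxels)
  k <- attr(lab, "n_objects")
  if (!is.na(expected_objects) && k != expected_objects) {
    warning("segmentation produced ", k, " objects (expected ",
            expected_objects, ")")
  }
  lab
}

#' Split merged objects with a seeded watershed (experimental)
#'
#' Ground-truth-free splitting of under-segmented (touching) chromosomes:
#' the anisotropic distance transform of the foreground is watershed-divided
#' (via the EBImage package) and the resulting fragments renumbered. Off by
#' default in the pipeline; useful when [segment_stack()] reports fewer than
#' the expected 46 objects.
#'
#' @param labels A `label_volume`.
#' @param tolerance Watershed flooding tolerance in nm of distance-transform
#'   height (larger = fewer splits).
#' @return A relabeled `label_volume`.
#' @export
split_touching <- function(labels, tolerance = 100) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("split_touching() needs the EBImage package")
  }
  voxel_nm <- attr(labels, "voxel_nm")
  d <- dim(labels)
  fg <- labels > 0
  edt <- sqrt(edt_sq_cpp(as.logical(fg), d, voxel_nm))
  ws <- EBImage::watershed(array(edt, dim = d), tolerance = tolerance)
  out <- array(as.integer(ws), dim = d)
  attr(out, "voxel_nm") <- voxel_nm
  attr(out, "n_objects") <- max(out)
  class(out) <- c("label_volume", class(out))
  out
}
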