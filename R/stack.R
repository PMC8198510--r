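# ImageStack container and multi-page 16-bit TIFF I/O.
#
# Voxel data live in a column-major array with dim = c(nx, ny, nz); voxel
# (i, j, k) (1-based) is centered at ((i-0.5)*sx, (j-0.5)*sy, (k-0.5)*sz) nm.

#' Construct an image stack
#'
#' @param data 3D numeric/integer array, dim `(nx, ny, nz)`, intensities in
#'   `[0, 65535]`.
#' @param voxel_nm Numeric length-3 spacing `(x, y, z)` in nm.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_nm) {
  if (length(dim(data)) != 3L) stop("stack data must be a 3D array")
  voxel_nm <- check_spacing(voxel_nm)
  structure(list(data = data, voxel_nm = voxel_nm), class = "image_stack")
}

check_spacing <- function(voxel_nm) {
  if (is.null(voxel_nm)) {
    stop("voxel spacing is required but missing: supply 'voxel_nm' ",
         "via argument, config, or a sidecar .json file")
  }
  voxel_nm <- as.numeric(voxel_nm)
  if (length(voxel_nm) == 1L) voxel_nm <- rep(voxel_nm, 3L)
  if (length(voxel_nm) != 3L || any(!is.finite(voxel_nm)) ||
      any(voxel_nm <= 0)) {
    stop("'voxel_nm' must be three positive spacings (x, y, z) in nm")
  }
  stats::setNames(voxel_nm, c("x", "y", "z"))
}

#' Physical extent of a stack along each axis
#'
#' Multiplies the voxel counts by the voxel spacing; e.g. 345 slices at 25 nm
#' sectioning span 8625 nm (8.6 um) axially.
#'
#' @param dims Integer voxel counts per axis (any length), or an
#'   `image_stack` (its `dim` and spacing are used and `voxel_nm` ignored).
#' @param voxel_nm Spacing per axis in nm, recycled to `length(dims)`.
#' @return Named numeric extents in nm.
#' @examples
#' stack_extent_nm(345, 25)  # 8625 nm axial extent
#' @export
stack_extent_nm <- function(dims, voxel_nm = NULL) {
  if (inherits(dims, "image_stack")) {
    voxel_nm <- dims$voxel_nm
    dims <- dim(dims$data)
  }
  if (is.null(voxel_nm)) stop("'voxel_nm' is required")
  dims * rep_len(as.numeric(voxel_nm), length(dims))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  ext <- stack_extent_nm(d, x$voxel_nm) / 1000
  cat(sprintf("image_stack: %d x %d x %d voxels @ (%g, %g, %g) nm\n",
              d[1], d[2], d[3], x$voxel_nm[1], x$voxel_nm[2], x$voxel_nm[3]))
  cat(sprintf("  physical extent: %.2f x %.2f x %.2f um; intensity range [%g, %g]\n",
              ext[1], ext[2], ext[3], min(x$data), max(x$data)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages become z-slices. Voxel spacing is resolved in priority order:
#' explicit `voxel_nm` argument, then a JSON sidecar (`<path>.json` with a
#' `voxel_nm` field, written by [write_stack()]); if neither is present an
#' error names the missing field. Inputs with less than 16 bits per sample
#' are widened with a warning (values preserved); RGB input is an error.
#'
#' @param path TIFF file path.
#' @param voxel_nm Optional spacing override `(x, y, z)` in nm.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_nm = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L) {
    stop("RGB/multi-channel TIFF is not supported; expected grayscale")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits < 16) {
    warning("input TIFF is ", bits, "-bit; widening to 16-bit (values preserved)")
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); nz <- length(pages)
  data <- array(0L, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- as.integer(round(t(pages[[k]])))
  if (is.null(voxel_nm) && file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    voxel_nm <- meta$voxel_nm
  }
  image_stack(data, voxel_nm)
}

#' Write an image stack (or label volume) as multi-page 16-bit TIFF
#'
#' Writes one uncompressed 16-bit grayscale page per z-slice plus a JSON
#' sidecar (`<path>.json`) holding the voxel spacing, so that
#' `read_stack(path)` round-trips voxel data bit-exactly and spacing exactly.
#'
#' @param stack An [image_stack()], or a 3D integer array (labels) in
#'   `[0, 65535]` accompanied by `voxel_nm`.
#' @param path Output TIFF path.
#' @param voxel_nm Spacing, required when `stack` is a bare array.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, voxel_nm = NULL) {
  if (inherits(stack, "image_stack")) {
    data <- stack$data
    voxel_nm <- stack$voxel_nm
  } else {
    data <- stack
    voxel_nm <- check_spacing(if (is.null(voxel_nm)) attr(stack, "voxel_nm") else voxel_nm)
  }
  if (min(data) < 0 || max(data) > 65535) {
    stop("intensities must lie in [0, 65535] for 16-bit output")
  }
  nz <- dim(data)[3]
  pages <- vector("list", nz)
  for (k in seq_len(nz)) pages[[k]] <- t(round(data[, , k])) / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(voxel_nm = unname(voxel_nm)),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Label volumes share the TIFF representation; keep explicit aliases so the
# pipeline reads naturally.

#' @rdname write_stack
#' @export
write_labels <- function(stack, path, voxel_nm = NULL) {
  write_stack(stack, path, voxel_nm)
}

#' Read a label volume written by [write_labels()]
#' @inheritParams read_stack
#' @return Integer 3D array with `voxel_nm` attribute.
#' @export
read_labels <- function(path, voxel_nm = NULL) {
  suppressWarnings(st <- read_stack(path, voxel_nm))
  lab <- st$data
  attr(lab, "voxel_nm") <- st$voxel_nm
  lab
}
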