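#' Spatial data model: CT volumes, binary masks, normalized volumes
#'
#' A `ct_volume` is a 3D dense array of Hounsfield-unit (HU) intensities with
#' per-axis voxel spacing in mm; a `ct_mask` is a voxel-aligned \{0,1\} array;
#' a `normalized_volume` holds network-ready intensities in \[0,1\]. Axis
#' order is (L, W, H) and voxel indices are 1-based in R code (0-based in the
#' on-disk convention). Orientation/affine metadata is carried through I/O but
#' never used for resampling: scans are accepted at their native spacing.
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric triple, mm per voxel along each axis.
#' @param id scan identifier string.
#' @param orientation optional 4x4 affine carried from a source file.
#' @return An object of class `ct_volume`, `ct_mask` or `normalized_volume`.
#' @name spatial-types
NULL

#' @rdname spatial-types
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), id = "scan",
                      orientation = NULL) {
  check_voxels(voxels, spacing)
  if (!all(is.finite(voxels))) stop("ct_volume: voxels must all be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing), id = id,
                 orientation = orientation),
            class = "ct_volume")
}

#' @rdname spatial-types
#' @export
ct_mask <- function(voxels, spacing = c(1, 1, 1), id = "scan",
                    orientation = NULL) {
  check_voxels(voxels, spacing)
  v <- voxels
  if (!all(v %in% c(0, 1))) stop("ct_mask: values must be in {0,1}")
  storage.mode(v) <- "integer"
  structure(list(voxels = v, spacing = as.numeric(spacing), id = id,
                 orientation = orientation),
            class = "ct_mask")
}

#' @rdname spatial-types
#' @export
normalized_volume <- function(voxels, spacing = c(1, 1, 1), id = "scan",
                              orientation = NULL) {
  check_voxels(voxels, spacing)
  if (min(voxels) < 0 || max(voxels) > 1)
    stop("normalized_volume: values must lie in [0, 1]")
  structure(list(voxels = voxels, spacing = as.numeric(spacing), id = id,
                 orientation = orientation),
            class = "normalized_volume")
}

check_voxels <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L)
    stop("expected 3D image, got rank ", length(dim(voxels)))
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume '%s': %s voxels, spacing %s mm, HU range [%g, %g]\n",
              x$id, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("Binary mask '%s': %s voxels, %d foreground\n",
              x$id, paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' @export
print.normalized_volume <- function(x, ...) {
  cat(sprintf("Normalized volume '%s': %s voxels in [%.3f, %.3f]\n",
              x$id, paste(dim(x$voxels), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a CT volume or mask from NIfTI
#'
#' Spacing is taken from the header `pixdim`; the full image xform is kept as
#' `orientation`. Masks are binarized: any nonzero integer label becomes 1
#' (multi-label annotation exports collapse to a single foreground class).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind `"volume"` for HU intensities, `"mask"` for a binary label map.
#' @param id scan identifier; defaults to the file name without extension.
#' @return A [ct_volume] or [ct_mask].
#' @export
read_nifti <- function(path, kind = c("volume", "mask"), id = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 3L)
    stop("expected 3D image, got ", length(dims), "D: ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  orient <- RNifti::xform(img)
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vox <- array(as.numeric(img), dim = dims)
  if (kind == "mask") {
    if (any(abs(vox - round(vox)) > 1e-6))
      stop("mask contains non-integer labels: ", path)
    ct_mask((round(vox) != 0) * 1L, spacing = spacing, id = id,
            orientation = orient)
  } else {
    ct_volume(vox, spacing = spacing, id = id, orientation = orient)
  }
}

#' Write a CT volume, mask or normalized volume to NIfTI
#'
#' Masks are stored as unsigned 8-bit integers (bit-exact round trip);
#' volumes and normalized volumes as 32-bit floats (round trip to float32
#' precision). Spacing is written to the header `pixdim`.
#'
#' @param obj a [ct_volume], [ct_mask] or [normalized_volume].
#' @param path destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(obj, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  datatype <- if (inherits(obj, "ct_mask")) "uint8" else "float"
  img <- RNifti::asNifti(obj$voxels)
  RNifti::pixdim(img) <- obj$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
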