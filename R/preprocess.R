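#' Preprocessing configuration
#'
#' Parameters of the bone-region extraction pipeline. Defaults follow the
#' published bone-window protocol for rib CT: binarize at 180 HU, drop
#' components smaller than 4000 mm^3, dilate, keep the largest component,
#' fill outside the mask with -300 HU, and display-window at level 300 /
#' width 1200 HU before mapping to \[0,1\].
#'
#' @param hu_threshold HU binarization threshold (voxel kept iff HU >=
#'   threshold).
#' @param min_component_mm3 minimum physical component volume retained, mm^3.
#' @param dilation_radius_voxels radius of the 6-connected unit-ball
#'   structuring element (L1 ball), in voxels.
#' @param dilation_iterations number of dilation applications.
#' @param fill_hu HU value written outside the bone mask.
#' @param window_level,window_width bone display window, HU.
#' @param connectivity neighborhood for component labeling: 6, 18 or 26.
#' @param fixed_window if `TRUE` (default) the normalization bounds are the
#'   window limits `level +- width/2`; if `FALSE`, the observed min/max.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_threshold = 180,
                              min_component_mm3 = 4000,
                              dilation_radius_voxels = 1L,
                              dilation_iterations = 3L,
                              fill_hu = -300,
                              window_level = 300,
                              window_width = 1200,
                              connectivity = 26L,
                              fixed_window = TRUE) {
  stopifnot(window_width > 0, min_component_mm3 >= 0,
            dilation_radius_voxels >= 0, dilation_iterations >= 0,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(hu_threshold = hu_threshold,
                 min_component_mm3 = min_component_mm3,
                 dilation_radius_voxels = as.integer(dilation_radius_voxels),
                 dilation_iterations = as.integer(dilation_iterations),
                 fill_hu = fill_hu, window_level = window_level,
                 window_width = window_width,
                 connectivity = as.integer(connectivity),
                 fixed_window = isTRUE(fixed_window)),
            class = "preprocess_config")
}

#' Binarize a CT volume at an HU threshold
#'
#' A voxel is foreground iff its intensity is `>=` the threshold (inclusive,
#' so boundary voxels at exactly the threshold are kept).
#'
#' @param vol a [ct_volume].
#' @param threshold HU threshold.
#' @return A [ct_mask].
#' @export
binarize_hu <- function(vol, threshold = 180) {
  stopifnot(inherits(vol, "ct_volume"))
  ct_mask((vol$voxels >= threshold) * 1L, spacing = vol$spacing, id = vol$id,
          orientation = vol$orientation)
}

#' Label connected components of a binary mask
#'
#' Component ids are assigned in increasing order of each component's first
#' voxel in linear (column-major) array order, which fixes a deterministic
#' tie-break for equal-size components downstream.
#'
#' @param mask a [ct_mask] or a 3D \{0,1\} array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of labels (0 = background, 1..K = components).
#' @export
label_components <- function(mask, connectivity = 26L) {
  v <- mask_array(mask)
  .cc_label(as.integer(v), dim(v), as.integer(connectivity))
}

mask_array <- function(mask) {
  if (inherits(mask, "ct_mask")) mask$voxels else {
    stopifnot(length(dim(mask)) == 3L)
    m <- (mask != 0) * 1L
    dim(m) <- dim(mask)
    m
  }
}

#' Remove connected components below a physical volume
#'
#' Component volume is voxel count times the product of spacing components
#' (mm^3 per voxel); removal is strict (`volume < min_mm3`), so a component
#' at exactly the cutoff survives.
#'
#' @param mask a [ct_mask].
#' @param min_mm3 minimum retained physical volume, mm^3.
#' @param connectivity component neighborhood.
#' @return A [ct_mask] with small components removed.
#' @export
remove_small_components <- function(mask, min_mm3 = 4000,
                                    connectivity = 26L) {
  stopifnot(inherits(mask, "ct_mask"))
  if (any(mask$spacing <= 0)) stop("mask spacing must be strictly positive")
  vox_mm3 <- prod(mask$spacing)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes * vox_mm3 >= min_mm3)
  out <- array(0L, dim(mask$voxels))
  if (length(keep)) out[lab %in% keep] <- 1L
  ct_mask(out, spacing = mask$spacing, id = mask$id,
          orientation = mask$orientation)
}

#' Morphological binary dilation
#'
#' The structuring element is the 6-connected unit ball iterated
#' `radius_voxels` times (an L1 ball of that radius), applied `iterations`
#' times; total growth reach is `radius_voxels * iterations` in L1 distance.
#' Output always contains the input; `radius = 0` or `iterations = 0` is the
#' identity.
#'
#' @param mask a [ct_mask].
#' @param radius_voxels structuring-element radius in voxels.
#' @param iterations number of applications.
#' @return Dilated [ct_mask].
#' @export
dilate <- function(mask, radius_voxels = 1L, iterations = 1L) {
  stopifnot(inherits(mask, "ct_mask"), radius_voxels >= 0, iterations >= 0)
  steps <- as.integer(radius_voxels) * as.integer(iterations)
  if (steps == 0L) return(mask)
  out <- .dilate6(as.integer(mask$voxels), dim(mask$voxels), steps)
  ct_mask(out, spacing = mask$spacing, id = mask$id,
          orientation = mask$orientation)
}

#' Keep only the largest connected component
#'
#' Ties on size are broken deterministically toward the component whose first
#' voxel comes earliest in linear array order (component labeling order).
#'
#' @param mask a [ct_mask].
#' @param connectivity component neighborhood.
#' @return A [ct_mask] containing one component (or empty, with a warning).
#' @export
largest_component <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "ct_mask"))
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) {
    warning("largest_component: empty input mask")
    return(mask)
  }
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  win <- which.max(sizes)  # first maximum = smallest first-voxel label
  out <- (lab == win) * 1L
  dim(out) <- dim(mask$voxels)
  ct_mask(out, spacing = mask$spacing, id = mask$id,
          orientation = mask$orientation)
}

#' Apply a bone mask to a CT volume
#'
#' Voxels inside the mask keep their original HU; everything outside is set
#' to `fill` (default -300 HU).
#'
#' @param vol a [ct_volume].
#' @param mask a voxel-aligned [ct_mask].
#' @param fill HU fill value outside the mask.
#' @return A [ct_volume].
#' @export
apply_bone_mask <- function(vol, mask, fill = -300) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "ct_mask"))
  if (!identical(dim(vol$voxels), dim(mask$voxels)))
    stop("volume and mask shapes differ")
  out <- ifelse(mask$voxels == 1L, vol$voxels, fill)
  dim(out) <- dim(vol$voxels)
  ct_volume(out, spacing = vol$spacing, id = vol$id,
            orientation = vol$orientation)
}

#' Bone-window intensity normalization
#'
#' Clips HU to the display window `[level - width/2, level + width/2]` and
#' maps it linearly to \[0,1\]. With the default bone window (300/1200) the
#' bounds are -300 and 900 HU, so the background fill of -300 HU maps to
#' exactly 0. With `fixed = FALSE` the observed min/max are used instead
#' (min-max normalization on the clipped data).
#'
#' @param vol a [ct_volume].
#' @param level,width window level and width, HU.
#' @param fixed use the window bounds (default) rather than observed min/max.
#' @return A [normalized_volume].
#' @export
window_normalize <- function(vol, level = 300, width = 1200, fixed = TRUE) {
  stopifnot(inherits(vol, "ct_volume"), width > 0)
  lo <- level - width / 2
  hi <- level + width / 2
  x <- pmin(pmax(vol$voxels, lo), hi)
  if (!fixed) {
    lo <- min(x)
    hi <- max(x)
    if (hi <= lo) hi <- lo + 1  # constant image -> all zeros
  }
  y <- (x - lo) / (hi - lo)
  dim(y) <- dim(vol$voxels)
  normalized_volume(y, spacing = vol$spacing, id = vol$id,
                    orientation = vol$orientation)
}

#' Bone-region extraction pipeline
#'
#' Runs the full preprocessing chain: HU binarization, small-component
#' removal (before dilation, so debris is not merged into bone), dilation
#' (bridging rib-spine gaps and covering the peri-cortical tissue), largest
#' connected component, masking with the fill value, and bone-window
#' normalization.
#'
#' @param vol a [ct_volume].
#' @param cfg a [preprocess_config].
#' @param verbose log per-stage voxel counts.
#' @return List with `normalized` (a [normalized_volume]) and `bone_mask`
#'   (a [ct_mask]).
#' @export
preprocess_pipeline <- function(vol, cfg = preprocess_config(),
                                verbose = FALSE) {
  stopifnot(inherits(vol, "ct_volume"), inherits(cfg, "preprocess_config"))
  say <- function(stage, m) if (verbose)
    message(sprintf("[preprocess] %-24s %d voxels", stage, sum(m$voxels)))
  m <- binarize_hu(vol, cfg$hu_threshold)
  say("binarize", m)
  m <- remove_small_components(m, cfg$min_component_mm3, cfg$connectivity)
  say("remove_small_components", m)
  m <- dilate(m, cfg$dilation_radius_voxels, cfg$dilation_iterations)
  say("dilate", m)
  if (sum(m$voxels) == 0L) {
    warning("preprocess_pipeline: no bone found; returning empty mask")
    nv <- normalized_volume(array(0, dim(vol$voxels)), spacing = vol$spacing,
                            id = vol$id, orientation = vol$orientation)
    return(list(normalized = nv, bone_mask = m))
  }
  m <- largest_component(m, cfg$connectivity)
  say("largest_component", m)
  masked <- apply_bone_mask(vol, m, cfg$fill_hu)
  norm <- window_normalize(masked, cfg$window_level, cfg$window_width,
                           fixed = cfg$fixed_window)
  list(normalized = norm, bone_mask = m)
}
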