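#' Training configuration
#'
#' Hyperparameters of the training loop. Defaults follow the published
#' protocol: Adam (beta1 0.9, beta2 0.999, eps 1e-8), initial learning rate
#' 1e-3, weight decay 1e-4, batch size 16, 100 epochs, 96^3 patches with a
#' 60/40 positive/negative sampling mix and flip/rotation/affine-scale
#' augmentation.
#'
#' @param batch_size patches per optimizer step.
#' @param epochs training epochs.
#' @param patches_per_epoch patches drawn per epoch across the training set.
#' @param lr initial learning rate.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param weight_decay L2 penalty added to gradients.
#' @param pos_fraction expected fraction of positive patches (0.6).
#' @param patch_size cubic patch edge, voxels; must be divisible by 8.
#' @param jitter maximum uniform centre jitter per axis for positive patches
#'   (default `patch_size / 4`).
#' @param alpha positive-voxel weight of the BCE term.
#' @param augment apply random flip/rotation/scale augmentation.
#' @param rot_deg maximum rotation magnitude, degrees.
#' @param scale_range affine scaling range.
#' @param seed RNG seed for sampling, augmentation and initialization.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 100L,
                         patches_per_epoch = 160L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         weight_decay = 1e-4, pos_fraction = 0.6,
                         patch_size = 96L, jitter = NULL, alpha = 5,
                         augment = TRUE, rot_deg = 15,
                         scale_range = c(0.9, 1.1), seed = 1L) {
  stopifnot(pos_fraction >= 0, pos_fraction <= 1, lr > 0, batch_size >= 1,
            epochs >= 1, patch_size %% 8L == 0L)
  if (is.null(jitter)) jitter <- patch_size %/% 4L
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 weight_decay = weight_decay, pos_fraction = pos_fraction,
                 patch_size = as.integer(patch_size),
                 jitter = as.integer(jitter), alpha = alpha,
                 augment = isTRUE(augment), rot_deg = rot_deg,
                 scale_range = scale_range, seed = as.integer(seed)),
            class = "train_config")
}

crop_patch <- function(arr, origin, size) {
  arr[origin[1] + seq_len(size) - 1L,
      origin[2] + seq_len(size) - 1L,
      origin[3] + seq_len(size) - 1L, drop = FALSE]
}

clip_origin <- function(centre, size, dims) {
  o <- as.integer(round(centre)) - size %/% 2L
  pmin(pmax(o, 1L), dims - size + 1L)
}

#' Sample balanced training patches from one scan
#'
#' Draws `n` cubic patches. Each draw is positive with probability
#' `pos_fraction`: positive patches are centred on a uniformly chosen voxel
#' of a uniformly chosen fracture component, with uniform jitter of up to
#' `jitter` voxels per axis, clipped to the scan bounds; negative patches
#' have a uniform origin among tissue-containing positions and contain no
#' fracture voxel (rejection sampling). A scan without fractures emits
#' negatives only, with a warning.
#'
#' @param vol a [normalized_volume] (network-ready intensities).
#' @param gt voxel-aligned fracture [ct_mask].
#' @param n number of patches.
#' @param cfg a [train_config] (patch size, positive fraction, jitter).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return List of `patch_sample` objects: `image`, `label`, `is_positive`,
#'   `origin`, `id`.
#' @export
sample_patches <- function(vol, gt, n, cfg = train_config(), seed = NULL) {
  stopifnot(inherits(vol, "normalized_volume"), inherits(gt, "ct_mask"))
  if (!identical(dim(vol$voxels), dim(gt$voxels)))
    stop("volume and ground truth shapes differ")
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(vol$voxels)
  ps <- cfg$patch_size
  if (any(dims < ps))
    stop("scan smaller than patch size along some axis")
  lab <- label_components(gt, 26L)
  ncomp <- max(lab)
  comp_vox <- if (ncomp > 0L) {
    idx <- which(lab > 0L)
    split(idx, lab[idx])
  } else list()
  if (ncomp == 0L)
    warning("scan '", vol$id, "' has no fracture; emitting negatives only")
  has_tissue <- vol$voxels > 1e-6
  out <- vector("list", n)
  for (t in seq_len(n)) {
    want_pos <- ncomp > 0L && stats::runif(1) < cfg$pos_fraction
    if (want_pos) {
      comp <- comp_vox[[sample.int(ncomp, 1L)]]
      v <- comp[sample.int(length(comp), 1L)]
      centre <- arrayInd(v, dims)[1, ] +
        sample.int(2L * cfg$jitter + 1L, 3L, replace = TRUE) -
        cfg$jitter - 1L
      origin <- clip_origin(centre, ps, dims)
      img <- crop_patch(vol$voxels, origin, ps)
      lbl <- crop_patch(gt$voxels, origin, ps)
      if (sum(lbl) == 0L) {  # jitter pushed the lesion out; recentre
        origin <- clip_origin(arrayInd(v, dims)[1, ], ps, dims)
        img <- crop_patch(vol$voxels, origin, ps)
        lbl <- crop_patch(gt$voxels, origin, ps)
      }
      pos <- TRUE
    } else {
      for (try in 1:200) {
        origin <- vapply(dims, function(d)
          sample.int(d - ps + 1L, 1L), 1L)
        lbl <- crop_patch(gt$voxels, origin, ps)
        img <- crop_patch(vol$voxels, origin, ps)
        if (sum(lbl) == 0L && any(img > 1e-6)) break
        if (try == 200) stop("could not draw a fracture-free tissue patch")
      }
      pos <- FALSE
    }
    out[[t]] <- structure(list(image = img, label = lbl, is_positive = pos,
                               origin = origin, id = vol$id),
                          class = "patch_sample")
  }
  out
}

#' Random flip / rotation / affine-scale augmentation
#'
#' Applies, with one shared transform for image and label: independent axis
#' flips (probability 0.5 each), a rotation of up to `rot_deg` degrees about
#' a random coordinate axis, and isotropic scaling in `scale_range`. The
#' image is resampled trilinearly (outside filled with 0), the label with
#' nearest-neighbour and re-binarized.
#'
#' @param sample a `patch_sample`.
#' @param rot_deg maximum rotation, degrees.
#' @param scale_range scaling interval.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return An augmented `patch_sample`.
#' @export
augment <- function(sample, rot_deg = 15, scale_range = c(0.9, 1.1),
                    seed = NULL) {
  stopifnot(inherits(sample, "patch_sample"))
  if (!is.null(seed)) set.seed(seed)
  img <- sample$image
  lbl <- sample$label
  d <- dim(img)
  flips <- stats::runif(3) < 0.5
  for (ax in which(flips)) {
    idx <- rev(seq_len(d[ax]))
    if (ax == 1) { img <- img[idx, , , drop = FALSE]
                   lbl <- lbl[idx, , , drop = FALSE] }
    if (ax == 2) { img <- img[, idx, , drop = FALSE]
                   lbl <- lbl[, idx, , drop = FALSE] }
    if (ax == 3) { img <- img[, , idx, drop = FALSE]
                   lbl <- lbl[, , idx, drop = FALSE] }
  }
  theta <- stats::runif(1, -rot_deg, rot_deg) * pi / 180
  axis <- sample.int(3L, 1L)
  sc <- stats::runif(1, scale_range[1], scale_range[2])
  R <- rotation_matrix(axis, theta)
  # resampling pulls source coordinates: invert rotation*scale
  A <- t(R) / sc
  centre <- (d - 1) / 2
  img2 <- .affine_resample(img, dim(img), as.numeric(A), centre,
                           c(0, 0, 0), 0, FALSE)
  lbl2 <- .affine_resample(as.numeric(lbl), dim(lbl), as.numeric(A), centre,
                           c(0, 0, 0), 0, TRUE)
  dim(img2) <- d
  lbl2 <- (lbl2 > 0.5) * 1L
  dim(lbl2) <- d
  structure(list(image = pmin(pmax(img2, 0), 1), label = lbl2,
                 is_positive = sum(lbl2) > 0L, origin = sample$origin,
                 id = sample$id),
            class = "patch_sample")
}

rotation_matrix <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  if (axis == 1)
    matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
  else if (axis == 2)
    matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
  else
    matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}
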