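#' Synthetic thorax phantom configuration
#'
#' Parameters of the synthetic chest-CT generator. The phantom emulates the
#' structure the detection pipeline relies on: a soft-tissue body on an air
#' background, a spine-connected ribcage whose bone exceeds the 180 HU
#' binarization threshold, small bright debris components each well under
#' the 4000 mm^3 size filter, and small fracture lesions on ribs marked in a
#' ground-truth mask and carrying a locally disrupted (callus-like, low
#' density) intensity. Ribs are parametric elliptical arcs rasterized as
#' tubes with a cortical shell and marrow core, attached to the spine
#' posteriorly and joined by a sternum column anteriorly, so the cage is one
#' connected component whose parts all clear the size filter.
#'
#' @param shape volume dimensions (default 160^3).
#' @param spacing voxel spacing, mm (default 1,1,1).
#' @param n_rib_pairs rib pairs (default 6).
#' @param rib_radius rib tube radius, voxels; sized so one rib exceeds the
#'   4000 mm^3 component filter on its own.
#' @param rib_hu,marrow_hu,spine_hu,tissue_hu,air_hu tissue intensities, HU.
#' @param rib_spine_gap gap between rib head and spine surface, voxels
#'   (default 0: attached, as costovertebral joints are at CT resolution).
#'   A positive gap must stay within the preprocessing dilation reach.
#' @param sternum include an anterior sternum column joining the rib ends,
#'   so a fractured rib stays connected to the cage at both ends (default
#'   `TRUE`; without it a through-fracture would orphan the anterior stump,
#'   which the component-size filter would then delete).
#' @param n_fractures range (min, max) of fractures per scan.
#' @param fracture_extent range of lesion extent along the rib, voxels.
#' @param fracture_hu lesion intensity (an HU dip relative to bone).
#' @param n_debris number of small bright debris components.
#' @param debris_hu debris intensity.
#' @param noise_sd additive Gaussian noise, HU.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(160L, 160L, 160L),
                           spacing = c(1, 1, 1), n_rib_pairs = 6L,
                           rib_radius = 3.2, rib_hu = 700, marrow_hu = 250,
                           spine_hu = 600, tissue_hu = 40, air_hu = -1000,
                           rib_spine_gap = 0, sternum = TRUE,
                           n_fractures = c(2L, 5L),
                           fracture_extent = c(4L, 12L), fracture_hu = 120,
                           n_debris = 5L, debris_hu = 500, noise_sd = 15) {
  stopifnot(length(shape) == 3L, all(shape >= 48L), n_rib_pairs >= 1L,
            rib_radius > 0, all(spacing > 0))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_rib_pairs = as.integer(n_rib_pairs),
                 rib_radius = rib_radius, rib_hu = rib_hu,
                 marrow_hu = marrow_hu, spine_hu = spine_hu,
                 tissue_hu = tissue_hu, air_hu = air_hu,
                 rib_spine_gap = rib_spine_gap, sternum = isTRUE(sternum),
                 n_fractures = as.integer(n_fractures),
                 fracture_extent = as.integer(fracture_extent),
                 fracture_hu = fracture_hu, n_debris = as.integer(n_debris),
                 debris_hu = debris_hu, noise_sd = noise_sd),
            class = "phantom_config")
}

#' Scaled-down easy-lesion phantom configuration
#'
#' A 96^3 phantom with fewer, thicker ribs and short fracture gaps. The
#' short extent keeps every lesion voxel within the dilation reach of the
#' surrounding cortical bone, so lesions stay inside the bone mask and
#' retain their distinctive intensity in the network input; this is the
#' setting used for scaled-down end-to-end training runs.
#'
#' @param shape volume dimensions.
#' @param ... overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_config_easy <- function(shape = c(96L, 96L, 96L), ...) {
  phantom_config(shape = shape, n_rib_pairs = 4L, rib_radius = 4,
                 n_fractures = c(2L, 3L), fracture_extent = c(4L, 6L),
                 noise_sd = 10, ...)
}

ball_offsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dx = s, dy = s, dz = s)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

stamp_balls <- function(dims, centres, offsets) {
  # linear voxel indices of balls stamped at integer centres, clipped
  n <- nrow(centres)
  ix <- rep(centres[, 1], each = nrow(offsets)) + offsets$dx
  iy <- rep(centres[, 2], each = nrow(offsets)) + offsets$dy
  iz <- rep(centres[, 3], each = nrow(offsets)) + offsets$dz
  ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
    iz >= 1 & iz <= dims[3]
  unique(ix[ok] + dims[1] * (iy[ok] - 1 + dims[2] * (iz[ok] - 1)))
}

#' Generate one synthetic thorax phantom
#'
#' Deterministic given `seed`: returns an HU volume plus the voxel-level
#' fracture ground-truth mask. All bone (rib, spine) voxels exceed 180 HU
#' before noise; every ground-truth voxel lies on a rib; debris components
#' are each strictly smaller than 4000 mm^3 by construction.
#'
#' @param cfg a [phantom_config].
#' @param seed integer RNG seed.
#' @param id scan identifier.
#' @return List with `volume` (a [ct_volume]) and `gt` (a [ct_mask]).
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L,
                             id = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(seed)
  d <- cfg$shape
  L <- d[1]; W <- d[2]; H <- d[3]
  if (H < cfg$n_rib_pairs * (2 * cfg$rib_radius + 4) + 16)
    stop("volume too small for ", cfg$n_rib_pairs, " rib pairs")
  cx <- (L + 1) / 2; cy <- (W + 1) / 2
  rx <- 0.44 * L; ry <- 0.40 * W
  vol <- array(cfg$air_hu, d)
  body2d <- outer(((seq_len(L) - cx) / rx)^2,
                  ((seq_len(W) - cy) / ry)^2, "+") <= 1
  vol[array(body2d, d)] <- cfg$tissue_hu
  # spine: posterior cylinder; rib arcs aim at its centre
  b_arc <- 0.62 * ry
  a_arc <- 0.80 * rx
  cys <- cy + b_arc
  spine_r <- max(4, round(0.05 * W))
  sp2d <- outer((seq_len(L) - cx)^2, (seq_len(W) - cys)^2, "+") <= spine_r^2
  sp3 <- array(sp2d, d)
  sp3[, , c(seq_len(4L), H - seq_len(4L) + 1L)] <- FALSE
  vol[sp3] <- cfg$spine_hu
  # ribs: elliptical arcs starting rib_spine_gap outside the spine surface
  offs_cort <- ball_offsets(cfg$rib_radius)
  offs_core <- ball_offsets(max(cfg$rib_radius - 2, 0.9))
  zs <- seq(10, H - 10 - 6, length.out = cfg$n_rib_pairs)
  # rib_spine_gap is the surface-to-surface separation; 0 means attached
  # (the tube is sunk 1.5 voxels into the spine so discretization cannot
  # disconnect the joint)
  start_dist <- spine_r + cfg$rib_radius +
    if (cfg$rib_spine_gap > 0) cfg$rib_spine_gap else -1.5
  ribs <- list()
  for (p in seq_len(cfg$n_rib_pairs)) {
    for (side in c(1, -1)) {
      th_all <- seq(pi / 2, -0.49 * pi, by = -0.5 / max(a_arc, b_arc))
      px0 <- cx + side * a_arc * cos(th_all)
      py0 <- cy + b_arc * sin(th_all)
      dist <- sqrt((px0 - cx)^2 + (py0 - cys)^2)
      keep <- which(dist >= start_dist)
      th <- th_all[keep]
      th <- th[th > -0.48 * pi]  # sweep to the front midline
      prog <- seq(0, 1, length.out = length(th))
      pts <- cbind(round(cx + side * a_arc * cos(th)),
                   round(cy + b_arc * sin(th)),
                   round(zs[p] + 6 * prog))
      cort <- stamp_balls(d, pts, offs_cort)
      core <- stamp_balls(d, pts, offs_core)
      vol[cort] <- cfg$rib_hu
      vol[core] <- cfg$marrow_hu
      ribs[[length(ribs) + 1L]] <- list(pts = pts, vox = cort)
    }
  }
  if (cfg$sternum) {
    # anterior column joining the rib ends; ~400 HU (ossified sternum)
    cyf <- cy - b_arc
    st2d <- outer((seq_len(L) - cx)^2, (seq_len(W) - cyf)^2, "+") <=
      max(5, cfg$rib_radius + 2)^2
    st3 <- array(st2d, d)
    zkeep <- seq(max(1L, round(min(zs) - 4)), min(H, round(max(zs) + 12)))
    st3[, , setdiff(seq_len(H), zkeep)] <- FALSE
    st3[vol >= 180] <- FALSE  # do not overwrite rib cortical bone
    vol[st3] <- 400
  }
  # fractures: transverse gaps on distinct ribs
  gt <- array(0L, d)
  nf <- if (length(cfg$n_fractures) > 1L)
    sample(cfg$n_fractures[1]:cfg$n_fractures[2], 1L) else cfg$n_fractures
  frac_ribs <- sample(seq_along(ribs), nf)
  for (fr in frac_ribs) {
    pts <- ribs[[fr]]$pts
    m <- nrow(pts)
    centre_i <- sample(seq(round(0.3 * m), round(0.7 * m)), 1L)
    ext <- sample(cfg$fracture_extent[1]:cfg$fracture_extent[2], 1L)
    ctr <- pts[centre_i, ]
    span <- min(m - 1L, max(4L, 2L * ext))
    tangent <- pts[min(m, centre_i + span %/% 2L), ] -
      pts[max(1L, centre_i - span %/% 2L), ]
    tangent <- tangent / sqrt(sum(tangent^2))
    # cortical notch: outer-shell tube voxels whose projection on the local
    # tangent lies within +-ext/2 of the fracture centre. The notch depth
    # stays within the preprocessing dilation reach, so the lesion remains
    # inside the bone mask, and the rib stays connected beneath it.
    depth <- min(cfg$rib_radius - 1, 1.8)
    rv <- ribs[[fr]]$vox
    co <- arrayInd(rv, d)
    rel <- sweep(co, 2, ctr)
    proj <- abs(rel %*% tangent)
    near <- which(rowSums(rel^2) <= (ext / 2 + cfg$rib_radius + 1)^2 &
                    proj <= ext / 2)
    if (length(near) == 0L) next
    dmin <- vapply(near, function(u) {
      sqrt(min(colSums((t(pts) - co[u, ])^2)))
    }, 1)
    fvox <- rv[near[dmin >= cfg$rib_radius - depth]]
    if (length(fvox) == 0L) next
    # constructive guarantee: every lesion voxel must lie within the
    # preprocessing dilation reach (L1 radius 3) of remaining bone, so the
    # bone mask always contains the whole lesion. Voxels that would sink
    # deeper (diagonal corners of the notch) stay cortical.
    fc <- arrayInd(fvox, d)
    lo <- pmax(apply(fc, 2, min) - 4L, 1L)
    hi <- pmin(apply(fc, 2, max) + 4L, d)
    sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sd_ <- dim(sub)
    floc <- (fc[, 1] - lo[1] + 1L) +
      sd_[1] * (fc[, 2] - lo[2] + (fc[, 3] - lo[3]) * sd_[2])
    sub[floc] <- cfg$fracture_hu
    cov <- .dilate6((sub >= 180) * 1L, sd_, 3L)
    ok <- cov[floc] == 1L
    if (!any(ok)) next
    # keep the largest connected part so each lesion is one component
    sel <- array(0L, sd_)
    sel[floc[ok]] <- 1L
    labf <- .cc_label(sel, sd_, 26L)
    sizes <- tabulate(labf[labf > 0L], nbins = max(labf))
    fvox <- fvox[ok][labf[floc[ok]] == which.max(sizes)]
    vol[fvox] <- cfg$fracture_hu
    gt[fvox] <- 1L
  }
  # debris: small bright components in the inner soft tissue
  if (cfg$n_debris > 0L) {
    voxmm <- prod(cfg$spacing)
    placed <- 0L
    guard <- 0L
    while (placed < cfg$n_debris && guard < 500L) {
      guard <- guard + 1L
      r <- stats::runif(1, 1.5, 3)
      ctr <- c(round(cx + stats::runif(1, -0.35, 0.35) * rx * 0.5),
               round(cy + stats::runif(1, -0.35, 0.2) * ry * 0.5),
               sample(10:(H - 10), 1L))
      box <- ball_offsets(r + 4)  # clearance beyond the dilation reach
      probe <- stamp_balls(d, matrix(ctr, 1), box)
      if (any(vol[probe] >= 180)) next  # keep clear of bone
      dv <- stamp_balls(d, matrix(ctr, 1), ball_offsets(r))
      if (length(dv) * voxmm >= 4000) next
      vol[dv] <- cfg$debris_hu
      placed <- placed + 1L
    }
  }
  if (cfg$noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, cfg$noise_sd), d)
  list(volume = ct_volume(vol, spacing = cfg$spacing, id = id),
       gt = ct_mask(gt, spacing = cfg$spacing, id = id))
}

#' Generate a phantom dataset on disk
#'
#' Writes `<id>.nii.gz` / `<id>_label.nii.gz` pairs plus a `manifest.csv`
#' with the per-scan seed (derived from `seed` by a fixed offset, so each
#' scan is independently reproducible), lesion count, and a 7:1:2
#' train/val/test split assignment by scan.
#'
#' @param n_scans number of phantoms.
#' @param cfg a [phantom_config].
#' @param seed base seed.
#' @param out_dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(n_scans, cfg = phantom_config(), seed = 1L,
                             out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", n_scans)
  cut1 <- floor(0.7 * n_scans)
  cut2 <- floor(0.8 * n_scans)
  for (i in seq_len(n_scans)) {
    sseed <- seed + 1000L * i
    sid <- sprintf("phantom%03d", i)
    ph <- generate_phantom(cfg, seed = sseed, id = sid)
    write_nifti(ph$volume, file.path(out_dir, paste0(sid, ".nii.gz")))
    write_nifti(ph$gt, file.path(out_dir, paste0(sid, "_label.nii.gz")))
    split <- if (i <= cut1) "train" else if (i <= cut2) "val" else "test"
    rows[[i]] <- data.frame(id = sid, seed = sseed,
                            n_lesions = max(label_components(ph$gt)),
                            split = split)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
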