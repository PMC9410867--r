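#' Plan sliding windows over a scan
#'
#' Per axis the origins are `0, step, 2*step, ...` (0-based); if the last
#' window would overrun, a final end-aligned origin `dim - size` is used so
#' that every voxel is covered. Axes shorter than the window are padded with
#' zeros up to `size` (predictions are cropped back afterwards).
#'
#' @param shape integer triple of scan dimensions.
#' @param size cubic window edge (default 96).
#' @param step window stride (default 48).
#' @return List of class `sliding_window_plan`: `origins` (matrix, 1-based),
#'   `size`, `step`, `shape`, `padded_shape`.
#' @export
plan_windows <- function(shape, size = 96L, step = 48L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), size >= 1L, step >= 1L)
  shape <- as.integer(shape)
  padded <- pmax(shape, size)
  axis_origins <- lapply(padded, function(d) {
    o <- seq(0L, max(d - size, 0L), by = step)
    if (o[length(o)] + size < d) o <- c(o, d - size)
    unique(o)
  })
  grid <- as.matrix(expand.grid(axis_origins[[1]], axis_origins[[2]],
                                axis_origins[[3]]))
  colnames(grid) <- NULL
  structure(list(origins = grid + 1L, size = as.integer(size),
                 step = as.integer(step), shape = shape,
                 padded_shape = padded),
            class = "sliding_window_plan")
}

#' @export
print.sliding_window_plan <- function(x, ...) {
  cat(sprintf("sliding-window plan: %d windows of %d^3 (step %d) over %s\n",
              nrow(x$origins), x$size, x$step,
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Whole-scan probability prediction by sliding window
#'
#' Forwards each planned window through the model and fuses overlapping
#' predictions by voxelwise averaging over the windows covering each voxel
#' (`fusion = "max"` takes the maximum instead). Background windows -- all
#' normalized intensities at or below `background_tol`, i.e. the -300 HU
#' fill -- are skipped; voxels covered by no retained window get probability
#' zero.
#'
#' @param model a `cfsg_model`, a fitted `cfsg_unet`, or a function mapping
#'   a 3D patch array to a probability array (useful for testing).
#' @param vol a [normalized_volume].
#' @param plan a [plan_windows()] plan; defaults to the standard 96/48 plan.
#' @param fusion `"mean"` (default) or `"max"` for overlap fusion.
#' @param background_tol skip threshold on normalized intensity.
#' @return 3D array of fused probabilities, same shape as the scan.
#' @export
predict_volume <- function(model, vol, plan = NULL, fusion = c("mean", "max"),
                           background_tol = 1e-6) {
  stopifnot(inherits(vol, "normalized_volume"))
  fusion <- match.arg(fusion)
  fwd <- if (is.function(model)) model
  else if (inherits(model, "cfsg_unet"))
    function(p) cfsg_forward(model$model, p)
  else if (inherits(model, "cfsg_model")) function(p) cfsg_forward(model, p)
  else stop("model must be a cfsg_model, cfsg_unet fit, or function")
  if (is.null(plan)) plan <- plan_windows(dim(vol$voxels))
  sz <- plan$size
  pad <- plan$padded_shape
  x <- vol$voxels
  if (any(pad > dim(x))) {
    xp <- array(0, pad)
    xp[seq_len(dim(x)[1]), seq_len(dim(x)[2]), seq_len(dim(x)[3])] <- x
    x <- xp
  }
  acc <- array(0, pad)
  cnt <- array(0L, pad)
  for (r in seq_len(nrow(plan$origins))) {
    o <- plan$origins[r, ]
    i1 <- o[1] + seq_len(sz) - 1L
    i2 <- o[2] + seq_len(sz) - 1L
    i3 <- o[3] + seq_len(sz) - 1L
    win <- x[i1, i2, i3, drop = FALSE]
    if (all(win <= background_tol)) next
    p <- fwd(win)
    if (fusion == "mean") {
      acc[i1, i2, i3] <- acc[i1, i2, i3] + p
      cnt[i1, i2, i3] <- cnt[i1, i2, i3] + 1L
    } else {
      acc[i1, i2, i3] <- pmax(acc[i1, i2, i3], p)
      cnt[i1, i2, i3] <- 1L
    }
  }
  out <- acc
  covered <- cnt > 0L
  if (fusion == "mean") out[covered] <- acc[covered] / cnt[covered]
  out[!covered] <- 0
  out[seq_len(plan$shape[1]), seq_len(plan$shape[2]), seq_len(plan$shape[3]),
      drop = FALSE]
}

#' Extract detection proposals from a probability map
#'
#' Binarizes the fused map at `>= threshold`, labels connected components,
#' removes components with fewer than `min_voxels` voxels (strict), scores
#' each survivor by the mean fused probability over its voxels, and returns
#' proposals sorted by descending confidence (ties: larger volume first,
#' then lower component id).
#'
#' @param prob_map 3D probability array in \[0,1\].
#' @param threshold binarization threshold (default 0.4).
#' @param min_voxels minimum component volume in voxels (default 300).
#' @param connectivity component neighborhood (default 26).
#' @param id scan identifier attached to each proposal.
#' @return List of `detection_proposal` objects: `voxels` (linear indices),
#'   `confidence`, `volume`, `bbox` (2x3 matrix), `id`.
#' @export
extract_proposals <- function(prob_map, threshold = 0.4, min_voxels = 300L,
                              connectivity = 26L, id = "scan") {
  stopifnot(length(dim(prob_map)) == 3L)
  m <- (prob_map >= threshold) * 1L
  dim(m) <- dim(prob_map)
  lab <- .cc_label(as.integer(m), dim(m), as.integer(connectivity))
  K <- max(lab)
  if (K == 0L) return(list())
  idx <- which(lab > 0L)
  comp <- split(idx, lab[idx])
  props <- list()
  for (k in seq_along(comp)) {
    vox <- comp[[k]]
    if (length(vox) < min_voxels) next
    co <- arrayInd(vox, dim(prob_map))
    props[[length(props) + 1L]] <- structure(
      list(voxels = vox, confidence = mean(prob_map[vox]),
           volume = length(vox),
           bbox = rbind(apply(co, 2, min), apply(co, 2, max)),
           id = id, component = as.integer(names(comp)[k])),
      class = "detection_proposal")
  }
  if (length(props) == 0L) return(props)
  conf <- vapply(props, `[[`, 1, "confidence")
  volu <- vapply(props, `[[`, 1, "volume")
  cid <- vapply(props, `[[`, 1L, "component")
  props[order(-conf, -volu, cid)]
}

#' @export
print.detection_proposal <- function(x, ...) {
  cat(sprintf(
    "proposal (%s): confidence %.3f, %d voxels, bbox [%s]-[%s]\n",
    x$id, x$confidence, x$volume,
    paste(x$bbox[1, ], collapse = ","), paste(x$bbox[2, ], collapse = ",")))
  invisible(x)
}

#' Predict fracture probabilities or detection proposals for a scan
#'
#' Sliding-window whole-scan inference for a fitted model: windows of
#' `window` voxels with stride `step` are forwarded and fused by averaging,
#' then (for `type = "proposals"`) thresholded and reduced to
#' connected-component detection proposals.
#'
#' @param object a fitted `cfsg_unet`.
#' @param newdata a [normalized_volume] (preprocessed scan).
#' @param type `"prob"` for the fused probability map, `"proposals"` for
#'   detection proposals.
#' @param window,step sliding-window size and stride.
#' @param threshold,min_voxels proposal extraction settings.
#' @param ... unused.
#' @return A probability array or a list of `detection_proposal`s.
#' @export
predict.cfsg_unet <- function(object, newdata, type = c("prob", "proposals"),
                              window = NULL, step = NULL, threshold = 0.4,
                              min_voxels = 300L, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "normalized_volume"))
  if (is.null(window)) window <- object$control$patch_size
  if (is.null(step)) step <- window %/% 2L
  plan <- plan_windows(dim(newdata$voxels), size = window, step = step)
  prob <- predict_volume(object, newdata, plan)
  if (type == "prob") return(prob)
  extract_proposals(prob, threshold = threshold, min_voxels = min_voxels,
                    id = newdata$id)
}

#' Serialize proposals to JSON
#'
#' @param proposals list of `detection_proposal`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proposals <- function(proposals, path) {
  rec <- lapply(proposals, function(p) list(
    id = p$id, confidence = p$confidence, volume = p$volume,
    bbox_min = as.integer(p$bbox[1, ]), bbox_max = as.integer(p$bbox[2, ]),
    voxels = as.integer(p$voxels)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
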