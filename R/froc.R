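#' Intersection over union of two voxel sets
#'
#' @param A,B vectors of linear voxel indices on the same grid; at least one
#'   must be nonempty.
#' @return `|A intersect B| / |A union B|` in \[0,1\].
#' @export
voxel_iou <- function(A, B) {
  if (length(A) == 0L && length(B) == 0L)
    stop("voxel_iou: both sets empty")
  inter <- length(intersect(A, B))
  inter / (length(A) + length(B) - inter)
}

#' Match detection proposals to ground-truth lesions in one scan
#'
#' Greedy one-to-one matching: proposals are visited in order of descending
#' confidence (ties broken toward larger volume, then lower component id);
#' a proposal is a true positive if its IoU with some not-yet-matched
#' ground-truth component strictly exceeds `iou_thresh` (the highest-IoU
#' candidate is consumed), otherwise a false positive. IoU exactly at the
#' threshold does not match.
#'
#' @param proposals list of `detection_proposal`s for one scan.
#' @param gt_components list of ground-truth voxel-index vectors (the
#'   connected components of the annotation mask).
#' @param iou_thresh IoU threshold (default 0.2, strict).
#' @return List of class `scan_evaluation`: `id`, `n_gt`, and a data frame
#'   `records` with per-proposal `confidence`, `tp`, `matched_gt`.
#' @export
match_scan <- function(proposals, gt_components, iou_thresh = 0.2) {
  if (length(proposals)) {
    conf <- vapply(proposals, `[[`, 1, "confidence")
    volu <- vapply(proposals, `[[`, 1, "volume")
    cid <- vapply(proposals, function(p) p$component %||% 0L, 1L)
    proposals <- proposals[order(-conf, -volu, cid)]
  }
  used <- rep(FALSE, length(gt_components))
  rec <- data.frame(confidence = numeric(0), tp = logical(0),
                    matched_gt = integer(0))
  for (p in proposals) {
    ious <- vapply(seq_along(gt_components), function(g) {
      if (used[g]) return(-1)
      voxel_iou(p$voxels, gt_components[[g]])
    }, 1)
    best <- if (length(ious)) which.max(ious) else 0L
    if (best > 0L && ious[best] > iou_thresh) {
      used[best] <- TRUE
      rec <- rbind(rec, data.frame(confidence = p$confidence, tp = TRUE,
                                   matched_gt = best))
    } else {
      rec <- rbind(rec, data.frame(confidence = p$confidence, tp = FALSE,
                                   matched_gt = NA_integer_))
    }
  }
  id <- if (length(proposals)) proposals[[1]]$id else "scan"
  structure(list(id = id, n_gt = length(gt_components), records = rec),
            class = "scan_evaluation")
}

#' Ground-truth lesions of an annotation mask
#'
#' Lesions are the connected components (connectivity 26) of the binary
#' annotation mask, as voxel-index sets.
#'
#' @param gt a [ct_mask].
#' @param connectivity component neighborhood.
#' @return List of integer vectors of linear voxel indices.
#' @export
gt_lesions <- function(gt, connectivity = 26L) {
  lab <- label_components(gt, connectivity)
  if (max(lab) == 0L) return(list())
  idx <- which(lab > 0L)
  unname(split(idx, lab[idx]))
}

#' FROC analysis over a set of evaluated scans
#'
#' Sweeps the confidence threshold over all proposal confidences; at each
#' threshold the sensitivity is total true positives over total ground-truth
#' lesions and the false-positive load is total false positives divided by
#' the number of scans (scans without lesions included). The sensitivity at
#' an operating point `r` FPs/scan is the maximum sensitivity over
#' thresholds whose FP load is at most `r` (0 if none); the summary score is
#' the arithmetic mean over the operating points.
#'
#' @param evaluations list of `scan_evaluation`s (one per scan).
#' @param rates FPs/scan operating points (default 0.5, 1, 2, 4, 8).
#' @return List of class `froc_result`: `rates`, `sensitivity` (%),
#'   `average` (%), and the full `curve` (FPs/scan, sensitivity) data frame.
#' @export
froc <- function(evaluations, rates = c(0.5, 1, 2, 4, 8)) {
  if (length(evaluations) == 0L) stop("no scan evaluations")
  total_gt <- sum(vapply(evaluations, `[[`, 1L, "n_gt"))
  if (total_gt < 1L) stop("zero ground-truth lesions across all scans")
  nscan <- length(evaluations)
  rec <- do.call(rbind, lapply(evaluations, `[[`, "records"))
  if (is.null(rec) || nrow(rec) == 0L) {
    curve <- data.frame(fps_per_scan = 0, sensitivity = 0)
    sens <- rep(0, length(rates))
  } else {
    thr <- sort(unique(rec$confidence))
    curve <- do.call(rbind, lapply(thr, function(t) {
      keep <- rec$confidence >= t
      data.frame(fps_per_scan = sum(keep & !rec$tp) / nscan,
                 sensitivity = sum(keep & rec$tp) / total_gt)
    }))
    sens <- vapply(rates, function(r) {
      ok <- curve$fps_per_scan <= r
      if (any(ok)) max(curve$sensitivity[ok]) else 0
    }, 1)
  }
  structure(list(rates = rates, sensitivity = 100 * sens,
                 average = mean(100 * sens), n_gt = total_gt,
                 n_scans = nscan, curve = curve),
            class = "froc_result")
}

#' @export
print.froc_result <- function(x, ...) {
  cat("FROC analysis:", x$n_gt, "lesions over", x$n_scans, "scans\n")
  df <- data.frame(`FPs/scan` = x$rates,
                   `sensitivity (%)` = sprintf("%.2f", x$sensitivity),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  cat(sprintf("average sensitivity: %.2f%%\n", x$average))
  invisible(x)
}

#' @export
plot.froc_result <- function(x, ...) {
  graphics::plot(x$curve$fps_per_scan, 100 * x$curve$sensitivity, type = "s",
                 xlab = "FPs/scan", ylab = "sensitivity (%)",
                 ylim = c(0, 100), ...)
  graphics::points(x$rates, x$sensitivity, pch = 16)
  invisible(x)
}

#' Average sensitivity over the five FROC operating points
#'
#' Arithmetic mean of the five per-rate sensitivities (in percent),
#' reported to two decimals.
#'
#' @param sens numeric vector of exactly five sensitivities, %.
#' @return Mean sensitivity, %, rounded to 2 decimals.
#' @export
average_sensitivity <- function(sens) {
  if (length(sens) != 5L)
    stop("expected the five operating-point sensitivities, got ",
         length(sens))
  round(mean(sens), 2)
}

#' Write FROC results as CSV
#'
#' @param result a `froc_result`.
#' @param path output CSV path; the full curve goes to `*_curve.csv`.
#' @return `path`, invisibly.
#' @export
write_froc <- function(result, path) {
  df <- data.frame(fps_per_scan = c(result$rates, NA),
                   sensitivity_pct = c(result$sensitivity, result$average))
  df$point <- c(sprintf("%g", result$rates), "average")
  utils::write.csv(df, path, row.names = FALSE)
  curve_path <- sub("\\.csv$", "_curve.csv", path)
  utils::write.csv(result$curve, curve_path, row.names = FALSE)
  invisible(path)
}
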