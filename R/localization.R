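# Detections are data.frames with columns
#   image_id, x_min, y_min, x_max, y_max, confidence
# and ground truth data.frames with columns
#   image_id, x_min, y_min, x_max, y_max
# where a normal image (no boxes) appears as a single row with NA
# coordinates, mirroring the Target=0 rows of the RSNA annotation dialect.

detection_frame <- function(image_id = character(), x_min = numeric(),
                            y_min = numeric(), x_max = numeric(),
                            y_max = numeric(), confidence = numeric()) {
  data.frame(image_id = as.character(image_id), x_min = x_min, y_min = y_min,
             x_max = x_max, y_max = y_max, confidence = confidence,
             stringsAsFactors = FALSE)
}

gt_boxes_of <- function(gts, id) {
  g <- gts[gts$image_id == id & !is.na(gts$x_min), , drop = FALSE]
  g
}

# 8-connectivity connected-component labelling of a logical matrix.
# Two-pass scan with union-find over provisional labels.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      nbr <- integer(0)
      if (i > 1L && labels[i - 1L, j]) nbr <- c(nbr, labels[i - 1L, j])
      if (j > 1L) {
        if (labels[i, j - 1L]) nbr <- c(nbr, labels[i, j - 1L])
        if (i > 1L && labels[i - 1L, j - 1L]) nbr <- c(nbr, labels[i - 1L, j - 1L])
        if (i < nr && labels[i + 1L, j - 1L]) nbr <- c(nbr, labels[i + 1L, j - 1L])
      }
      if (length(nbr) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[i, j] <- nxt
      } else {
        roots <- unique(vapply(nbr, find, integer(1)))
        keep <- min(roots)
        labels[i, j] <- keep
        for (r in roots) parent[r] <- keep
      }
    }
  }
  if (nxt == 0L) return(labels)
  # flatten and renumber 1..n
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  nonzero <- labels > 0L
  labels[nonzero] <- remap[labels[nonzero]]
  labels
}

#' Propose detection boxes from a relevance map
#'
#' Connected components (8-connectivity) of the nonzero pixels of a
#' display-thresholded relevance map become candidate regions of interest.
#' Each component yields one detection: the tight half-open box around its
#' pixels, with confidence equal to the highest map score inside the box
#' multiplied by the model's abnormal-class probability for the image.
#'
#' @param map A [relevance_map()], already thresholded so that nonzero
#'   pixels mark candidate regions.
#' @param classification_score The model's abnormal-class probability for
#'   this image, used to weight the heatmap peak.
#' @param min_area Components with fewer pixels than this are dropped
#'   (default 0: keep all).
#' @param image_id Identifier recorded on each detection.
#' @return A detection data frame (possibly zero rows) with columns
#'   `image_id, x_min, y_min, x_max, y_max, confidence`.
#' @export
extract_boxes <- function(map, classification_score, min_area = 0,
                          image_id = "image") {
  labels <- label_components(unclass(map) > 0)
  n <- max(labels)
  if (n == 0L) return(detection_frame())
  out <- vector("list", n)
  for (comp in seq_len(n)) {
    idx <- which(labels == comp, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    # rows are y, columns are x; 0-based half-open extents
    out[[comp]] <- detection_frame(
      image_id = image_id,
      x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
      x_max = max(idx[, 2]),     y_max = max(idx[, 1]),
      confidence = max(map[idx]) * classification_score
    )
  }
  kept <- out[!vapply(out, is.null, logical(1))]
  if (length(kept) == 0L) return(detection_frame())
  do.call(rbind, c(kept, list(make.row.names = FALSE)))
}

#' Label detections as true or false positives
#'
#' Within each image, detections are processed in descending confidence
#' order; a detection is a true positive if its best-IoU not-yet-matched
#' ground-truth box reaches `iou_threshold`, and that box is then consumed
#' (each ground-truth box can validate at most one detection). Everything
#' else — including detections on images without ground truth — is a false
#' positive.
#'
#' @param dets Detection data frame.
#' @param gts Ground-truth data frame.
#' @param iou_threshold Minimum IoU for a match.
#' @return `dets` with an added logical column `tp`, ordered by descending
#'   confidence; the total number of ground-truth boxes is attached as
#'   attribute `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_threshold) {
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  dets$tp <- logical(nrow(dets))
  gt_used <- rep(FALSE, nrow(gts))
  for (i in seq_len(nrow(dets))) {
    rows <- which(gts$image_id == dets$image_id[i] & !is.na(gts$x_min) & !gt_used)
    if (length(rows) == 0L) next
    d <- bbox(dets$x_min[i], dets$y_min[i], dets$x_max[i], dets$y_max[i])
    ious <- vapply(rows, function(r)
      iou(d, bbox(gts$x_min[r], gts$y_min[r], gts$x_max[r], gts$y_max[r])),
      numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      dets$tp[i] <- TRUE
      gt_used[rows[best]] <- TRUE
    }
  }
  attr(dets, "n_gt") <- sum(!is.na(gts$x_min))
  rownames(dets) <- NULL
  dets
}

#' Precision-recall curve at a fixed IoU threshold
#'
#' Sweeps the confidence threshold over all distinct detection confidences
#' from strictest to loosest; at each threshold precision is
#' `TP / (TP + FP)` over the detections kept and recall is `TP / (total
#' ground-truth boxes)`.
#'
#' @inheritParams match_detections
#' @return A data frame of class `pr_curve` with columns `confidence`,
#'   `precision`, `recall`, and attribute `iou_threshold`.
#' @export
pr_curve <- function(dets, gts, iou_threshold) {
  n_gt <- sum(!is.na(gts$x_min))
  if (n_gt == 0L) stop("recall is undefined without ground-truth boxes")
  labelled <- match_detections(dets, gts, iou_threshold)
  if (nrow(labelled) == 0L) {
    out <- data.frame(confidence = numeric(), precision = numeric(),
                      recall = numeric())
  } else {
    tp_cum <- cumsum(labelled$tp)
    fp_cum <- cumsum(!labelled$tp)
    keep <- !duplicated(labelled$confidence, fromLast = TRUE)  # per distinct confidence
    out <- data.frame(confidence = labelled$confidence[keep],
                      precision = (tp_cum / (tp_cum + fp_cum))[keep],
                      recall = (tp_cum / n_gt)[keep])
  }
  structure(out, iou_threshold = iou_threshold, n_gt = n_gt,
            class = c("pr_curve", "data.frame"))
}

#' Average precision of a precision-recall curve
#'
#' The all-point average of precision across recall: the sum of
#' `(r_i - r_{i-1}) * p_i` over the sweep, with `r_0 = 0`. An empty curve
#' (no detections) scores 0.
#'
#' @param curve A [pr_curve()].
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  if (nrow(curve) == 0L) return(0)
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Mean average precision over a set of IoU thresholds
#'
#' The arithmetic mean of [average_precision()] computed at each IoU
#' threshold. The default grid is 10 evenly spaced thresholds from 0.10 to
#' 0.60 inclusive (mAP@\[0.1 0.6\]), a range that avoids the degenerate
#' extremes of very loose and very strict matching.
#'
#' @inheritParams match_detections
#' @param thresholds Non-empty numeric vector of IoU thresholds.
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(dets, gts,
                                   thresholds = seq(0.1, 0.6, length.out = 10)) {
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  mean(vapply(thresholds,
              function(t) average_precision(pr_curve(dets, gts, t)),
              numeric(1)))
}

#' Mean per-image IoU of detections against ground truth
#'
#' For each image carrying ground-truth boxes, ground-truth boxes and
#' detections are greedily paired by descending IoU (each box and each
#' detection used at most once); unpaired ground-truth boxes contribute 0.
#' The image score is the mean IoU over its ground-truth boxes, and the
#' returned value is the mean over images.
#'
#' @inheritParams match_detections
#' @return Mean IoU in `[0, 1]`.
#' @export
mean_image_iou <- function(dets, gts) {
  ids <- unique(gts$image_id[!is.na(gts$x_min)])
  if (length(ids) == 0L) stop("no ground-truth boxes")
  per_image <- vapply(ids, function(id) {
    g <- gt_boxes_of(gts, id)
    d <- dets[dets$image_id == id, , drop = FALSE]
    if (nrow(d) == 0L) return(0)
    gb <- df_to_boxes(g)
    db <- df_to_boxes(d)
    M <- outer(seq_along(gb), seq_along(db),
               Vectorize(function(i, j) iou(gb[[i]], db[[j]])))
    M <- matrix(M, nrow = length(gb))
    scores <- numeric(length(gb))
    while (any(M > 0)) {
      w <- which(M == max(M), arr.ind = TRUE)[1, , drop = TRUE]
      scores[w[1]] <- M[w[1], w[2]]
      M[w[1], ] <- -1  # consume the GT box
      M[, w[2]] <- -1  # consume the detection
    }
    mean(scores)
  }, numeric(1))
  mean(per_image)
}

#' Full localization summary for one model's detections
#'
#' @inheritParams mean_average_precision
#' @return List with `iou_mean`, `ap_per_threshold` (named), `map`,
#'   `n_images`, `n_gt_boxes` — the JSON-ready metric record.
#' @export
localization_summary <- function(dets, gts,
                                 thresholds = seq(0.1, 0.6, length.out = 10)) {
  aps <- vapply(thresholds,
                function(t) average_precision(pr_curve(dets, gts, t)),
                numeric(1))
  names(aps) <- sprintf("%.3f", thresholds)
  list(iou_mean = mean_image_iou(dets, gts),
       ap_per_threshold = as.list(aps),
       map = mean(aps),
       n_images = length(unique(gts$image_id[!is.na(gts$x_min)])),
       n_gt_boxes = sum(!is.na(gts$x_min)))
}
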