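# Shared fixture builders. Everything is generated in code, seeded by the
# caller, so the suite carries no data files.

random_stack <- function(u, v, K) {
  feature_stack(array(stats::rnorm(u * v * K), c(u, v, K)))
}

random_gap_head <- function(K, N) {
  list(W = matrix(stats::rnorm(K * N), K, N), b = stats::rnorm(N))
}

random_map <- function(nr, nc, id = "m") {
  relevance_map(matrix(stats::runif(nr * nc), nr, nc), source_id = id)
}

# random detection/ground-truth instance on a toy canvas
random_eval_instance <- function(n_det_max = 10, n_gt_max = 5, n_images = 2) {
  ids <- sprintf("im%d", seq_len(n_images))
  gt <- do.call(rbind, lapply(ids, function(id) {
    n <- sample.int(n_gt_max, 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      x <- runif(1, 0, 80); y <- runif(1, 0, 80)
      data.frame(image_id = id, x_min = x, y_min = y,
                 x_max = x + runif(1, 5, 20), y_max = y + runif(1, 5, 20))
    }))
  }))
  n_det <- sample.int(n_det_max, 1)
  dets <- do.call(rbind, lapply(seq_len(n_det), function(i) {
    x <- runif(1, 0, 80); y <- runif(1, 0, 80)
    data.frame(image_id = sample(ids, 1), x_min = x, y_min = y,
               x_max = x + runif(1, 5, 20), y_max = y + runif(1, 5, 20),
               confidence = runif(1))
  }))
  list(dets = dets, gt = gt)
}

# Independent average-precision oracle: recompute the PR curve point by
# point from scratch (explicit threshold loop, no shared code with the
# implementation) and integrate with the same all-point rule.
ap_bruteforce <- function(dets, gts, iou_threshold) {
  n_gt <- sum(!is.na(gts$x_min))
  if (nrow(dets) == 0L) return(0)
  # label detections greedily in confidence order, per image
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(dets))
  box_iou <- function(a, b) {
    ix <- min(a[3], b[3]) - max(a[1], b[1])
    iy <- min(a[4], b[4]) - max(a[2], b[2])
    if (ix <= 0 || iy <= 0) return(0)
    inter <- ix * iy
    inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  for (i in seq_len(nrow(dets))) {
    cand <- which(gts$image_id == dets$image_id[i] & !is.na(gts$x_min) & !used)
    if (!length(cand)) next
    vals <- sapply(cand, function(r)
      box_iou(as.numeric(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
              as.numeric(gts[r, c("x_min", "y_min", "x_max", "y_max")])))
    j <- cand[which.max(vals)]
    if (max(vals) >= iou_threshold) { tp[i] <- TRUE; used[j] <- TRUE }
  }
  prec <- rec <- numeric(0)
  for (thr in sort(unique(dets$confidence), decreasing = TRUE)) {
    keep <- dets$confidence >= thr
    prec <- c(prec, sum(tp[keep]) / sum(keep))
    rec <- c(rec, sum(tp[keep]) / n_gt)
  }
  sum(diff(c(0, rec)) * prec)
}

# tiny trained-ish adapter: random conv weights, random (nonzero) head
seeded_tiny_cnn <- function(seed = 5, size = 16L, k0 = 2L) {
  m <- build_tiny_cnn(tiny_cnn_spec(size, 1L, kernels_initial = k0), seed = seed)
  set.seed(seed + 999)
  m$env$par$Wd <- matrix(rnorm(length(m$env$par$Wd), sd = 0.5),
                         nrow(m$env$par$Wd), 2L)
  m$env$par$bd <- rnorm(2, sd = 0.1)
  crmens:::refresh_linear_head(m)
}
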