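# Seed-reproducible synthetic chest-like images: a brighter "body" field,
# two darker elliptical lung fields (whose union is the lung mask), smooth
# low-frequency noise, and — for abnormal samples — localized bright
# Gaussian "opacity" blobs with known ground-truth boxes. A desk-scale
# stand-in for the weak-supervision setting of radiograph collections:
# image-level labels for all samples, boxes for the abnormal ones.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

lung_geometry <- function(size) {
  list(cx = c(0.30, 0.70) * size, cy = c(0.48, 0.48) * size,
       a = 0.16 * size, b = 0.30 * size)
}

lung_mask_matrix <- function(size) {
  g <- lung_geometry(size)
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)  # x per col
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), size, size) # y per row
  m <- matrix(0L, size, size)
  for (i in 1:2) {
    inside <- ((xs - g$cx[i]) / g$a)^2 + ((ys - g$cy[i]) / g$b)^2 <= 1
    m[inside] <- 1L
  }
  m
}

boxes_intersect <- function(a, b) {
  min(a[["x_max"]], b[["x_max"]]) > max(a[["x_min"]], b[["x_min"]]) &&
    min(a[["y_max"]], b[["y_max"]]) > max(a[["y_min"]], b[["y_min"]])
}

#' Generate one synthetic chest-like sample
#'
#' Deterministic given `seed`: the same call reproduces the image bit for
#' bit. Abnormal samples carry `n_lesions` additive 2-D Gaussian bright
#' blobs, each centered inside a randomly chosen lung ellipse; the
#' ground-truth box of a blob is its `+/- 2 sigma` rectangle (covering
#' ~95% of the blob's mass) clipped to the lung-mask bounding box. Lesions
#' are placed without overlap; if `n_lesions` cannot be placed, a
#' placement error is raised.
#'
#' @param seed Integer seed.
#' @param size Image side in pixels (>= 32, default 64).
#' @param n_lesions Number of opacity blobs (0 = normal).
#' @param contrast Peak blob amplitude in (0, 1]; default 0.6 is high
#'   enough for tiny models to learn the task quickly.
#' @return A list of class `synthetic_sample` with fields `image` (matrix
#'   in `[0, 1]`), `label` (`"normal"`/`"abnormal"`), `lesion_boxes` (list
#'   of [bbox()]), `mask` (binary matrix), `seed`.
#' @export
generate_sample <- function(seed, size = 64L, n_lesions = 0L, contrast = 0.6) {
  if (size < 32L) stop("size must be at least 32")
  if (n_lesions < 0L) stop("n_lesions must be non-negative")
  if (contrast <= 0 || contrast > 1) stop("contrast must lie in (0, 1]")
  with_local_seed(seed, {
    g <- lung_geometry(size)
    mask <- lung_mask_matrix(size)
    img <- matrix(0.45, size, size)
    img[mask == 1L] <- 0.20
    # smooth low-frequency noise + fine grain
    coarse <- matrix(stats::rnorm(64, sd = 0.04), 8, 8)
    img <- img + resize_bilinear(coarse, size, size) +
      matrix(stats::rnorm(size * size, sd = 0.015), size, size)
    mask_box <- mask_to_bbox(mask)
    boxes <- list()
    if (n_lesions > 0L) {
      xs <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
      ys <- matrix(rep(seq_len(size) - 0.5, times = size), size, size)
      tries <- 0L
      while (length(boxes) < n_lesions) {
        tries <- tries + 1L
        if (tries > 200L)
          stop("placement error: could not fit ", n_lesions,
               " non-overlapping lesions inside the lung fields")
        lung <- sample.int(2L, 1L)
        # uniform point in the chosen lung ellipse
        repeat {
          px <- g$cx[lung] + g$a * stats::runif(1, -1, 1)
          py <- g$cy[lung] + g$b * stats::runif(1, -1, 1)
          if (((px - g$cx[lung]) / g$a)^2 + ((py - g$cy[lung]) / g$b)^2 <= 1) break
        }
        sigma <- size * stats::runif(1, 0.05, 0.09)
        box <- bbox(max(px - 2 * sigma, mask_box[["x_min"]]),
                    max(py - 2 * sigma, mask_box[["y_min"]]),
                    min(px + 2 * sigma, mask_box[["x_max"]]),
                    min(py + 2 * sigma, mask_box[["y_max"]]))
        if (any(vapply(boxes, boxes_intersect, logical(1), b = box))) next
        img <- img + contrast * exp(-((xs - px)^2 + (ys - py)^2) / (2 * sigma^2))
        boxes <- c(boxes, list(box))
      }
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    structure(list(image = img,
                   label = if (n_lesions > 0L) "abnormal" else "normal",
                   lesion_boxes = boxes, mask = mask, seed = seed),
              class = "synthetic_sample")
  })
}

#' Generate a labelled synthetic dataset with an annotation manifest
#'
#' Class counts follow the rounded abnormal fraction; per-sample seeds are
#' derived from the master seed by one seeded draw (counter-based), so the
#' dataset is reproducible and different master seeds give disjoint sample
#' streams. Abnormal samples carry 1-2 lesions.
#'
#' @param n Number of samples (>= 2).
#' @param abnormal_fraction Fraction of abnormal samples, strictly between
#'   0 and 1.
#' @param seed Master seed.
#' @param size,contrast Passed to [generate_sample()].
#' @return A list of class `synthetic_dataset` with `samples` (list of
#'   [generate_sample()] results, named by sample id) and `manifest` (an
#'   RSNA-dialect data frame: `patientId, x, y, width, height, Target`,
#'   one row per lesion box and one empty-coordinate `Target = 0` row per
#'   normal sample).
#' @export
generate_dataset <- function(n, abnormal_fraction = 0.5, seed = 1L,
                             size = 64L, contrast = 0.6) {
  if (n < 2L) stop("n must be at least 2")
  if (abnormal_fraction <= 0 || abnormal_fraction >= 1)
    stop("abnormal_fraction must lie strictly between 0 and 1")
  n_abn <- round(n * abnormal_fraction)
  if (n_abn == 0L || n_abn == n) stop("degenerate class split for this n")
  with_local_seed(seed, {
    sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
    labels_abn <- sample(rep(c(TRUE, FALSE), c(n_abn, n - n_abn)))
    lesion_counts <- ifelse(labels_abn, sample(1:2, n, replace = TRUE), 0L)
  })
  ids <- sprintf("s%04d", seq_len(n))
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(sample_seeds[i], size = size,
                         n_lesions = lesion_counts[i], contrast = contrast)
    samples[[i]] <- s
    rows[[i]] <- if (s$label == "normal") {
      data.frame(patientId = ids[i], x = NA_real_, y = NA_real_,
                 width = NA_real_, height = NA_real_, Target = 0L)
    } else {
      do.call(rbind, lapply(s$lesion_boxes, function(b)
        data.frame(patientId = ids[i], x = b[["x_min"]], y = b[["y_min"]],
                   width = b[["x_max"]] - b[["x_min"]],
                   height = b[["y_max"]] - b[["y_min"]], Target = 1L)))
    }
  }
  names(samples) <- ids
  structure(list(samples = samples,
                 manifest = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  lab <- vapply(x$samples, `[[`, character(1), "label")
  cat(sprintf("<synthetic_dataset: %d samples (%d abnormal), %d GT boxes>\n",
              length(lab), sum(lab == "abnormal"), sum(x$manifest$Target == 1L)))
  invisible(x)
}

#' Labels and ground-truth table of a synthetic dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @return `dataset_labels()`: named character vector of labels.
#'   `dataset_gt()`: the internal half-open ground-truth data frame
#'   (normal samples appear with NA coordinates).
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$samples, `[[`, character(1), "label")
}

#' @rdname dataset_labels
#' @export
dataset_gt <- function(dataset) {
  rsna_to_gt(dataset$manifest)
}

#' Write a synthetic dataset to disk
#'
#' Images and masks as grayscale PNG files, the manifest as an
#' RSNA-dialect CSV.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$samples)) {
    s <- dataset$samples[[id]]
    png::writePNG(s$image, file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(s$mask + 0, file.path(dir, "masks", paste0(id, ".png")))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
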