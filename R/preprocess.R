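# Images are numeric matrices, rows = y (top to bottom), cols = x.

#' Tight bounding box of a binary lung mask
#'
#' The smallest half-open box containing every nonzero mask pixel — the
#' crop applied after segmentation so the classifier sees lung pixels
#' rather than background anatomy. Two disjoint lung fields yield one box
#' spanning both.
#'
#' @param mask Binary matrix (0/1), at least one nonzero pixel.
#' @return A [bbox()] in 0-based half-open pixel coordinates.
#' @export
mask_to_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no lung found: mask has no nonzero pixel")
  bbox(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
       x_max = max(idx[, 2]), y_max = max(idx[, 1]))
}

#' Crop an image to a box and resize to a fixed output size
#'
#' Bilinear rescale of the crop to `output_size` (default 256 x 256). The
#' aspect ratio is not preserved: the crop is stretched to the fixed
#' dimensions. The source box is returned alongside so detections in
#' resized coordinates can be mapped back.
#'
#' @param image Numeric matrix.
#' @param box A [bbox()] lying within the image.
#' @param output_size Integer `(H, W)`, default `c(256, 256)`.
#' @return List with `image` (resized crop) and `crop_record`
#'   (`list(box, output_size)`).
#' @export
crop_and_resize <- function(image, box, output_size = c(256L, 256L)) {
  if (box[["x_min"]] < 0 || box[["y_min"]] < 0 ||
      box[["x_max"]] > ncol(image) || box[["y_max"]] > nrow(image))
    stop("crop box lies outside the image")
  rows <- (box[["y_min"]] + 1):box[["y_max"]]
  cols <- (box[["x_min"]] + 1):box[["x_max"]]
  crop <- image[rows, cols, drop = FALSE]
  out <- resize_bilinear(crop, output_size[1], output_size[2])
  list(image = out, crop_record = list(box = box, output_size = output_size))
}

#' 3x3 median filter with reflected borders
#'
#' Each pixel is replaced by the median of its 3x3 neighbourhood; the
#' border is handled by reflecting the edge rows/columns. Removes impulse
#' noise while preserving edges, and never produces values outside the
#' input range.
#'
#' @param image Numeric matrix (at least 1 x 1).
#' @return Filtered matrix of the same size.
#' @export
median_filter3 <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- c(1L, seq_len(nr), nr)  # reflect pad by edge duplication
  ci <- c(1L, seq_len(nc), nc)
  pad <- image[ri, ci, drop = FALSE]
  neigh <- matrix(0, nr * nc, 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    neigh[, k] <- as.vector(pad[di + seq_len(nr), dj + seq_len(nc)])
  }
  matrix(apply(neigh, 1L, stats::median), nr, nc)
}

#' Fit dataset-level normalization statistics
#'
#' Mean and standard deviation of pixel intensities pooled over a training
#' split of already min-max-rescaled images. The statistics are
#' dataset-level, not per-image, so every image is mapped through the same
#' affine transform; persist them with [save_norm_stats()].
#'
#' @param images List of numeric matrices (after filtering and `[0, 1]`
#'   rescale).
#' @return List of class `norm_stats` with `mean` and `sd`.
#' @export
fit_norm_stats <- function(images) {
  v <- unlist(lapply(images, as.vector), use.names = FALSE)
  s <- stats::sd(v)
  structure(list(mean = mean(v), sd = if (s > 0) s else 1), class = "norm_stats")
}

#' @rdname fit_norm_stats
#' @param stats A `norm_stats` object.
#' @param path JSON file path.
#' @export
save_norm_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_norm_stats
#' @export
load_norm_stats <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = s$mean, sd = s$sd), class = "norm_stats")
}

#' Condition a cropped lung image for classification
#'
#' The post-segmentation pipeline: (a) 3x3 median filter with reflected
#' borders; (b) min-max rescale to `[0, 1]` (a constant image maps to all
#' zeros); (c) optionally, standardization by dataset-level mean and
#' standard deviation fitted on a training split. Step (c) requires fitted
#' statistics — asking for standardization without them is an error, not a
#' silent per-image fallback.
#'
#' @param image Single-channel numeric matrix.
#' @param stats Optional [fit_norm_stats()] result.
#' @param standardize Apply step (c); defaults to `TRUE` whenever `stats`
#'   is supplied.
#' @return Conditioned matrix.
#' @export
condition <- function(image, stats = NULL, standardize = !is.null(stats)) {
  if (standardize && is.null(stats))
    stop("standardization requested but normalization statistics are not fitted")
  x <- median_filter3(image)
  rng <- range(x)
  x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  if (standardize) x <- (x - stats$mean) / stats$sd
  x
}
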