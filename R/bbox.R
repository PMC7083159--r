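#' Axis-aligned bounding box
#'
#' Boxes are 0-based and half-open: a box covers pixel columns
#' `[x_min, x_max)` and rows `[y_min, y_max)`, so its area is
#' `(x_max - x_min) * (y_max - y_min)`. This is the convention used
#' throughout the package; the RSNA-style `(x, y, width, height)` records
#' convert as `x_min = x`, `x_max = x + width`.
#'
#' @param x_min,y_min,x_max,y_max Pixel coordinates (0-based, half-open).
#' @return A named numeric vector of class `bbox`.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' bbox_area(b)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) stop("bbox coordinates must be finite")
  if (b["x_max"] <= b["x_min"] || b["y_max"] <= b["y_min"])
    stop("degenerate bbox: x_max must exceed x_min and y_max must exceed y_min")
  class(b) <- "bbox"
  b
}

#' @rdname bbox
#' @param b A `bbox`.
#' @export
bbox_area <- function(b) {
  unname((b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]]))
}

#' Intersection over union of two boxes
#'
#' The localization match criterion: area of the overlap divided by area of
#' the union of the two boxes. Symmetric, in `[0, 1]`, and equal to 1 only
#' for identical boxes.
#'
#' @param a,b `bbox` objects (or named vectors with the same fields).
#' @return A proportion in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  for (box in list(a, b)) {
    if (box[["x_max"]] <= box[["x_min"]] || box[["y_max"]] <= box[["y_min"]])
      stop("degenerate bbox passed to iou()")
  }
  ix <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  iy <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

# rowwise boxes in a data.frame <-> list of bbox
df_to_boxes <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    bbox(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i]))
}
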