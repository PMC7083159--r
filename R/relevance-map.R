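#' Relevance map container
#'
#' A relevance map is a non-negative 2-D grid of saliency scores, either at
#' the spatial resolution of the deepest convolutional feature maps
#' (`u x v`) or upscaled to the input-image size. The matrix carries the
#' identity of the model that produced it and the input size it refers to.
#'
#' @param values Numeric matrix of non-negative, finite relevance scores.
#' @param source_id Character scalar naming the producing model.
#' @param input_size Integer `(H, W)` of the classifier input image, in
#'   pixels; defaults to the map's own dimensions.
#' @return A matrix of class `relevance_map` with attributes `source_id`
#'   and `input_size`.
#' @export
relevance_map <- function(values, source_id = "model", input_size = dim(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("relevance map values must be finite numerics")
  if (any(values < 0)) stop("relevance map values must be non-negative")
  structure(values,
            source_id = as.character(source_id)[1],
            input_size = as.integer(input_size),
            class = c("relevance_map", "matrix", "array"))
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map %dx%d source=%s input=%s max=%.4g>\n",
              nrow(x), ncol(x), attr(x, "source_id"),
              paste(attr(x, "input_size"), collapse = "x"), max(x)))
  invisible(x)
}

# 1-D linear interpolation matrix (align-corners): rows are output samples,
# columns input samples; each row has at most two positive weights summing
# to 1, so interpolated values are convex combinations of the inputs.
interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    M[, 1L] <- 1
    return(M)
  }
  pos <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 1L)
  frac <- pos - lo
  M[cbind(seq_len(n_out), lo)] <- 1 - frac
  M[cbind(seq_len(n_out), lo + 1L)] <- M[cbind(seq_len(n_out), lo + 1L)] + frac
  M
}

# bilinear resize of a plain matrix (align-corners convention)
resize_bilinear <- function(x, height, width) {
  Ry <- interp_matrix(nrow(x), height)
  Rx <- interp_matrix(ncol(x), width)
  Ry %*% x %*% t(Rx)
}

#' Upscale a relevance map
#'
#' Bilinear interpolation of a relevance map to the input-image size, the
#' first step when fusing maps produced at different feature-map
#' resolutions. Interpolated values are convex combinations of the original
#' scores, so non-negativity is preserved and the maximum cannot grow.
#'
#' @param map A [relevance_map()].
#' @param target Integer `(H, W)` target size; each dimension must be at
#'   least the corresponding map dimension.
#' @return A `relevance_map` of size `H x W`.
#' @export
upscale_map <- function(map, target) {
  target <- as.integer(target)
  if (length(target) != 2L || any(target <= 0L))
    stop("target size must be two positive integers")
  if (target[1] < nrow(map) || target[2] < ncol(map))
    stop("upscale_map() cannot shrink a map")
  out <- resize_bilinear(unclass(map), target[1], target[2])
  out[out < 0] <- 0  # guard against tiny negative round-off
  relevance_map(out, source_id = attr(map, "source_id"),
                input_size = attr(map, "input_size"))
}

#' Threshold a relevance map at a fraction of its maximum
#'
#' Scores below `fraction * max(map)` are set to zero; all other scores are
#' kept unchanged. Used with `fraction = 0.1` to suppress the noisy
#' low-score floor of each map before and after ensemble averaging. The
#' operation is idempotent for a fixed fraction.
#'
#' @param map A [relevance_map()].
#' @param fraction Proportion in `[0, 1)` of the map maximum.
#' @return A `relevance_map` of the same size.
#' @export
threshold_map <- function(map, fraction = 0.1) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  v <- unclass(map)
  v[v < fraction * max(v)] <- 0
  relevance_map(v, source_id = attr(map, "source_id"),
                input_size = attr(map, "input_size"))
}
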