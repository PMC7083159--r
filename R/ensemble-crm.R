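#' Fuse relevance maps from several models into an ensemble map
#'
#' The fusion pipeline: each map is (1) upscaled to the input-image size,
#' (2) optionally divided by its own maximum so that models with different
#' raw score scales contribute equally, (3) thresholded at
#' `threshold_fraction` of its own maximum to drop the noisy low-score
#' floor, then (4) the maps are averaged elementwise, and (5) the average
#' is display-thresholded at `threshold_fraction` of *its* maximum. The
#' result highlights regions several models agree on and compensates for
#' regions any single model misses.
#'
#' @param maps Non-empty list of [relevance_map()] objects.
#' @param input_size Integer `(H, W)` common target size; no map may exceed
#'   it.
#' @param threshold_fraction Proportion of each map's maximum below which
#'   scores are zeroed (default 0.10).
#' @param normalize_scale Divide each map by its own maximum before
#'   averaging (default `TRUE`); zero maps stay zero and participate in the
#'   average as zeros.
#' @return A [relevance_map()] of size `input_size` with
#'   `source_id = "ensemble(<ids>)"`. With `normalize_scale = TRUE` all
#'   values lie in `[0, 1]`.
#' @export
ensemble_crm <- function(maps, input_size,
                         threshold_fraction = 0.1, normalize_scale = TRUE) {
  if (!is.list(maps) || length(maps) == 0L)
    stop("maps must be a non-empty list of relevance maps")
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in [0, 1)")
  input_size <- as.integer(input_size)
  ids <- vapply(maps, function(m) attr(m, "source_id") %||% "map", character(1))
  acc <- matrix(0, input_size[1], input_size[2])
  for (m in maps) {
    if (nrow(m) > input_size[1] || ncol(m) > input_size[2])
      stop("map ", attr(m, "source_id"), " is larger than the target input size")
    up <- unclass(upscale_map(m, input_size))
    mx <- max(up)
    if (normalize_scale && mx > 0) up <- up / mx
    up[up < threshold_fraction * max(up)] <- 0
    acc <- acc + up
  }
  avg <- acc / length(maps)
  avg[avg < threshold_fraction * max(avg)] <- 0  # display threshold
  relevance_map(avg, source_id = sprintf("ensemble(%s)", paste(ids, collapse = ",")),
                input_size = input_size)
}

#' Select the top-k models by localization performance
#'
#' Orders models by mean IoU (ties broken by mAP, then by name) and returns
#' the best `k` — the rule used to pick the constituents of the top-3,
#' top-5 and top-7 ensemble maps.
#'
#' @param scores Data frame with columns `model`, `iou` and `map`
#'   (mean IoU and mAP per model).
#' @param k Number of models to keep, `1 <= k <= nrow(scores)`.
#' @return Character vector of `k` model names, best first.
#' @export
top_k_by_localization <- function(scores, k) {
  stopifnot(is.data.frame(scores), all(c("model", "iou", "map") %in% names(scores)))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(scores)) stop("k exceeds the number of models")
  ord <- order(-scores$iou, -scores$map, scores$model)
  as.character(scores$model[ord][seq_len(k)])
}
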