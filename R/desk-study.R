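#' Run the desk-scale localization study end to end
#'
#' The package's whole pipeline on synthetic data: simulate a two-class
#' dataset, train several tiny CNNs, compute each model's relevance maps
#' on the held-out test split, turn them into detections, score IoU/mAP
#' per model, and fuse the top-`k` models' maps into an ensemble map that
#' is scored the same way. Mirrors, at desk scale, the comparison between
#' individual and ensemble heatmap localization.
#'
#' The ensemble detection confidence uses the mean abnormal-class
#' probability of the fused models, matching the heatmap-peak-times-
#' classification-score confidence rule applied to the averaged map.
#'
#' @param seed Master seed; dataset, splits, model initialization and
#'   training all derive from it.
#' @param n,size,contrast Dataset parameters (see [generate_dataset()]).
#' @param n_models Number of tiny CNNs to train.
#' @param epochs Maximum training epochs per model.
#' @param top_k Models fused into the ensemble map (default 3).
#' @param min_area Minimum connected-component area, in pixels, for a
#'   detection proposal.
#' @return List with `accuracy` (named per-model held-out accuracies),
#'   `per_model` (data frame: model, iou, map), `ensemble` (list: iou,
#'   map), `top_models`, `n_test`, and `fit` (the [train_demo()] result).
#' @export
run_desk_study <- function(seed, n = 200L, size = 64L, contrast = 0.6,
                           n_models = 3L, epochs = 10L, top_k = 3L,
                           min_area = 4L) {
  dataset <- generate_dataset(n, abnormal_fraction = 0.5, seed = seed,
                              size = size, contrast = contrast)
  models <- lapply(seq_len(n_models), function(j)
    build_tiny_cnn(tiny_cnn_spec(size, depth = 1L, kernels_initial = 16L),
                   seed = seed * 100L + j, id = sprintf("tiny-%d", j)))
  fit <- train_demo(models, dataset, epochs = epochs, seed = seed)

  gt <- dataset_gt(dataset)
  test_ids <- fit$split$test
  gt_test <- gt[gt$image_id %in% test_ids, , drop = FALSE]
  imgs <- lapply(dataset$samples, `[[`, "image")[test_ids]

  maps <- lapply(fit$models, function(m)
    lapply(imgs, function(im) crm_for_image(m, im)))
  probs <- lapply(fit$models, function(m) tiny_cnn_predict(m, imgs))
  ids <- vapply(fit$models, `[[`, character(1), "id")
  names(maps) <- names(probs) <- ids

  detections_for <- function(map_list, conf, target = c(size, size)) {
    do.call(rbind, lapply(seq_along(test_ids), function(i) {
      m <- threshold_map(upscale_map(map_list[[i]], target), 0.1)
      extract_boxes(m, conf[i], min_area = min_area, image_id = test_ids[i])
    }))
  }

  per_model <- do.call(rbind, lapply(ids, function(id) {
    dets <- detections_for(maps[[id]], probs[[id]])
    data.frame(model = id,
               iou = mean_image_iou(dets, gt_test),
               map = mean_average_precision(dets, gt_test))
  }))

  top <- top_k_by_localization(per_model, min(top_k, n_models))
  conf_ens <- rowMeans(do.call(cbind, probs[top]))
  ens_dets <- do.call(rbind, lapply(seq_along(test_ids), function(i) {
    ens <- ensemble_crm(lapply(maps[top], `[[`, i), input_size = c(size, size))
    extract_boxes(ens, conf_ens[i], min_area = min_area,
                  image_id = test_ids[i])
  }))

  list(accuracy = fit$accuracy,
       per_model = per_model,
       ensemble = list(iou = mean_image_iou(ens_dets, gt_test),
                       map = mean_average_precision(ens_dets, gt_test)),
       top_models = top,
       n_test = length(test_ids),
       fit = fit)
}
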