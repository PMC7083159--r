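#' Class-selective relevance map by brute-force removal
#'
#' Scores every spatial element `(l, m)` of the deepest-conv feature maps
#' by how much its removal perturbs the classifier output across *all*
#' output nodes:
#' \deqn{R(l,m) = \sum_{c=1}^{N} (S_c - S_c(l,m))^2}
#' where `S_c` is the score at output node `c` for the unmodified stack and
#' `S_c(l,m)` the score after zeroing all `K` channel values at `(l, m)`.
#' Elements that push the winning class up *or* competing classes down both
#' earn large scores, which is what makes the map class-discriminative.
#'
#' Scores are taken at the logits by default; `score_kind = "probability"`
#' measures the same removals through the softmax instead.
#'
#' @param adapter A [model_adapter()].
#' @param stack A [feature_stack()] from `adapter$features()` (or
#'   dimensionally compatible with its head).
#' @param score_kind `"logit"` (default) or `"probability"`.
#' @return A [relevance_map()] of size `u x v`.
#' @seealso [crm_closed_form()] for the exact shortcut available with a
#'   GAP-plus-linear head.
#' @export
crm_bruteforce <- function(adapter, stack, score_kind = c("logit", "probability")) {
  score_kind <- match.arg(score_kind)
  stack <- feature_stack(stack)
  d <- dim(stack)
  base <- as.numeric(adapter$head_forward(stack, score_kind))
  R <- matrix(0, d[1], d[2])
  work <- unclass(stack)
  for (l in seq_len(d[1])) {
    for (m in seq_len(d[2])) {
      saved <- work[l, m, ]
      work[l, m, ] <- 0
      s <- as.numeric(adapter$head_forward(work, score_kind))
      work[l, m, ] <- saved  # restore before the next removal
      R[l, m] <- sum((base - s)^2)
    }
  }
  relevance_map(R, source_id = adapter$id,
                input_size = adapter$input_size %||% d[1:2])
}

#' Class-selective relevance map, closed form for GAP-linear heads
#'
#' With a global-average-pooling head feeding a dense layer, zeroing the
#' spatial element `(l, m)` lowers logit `c` by exactly
#' `(1/Z) * sum_k W[k,c] * f_k(l,m)` with `Z = u*v`, so the brute-force
#' removal score has the closed form
#' \deqn{R(l,m) = \sum_c \left(\frac{1}{Z}\sum_k W_{kc} f_k(l,m)\right)^2}
#' This is algebraically identical to [crm_bruteforce()] at the logits and
#' costs one matrix product instead of `u*v` forward passes.
#'
#' @param stack A [feature_stack()] (`u x v x K`).
#' @param W `K x N` head weight matrix.
#' @param b Length-`N` bias (unused by the formula — removal differences
#'   cancel it — but accepted so a linear-head descriptor can be passed
#'   through unchanged).
#' @param source_id Identifier recorded on the output map.
#' @return A [relevance_map()] of size `u x v`.
#' @export
crm_closed_form <- function(stack, W, b = NULL, source_id = "model") {
  stack <- feature_stack(stack)
  d <- dim(stack)
  W <- as.matrix(W)
  if (d[3] != nrow(W))
    stop("feature stack has ", d[3], " channels but W has ", nrow(W), " rows")
  Z <- d[1] * d[2]
  flat <- matrix(unclass(stack), nrow = Z, ncol = d[3])  # (l,m) x k
  delta <- (flat %*% W) / Z                              # (l,m) x c
  R <- matrix(rowSums(delta^2), d[1], d[2])
  relevance_map(R, source_id = source_id, input_size = d[1:2])
}

#' Relevance map straight from an adapter and an image
#'
#' Runs the adapter's feature extractor, then uses the exact closed form if
#' the adapter declares a GAP-linear head, falling back to brute force
#' otherwise.
#'
#' @param adapter A [model_adapter()].
#' @param image Input image (matrix) in the adapter's expected size.
#' @param score_kind Passed to [crm_bruteforce()] when brute force is used.
#' @return A [relevance_map()].
#' @export
crm_for_image <- function(adapter, image, score_kind = "logit") {
  stack <- adapter$features(image)
  if (!is.null(adapter$linear_head) && identical(score_kind, "logit")) {
    m <- crm_closed_form(stack, adapter$linear_head$W, adapter$linear_head$b,
                         source_id = adapter$id)
    attr(m, "input_size") <- as.integer(adapter$input_size %||% dim(image))
    m
  } else {
    crm_bruteforce(adapter, stack, score_kind)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
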