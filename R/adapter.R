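#' Feature stack from the deepest convolutional layer
#'
#' A rank-3 array of activations indexed `(l, m, k)`: spatial row `l`,
#' spatial column `m`, channel `k`. This is the object whose spatial
#' elements are removed one at a time when computing a relevance map.
#'
#' @param values Numeric array of dimension `u x v x K`, all finite.
#' @return An array of class `feature_stack`.
#' @export
feature_stack <- function(values) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("feature stack must be a rank-3 array (rows x cols x channels)")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("feature stack activations must be finite")
  structure(values, class = c("feature_stack", "array"))
}

#' Class scores at the output layer
#'
#' One prediction score per output node, either pre-softmax logits or
#' post-softmax probabilities (which must then sum to 1).
#'
#' @param scores Numeric vector, length >= 2.
#' @param score_kind `"logit"` or `"probability"`.
#' @return A numeric vector of class `class_scores` with attribute
#'   `score_kind`.
#' @export
class_scores <- function(scores, score_kind = c("logit", "probability")) {
  score_kind <- match.arg(score_kind)
  scores <- as.numeric(scores)
  if (length(scores) < 2L) stop("need at least two output nodes")
  if (any(!is.finite(scores))) stop("class scores must be finite")
  if (score_kind == "probability") {
    if (any(scores < 0 | scores > 1) || abs(sum(scores) - 1) > 1e-6)
      stop("probability scores must lie in [0,1] and sum to 1")
  }
  structure(scores, score_kind = score_kind, class = "class_scores")
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Model adapter contract
#'
#' The bridge between a trained classifier and the saliency machinery. An
#' adapter exposes (a) `features(image)`, returning the [feature_stack()]
#' of the deepest convolutional layer; (b) `head_forward(stack,
#' score_kind)`, running the classifier head on a (possibly modified)
#' stack; and optionally (c) a linear-head descriptor `list(W, b)` with `W`
#' a `K x N` weight matrix and `b` a length-`N` bias such that the logit of
#' node `c` is `(1/Z) * sum_{l,m,k} W[k,c] * f_k(l,m) + b[c]` with
#' `Z = u*v` — the exact head of a global-average-pooling (GAP) classifier.
#' Stochastic layers (dropout) must be disabled inside `head_forward` so
#' repeated calls are deterministic.
#'
#' @param features Function `image -> feature_stack`.
#' @param head_forward Function `(feature_stack, score_kind) -> class_scores`.
#' @param linear_head Optional `list(W = K x N matrix, b = length-N vector)`.
#' @param id Character identifier for the model.
#' @param input_size Integer `(H, W)` the model consumes.
#' @return A list of class `model_adapter`.
#' @export
model_adapter <- function(features, head_forward, linear_head = NULL,
                          id = "model", input_size = NULL) {
  stopifnot(is.function(features), is.function(head_forward))
  if (!is.null(linear_head)) {
    stopifnot(is.matrix(linear_head$W), is.numeric(linear_head$b),
              ncol(linear_head$W) == length(linear_head$b))
  }
  structure(list(features = features, head_forward = head_forward,
                 linear_head = linear_head, id = id,
                 input_size = input_size),
            class = "model_adapter")
}

#' @export
print.model_adapter <- function(x, ...) {
  cat(sprintf("<model_adapter %s%s>\n", x$id,
              if (is.null(x$linear_head)) "" else
                sprintf(", GAP-linear head K=%d N=%d",
                        nrow(x$linear_head$W), ncol(x$linear_head$W))))
  invisible(x)
}

#' Adapter wrapping a bare GAP-plus-linear head
#'
#' Convenience constructor for tests and worked examples: a classifier
#' whose head is global average pooling followed by a dense layer, with no
#' feature extractor (the feature stack is supplied directly).
#'
#' @param W `K x N` weight matrix.
#' @param b Length-`N` bias vector (default zeros).
#' @param id Model identifier.
#' @return A [model_adapter()].
#' @export
gap_linear_adapter <- function(W, b = rep(0, ncol(W)), id = "gap-linear") {
  W <- as.matrix(W)
  b <- as.numeric(b)
  head_fwd <- function(stack, score_kind = c("logit", "probability")) {
    score_kind <- match.arg(score_kind)
    d <- dim(stack)
    if (d[3] != nrow(W))
      stop("feature stack has ", d[3], " channels but head expects ", nrow(W))
    gap <- apply(stack, 3L, mean)  # spatial mean per channel
    z <- drop(crossprod(W, gap)) + b
    if (score_kind == "probability") {
      class_scores(softmax(z), "probability")
    } else {
      class_scores(z, "logit")
    }
  }
  model_adapter(
    features = function(image) stop("gap_linear_adapter has no feature extractor"),
    head_forward = head_fwd,
    linear_head = list(W = W, b = b),
    id = id
  )
}
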