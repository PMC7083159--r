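# A probability table is a data.frame with columns
#   image_id, p_abnormal, p_normal
# (rows summing to 1) plus attribute model_id; one table per base model.

#' Build / validate a class-probability table
#'
#' @param p_abnormal,p_normal Per-sample class probabilities; each row must
#'   sum to 1 (tolerance 1e-6).
#' @param model_id Identifier of the producing model.
#' @param image_id Optional sample identifiers (default `s1, s2, ...`).
#' @return A data.frame of class `probability_table`.
#' @export
probability_table <- function(p_abnormal, p_normal = 1 - p_abnormal,
                              model_id = "model", image_id = NULL) {
  n <- length(p_abnormal)
  if (is.null(image_id)) image_id <- sprintf("s%d", seq_len(n))
  if (any(p_abnormal < -1e-9 | p_abnormal > 1 + 1e-9) ||
      any(p_normal < -1e-9 | p_normal > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  if (any(abs(p_abnormal + p_normal - 1) > 1e-6))
    stop("each row of a probability table must sum to 1")
  structure(data.frame(image_id = as.character(image_id),
                       p_abnormal = as.numeric(p_abnormal),
                       p_normal = as.numeric(p_normal),
                       stringsAsFactors = FALSE),
            model_id = as.character(model_id)[1],
            class = c("probability_table", "data.frame"))
}

check_same_samples <- function(predictions) {
  if (!is.list(predictions) || length(predictions) == 0L)
    stop("need at least one model's predictions")
  n <- vapply(predictions, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop("prediction tables disagree on the number of samples")
  invisible(n[1])
}

#' Majority-vote ensemble of class predictions
#'
#' Each model casts a vote: abnormal if its abnormal-class probability
#' reaches `threshold`, normal otherwise. The modal label wins; with an
#' even model count, ties resolve to abnormal (the triage-conservative
#' choice). With an odd voter count, e.g. seven models, a tie cannot
#' occur.
#'
#' @param predictions List of [probability_table()]s over the same samples.
#' @param threshold Vote-casting probability threshold (default 0.5).
#' @return Character vector of `"abnormal"` / `"normal"`, one per sample.
#' @export
majority_vote <- function(predictions, threshold = 0.5) {
  check_same_samples(predictions)
  votes <- vapply(predictions, function(p) p$p_abnormal >= threshold,
                  logical(nrow(predictions[[1]])))
  votes <- matrix(votes, ncol = length(predictions))
  n_abn <- rowSums(votes)
  ifelse(n_abn >= length(predictions) / 2, "abnormal", "normal")
}

#' Simple-averaging ensemble
#'
#' Elementwise arithmetic mean of the constituent models' probability
#' tables; rows of the result still sum to 1.
#'
#' @inheritParams majority_vote
#' @return A [probability_table()] with `model_id = "average(<ids>)"`.
#' @export
simple_average <- function(predictions) {
  check_same_samples(predictions)
  weighted_average(predictions,
                   rep(1 / length(predictions), length(predictions)),
                   model_id_prefix = "average")
}

#' Weighted-averaging ensemble
#'
#' Convex combination `sum_j w_j P_j` of the constituent probability
#' tables, with non-negative weights summing to 1. Uniform weights recover
#' [simple_average()]; higher weights award more influence to stronger
#' base models (the study's choice for its two strongest models was
#' `[0.25, 0.25, 0.1, 0.1, 0.1, 0.1, 0.1]`).
#'
#' @inheritParams majority_vote
#' @param weights Numeric vector, one non-negative weight per model,
#'   summing to 1 within 1e-6.
#' @param model_id_prefix Prefix for the output `model_id`.
#' @return A [probability_table()].
#' @export
weighted_average <- function(predictions, weights, model_id_prefix = "weighted") {
  check_same_samples(predictions)
  if (length(weights) != length(predictions))
    stop("need exactly one weight per model")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1")
  p_abn <- Reduce(`+`, Map(function(p, w) w * p$p_abnormal, predictions, weights))
  p_nrm <- Reduce(`+`, Map(function(p, w) w * p$p_normal, predictions, weights))
  ids <- vapply(predictions, function(p) attr(p, "model_id") %||% "model",
                character(1))
  probability_table(p_abn, p_nrm,
                    model_id = sprintf("%s(%s)", model_id_prefix,
                                       paste(ids, collapse = ",")),
                    image_id = predictions[[1]]$image_id)
}

# --- small seeded MLP engine (one ReLU hidden layer + softmax) ----------
# Used by the stacking meta-learner. Full-batch gradient descent with
# momentum, cross-entropy loss, early stopping on a held-out split.

mlp_init <- function(n_in, n_hidden, n_out, seed) {
  set.seed(seed)
  list(W1 = matrix(rnorm(n_in * n_hidden, sd = sqrt(2 / n_in)), n_in, n_hidden),
       b1 = rep(0, n_hidden),
       W2 = matrix(rnorm(n_hidden * n_out, sd = sqrt(2 / n_hidden)), n_hidden, n_out),
       b2 = rep(0, n_out))
}

mlp_forward <- function(par, X) {
  H <- pmax(X %*% par$W1 + rep(par$b1, each = nrow(X)), 0)
  Z <- H %*% par$W2 + rep(par$b2, each = nrow(X))
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(H = H, P = P)
}

mlp_loss <- function(P, Y) -mean(log(pmax(rowSums(P * Y), 1e-12)))

mlp_step <- function(par, vel, X, Y, lr, momentum) {
  n <- nrow(X)
  fw <- mlp_forward(par, X)
  dZ <- (fw$P - Y) / n
  gW2 <- crossprod(fw$H, dZ)
  gb2 <- colSums(dZ)
  dH <- dZ %*% t(par$W2) * (fw$H > 0)
  gW1 <- crossprod(X, dH)
  gb1 <- colSums(dH)
  g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  for (nm in names(par)) {
    vel[[nm]] <- momentum * vel[[nm]] - lr * g[[nm]]
    par[[nm]] <- par[[nm]] + vel[[nm]]
  }
  list(par = par, vel = vel)
}

mlp_train <- function(X, Y, n_hidden, seed, epochs = 400, lr = 0.5,
                      momentum = 0.9, val_fraction = 0.2, patience = 25) {
  set.seed(seed)
  n <- nrow(X)
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("training split is empty")
  par <- mlp_init(ncol(X), n_hidden, ncol(Y), seed + 1L)
  vel <- lapply(par, function(p) p * 0)
  best <- list(par = par, loss = Inf, epoch = 0L)
  for (ep in seq_len(epochs)) {
    st <- mlp_step(par, vel, X[tr_idx, , drop = FALSE], Y[tr_idx, , drop = FALSE],
                   lr, momentum)
    par <- st$par; vel <- st$vel
    vl <- mlp_loss(mlp_forward(par, X[val_idx, , drop = FALSE])$P,
                   Y[val_idx, , drop = FALSE])
    if (vl < best$loss - 1e-6) best <- list(par = par, loss = vl, epoch = ep)
    if (ep - best$epoch >= patience) break  # early stopping
  }
  best
}

#' Fit a stacking meta-learner over frozen base-model predictions
#'
#' Stacked generalization: the per-model class probabilities are
#' concatenated per sample into one input vector (two entries per model —
#' with seven base models, a 14-element vector), and a small neural network
#' — one hidden layer (default 14 rectifier units) plus a softmax output —
#' learns to combine them. The base models are frozen: their predictions
#' are inputs and are never modified. Training minimizes cross-entropy with
#' early stopping on a held-out split and is deterministic given `seed`.
#'
#' @param predictions List of [probability_table()]s (the base learners'
#'   outputs on the training samples).
#' @param labels Character or factor vector of `"abnormal"` / `"normal"`
#'   truth labels, one per sample.
#' @param hidden_units Hidden-layer width (default 14).
#' @param seed Integer seed controlling the split and initialization.
#' @param epochs Maximum training epochs.
#' @return An object of class `stacking_model`.
#' @export
fit_stacking <- function(predictions, labels, hidden_units = 14L, seed = 1L,
                         epochs = 400L) {
  check_same_samples(predictions)
  X <- stack_inputs(predictions)
  if (length(labels) != nrow(X))
    stop("labels must match the number of samples")
  y <- as.character(labels)
  if (!all(y %in% c("abnormal", "normal")))
    stop('labels must be "abnormal" or "normal"')
  Y <- cbind(abnormal = y == "abnormal", normal = y == "normal") * 1
  fit <- mlp_train(X, Y, n_hidden = hidden_units, seed = seed, epochs = epochs)
  structure(list(par = fit$par, input_width = ncol(X),
                 hidden_units = hidden_units,
                 n_models = length(predictions),
                 val_loss = fit$loss, seed = seed),
            class = "stacking_model")
}

stack_inputs <- function(predictions) {
  do.call(cbind, lapply(predictions, function(p)
    cbind(p$p_abnormal, p$p_normal)))
}

#' Predict with a trained stacking meta-learner
#'
#' @param object A `stacking_model` from [fit_stacking()].
#' @param predictions List of base-model [probability_table()]s over the
#'   samples to score (same models, same order as at fit time).
#' @param ... Unused.
#' @return A [probability_table()] with `model_id = "stack"`.
#' @export
predict.stacking_model <- function(object, predictions, ...) {
  check_same_samples(predictions)
  X <- stack_inputs(predictions)
  if (ncol(X) != object$input_width)
    stop("input width ", ncol(X), " does not match the fitted meta-learner (",
         object$input_width, ")")
  P <- mlp_forward(object$par, X)$P
  probability_table(P[, 1], P[, 2], model_id = "stack",
                    image_id = predictions[[1]]$image_id)
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("<stacking_model: %d base models, input %d, hidden %d, val loss %.4f>\n",
              x$n_models, x$input_width, x$hidden_units, x$val_loss))
  invisible(x)
}
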