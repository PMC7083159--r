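# Tiny trainable CNNs following the study-style architecture rules:
# a linear stack of depth-wise separable 5x5 convolution blocks (depthwise
# conv + pointwise 1x1 conv + ReLU), organized in three sections of `depth`
# identical blocks (3 * depth blocks in total) with the kernel count
# doubling per section, a 2x2 max-pool between sections, and a head of
# global average pooling -> dropout 0.5 (training only) -> dense softmax
# over two classes. The deepest conv output feeds GAP directly, so the
# head is exactly the GAP-plus-linear form required for the closed-form
# relevance map.
#
# Everything (forward, backprop, SGD) is implemented in matrix form; no
# deep-learning framework is involved.

#' Specification of a tiny separable-convolution CNN
#'
#' @param image_size Input side in pixels (multiple of 4, >= 8).
#' @param depth Blocks per section (>= 1); total conv blocks = `3 * depth`.
#' @param kernels_initial Kernels in the first section; defaults to
#'   `ceiling(image_size / sqrt(depth))`, and doubles per section.
#' @return List of class `tiny_cnn_spec` with fields `image_size`, `depth`,
#'   `kernels_initial`, `n_blocks`, `section_kernels`.
#' @export
tiny_cnn_spec <- function(image_size, depth,
                          kernels_initial = ceiling(image_size / sqrt(depth))) {
  if (depth < 1L) stop("depth must be at least 1")
  if (image_size < 8L || image_size %% 4L != 0L)
    stop("image_size must be a multiple of 4, at least 8")
  structure(list(image_size = as.integer(image_size), depth = as.integer(depth),
                 kernels_initial = as.integer(kernels_initial),
                 n_blocks = 3L * as.integer(depth),
                 section_kernels = as.integer(kernels_initial * c(1L, 2L, 4L))),
            class = "tiny_cnn_spec")
}

# --- separable conv primitives (x as s x s x C arrays) ------------------

dw_offsets <- expand.grid(di = 0:4, dj = 0:4)

pad2 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 4L, d[2] + 4L, d[3]))
  xp[3:(d[1] + 2L), 3:(d[2] + 2L), ] <- x
  xp
}

dw_conv <- function(x, w) {  # w: 25 x C
  d <- dim(x)
  s2 <- d[1] * d[2]
  xp <- pad2(x)
  acc <- matrix(0, s2, d[3])
  for (o in seq_len(25L)) {
    sub <- xp[dw_offsets$di[o] + seq_len(d[1]), dw_offsets$dj[o] + seq_len(d[2]), ,
              drop = FALSE]
    dim(sub) <- c(s2, d[3])
    acc <- acc + sub * rep(w[o, ], each = s2)
  }
  array(acc, d)
}

dw_conv_back <- function(x, w, dy) {
  d <- dim(x)
  s2 <- d[1] * d[2]
  xp <- pad2(x)
  dy_mat <- dy; dim(dy_mat) <- c(s2, d[3])
  dW <- matrix(0, 25L, d[3])
  dxp <- array(0, dim(xp))
  for (o in seq_len(25L)) {
    ri <- dw_offsets$di[o] + seq_len(d[1])
    ci <- dw_offsets$dj[o] + seq_len(d[2])
    sub <- xp[ri, ci, , drop = FALSE]
    dim(sub) <- c(s2, d[3])
    dW[o, ] <- colSums(sub * dy_mat)
    contrib <- dy_mat * rep(w[o, ], each = s2)
    dim(contrib) <- d
    dxp[ri, ci, ] <- dxp[ri, ci, , drop = FALSE] + contrib
  }
  list(dW = dW, dx = dxp[3:(d[1] + 2L), 3:(d[2] + 2L), , drop = FALSE])
}

pw_conv <- function(x, P, b) {  # P: Cin x Cout
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  ym <- xm %*% P + rep(b, each = d[1] * d[2])
  array(ym, c(d[1], d[2], ncol(P)))
}

maxpool2 <- function(x) {
  d <- dim(x)
  oi <- seq(1L, d[1], by = 2L); ei <- oi + 1L
  a1 <- x[oi, oi, , drop = FALSE]; a2 <- x[ei, oi, , drop = FALSE]
  a3 <- x[oi, ei, , drop = FALSE]; a4 <- x[ei, ei, , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  m1 <- a1 == m
  m2 <- (a2 == m) & !m1
  m3 <- (a3 == m) & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  list(out = m, masks = list(m1, m2, m3, m4))
}

maxpool2_back <- function(dy, masks, in_dim) {
  dx <- array(0, in_dim)
  oi <- seq(1L, in_dim[1], by = 2L); ei <- oi + 1L
  dx[oi, oi, ] <- dy * masks[[1]]
  dx[ei, oi, ] <- dy * masks[[2]]
  dx[oi, ei, ] <- dy * masks[[3]]
  dx[ei, ei, ] <- dy * masks[[4]]
  dx
}

# --- parameter initialization ------------------------------------------

tiny_cnn_init <- function(spec, seed) {
  set.seed(seed)
  blocks <- list()
  c_in <- 1L
  for (sec in 1:3) {
    c_out <- spec$section_kernels[sec]
    for (b in seq_len(spec$depth)) {
      blocks[[length(blocks) + 1L]] <- list(
        dw = matrix(stats::rnorm(25L * c_in, sd = sqrt(2 / 25)), 25L, c_in),
        pw = matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
        pb = rep(0, c_out),
        section = sec
      )
      c_in <- c_out
    }
  }
  K <- spec$section_kernels[3]
  # zero-initialized head: the first training phase is then a plain
  # logistic fit on the random conv features, which stabilizes the start
  list(blocks = blocks,
       Wd = matrix(0, K, 2L),
       bd = rep(0, 2L))
}

# forward through the conv trunk; keep = TRUE retains per-layer caches
tiny_cnn_trunk <- function(par, image, spec, keep = FALSE) {
  x <- array(image, c(spec$image_size, spec$image_size, 1L))
  cache <- list()
  sec_of <- vapply(par$blocks, `[[`, integer(1), "section")
  for (i in seq_along(par$blocks)) {
    blk <- par$blocks[[i]]
    pre <- dw_conv(x, blk$dw)
    z <- pw_conv(pre, blk$pw, blk$pb)
    a <- pmax(z, 0)
    if (keep) cache[[i]] <- list(x_in = x, pre = pre, relu_mask = z > 0)
    x <- a
    last_of_section <- i == max(which(sec_of == blk$section))
    if (last_of_section && blk$section < 3L) {
      mp <- maxpool2(x)
      if (keep) cache[[i]]$pool <- list(masks = mp$masks, in_dim = dim(x))
      x <- mp$out
    }
  }
  list(features = x, cache = cache)
}

tiny_cnn_logits <- function(par, feats) {
  g <- apply(feats, 3L, mean)
  drop(crossprod(par$Wd, g)) + par$bd
}

# full backward pass for one sample; returns gradient list matching par
tiny_cnn_grad <- function(par, image, y_onehot, spec, drop_mask = NULL) {
  fw <- tiny_cnn_trunk(par, image, spec, keep = TRUE)
  feats <- fw$features
  K <- dim(feats)[3]
  g <- apply(feats, 3L, mean)
  if (!is.null(drop_mask)) g <- g * drop_mask
  z <- drop(crossprod(par$Wd, g)) + par$bd
  p <- softmax(z)
  dz <- p - y_onehot
  gWd <- outer(g, dz)
  gbd <- dz
  dg <- drop(par$Wd %*% dz)
  if (!is.null(drop_mask)) dg <- dg * drop_mask
  s2 <- prod(dim(feats)[1:2])
  dx <- array(rep(dg / s2, each = s2), dim(feats))  # GAP spreads gradient
  gblocks <- vector("list", length(par$blocks))
  for (i in rev(seq_along(par$blocks))) {
    blk <- par$blocks[[i]]
    cc <- fw$cache[[i]]
    if (!is.null(cc$pool)) dx <- maxpool2_back(dx, cc$pool$masks, cc$pool$in_dim)
    dx <- dx * cc$relu_mask
    d <- dim(dx)
    dx_mat <- dx; dim(dx_mat) <- c(d[1] * d[2], d[3])
    pre_mat <- cc$pre; dim(pre_mat) <- c(d[1] * d[2], dim(cc$pre)[3])
    gpw <- crossprod(pre_mat, dx_mat)
    gpb <- colSums(dx_mat)
    dpre <- dx_mat %*% t(blk$pw)
    dim(dpre) <- dim(cc$pre)
    bk <- dw_conv_back(cc$x_in, blk$dw, dpre)
    gblocks[[i]] <- list(dw = bk$dW, pw = gpw, pb = gpb)
    dx <- bk$dx
  }
  list(grad = list(blocks = gblocks, Wd = gWd, bd = gbd),
       loss = -log(max(sum(p * y_onehot), 1e-12)),
       p = p)
}

#' Build a tiny CNN and expose it through the adapter contract
#'
#' Constructs a randomly initialized (seeded) tiny CNN from a
#' [tiny_cnn_spec()] and wraps it as a [model_adapter()]: `features()`
#' returns the deepest-conv feature stack, `head_forward()` runs the
#' GAP-plus-dense head (dropout disabled, deterministic), and
#' `linear_head` carries the exact `(W, b)` descriptor of the head.
#' Parameters live in a mutable environment so the same adapter reflects
#' subsequent training.
#'
#' @param spec A [tiny_cnn_spec()].
#' @param seed Integer seed for weight initialization.
#' @param id Model identifier.
#' @return A `model_adapter` (also of class `tiny_cnn`).
#' @export
build_tiny_cnn <- function(spec, seed = 1L, id = sprintf("tiny-cnn-%d", seed)) {
  stopifnot(inherits(spec, "tiny_cnn_spec"))
  env <- new.env(parent = emptyenv())
  env$par <- tiny_cnn_init(spec, seed)
  env$norm <- NULL  # dataset-level (mean, sd), set after training
  features <- function(image) {
    if (!all(dim(image) == spec$image_size))
      stop("image must be ", spec$image_size, "x", spec$image_size)
    if (!is.null(env$norm)) image <- (image - env$norm$mean) / env$norm$sd
    feature_stack(tiny_cnn_trunk(env$par, image, spec)$features)
  }
  head_forward <- function(stack, score_kind = c("logit", "probability")) {
    score_kind <- match.arg(score_kind)
    z <- tiny_cnn_logits(env$par, unclass(stack))
    if (score_kind == "probability") class_scores(softmax(z), "probability")
    else class_scores(z, "logit")
  }
  adapter <- model_adapter(features, head_forward,
                           linear_head = list(W = env$par$Wd, b = env$par$bd),
                           id = id,
                           input_size = c(spec$image_size, spec$image_size))
  adapter$spec <- spec
  adapter$env <- env
  adapter$seed <- seed
  class(adapter) <- c("tiny_cnn", class(adapter))
  adapter
}

# keep the public linear_head descriptor in sync with trained parameters
refresh_linear_head <- function(model) {
  model$linear_head <- list(W = model$env$par$Wd, b = model$env$par$bd)
  model
}

#' Predict abnormal-class probability with a tiny CNN
#'
#' Applies the model's stored dataset-level normalization (if any) before
#' the forward pass, so raw `[0, 1]` images can be scored directly.
#'
#' @param model A [build_tiny_cnn()] adapter.
#' @param images List of image matrices.
#' @return Numeric vector of abnormal-class probabilities (class order in
#'   the head is `(abnormal, normal)`).
#' @export
tiny_cnn_predict <- function(model, images) {
  nrm <- model$env$norm
  vapply(images, function(im) {
    if (!is.null(nrm)) im <- (im - nrm$mean) / nrm$sd
    z <- tiny_cnn_logits(model$env$par, tiny_cnn_trunk(model$env$par, im,
                                                      model$spec)$features)
    softmax(z)[1]
  }, numeric(1))
}

# Adam update over the nested parameter list; opt carries first/second
# moment estimates and the step counter.
adam_init <- function(par) {
  list(m = zero_like(par), v = zero_like(par), t = 0L)
}

adam_update <- function(par, opt, grad, lr, n, lr_head = lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  upd <- function(p, m, v, g, rate = lr) {
    g <- g / n
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - rate * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(par$blocks)) {
    for (nm in c("dw", "pw", "pb")) {
      u <- upd(par$blocks[[i]][[nm]], opt$m$blocks[[i]][[nm]],
               opt$v$blocks[[i]][[nm]], grad$blocks[[i]][[nm]])
      par$blocks[[i]][[nm]] <- u$p
      opt$m$blocks[[i]][[nm]] <- u$m
      opt$v$blocks[[i]][[nm]] <- u$v
    }
  }
  for (nm in c("Wd", "bd")) {
    u <- upd(par[[nm]], opt$m[[nm]], opt$v[[nm]], grad[[nm]], rate = lr_head)
    par[[nm]] <- u$p
    opt$m[[nm]] <- u$m
    opt$v[[nm]] <- u$v
  }
  list(par = par, opt = opt)
}

zero_like <- function(par) {
  rapply(par, function(x) x * 0, how = "replace")
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(a$blocks))
    for (nm in c("dw", "pw", "pb"))
      a$blocks[[i]][[nm]] <- a$blocks[[i]][[nm]] + b$blocks[[i]][[nm]]
  a$Wd <- a$Wd + b$Wd
  a$bd <- a$bd + b$bd
  a
}

#' Train a tiny CNN by minibatch gradient descent with early stopping
#'
#' Cross-entropy loss, Adam updates, dropout 0.5 on the GAP features
#' during training only, early stopping on validation loss (the best
#' parameters are restored). Deterministic given `seed`.
#'
#' @param model A [build_tiny_cnn()] adapter (modified in place and
#'   returned).
#' @param images,labels Training images (list of matrices) and
#'   `"abnormal"`/`"normal"` labels.
#' @param val_images,val_labels Validation split for early stopping.
#' @param epochs Maximum epochs (default 10).
#' @param lr,lr_head,batch_size Optimizer hyperparameters; the dense head
#'   trains at `lr_head` (default `10 * lr`), the usual arrangement when a
#'   freshly initialized linear head sits on slowly adapting features.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Seed for shuffling and dropout.
#' @return The trained model adapter, with attribute `history` (per-epoch
#'   validation loss/accuracy) attached.
#' @export
train_tiny_cnn <- function(model, images, labels, val_images, val_labels,
                           epochs = 10L, lr = 0.01, lr_head = 10 * lr,
                           batch_size = 4L, patience = 5L, seed = 1L) {
  stopifnot(inherits(model, "tiny_cnn"))
  if (length(images) == 0L || length(val_images) == 0L)
    stop("empty training or validation split")
  y <- as_binary_labels(labels)      # 1 = abnormal
  yv <- as_binary_labels(val_labels)
  spec <- model$spec
  env <- model$env
  opt <- adam_init(env$par)
  best <- list(par = env$par, loss = Inf, epoch = 0L)
  K <- spec$section_kernels[3]
  history <- NULL
  set.seed(seed)
  restarts <- 0L
  for (ep in seq_len(epochs)) {
    # a run stuck near chance after several epochs is a failed
    # initialization basin: reinitialize once (seeded) and keep going
    # within the same epoch budget
    if (ep >= 5L && restarts < 1L &&
        all(history$val_accuracy < 0.7)) {
      restarts <- restarts + 1L
      env$par <- tiny_cnn_init(spec, model$seed + 7919L * restarts)
      opt <- adam_init(env$par)
      best$epoch <- ep  # give the restart its own patience window
    }
    ord <- sample(seq_along(images))
    for (start in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in idx) {
        drop_mask <- stats::rbinom(K, 1L, 0.5) * 2  # inverted dropout, p = 0.5
        gr <- tiny_cnn_grad(env$par, images[[i]],
                            if (y[i] == 1L) c(1, 0) else c(0, 1),
                            spec, drop_mask = drop_mask)
        acc <- add_grads(acc, gr$grad)
      }
      st <- adam_update(env$par, opt, acc, lr, length(idx), lr_head = lr_head)
      env$par <- st$par; opt <- st$opt
    }
    pv <- tiny_cnn_predict(model, val_images)
    vloss <- -mean(log(pmax(ifelse(yv == 1L, pv, 1 - pv), 1e-12)))
    if (!is.finite(vloss)) vloss <- Inf
    vacc <- mean((pv >= 0.5) == (yv == 1L))
    history <- rbind(history, data.frame(epoch = ep, val_loss = vloss,
                                         val_accuracy = vacc))
    if (vloss < best$loss - 1e-5) best <- list(par = env$par, loss = vloss,
                                               epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  env$par <- best$par
  model <- refresh_linear_head(model)
  attr(model, "history") <- history
  model
}

#' Train several tiny CNNs on a synthetic dataset and collect predictions
#'
#' Splits the dataset by sample id into disjoint train / validation / test
#' parts (60/20/20, seeded), trains each model with [train_tiny_cnn()],
#' and returns the trained adapters together with each model's
#' [probability_table()] on the held-out test split — the desk-scale
#' analogue of fine-tuning a bank of classifiers and collecting their
#' test-set softmax outputs.
#'
#' @param models List of [build_tiny_cnn()] adapters.
#' @param dataset A [generate_dataset()] result.
#' @param epochs Maximum epochs per model.
#' @param seed Master seed (split and per-model training seeds derive from
#'   it).
#' @return List with `models` (trained adapters), `tables` (per-model
#'   probability tables on the test split), `split` (the id partition),
#'   `accuracy` (named held-out accuracies).
#' @export
train_demo <- function(models, dataset, epochs = 10L, seed = 1L) {
  ids <- names(dataset$samples)
  if (length(ids) < 10L) stop("dataset too small to split")
  labels <- dataset_labels(dataset)
  split <- with_local_seed(seed, {
    ord <- sample(ids)
    n <- length(ord)
    n_tr <- floor(0.6 * n); n_va <- floor(0.2 * n)
    list(train = ord[seq_len(n_tr)],
         val = ord[n_tr + seq_len(n_va)],
         test = ord[(n_tr + n_va + 1L):n])
  })
  imgs <- lapply(dataset$samples, `[[`, "image")
  # dataset-level standardization fitted on the training split only
  norm <- fit_norm_stats(imgs[split$train])
  cimgs <- lapply(imgs, function(im) (im - norm$mean) / norm$sd)
  tables <- list()
  accs <- numeric(0)
  for (j in seq_along(models)) {
    m <- train_tiny_cnn(models[[j]],
                        cimgs[split$train], labels[split$train],
                        cimgs[split$val], labels[split$val],
                        epochs = epochs, seed = seed + j)
    m$env$norm <- norm  # adapters now standardize raw images themselves
    models[[j]] <- m
    p <- tiny_cnn_predict(m, imgs[split$test])
    tables[[m$id]] <- probability_table(p, 1 - p, model_id = m$id,
                                        image_id = split$test)
    accs[m$id] <- mean((p >= 0.5) == (labels[split$test] == "abnormal"))
  }
  list(models = models, tables = tables, split = split, accuracy = accs,
       norm = norm)
}
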