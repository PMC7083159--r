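# Synthetic image generator and the tiny-CNN model factory.

test_that("samples are deterministic per seed and label-consistent", {
  s1 <- generate_sample(31, n_lesions = 2)
  s2 <- generate_sample(31, n_lesions = 2)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$lesion_boxes, s2$lesion_boxes)
  expect_identical(s1$label, "abnormal")
  expect_length(s1$lesion_boxes, 2L)
  normal <- generate_sample(32, n_lesions = 0)
  expect_identical(normal$label, "normal")
  expect_length(normal$lesion_boxes, 0L)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_true(all(s1$mask %in% c(0L, 1L)))
})

test_that("lesion boxes lie inside the lung-mask bounding box", {
  for (seed in 1:15) {
    s <- generate_sample(seed, n_lesions = sample(1:2, 1))
    mb <- mask_to_bbox(s$mask)
    for (b in s$lesion_boxes) {
      expect_gte(b[["x_min"]], mb[["x_min"]])
      expect_gte(b[["y_min"]], mb[["y_min"]])
      expect_lte(b[["x_max"]], mb[["x_max"]])
      expect_lte(b[["y_max"]], mb[["y_max"]])
    }
  }
})

test_that("impossible lesion placement raises a placement error", {
  expect_error(generate_sample(1, size = 32, n_lesions = 40), "placement")
})

test_that("datasets honour class fractions, manifests, and seed streams", {
  ds <- generate_dataset(30, 0.5, seed = 21)
  labels <- dataset_labels(ds)
  expect_equal(sum(labels == "abnormal"), 15L)
  # manifest rows = normals + total lesion boxes
  n_boxes <- sum(vapply(ds$samples, function(s) length(s$lesion_boxes), 0L))
  expect_equal(nrow(ds$manifest), sum(labels == "normal") + n_boxes)
  # reproducible; different master seeds give different images
  ds2 <- generate_dataset(30, 0.5, seed = 21)
  expect_identical(ds$samples[[1]]$image, ds2$samples[[1]]$image)
  ds3 <- generate_dataset(30, 0.5, seed = 22)
  imgs1 <- lapply(ds$samples, `[[`, "image")
  imgs3 <- lapply(ds3$samples, `[[`, "image")
  expect_false(any(mapply(identical, imgs1, imgs3)))
  # ground-truth table matches lesion boxes
  gt <- dataset_gt(ds)
  expect_equal(sum(!is.na(gt$x_min)), n_boxes)
  expect_error(generate_dataset(30, 0, seed = 1), "strictly between")
  expect_error(generate_dataset(1, 0.5, seed = 1), "at least 2")
})

test_that("dataset round-trips through PNG + manifest on disk", {
  ds <- generate_dataset(6, 0.5, seed = 33, size = 32)
  dir <- tempfile()
  write_dataset(ds, dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_setequal(unique(manifest$patientId), names(ds$samples))
  img <- read_image(file.path(dir, "images", paste0(names(ds$samples)[1], ".png")))
  expect_equal(dim(img), dim(ds$samples[[1]]$image))
  expect_lt(max(abs(img - ds$samples[[1]]$image)), 1 / 255)  # 8-bit quantization
})

test_that("tiny CNN specs follow the architecture rules", {
  expect_equal(tiny_cnn_spec(64L, 1L)$n_blocks, 3L)
  s <- tiny_cnn_spec(64L, 4L)
  expect_equal(s$kernels_initial, 32L)       # ceil(64 / sqrt(4))
  expect_equal(s$n_blocks, 12L)
  expect_equal(s$section_kernels, c(32L, 64L, 128L))  # doubles per section
  expect_error(tiny_cnn_spec(64L, 0L), "depth")
})

test_that("built models satisfy the adapter linear-head agreement contract", {
  m <- seeded_tiny_cnn(seed = 41, size = 16L, k0 = 2L)
  set.seed(42)
  img <- matrix(runif(256), 16, 16)
  stack <- m$features(img)
  expect_s3_class(stack, "feature_stack")
  expect_equal(dim(stack), c(4L, 4L, 8L))  # 16 / 4 spatial, 4 * k0 channels
  logits <- as.numeric(m$head_forward(stack, "logit"))
  W <- m$linear_head$W; b <- m$linear_head$b
  gap <- apply(unclass(stack), 3, mean)
  expect_equal(logits, drop(crossprod(W, gap)) + b, tolerance = 1e-10)
  probs <- as.numeric(m$head_forward(stack, "probability"))
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  # head_forward is deterministic (no live dropout at inference)
  expect_identical(as.numeric(m$head_forward(stack, "logit")), logits)
})

test_that("analytic gradients match finite differences on a tiny model", {
  spec <- tiny_cnn_spec(8L, 1L, kernels_initial = 2L)
  m <- build_tiny_cnn(spec, seed = 3)
  set.seed(4)
  m$env$par$Wd <- matrix(rnorm(8 * 2, sd = 0.3), 8, 2)
  par <- m$env$par
  img <- matrix(runif(64), 8, 8)
  gr <- crmens:::tiny_cnn_grad(par, img, c(1, 0), spec)
  lossfn <- function(p) {
    f <- crmens:::tiny_cnn_trunk(p, img, spec)$features
    -log(crmens:::softmax(crmens:::tiny_cnn_logits(p, f))[1])
  }
  eps <- 1e-6
  for (bi in 1:3) for (nm in c("dw", "pw", "pb")) {
    v <- par$blocks[[bi]][[nm]]
    for (j in sample(length(v), min(3, length(v)))) {
      p2 <- par
      p2$blocks[[bi]][[nm]][j] <- p2$blocks[[bi]][[nm]][j] + eps
      num <- (lossfn(p2) - lossfn(par)) / eps
      expect_equal(gr$grad$blocks[[bi]][[nm]][j], num, tolerance = 1e-3)
    }
  }
})

test_that("an untrained zero-head model predicts exactly chance", {
  m <- build_tiny_cnn(tiny_cnn_spec(16L, 1L, kernels_initial = 2L), seed = 5)
  p <- tiny_cnn_predict(m, list(matrix(runif(256), 16, 16)))
  expect_equal(p, 0.5, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("shuffled labels stop a tiny model from beating chance", {
  set.seed(71)
  ds <- generate_dataset(40, 0.5, seed = 71, size = 32)
  labels <- sample(dataset_labels(ds))  # break the image-label link
  imgs <- lapply(ds$samples, `[[`, "image")
  m <- build_tiny_cnn(tiny_cnn_spec(32L, 1L, kernels_initial = 4L), seed = 72)
  m <- train_tiny_cnn(m, imgs[1:28], labels[1:28], imgs[29:40], labels[29:40],
                      epochs = 3, seed = 73)
  p <- tiny_cnn_predict(m, imgs[29:40])
  acc <- mean((p >= 0.5) == (labels[29:40] == "abnormal"))
  expect_lte(acc, 0.8)  # no better than chance, up to small-sample noise
})
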