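# Combining per-model class probabilities: voting, averaging, weighting,
# stacking.

make_tables <- function(mat_list, ids = NULL) {
  lapply(seq_along(mat_list), function(j)
    probability_table(mat_list[[j]], 1 - mat_list[[j]],
                      model_id = paste0("m", j), image_id = ids))
}

test_that("majority vote equals an independent mode over all 128 seven-voter patterns", {
  patterns <- expand.grid(rep(list(c(0L, 1L)), 7))
  for (r in seq_len(nrow(patterns))) {
    votes <- as.integer(patterns[r, ])
    tables <- make_tables(lapply(votes, function(v) if (v) 0.9 else 0.1))
    got <- majority_vote(tables)
    want <- if (sum(votes) > 7 / 2) "abnormal" else "normal"
    expect_identical(got, want)
    # an odd voter count can never tie
    expect_true(sum(votes) != 7 - sum(votes))
  }
})

test_that("vote ties with an even model count resolve to abnormal", {
  tables <- make_tables(list(c(0.9, 0.1), c(0.1, 0.9)))
  expect_identical(majority_vote(tables), c("abnormal", "abnormal"))
})

test_that("simple averaging is the elementwise mean and keeps rows stochastic", {
  tables <- make_tables(list(0.8, 0.4))
  avg <- simple_average(tables)
  expect_equal(avg$p_abnormal, 0.6)
  expect_equal(avg$p_abnormal + avg$p_normal, 1)
  same <- make_tables(list(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(simple_average(same)$p_abnormal, c(0.3, 0.7))
  set.seed(5)
  rnd <- make_tables(replicate(4, runif(10), simplify = FALSE))
  expect_true(all(abs(simple_average(rnd)$p_abnormal +
                        simple_average(rnd)$p_normal - 1) < 1e-12))
})

test_that("weighted averaging is convex and reduces to simple averaging", {
  set.seed(6)
  mats <- replicate(7, runif(5), simplify = FALSE)
  tables <- make_tables(mats)
  uw <- weighted_average(tables, rep(1 / 7, 7))
  expect_equal(uw$p_abnormal, simple_average(tables)$p_abnormal,
               tolerance = 1e-12)
  onehot <- c(0, 0, 1, 0, 0, 0, 0)
  expect_equal(weighted_average(tables, onehot)$p_abnormal, mats[[3]])
  w <- c(0.25, 0.25, 0.1, 0.1, 0.1, 0.1, 0.1)
  got <- weighted_average(tables, w)$p_abnormal
  hand <- Reduce(`+`, Map(`*`, mats, w))
  expect_equal(got, hand, tolerance = 1e-12)
  P <- do.call(cbind, mats)
  expect_true(all(got >= apply(P, 1, min) - 1e-12 &
                    got <= apply(P, 1, max) + 1e-12))
  expect_error(weighted_average(tables, rep(0.2, 7)), "sum to 1")
  expect_error(weighted_average(tables, rep(0.5, 2)), "one weight per model")
})

test_that("probability tables validate their rows", {
  expect_error(probability_table(c(0.5, 0.8), c(0.4, 0.2)), "sum to 1")
  expect_error(probability_table(1.2, -0.2), "\\[0, 1\\]")
  expect_error(simple_average(list(probability_table(c(0.5, 0.5)),
                                   probability_table(0.5))),
               "disagree")
})

# linearly separable construction: two informative base models plus noise
separable_fixture <- function(n, n_models = 7, seed = 1) {
  set.seed(seed)
  y <- rep(c("abnormal", "normal"), length.out = n)
  mats <- lapply(seq_len(n_models), function(j) {
    if (j <= 2) pmin(pmax(ifelse(y == "abnormal", 0.85, 0.15) +
                            rnorm(n, sd = 0.05), 0), 1)
    else runif(n)
  })
  list(tables = make_tables(mats), y = y)
}

test_that("stacking learns a separable combination and is seed-deterministic", {
  fx <- separable_fixture(120)
  meta <- fit_stacking(fx$tables, fx$y, seed = 3)
  expect_equal(meta$input_width, 14L)  # 7 models x 2 classes
  pred <- predict(meta, fx$tables)
  expect_true(all(abs(pred$p_abnormal + pred$p_normal - 1) < 1e-6))
  train_acc <- mean((pred$p_abnormal >= 0.5) == (fx$y == "abnormal"))
  expect_gte(train_acc, 0.95)
  # held-out: same generator, fresh draw
  fx2 <- separable_fixture(60, seed = 9)
  pred2 <- predict(meta, fx2$tables)
  expect_gte(mean((pred2$p_abnormal >= 0.5) == (fx2$y == "abnormal")), 0.9)
  # determinism
  meta2 <- fit_stacking(fx$tables, fx$y, seed = 3)
  expect_identical(meta$par, meta2$par)
  # permuting samples permutes outputs identically
  perm <- sample(seq_len(120))
  permuted <- lapply(fx$tables, function(t)
    probability_table(t$p_abnormal[perm], t$p_normal[perm],
                      image_id = t$image_id[perm]))
  expect_equal(predict(meta, permuted)$p_abnormal, pred$p_abnormal[perm],
               tolerance = 1e-12)
  # frozen-base contract: inputs unchanged by fitting
  expect_equal(fx$tables[[1]]$p_abnormal, separable_fixture(120)$tables[[1]]$p_abnormal)
})

test_that("stacking rejects width mismatches", {
  fx <- separable_fixture(40)
  meta <- fit_stacking(fx$tables, fx$y, seed = 2)
  expect_error(predict(meta, fx$tables[1:3]), "input width")
})

test_that("stacking behaves comparably to an established single-hidden-layer net", {
  skip_if_not_installed("nnet")
  fx <- separable_fixture(120, seed = 4)
  X <- do.call(cbind, lapply(fx$tables, function(t) cbind(t$p_abnormal, t$p_normal)))
  set.seed(1)
  ref <- nnet::nnet(X, nnet::class.ind(factor(fx$y)), size = 14, softmax = TRUE,
                    trace = FALSE, maxit = 200)
  ref_acc <- mean((predict(ref)[, "abnormal"] >= 0.5) == (fx$y == "abnormal"))
  meta <- fit_stacking(fx$tables, fx$y, seed = 4)
  own_acc <- mean((predict(meta, fx$tables)$p_abnormal >= 0.5) ==
                    (fx$y == "abnormal"))
  expect_gte(own_acc, ref_acc - 0.05)
})
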