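test_that("stratified 4:1 split gives the canonical per-class counts", {
  sp <- split_dataset(label_samples(rep(0:7, each = 100)), rng_seed = 3)
  expect_length(sp$train, 640L)
  expect_length(sp$test, 160L)
  test_labels <- vapply(sp$test, `[[`, integer(1), "label")
  expect_equal(unname(table(test_labels)), rep(20L, 8L), ignore_attr = TRUE)

  sp2 <- split_dataset(label_samples(rep(0L, 5)), rng_seed = 1)
  expect_length(sp2$train, 4L)
  expect_length(sp2$test, 1L)

  sp3 <- split_dataset(label_samples(rep(0:2, each = 7)), rng_seed = 1)
  expect_length(sp3$train, 18L)
  expect_length(sp3$test, 3L)

  # disjoint and covering, deterministic under the seed
  labs <- rep(0:2, times = c(10, 15, 20))
  samples <- label_samples(labs)
  for (i in seq_along(samples)) samples[[i]]$id <- i
  a <- split_dataset(samples, rng_seed = 9)
  b <- split_dataset(samples, rng_seed = 9)
  ids <- function(x) vapply(x, `[[`, integer(1), "id")
  expect_identical(ids(a$test), ids(b$test))
  expect_length(intersect(ids(a$train), ids(a$test)), 0L)
  expect_setequal(c(ids(a$train), ids(a$test)), seq_along(samples))
})

test_that("cross-entropy matches closed-form values", {
  expect_equal(cross_entropy(c(1, 0, 0), c(1, 1e-9, 1e-9)), 0, tolerance = 1e-8)
  expect_equal(cross_entropy(c(0, 1, 0, 0, 0, 0, 0, 0), rep(1 / 8, 8)), log(8))
  expect_equal(cross_entropy(c(1, 0, 0), c(0.7, 0.2, 0.1)), -log(0.7))
  # integer labels and matrix batches
  yh <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  expect_equal(cross_entropy(c(0L, 1L), yh), mean(-log(c(0.7, 0.8))))
  # logits are softmaxed inside the loss
  lg <- rbind(c(2, 0, -1), c(0, 3, 0))
  pr <- t(apply(lg, 1, function(z) exp(z) / sum(exp(z))))
  expect_equal(cross_entropy(c(0L, 1L), lg, type = "logit"),
               cross_entropy(c(0L, 1L), pr))
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.3)), "sum to 1")
  expect_error(cross_entropy(c(0L), matrix(c(NaN, 1), 1)), "non-finite")
})

test_that("confusion-matrix metrics match hand arithmetic", {
  cm <- matrix(c(50L, 5L, 10L, 35L), 2)   # rows = true, cols = predicted
  r <- metrics_from_confusion(cm)
  expect_equal(r$overall_accuracy, 85 / 100, tolerance = 1e-12)
  expect_equal(r$per_class$precision[1], 50 / 55, tolerance = 1e-12)
  expect_equal(r$per_class$recall[1], 50 / 60, tolerance = 1e-12)
  expect_equal(r$per_class$f1[1],
               2 * (50 / 55) * (50 / 60) / (50 / 55 + 50 / 60), tolerance = 1e-12)

  perfect <- diag(c(7L, 9L, 4L))
  rp <- metrics_from_confusion(perfect)
  expect_equal(rp$overall_accuracy, 1)
  expect_equal(rp$macro_precision, 1)
  expect_equal(rp$macro_recall, 1)
  expect_equal(rp$macro_f1, 1)

  # every prediction lands in class 1 of 4: macro F1 sits below accuracy
  lump <- matrix(0L, 4, 4); lump[, 1] <- c(10L, 10L, 10L, 10L)
  expect_warning(rl <- metrics_from_confusion(lump), "0/0")
  expect_lt(rl$macro_f1, rl$overall_accuracy)
  expect_equal(rl$per_class$precision[2:4], rep(0, 3))
})

test_that("one-vs-rest counts always partition the sample total", {
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 4), k)
    suppressWarnings(r <- metrics_from_confusion(cm))
    with(r$per_class, expect_equal(tp + tn + fp + fn, rep(sum(cm), k)))
    # F1 is the harmonic mean of precision and recall
    with(r$per_class, expect_equal(
      f1, ifelse(precision + recall == 0, 0,
                 2 / (1 / pmax(precision, 1e-300) + 1 / pmax(recall, 1e-300)))))
    expect_true(all(unlist(r$per_class[, c("precision", "recall", "f1")]) >= 0))
    expect_true(all(unlist(r$per_class[, c("precision", "recall", "f1")]) <= 1))
  }
})

test_that("training reduces the loss on a separable task, deterministically", {
  ds <- make_dataset(separable_spec(seed = 2))
  sp <- split_dataset(ds, rng_seed = 2)
  spec <- model_spec(2, c(16, 16, 16))
  cfg <- train_config(epochs = 30, batch_size = 4, rng_seed = 2)

  m <- build_model(spec, 5, rng_seed = 2)
  tr1 <- train(m, sp$train, cfg)
  expect_lt(tail(tr1$history$train_loss, 1), tr1$history$train_loss[1])
  # 5-epoch moving average trends downward overall
  ma <- stats::filter(tr1$history$train_loss, rep(1 / 5, 5))
  ma <- ma[!is.na(ma)]
  expect_lt(tail(ma, 1), ma[1])

  tr2 <- train(m, sp$train, cfg)
  expect_identical(tr1$history$train_loss, tr2$history$train_loss)

  # zero epochs: untouched weights, empty history
  tr0 <- train(m, sp$train, train_config(epochs = 0, rng_seed = 2))
  expect_identical(tr0$model$conv[[1]]$K, m$conv[[1]]$K)
  expect_identical(nrow(tr0$history), 0L)

  expect_error(train(m, sp$train[1:3], train_config(epochs = 1, batch_size = 8)),
               "exceeds")
})

test_that("the separable task is learned to high held-out accuracy", {
  wins <- 0L
  for (seed in 1:3) {
    ds <- make_dataset(separable_spec(seeds_per_class = 20L, seed = seed))
    sp <- split_dataset(ds, rng_seed = seed)
    m <- build_model(model_spec(2, c(16, 16, 16)), 5, rng_seed = seed)
    tr <- train(m, sp$train, train_config(epochs = 40, batch_size = 4,
                                          rng_seed = seed))
    rep <- evaluate(tr$model, sp$test)
    if (rep$overall_accuracy >= 0.9) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("evaluation breaks argmax ties toward the lowest class index", {
  ds <- make_dataset(separable_spec(seeds_per_class = 3L, seed = 4))
  m <- build_model(model_spec(2, c(16, 16, 16)), 3, rng_seed = 4)
  # zero the output layer: every sample yields identical logits
  k <- length(m$fc)
  m$fc[[k]]$W[] <- 0
  m$fc[[k]]$b[] <- 0
  suppressWarnings(rep <- evaluate(m, ds))
  expect_equal(sum(rep$confusion[, 1]), length(ds))

  bad <- ds
  bad[[1]]$label <- 5L
  expect_error(evaluate(m, bad), "n_classes")
})
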