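#' Training configuration
#'
#' Adam hyperparameters at the field's standard defaults (learning rate
#' 0.001, decay rates 0.9/0.999, epsilon 1e-8), mini-batch size, epoch count
#' and the RNG seed governing shuffling and dropout.
#'
#' @param lr learning rate alpha. Default 0.001.
#' @param beta1,beta2 Adam exponential decay rates for the first and second
#'   moment estimates.
#' @param eps Adam stability constant.
#' @param epochs training epochs (0 means return the model untouched).
#' @param batch_size mini-batch size. Default 8.
#' @param rng_seed integer seed for shuffling and dropout.
#' @param selection_metric metric used by the depth search: `"accuracy"` or
#'   `"macro_f1"`.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         epochs = 100L, batch_size = 8L, rng_seed = 1L,
                         selection_metric = c("accuracy", "macro_f1")) {
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, epochs >= 0,
            batch_size >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed),
                 selection_metric = match.arg(selection_metric)),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Splits a labeled sample list 4:1 by default: per class, `floor(n_c * test_fraction / (1 - ... ))`
#' — concretely `floor(n_c / 5)` samples go to test and the remainder to
#' train, so 8 classes x 100 seeds give 640 train / 160 test. Deterministic
#' given the seed; the two sets are disjoint and cover the input.
#'
#' @param samples list of samples, each with a `label` field (0-based class id).
#' @param test_fraction fraction held out. Default 1/5.
#' @param stratified split per class (default) or globally.
#' @param rng_seed integer seed.
#' @return list with `train` and `test` sample lists.
#' @export
split_dataset <- function(samples, test_fraction = 1/5, stratified = TRUE,
                          rng_seed = 1L) {
  stopifnot(length(samples) >= 2L, test_fraction > 0, test_fraction < 1)
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rng_seed)
  test_idx <- integer(0)
  if (stratified) {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < 1L) stop("empty class under stratification: ", cl)
      n_test <- floor(length(idx) * test_fraction)
      if (n_test > 0L)
        test_idx <- c(test_idx, sample(idx, n_test))
    }
  } else {
    test_idx <- sample(seq_along(samples), floor(length(samples) * test_fraction))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(train = samples[setdiff(seq_along(samples), test_idx)],
       test = samples[sort(test_idx)])
}

#' Cross-entropy loss
#'
#' \deqn{L(y, \hat y) = -\sum_i y_i \log \hat y_i} for a one-hot true label
#' and a predicted probability vector; for a batch (matrix rows) the mean
#' over samples. With `type = "logit"` the inputs are raw scores converted to
#' probabilities by the normalized-exponential (softmax) transform inside the
#' loss, in its numerically stable log-sum-exp form.
#'
#' @param y true labels: one-hot vector/matrix, or 0-based integer vector.
#' @param y_hat predicted probabilities (rows summing to 1) or logits.
#' @param type `"prob"` (default) or `"logit"`.
#' @return mean loss, a scalar.
#' @export
cross_entropy <- function(y, y_hat, type = c("prob", "logit")) {
  type <- match.arg(type)
  if (is.null(dim(y_hat))) y_hat <- matrix(y_hat, nrow = 1)
  if (any(!is.finite(y_hat))) stop("non-finite values in predictions")
  one_hot <- (!is.null(dim(y))) ||
    (nrow(y_hat) == 1L && length(y) == ncol(y_hat) && sum(y) == 1 &&
       all(y %in% c(0, 1)))
  labels <- if (one_hot) {
    ym <- if (is.null(dim(y))) matrix(y, nrow = 1) else y
    as.integer(apply(ym, 1, which.max) - 1L)
  } else {
    as.integer(y)
  }
  if (type == "prob") {
    sums <- rowSums(y_hat)
    if (any(abs(sums - 1) > 1e-6)) stop("probability rows must sum to 1")
    if (any(y_hat <= 0 | y_hat > 1)) stop("probabilities must lie in (0, 1]")
    -mean(log(y_hat[cbind(seq_len(nrow(y_hat)), labels + 1L)]))
  } else {
    softmax_ce(y_hat, labels)$loss
  }
}

sample_array <- function(s) {
  x <- s$cube
  if (is_hypercube(x)) x$data else x
}

#' Train a model with Adam and cross-entropy
#'
#' Mini-batch gradient descent with bias-corrected first and second moment
#' estimates (Adam), softmax cross-entropy loss, seeded shuffling and
#' dropout. Per-epoch mean training loss, training accuracy and wall time
#' are recorded; single-threaded runs with the same seed are bit-identical.
#'
#' @param model a `vd_cnn` from [build_model].
#' @param train_set list of samples (`cube` + 0-based `label`).
#' @param config a [train_config].
#' @param log_csv optional path; per-epoch rows are appended as CSV.
#' @return list with `model` (trained) and `history` (data.frame of epoch,
#'   train_loss, train_acc, wall_time).
#' @export
train <- function(model, train_set, config, log_csv = NULL) {
  stopifnot(inherits(model, "vd_cnn"), inherits(config, "train_config"))
  n <- length(train_set)
  if (config$batch_size > n)
    stop(sprintf("batch_size %d exceeds dataset size %d", config$batch_size, n))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), wall_time = numeric(0))
  if (config$epochs == 0L) return(list(model = model, history = history))
  xs_all <- lapply(train_set, sample_array)
  labels <- vapply(train_set, function(s) as.integer(s$label), integer(1))
  if (any(labels < 0L | labels >= model$spec$n_classes))
    stop("label outside [0, n_classes)")
  state <- adam_init(model)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$rng_seed)
  for (ep in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    perm <- sample(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    ep_correct <- 0L
    for (st in starts) {
      idx <- perm[st:min(st + config$batch_size - 1L, n)]
      fw <- nn_forward(model, xs_all[idx], training = TRUE)
      model <- fw$model  # batch-norm running stats advanced
      ce <- softmax_ce(fw$logits, labels[idx])
      grads <- nn_backward(model, fw$caches, ce$dlogits)
      upd <- adam_step(model, grads, state, config$lr, config$beta1,
                       config$beta2, config$eps)
      model <- upd$model
      state <- upd$state
      ep_loss <- ep_loss + ce$loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(ce$probs, ties.method = "first") - 1L
                                     == labels[idx])
    }
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / n, train_acc = ep_correct / n,
      wall_time = proc.time()[["elapsed"]] - t0))
    if (!is.null(log_csv))
      utils::write.table(history[nrow(history), ], log_csv, sep = ",",
                         row.names = FALSE, col.names = !file.exists(log_csv),
                         append = file.exists(log_csv))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(model = model, history = history)
}

#' Confusion matrix from labels and predictions
#'
#' @param truth,pred 0-based integer class vectors of equal length.
#' @param n_classes number of classes.
#' @return an `n x n` count matrix, rows = true class, cols = predicted.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  if (any(truth < 0L | truth >= n_classes) || any(pred < 0L | pred >= n_classes))
    stop("label outside [0, n_classes)")
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1), pred = 0:(n_classes - 1)))
  for (i in seq_along(truth)) m[truth[i] + 1L, pred[i] + 1L] <-
      m[truth[i] + 1L, pred[i] + 1L] + 1L
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest counts give precision TP/(TP+FP), recall TP/(TP+FN)
#' and F1 = 2PR/(P+R); `accuracy` is the overall trace/total. Macro metrics
#' are unweighted class means. Empty 0/0 cells yield 0 with a warning rather
#' than NaN.
#'
#' @param confusion square count matrix (rows = true, cols = predicted).
#' @return an `eval_report` list.
#' @export
metrics_from_confusion <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  total <- sum(confusion)
  k <- nrow(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) warning(sprintf("0/0 in %s for class(es) %s; reporting 0",
                                  what, paste(which(bad) - 1L, collapse = ",")))
    out <- ifelse(bad, 0, num / den)
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  structure(list(
    confusion = confusion,
    overall_accuracy = sum(tp) / total,
    per_class = data.frame(class = seq_len(k) - 1L, tp = tp, tn = tn, fp = fp,
                           fn = fn, precision = precision, recall = recall,
                           f1 = f1),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy %.4f, macro P/R/F1 %.4f/%.4f/%.4f\n",
              sum(x$confusion), x$overall_accuracy, x$macro_precision,
              x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Evaluate a model on a test set
#'
#' Predictions are the argmax of the logits (ties resolved to the lowest
#' class index); metrics come from the one-vs-rest confusion-matrix counts
#' via [metrics_from_confusion].
#'
#' @param model a `vd_cnn`.
#' @param test_set nonempty list of samples (`cube` + 0-based `label`).
#' @param batch_size forward-pass batch size. Default 16.
#' @return an `eval_report`.
#' @export
evaluate <- function(model, test_set, batch_size = 16L) {
  stopifnot(length(test_set) >= 1L)
  truth <- vapply(test_set, function(s) as.integer(s$label), integer(1))
  if (any(truth < 0L | truth >= model$spec$n_classes))
    stop("label outside [0, n_classes)")
  xs <- lapply(test_set, sample_array)
  pred <- integer(0)
  for (st in seq(1L, length(xs), by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, length(xs))
    lg <- predict_logits(model, xs[idx])
    pred <- c(pred, max.col(lg, ties.method = "first") - 1L)
  }
  metrics_from_confusion(confusion_matrix(truth, pred, model$spec$n_classes))
}
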