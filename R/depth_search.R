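#' Candidate kernel-depth grid
#'
#' The arithmetic schedule `start, start + step, ...` up to `d_max`
#' (`D_k(t+1) = D_k(t) + 2` with the default step), e.g. 3..25 gives the 12
#' candidate depths of the full search.
#'
#' @param start first depth, odd. Default 3.
#' @param d_max termination bound. Default 25.
#' @param step increment. Default 2 (keeps depths odd).
#' @return integer vector of candidate depths.
#' @export
depth_grid <- function(start = 3L, d_max = 25L, step = 2L) {
  start <- as.integer(start); d_max <- as.integer(d_max); step <- as.integer(step)
  if (start %% 2L == 0L) stop("`start` must be odd")
  if (start > d_max) stop("`start` exceeds `d_max`")
  if (step < 1L) stop("`step` must be positive")
  seq.int(start, d_max, by = step)
}

#' Exhaustive kernel-depth search
#'
#' For each candidate depth: build a freshly initialized model (seed derived
#' from the base seed so every depth starts from comparable conditions),
#' train it on one fixed train split, and score `P(D_k)` on the fixed
#' evaluation split. The selected depth `D_best = argmax P(D_k)`; ties go to
#' the smallest (cheapest) depth. A depth whose shape planning fails is
#' recorded as a failure and the remaining depths still run.
#'
#' Results are resumable: when `cache_dir` is given, each depth's result is
#' stored keyed by (depth, seed) and reused if its stored configuration
#' matches exactly.
#'
#' @param train_set,test_set sample lists from one fixed [split_dataset] call.
#' @param spec a [model_spec].
#' @param base_config a [train_config]; `rng_seed` is the search's base seed
#'   and `selection_metric` defines `P`.
#' @param grid candidate depths from [depth_grid].
#' @param cache_dir optional directory for per-depth result caching.
#' @param keep_models keep each trained model in the result. Default FALSE.
#' @param verbose print one line per depth.
#' @return a `depth_search_result` with `grid`, `scores`, `histories`,
#'   `reports`, `failures` and `d_best`.
#' @export
depth_search <- function(train_set, test_set, spec, base_config,
                         grid = depth_grid(), cache_dir = NULL,
                         keep_models = FALSE, verbose = FALSE) {
  stopifnot(length(grid) >= 1L, inherits(base_config, "train_config"))
  scores <- rep(NA_real_, length(grid))
  histories <- vector("list", length(grid))
  reports <- vector("list", length(grid))
  models <- if (keep_models) vector("list", length(grid)) else NULL
  failures <- character(0)
  fingerprint <- list(spec = spec, config = base_config,
                      n_train = length(train_set), n_test = length(test_set))
  for (g in seq_along(grid)) {
    d <- grid[g]
    seed_d <- base_config$rng_seed  # common base seed isolates the depth effect
    cached <- NULL
    cache_file <- NULL
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      cache_file <- file.path(cache_dir,
                              sprintf("depth%02d_seed%d.rds", d, seed_d))
      if (file.exists(cache_file)) {
        prev <- readRDS(cache_file)
        if (identical(prev$fingerprint, fingerprint)) cached <- prev
      }
    }
    if (!is.null(cached)) {
      scores[g] <- cached$score
      histories[[g]] <- cached$history
      reports[[g]] <- cached$report
    } else {
      res <- tryCatch({
        model <- build_model(spec, d, rng_seed = seed_d)
        cfg <- base_config
        cfg$rng_seed <- seed_d
        tr <- train(model, train_set, cfg)
        rep <- evaluate(tr$model, test_set)
        score <- switch(base_config$selection_metric,
                        accuracy = rep$overall_accuracy,
                        macro_f1 = rep$macro_f1)
        list(score = score, history = tr$history, report = rep,
             model = tr$model)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("depth %d: %s", d, conditionMessage(res)))
        next
      }
      scores[g] <- res$score
      histories[[g]] <- res$history
      reports[[g]] <- res$report
      if (keep_models) models[[g]] <- res$model
      if (!is.null(cache_file))
        saveRDS(list(fingerprint = fingerprint, score = res$score,
                     history = res$history, report = res$report), cache_file)
    }
    if (verbose)
      message(sprintf("depth %2d: %s = %.4f", d,
                      base_config$selection_metric, scores[g]))
  }
  if (all(is.na(scores))) stop("every candidate depth failed: ",
                               paste(failures, collapse = "; "))
  d_best <- grid[which.max(scores)]  # which.max skips NA, first max = smallest depth
  structure(list(grid = grid, scores = scores, histories = histories,
                 reports = reports, failures = failures, d_best = d_best,
                 selection_metric = base_config$selection_metric),
            class = "depth_search_result")
}

#' @export
print.depth_search_result <- function(x, ...) {
  cat(sprintf("<depth_search_result> metric %s\n", x$selection_metric))
  for (g in seq_along(x$grid))
    cat(sprintf("  d = %2d  P = %s%s\n", x$grid[g],
                ifelse(is.na(x$scores[g]), "failed", sprintf("%.4f", x$scores[g])),
                ifelse(x$grid[g] == x$d_best, "  <- D_best", "")))
  invisible(x)
}
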