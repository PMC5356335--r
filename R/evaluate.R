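#' Misclassification rate
#'
#' @param labels True labels in \{-1, +1\}.
#' @param predictions Predicted labels in \{-1, +1\}.
#' @return Fraction of mismatches in \[0, 1\].
#' @export
error_rate <- function(labels, predictions) {
  if (length(labels) != length(predictions) || length(labels) < 1L)
    stop("labels and predictions must have equal positive length", call. = FALSE)
  mean(labels != predictions)
}

#' Area under the ROC curve
#'
#' Rank-statistic definition: the probability that a uniformly drawn positive
#' instance receives a higher score than a uniformly drawn negative one, with
#' ties credited 1/2. Computed from mid-ranks, equivalent to the
#' Wilcoxon–Mann–Whitney statistic.
#'
#' @param labels True labels in \{-1, +1\}; both classes must be present.
#' @param scores Real-valued scores (higher means more positive); typically
#'   the multi-model's averaged raw output `phi`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC requires both classes to be present", call. = FALSE)
  r <- rank(scores)  # mid-ranks handle ties with credit 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment. Fold labels are dealt round-robin from a
# global rotation that continues across classes, so overall fold sizes stay
# balanced even when k exceeds a class count (e.g. leave-one-out), while
# per-class fold counts still differ by at most one. The assignment of the
# dealt labels to instances within each class is shuffled.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (c in sort(unique(y))) {
      idx <- which(y == c)
      lab <- (offset + seq_along(idx) - 1L) %% k + 1L
      folds[idx] <- sample(lab)
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into k stratified folds, trains the multi-model on each
#' training complement and scores the held-out fold. Fold means are reported
#' with a 95% t-interval half-width over the k folds, the
#' "mean plus/minus half-width" convention.
#'
#' @param data A [labeled_dataset()].
#' @param k Number of folds (>= 2); every fold must contain both classes.
#' @param config Named list of arguments passed to [train_multimodel()]
#'   (e.g. `list(S = 5, T = 20, eta = 0.5, mode = "none")`).
#' @param seed Integer seed for fold assignment (also reused as the training
#'   seed when `config` does not set one).
#' @return An object of class `eval_report`: list with `per_fold` (data frame
#'   of fold, error, auroc), `error` and `auroc` (each `c(mean, half_width)`),
#'   `k`, `folds` (assignment vector).
#' @export
kfold_cv <- function(data, k, config, seed = 1L) {
  N <- n_instances(data)
  if (k < 2 || k > N) stop("k must be in [2, N]", call. = FALSE)
  folds <- stratified_folds(data$y, k, seed)
  if (is.null(config$seed)) config$seed <- seed
  per_fold <- lapply(seq_len(k), function(f) {
    train <- dataset_subset(data, which(folds != f))
    if (length(unique(train$y)) < 2L)
      stop("infeasible stratification: a training fold misses one class",
           call. = FALSE)
    test <- dataset_subset(data, which(folds == f))
    model <- do.call(train_multimodel, c(list(data = train), config))
    pred <- predict(model, test$x)
    # fold AUROC is undefined when the held-out fold has a single class
    # (e.g. leave-one-out); the error rate is always defined
    auc <- if (length(unique(test$y)) == 2L) auroc(test$y, pred$phi) else NA_real_
    data.frame(fold = f,
               error = error_rate(test$y, pred$label),
               auroc = auc)
  })
  per_fold <- do.call(rbind, per_fold)
  ci <- function(v) {
    v <- v[!is.na(v)]
    m <- mean(v)
    hw <- if (length(v) > 1)
      stats::qt(0.975, df = length(v) - 1) * stats::sd(v) / sqrt(length(v))
    else 0
    c(mean = m, half_width = hw)
  }
  structure(list(per_fold = per_fold,
                 error = ci(per_fold$error),
                 auroc = ci(per_fold$auroc),
                 k = k, folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV\n  error: %.4f +/- %.4f\n  AUROC: %.4f +/- %.4f\n",
              x$k, x$error[1], x$error[2], x$auroc[1], x$auroc[2]))
  invisible(x)
}

#' Paired comparison of two model configurations
#'
#' Trains both configurations on identical synthetic train/test replicates
#' (same data and subsample seeds) and summarizes the per-seed test-error
#' deltas `error_a - error_b` with a one-sided sign test (alternative: config
#' b has lower error, i.e. deltas tend positive) and a paired t summary.
#'
#' @param config_a,config_b Named argument lists for [train_multimodel()];
#'   per-replicate seeds are filled in automatically.
#' @param synth A [synth_spec()] describing the training distribution.
#' @param n_seeds Number of paired replicates.
#' @param n_test Test-set size drawn from the same distribution.
#' @param seed Master seed; replicate r uses `seed + r` streams.
#' @return List with `deltas`, `mean_delta`, `sign_test` (one-sided
#'   `binom.test` p-value over non-zero deltas), `t_test` (one-sided paired t
#'   p-value), `errors_a`, `errors_b`.
#' @export
paired_compare <- function(config_a, config_b, synth, n_seeds,
                           n_test = 1000L, seed = 1L) {
  errs <- vapply(seq_len(n_seeds), function(r) {
    sp_train <- synth
    sp_train$seed <- seed + 2L * r
    sp_test <- synth
    sp_test$n <- n_test
    sp_test$seed <- seed + 2L * r + 1L
    train <- gaussian_blobs(sp_train)
    test <- gaussian_blobs(sp_test)
    ca <- config_a; cb <- config_b
    ca$seed <- cb$seed <- seed + 2L * r
    ma <- do.call(train_multimodel, c(list(data = train), ca))
    mb <- do.call(train_multimodel, c(list(data = train), cb))
    c(error_rate(test$y, predict(ma, test$x)$label),
      error_rate(test$y, predict(mb, test$x)$label))
  }, numeric(2))
  deltas <- errs[1, ] - errs[2, ]
  nz <- deltas[deltas != 0]
  sign_p <- if (length(nz) > 0) {
    stats::binom.test(sum(nz > 0), length(nz), p = 0.5,
                      alternative = "greater")$p.value
  } else 1
  t_p <- if (stats::sd(deltas) > 0) {
    stats::t.test(deltas, alternative = "greater")$p.value
  } else if (mean(deltas) > 0) 0 else 1
  list(deltas = deltas, mean_delta = mean(deltas),
       sign_test = sign_p, t_test = t_p,
       errors_a = errs[1, ], errors_b = errs[2, ])
}
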