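#' Uniform initial boosting weights
#'
#' @param N Number of training instances.
#' @return Numeric vector `rep(1/N, N)`, a probability distribution.
#' @export
init_weights <- function(N) {
  stopifnot(N >= 1)
  rep(1 / N, N)
}

# Multiplicative Gentle Boost weight update: w_i <- w_i * exp(-y_i f(x_i)),
# floored at 1e-300 to avoid underflow on long runs, then renormalized.
update_weights <- function(w, y, fx) {
  w2 <- w * exp(-y * fx)
  w2 <- pmax(w2, 1e-300)
  w2 / sum(w2)
}

#' Run one boosting round
#'
#' Fits a regression stump to the weighted data and applies the Gentle Boost
#' multiplicative update `w_i' proportional to w_i * exp(-y_i f_t(x_i))`,
#' renormalized to a probability distribution.
#'
#' @param data A [labeled_dataset()] (the ensemble's training subset).
#' @param w Current weight vector over `data`.
#' @return List with `stump` (the fitted weak learner) and `w` (the updated
#'   weights).
#' @export
boost_round <- function(data, w) {
  st <- fit_stump(data, w)
  fx <- stump_predict(st, data$x)
  list(stump = st, w = update_weights(w, data$y, fx))
}

#' Train a Gentle Boost ensemble
#'
#' Runs `T` rounds of boosting with regression stumps on one training subset.
#' Training is deterministic for fixed data: stump fitting breaks ties by
#' feature index then threshold, and there is no other source of randomness.
#'
#' @param data A [labeled_dataset()].
#' @param T Number of boosting rounds (>= 1).
#' @param training_ids Optional identifiers of the training instances within a
#'   parent dataset (stored for provenance).
#' @param weight_trace If `TRUE`, keep the per-round weight vectors.
#' @return An object of class `gentleboost`: list with `stumps` (length-T
#'   list), `T`, `training_ids` and optionally `weight_trace`.
#' @export
gb_train <- function(data, T, training_ids = data$ids, weight_trace = FALSE) {
  stopifnot(T >= 1)
  w <- init_weights(n_instances(data))
  stumps <- vector("list", T)
  trace <- if (weight_trace) vector("list", T) else NULL
  for (t in seq_len(T)) {
    r <- boost_round(data, w)
    stumps[[t]] <- r$stump
    w <- r$w
    if (weight_trace) trace[[t]] <- w
  }
  structure(list(stumps = stumps, T = T, training_ids = training_ids,
                 weight_trace = trace),
            class = "gentleboost")
}

#' Raw ensemble output F(x)
#'
#' The Gentle Boost ensemble's confidence: the sum of its stumps' real-valued
#' predictions, so `|F(x)| <= T` for stumps fitted to -1/+1 labels.
#'
#' @param model A `gentleboost` model.
#' @param x Feature vector or matrix (instances in rows).
#' @return Numeric F(x), one value per instance.
#' @export
gb_predict_raw <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  out <- numeric(nrow(x))
  for (st in model$stumps) out <- out + stump_predict(st, x)
  out
}

#' Numerically stable sigmoid
#'
#' `g(z) = 1 / (1 + exp(-z))`, evaluated without overflow for large `|z|`
#' (the raw ensemble output can reach `T` in magnitude). `g(0) = 0.5`.
#'
#' @param z Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Class probability of a Gentle Boost ensemble
#'
#' Maps the raw confidence through the sigmoid: `g(F(x))`. An instance is
#' labeled positive when the probability exceeds 0.5.
#'
#' @inheritParams gb_predict_raw
#' @return Probabilities in (0, 1).
#' @export
gb_predict_proba <- function(model, x) {
  sigmoid(gb_predict_raw(model, x))
}

#' Empirical exponential loss
#'
#' `(1/N) * sum_i exp(-y_i F(x_i))` — the loss Gentle Boost descends. For two
#' correctly classified instances, the one with the smaller margin always
#' carries the larger per-instance loss.
#'
#' @param model A `gentleboost` model.
#' @param data A [labeled_dataset()].
#' @return Nonnegative scalar; equals 1 when F is identically 0.
#' @export
empirical_exp_loss <- function(model, data) {
  mean(exp(-data$y * gb_predict_raw(model, data$x)))
}

#' @export
print.gentleboost <- function(x, ...) {
  cat(sprintf("<gentleboost> T = %d stumps, trained on %d instances\n",
              x$T, length(x$training_ids)))
  invisible(x)
}
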