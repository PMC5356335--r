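# Brute-force oracles kept deliberately naive and independent of the
# implementation paths they check.

# Exhaustive weighted-least-squares stump search: every feature, every
# midpoint between consecutive distinct sorted values, leaf values = weighted
# label means. Returns the minimal achievable weighted SSE.
brute_stump_loss <- function(x, y, w) {
  best <- Inf
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      left <- x[, j] <= thr
      ml <- if (sum(w[left]) > 0) sum(w[left] * y[left]) / sum(w[left]) else 0
      mr <- if (sum(w[!left]) > 0) sum(w[!left] * y[!left]) / sum(w[!left]) else 0
      loss <- sum(w[left] * (y[left] - ml)^2) + sum(w[!left] * (y[!left] - mr)^2)
      if (loss < best) best <- loss
    }
  }
  if (is.infinite(best))  # every feature constant: degenerate stump
    best <- sum(w * (y - sum(w * y) / sum(w))^2)
  best
}

# Pairwise AUROC: fraction of (positive, negative) pairs where the positive
# outranks the negative, ties counted 1/2.
brute_auroc <- function(labels, scores) {
  sp <- scores[labels > 0]
  sn <- scores[labels < 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Weighted SSE of a fitted stump, recomputed directly.
stump_loss <- function(st, x, y, w) {
  pred <- ifelse(x[, st$feature] <= st$threshold, st$left, st$right)
  sum(w * (y - pred)^2)
}

random_probability_weights <- function(n) {
  w <- stats::runif(n)
  w / sum(w)
}

random_dataset <- function(n, d) {
  labeled_dataset(matrix(stats::rnorm(n * d), nrow = n),
                  sample(c(-1, 1), n, replace = TRUE))
}

# A gentleboost shell around hand-built stumps (for prediction arithmetic).
constant_model <- function(value) {
  st <- structure(list(feature = 1L, threshold = Inf, left = value,
                       right = value, degenerate = TRUE), class = "stump")
  structure(list(stumps = list(st), T = 1L, training_ids = integer(0),
                 weight_trace = NULL), class = "gentleboost")
}
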