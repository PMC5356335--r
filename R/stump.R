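#' Fit a weighted regression stump
#'
#' The weak learner inside every Gentle Boost round: a depth-1 regression tree
#' with one feature, one threshold and two real-valued leaves. The stump
#' minimizes the weighted squared error
#' \deqn{\sum_i w_i (y_i - f(x_i))^2}
#' over all (feature, threshold) pairs; candidate thresholds are the midpoints
#' between consecutive distinct sorted values of each feature, and each leaf
#' value is the weighted mean of the labels on its side. With labels in
#' \{-1, +1\} and probability weights, both leaf values lie in \[-1, +1\], so
#' the stump's output is a real-valued confidence.
#'
#' Ties in the loss are broken deterministically by lowest feature index, then
#' lowest threshold. Instances with `x[feature] <= threshold` go to the left
#' leaf. If every feature is constant the stump is degenerate: both leaves
#' equal the weighted mean label.
#'
#' @param data A [labeled_dataset()].
#' @param w Nonnegative weight vector of length N summing to 1.
#' @return An object of class `stump`: list with `feature` (1-based column
#'   index), `threshold`, `left`, `right`, `degenerate`.
#' @export
fit_stump <- function(data, w) {
  x <- data$x; y <- data$y
  N <- nrow(x); d <- ncol(x)
  if (length(w) != N) stop("weight vector length must equal N", call. = FALSE)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)

  tot_w <- sum(w)
  tot_wy <- sum(w * y)
  sse0 <- sum(w * y^2)  # constant part of the weighted SSE

  best_loss <- Inf
  best <- NULL
  for (j in seq_len(d)) {
    xj <- x[, j]
    o <- order(xj)
    xo <- xj[o]
    cw <- cumsum(w[o])
    cwy <- cumsum((w * y)[o])
    cut <- which(diff(xo) > 0)  # split after these sorted positions
    if (length(cut) == 0L) next
    wl <- cw[cut]; wyl <- cwy[cut]
    wr <- tot_w - wl; wyr <- tot_wy - wyl
    # zero-weight sides contribute nothing and get leaf value 0
    terml <- ifelse(wl > 0, wyl^2 / wl, 0)
    termr <- ifelse(wr > 0, wyr^2 / wr, 0)
    loss <- sse0 - terml - termr
    b <- which.min(loss)  # lowest threshold on exact ties (cuts are ascending)
    if (loss[b] < best_loss) {  # strict: keeps lowest feature index on ties
      best_loss <- loss[b]
      k <- cut[b]
      best <- list(feature = j,
                   threshold = (xo[k] + xo[k + 1L]) / 2,
                   left = if (wl[b] > 0) wyl[b] / wl[b] else 0,
                   right = if (wr[b] > 0) wyr[b] / wr[b] else 0,
                   degenerate = FALSE)
    }
  }
  if (is.null(best)) {
    m <- if (tot_w > 0) tot_wy / tot_w else 0
    best <- list(feature = 1L, threshold = Inf, left = m, right = m,
                 degenerate = TRUE)
  }
  structure(best, class = "stump")
}

#' Predict with a regression stump
#'
#' @param stump A `stump`.
#' @param x A numeric feature vector, or a matrix with one instance per row.
#' @return Real-valued confidence(s): `left` where the split feature is
#'   `<= threshold`, `right` otherwise (boundary values go left).
#' @export
stump_predict <- function(stump, x) {
  if (is.matrix(x)) {
    v <- x[, stump$feature]
  } else {
    if (length(x) < stump$feature)
      stop("instance has fewer features than the stump expects", call. = FALSE)
    v <- x[stump$feature]
  }
  ifelse(v <= stump$threshold, stump$left, stump$right)
}

#' @export
print.stump <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<stump> degenerate, value = %.4f\n", x$left))
  } else {
    cat(sprintf("<stump> x[%d] <= %.4g ? %.4f : %.4f\n",
                x$feature, x$threshold, x$left, x$right))
  }
  invisible(x)
}
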