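#' Specification for a synthetic two-class Gaussian problem
#'
#' Describes the controlled input distribution used by the simulation and
#' property tests: two spherical unit-variance Gaussian classes in d
#' dimensions whose means are `overlap` pooled standard deviations apart
#' along the first axis. The separation fixes the Bayes error in closed form
#' ([bayes_error()]), so quantitative checks need no external data.
#'
#' @param n Sample size (>= 4).
#' @param d Dimension (>= 1).
#' @param overlap Distance between class means in pooled-sigma units (>= 0);
#'   0 means indistinguishable classes, 2.56 gives roughly 10% Bayes error.
#' @param imbalance Positive-class fraction in (0, 1).
#' @param seed Integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n, d = 2L, overlap = 2.56, imbalance = 0.5, seed = 1L) {
  stopifnot(n >= 4, d >= 1, overlap >= 0, imbalance > 0, imbalance < 1)
  structure(list(n = as.integer(n), d = as.integer(d), overlap = overlap,
                 imbalance = imbalance, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Closed-form Bayes error of the Gaussian blob problem
#'
#' For two unit-variance Gaussian classes separated by `overlap` along one
#' axis with prior positive fraction `imbalance`, the optimal rule thresholds
#' the discriminating axis at `c = log((1 - pi) / pi) / overlap` (0 when
#' balanced) and errs with probability
#' `pi * Phi(c - overlap/2) + (1 - pi) * (1 - Phi(c + overlap/2))`.
#' For the balanced case this reduces to `Phi(-overlap / 2)`.
#'
#' @param overlap Mean separation in pooled-sigma units.
#' @param imbalance Positive-class prior.
#' @return The Bayes error rate.
#' @export
bayes_error <- function(overlap, imbalance = 0.5) {
  if (overlap == 0) return(min(imbalance, 1 - imbalance))
  p <- imbalance
  cc <- log((1 - p) / p) / overlap
  p * stats::pnorm(cc - overlap / 2) +
    (1 - p) * (1 - stats::pnorm(cc + overlap / 2))
}

#' Generate a two-class Gaussian dataset
#'
#' Draws `round(imbalance * n)` positive and the remaining negative instances
#' from spherical unit-variance Gaussians centered at `+overlap/2` and
#' `-overlap/2` on the first axis (all other coordinates are pure noise).
#' Rows are shuffled; generation is deterministic per seed.
#'
#' @param spec A [synth_spec()].
#' @return A [labeled_dataset()].
#' @export
gaussian_blobs <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n_pos <- round(spec$imbalance * spec$n)
  n_neg <- spec$n - n_pos
  if (n_pos < 1L || n_neg < 1L)
    stop("imbalance leaves a class empty at this n", call. = FALSE)
  with_seed(spec$seed, {
    x <- matrix(stats::rnorm(spec$n * spec$d), nrow = spec$n, ncol = spec$d)
    y <- c(rep(1, n_pos), rep(-1, n_neg))
    x[, 1L] <- x[, 1L] + y * spec$overlap / 2
    perm <- sample.int(spec$n)
    labeled_dataset(x[perm, , drop = FALSE], y[perm])
  })
}

#' Deterministic pathological fixture datasets
#'
#' Small hand-built datasets exercising degenerate code paths: constant
#' features (forces a degenerate stump), duplicated instances (exercises the
#' W-CLB duplicate guard), a single positive instance (trips subsampling
#' preconditions at small eta), and one-dimensional interleaved labels (not
#' separable by a single stump).
#'
#' @return Named list of [labeled_dataset()]s: `constant_features`,
#'   `duplicated_instances`, `single_positive`, `interleaved_1d`.
#' @export
edge_fixtures <- function() {
  list(
    constant_features = labeled_dataset(
      matrix(1, nrow = 6, ncol = 2), c(1, 1, 1, -1, -1, -1)),
    duplicated_instances = labeled_dataset(
      matrix(rep(c(0, 0, 1, 1, 2, 2, 3, 3), each = 1), ncol = 1),
      c(-1, -1, -1, -1, 1, 1, 1, 1)),
    single_positive = labeled_dataset(
      matrix(seq_len(8), ncol = 1), c(1, rep(-1, 7))),
    interleaved_1d = labeled_dataset(
      matrix(1:8, ncol = 1), c(-1, 1, -1, 1, -1, 1, -1, 1))
  )
}
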