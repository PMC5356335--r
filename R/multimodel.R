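#' Train the bi-level collaborative multi-model
#'
#' Builds `L = S * T` weak learners grouped into S Gentle Boost ensembles of T
#' regression stumps each, trained on stratified subsamples drawn without
#' replacement (subbagging). Collaboration between the ensembles is optional:
#' \describe{
#'   \item{`"none"`}{independent training per subset;}
#'   \item{`"wclb"`}{weak-learner collaboration — lock-step training with a
#'     stochastic per-round ring exchange of instances ([train_wclb()]);}
#'   \item{`"sclb"`}{strong-learner collaboration — independent training
#'     followed by pairwise exchange-and-retrain with revert ([sclb_run()]).}
#' }
#' Training is deterministic for a fixed seed.
#'
#' @param data A [labeled_dataset()]; both classes must be present.
#' @param S Number of boosting ensembles (>= 1; collaboration needs S >= 2).
#' @param T Boosting rounds per ensemble.
#' @param eta Subset size as a fraction of N, in (0, 1].
#' @param mode Collaboration mode: `"none"`, `"wclb"` or `"sclb"`.
#' @param p_c W-CLB collaboration probability per repetition.
#' @param n_exc Instances exchanged per collaboration.
#' @param seed Integer master seed (subsampling and the W-CLB schedule).
#' @param sclb_passes Number of S-CLB passes over all pairs.
#' @param sclb_loss Acceptance error for S-CLB: `"zero_one"` or
#'   `"exponential"`.
#' @param sclb_strict Accept only strict error decreases in S-CLB.
#' @param wclb_swap Donor gives up donated instances in W-CLB (default: copy).
#' @return An object of class `subbag_model`: list with `ensembles`, `plan`,
#'   `subsets` (post-collaboration index vectors), `config`, `log` (exchange
#'   events) and, for S-CLB, `error_trace`.
#' @export
train_multimodel <- function(data, S, T, eta = 0.5,
                             mode = c("none", "wclb", "sclb"),
                             p_c = 0.1, n_exc = 1L, seed = 1L,
                             sclb_passes = 1L,
                             sclb_loss = "zero_one", sclb_strict = FALSE,
                             wclb_swap = FALSE) {
  mode <- match.arg(mode)
  stopifnot(S >= 1, T >= 1)
  if (mode != "none" && S < 2L)
    stop("collaboration requires S >= 2 ensembles", call. = FALSE)
  plan <- stratified_subsample(data, S, eta, seed)
  log <- empty_event_log()
  attr(log, "n_tentative") <- 0L
  attr(log, "n_successful") <- 0L
  error_trace <- NULL
  if (mode == "wclb") {
    cfg <- wclb_config(p_c = p_c, n_exc = n_exc, seed = seed, swap = wclb_swap)
    res <- train_wclb(data, plan, T, cfg)
    ens <- res$ensembles
    subsets <- res$subsets
    log <- res$log
  } else {
    ens <- lapply(plan$subsets, function(idx)
      gb_train(dataset_subset(data, idx), T, training_ids = data$ids[idx]))
    subsets <- plan$subsets
    if (mode == "sclb") {
      res <- sclb_run(ens, subsets, data, n_exc, passes = sclb_passes,
                      loss = sclb_loss, strict = sclb_strict)
      ens <- res$ensembles
      subsets <- res$subsets
      log <- res$log
      error_trace <- res$error_trace
    }
  }
  structure(list(ensembles = ens, plan = plan, subsets = subsets,
                 config = list(S = S, T = T, eta = eta, mode = mode,
                               p_c = p_c, n_exc = as.integer(n_exc),
                               seed = as.integer(seed)),
                 log = log, error_trace = error_trace),
            class = "subbag_model")
}

#' Predict with the multi-model
#'
#' The per-ensemble totals are averaged, `Phi(x) = (1/S) * sum_j F_j(x)`, to
#' mimic majority voting; `sign(Phi(x))` is the predicted class label, with
#' `sign(0)` fixed to +1. The probability column applies the sigmoid to the
#' averaged output.
#'
#' @param object A `subbag_model`.
#' @param x Feature matrix (instances in rows) or a single feature vector.
#' @param ... Unused.
#' @return Data frame with one row per instance: `phi` (averaged raw output),
#'   `label` (-1/+1) and `proba` (`sigmoid(phi)`).
#' @export
predict.subbag_model <- function(object, x, ...) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  phi <- Reduce(`+`, lapply(object$ensembles, gb_predict_raw, x = x)) /
    length(object$ensembles)
  data.frame(phi = phi,
             label = ifelse(phi >= 0, 1, -1),
             proba = sigmoid(phi))
}

#' @export
print.subbag_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<subbag_model> S = %d ensembles x T = %d stumps (L = %d), eta = %.2f, mode = %s\n",
              cfg$S, cfg$T, cfg$S * cfg$T, cfg$eta, cfg$mode))
  if (cfg$mode != "none")
    cat(sprintf("  collaborations: %d tentative, %d successful\n",
                attr(x$log, "n_tentative"), attr(x$log, "n_successful")))
  invisible(x)
}

#' Prospective collaboration counts
#'
#' The accounting identities for the two schemes: W-CLB attempts
#' `T * p_c * n_exc` collaborations in expectation (each touching all S
#' ensembles), while one S-CLB pass visits `S * (S - 1) / 2` pairs for
#' `S * (S - 1) * n_exc / 2` prospective exchanges, exactly.
#'
#' @param scheme `"wclb"` or `"sclb"`.
#' @param S,T,p_c,n_exc Model parameters (only those relevant to the scheme
#'   are used).
#' @return Expected (W-CLB) or exact (S-CLB) prospective collaboration count.
#' @export
prospective_collaborations <- function(scheme = c("wclb", "sclb"),
                                       S = NULL, T = NULL, p_c = NULL,
                                       n_exc = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "wclb") T * p_c * n_exc else S * (S - 1) * n_exc / 2
}
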