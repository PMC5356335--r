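#' One S-CLB collaboration pair
#'
#' A collaboration pair (initiator, predecessor) of fully trained ensembles
#' goes through three steps: (1) the initiator selects its `n_exc`
#' weakest-conviction correctly classified instances and the predecessor its
#' `n_exc` strongest-conviction ones; (2) the selections are swapped between
#' the two training subsets (element-wise; a swap that would duplicate an
#' instance within a subset is skipped); (3) both ensembles are retrained from
#' scratch on the modified subsets. The exchange is accepted only if the
#' multi-model's empirical error on the full training set does not increase
#' (strictly decreases when `strict = TRUE`); otherwise subsets and models
#' revert, which guarantees the empirical-error trace never increases.
#'
#' @param ens List of the S current `gentleboost` ensembles.
#' @param subsets List of the S current index vectors into `data`.
#' @param j,k Initiator and predecessor positions (k < j).
#' @param n_exc Number of instances to exchange.
#' @param data The full training [labeled_dataset()].
#' @param err_cur Current empirical 0-1 error of the multi-model.
#' @param loss Error used for acceptance: `"zero_one"` (default) or
#'   `"exponential"` (mean exponential loss of the averaged output).
#' @param strict If `TRUE`, accept only strict decreases.
#' @return List with `ens`, `subsets`, `err` (error after the pair),
#'   `accepted`, `events` (per-instance exchange rows).
#' @export
sclb_pair <- function(ens, subsets, j, k, n_exc, data, err_cur,
                      loss = c("zero_one", "exponential"), strict = FALSE) {
  loss <- match.arg(loss)
  sub_j <- dataset_subset(data, subsets[[j]])
  sub_k <- dataset_subset(data, subsets[[k]])
  m_j <- margin(ens[[j]], sub_j$x, sub_j$y)
  m_k <- margin(ens[[k]], sub_k$x, sub_k$y)
  weak_pos <- rank_correct(m_j, subsets[[j]], n_exc, weakest = TRUE)
  strong_pos <- rank_correct(m_k, subsets[[k]], n_exc, weakest = FALSE)
  if (length(weak_pos) == 0L || length(strong_pos) == 0L) {
    return(list(ens = ens, subsets = subsets, err = err_cur, accepted = FALSE,
                events = empty_event_log()))
  }
  n_swap <- min(length(weak_pos), length(strong_pos))
  idx_j <- subsets[[j]]
  idx_k <- subsets[[k]]
  events <- vector("list", n_swap)
  any_swapped <- FALSE
  for (i in seq_len(n_swap)) {
    pj <- weak_pos[i]; pk <- strong_pos[i]
    row_a <- idx_j[pj]  # initiator's weakest correct
    row_b <- idx_k[pk]  # predecessor's strongest correct
    ok <- !(row_b %in% idx_j[-pj]) && !(row_a %in% idx_k[-pk])
    if (ok) {
      idx_j[pj] <- row_b
      idx_k[pk] <- row_a
      any_swapped <- TRUE
    }
    events[[i]] <- data.frame(scheme = "sclb", round = NA_integer_, rep = i,
                              tau = NA_integer_, ensemble = j,
                              removed_id = data$ids[row_a],
                              added_id = data$ids[row_b],
                              removed_margin = m_j[pj],
                              added_margin = m_k[pk],
                              tentative = TRUE, successful = ok)
  }
  events <- do.call(rbind, events)
  if (!any_swapped) {
    events$successful <- FALSE
    return(list(ens = ens, subsets = subsets, err = err_cur, accepted = FALSE,
                events = events))
  }
  new_j <- gb_train(dataset_subset(data, idx_j), ens[[j]]$T,
                    training_ids = data$ids[idx_j])
  new_k <- gb_train(dataset_subset(data, idx_k), ens[[k]]$T,
                    training_ids = data$ids[idx_k])
  cand_ens <- ens
  cand_ens[[j]] <- new_j
  cand_ens[[k]] <- new_k
  err_new <- multimodel_empirical_error(cand_ens, data, loss)
  accept <- if (strict) err_new < err_cur else err_new <= err_cur
  if (accept) {
    subsets[[j]] <- idx_j
    subsets[[k]] <- idx_k
    list(ens = cand_ens, subsets = subsets, err = err_new, accepted = TRUE,
         events = events)
  } else {
    events$successful <- FALSE
    list(ens = ens, subsets = subsets, err = err_cur, accepted = FALSE,
         events = events)
  }
}

# Empirical error of the averaged multi-model output on `data`.
multimodel_empirical_error <- function(ens, data, loss = "zero_one") {
  phi <- Reduce(`+`, lapply(ens, gb_predict_raw, x = data$x)) / length(ens)
  if (loss == "exponential") {
    mean(exp(-data$y * phi))
  } else {
    pred <- ifelse(phi >= 0, 1, -1)  # sign(0) := +1
    mean(pred != data$y)
  }
}

#' Run strong-learner collaboration over all pairs
#'
#' Iterates the collaboration pairs (initiator j = 2..S, predecessor
#' k = 1..j-1) in sequence order — S(S-1)/2 pairs per pass, so the iteration
#' count grows quadratically with S — calling [sclb_pair()] on each. The
#' iteration counter tau increments once per pair, and the recorded
#' empirical-error trace is non-increasing by construction because harmful
#' exchanges revert. Total prospective exchanges per pass:
#' `S * (S - 1) * n_exc / 2`.
#'
#' @param ens List of S fully trained `gentleboost` ensembles (S >= 2).
#' @param subsets List of S index vectors into `data`.
#' @param data The full training [labeled_dataset()].
#' @param n_exc Instances exchanged per collaboration.
#' @param passes Number of full passes over the pairs (default 1).
#' @param loss,strict Acceptance rule, see [sclb_pair()].
#' @return List with `ensembles`, `subsets`, `log` (event data frame with
#'   `tau` filled in and attributes `n_tentative`, `n_successful`) and
#'   `error_trace` (empirical error after each tau, starting from tau = 0).
#' @export
sclb_run <- function(ens, subsets, data, n_exc, passes = 1L,
                     loss = c("zero_one", "exponential"), strict = FALSE) {
  loss <- match.arg(loss)
  S <- length(ens)
  if (S < 2L) stop("S-CLB requires at least 2 ensembles", call. = FALSE)
  err <- multimodel_empirical_error(ens, data, loss)
  trace <- err
  tau <- 0L
  events <- list()
  n_acc <- 0L
  for (pass in seq_len(passes)) {
    for (j in 2:S) {
      for (k in seq_len(j - 1L)) {
        tau <- tau + 1L
        res <- sclb_pair(ens, subsets, j, k, n_exc, data, err,
                         loss = loss, strict = strict)
        ens <- res$ens
        subsets <- res$subsets
        err <- res$err
        trace <- c(trace, err)
        if (res$accepted) n_acc <- n_acc + 1L
        if (nrow(res$events)) {
          res$events$tau <- tau
          events[[length(events) + 1L]] <- res$events
        }
      }
    }
  }
  log <- if (length(events)) do.call(rbind, events) else empty_event_log()
  attr(log, "n_tentative") <- tau
  attr(log, "n_successful") <- n_acc
  list(ensembles = ens, subsets = subsets, log = log, error_trace = trace)
}
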