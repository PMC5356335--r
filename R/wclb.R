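#' Margin (conviction) of labeled instances
#'
#' The margin of instance (x, y) under an ensemble is `y * F(x)`: positive iff
#' the instance is correctly classified, with magnitude measuring the
#' confidence of the prediction. Boosting is a margin-maximization process,
#' and both collaboration schemes select instances by margin.
#'
#' @param model A `gentleboost` model (possibly partial, mid-training).
#' @param x Feature vector or matrix.
#' @param y Label(s) in \{-1, +1\}.
#' @return Numeric margin(s).
#' @export
margin <- function(model, x, y) {
  y * gb_predict_raw(model, x)
}

# Order correctly classified instances (margin > 0) by margin, ties broken by
# instance id; returns positions within `margins`/`ids`, ascending margin if
# weakest, descending if strongest.
rank_correct <- function(margins, ids, k, weakest) {
  pos <- which(margins > 0)
  if (length(pos) == 0L) return(integer(0))
  m <- if (weakest) margins[pos] else -margins[pos]
  ord <- pos[order(m, ids[pos])]
  ord[seq_len(min(k, length(ord)))]
}

#' Select the weakest-conviction correctly classified instances
#'
#' Returns the k correctly classified (margin > 0) instances with the smallest
#' margins, in ascending margin order; ties are broken by instance id. Fewer
#' than k are returned when fewer correct instances exist, and an empty
#' selection signals that an exchange must be skipped.
#'
#' @param model A `gentleboost` model.
#' @param subset A [labeled_dataset()] (the ensemble's training subset).
#' @param k Number of instances to select (>= 1).
#' @return Vector of instance ids (possibly empty).
#' @export
select_weakest_correct <- function(model, subset, k) {
  stopifnot(k >= 1)
  m <- margin(model, subset$x, subset$y)
  subset$ids[rank_correct(m, subset$ids, k, weakest = TRUE)]
}

#' Select the strongest-conviction correctly classified instances
#'
#' Mirror of [select_weakest_correct()]: the k correct instances with the
#' largest margins, descending.
#'
#' @inheritParams select_weakest_correct
#' @return Vector of instance ids (possibly empty).
#' @export
select_strongest_correct <- function(model, subset, k) {
  stopifnot(k >= 1)
  m <- margin(model, subset$x, subset$y)
  subset$ids[rank_correct(m, subset$ids, k, weakest = FALSE)]
}

#' W-CLB configuration
#'
#' @param p_c Probability of attempting a collaboration at each of the
#'   `n_exc` repetitions within a boosting round, in \[0, 1\].
#' @param n_exc Number of exchange repetitions per round (>= 1).
#' @param seed Integer seed for the collaboration schedule.
#' @param swap If `TRUE` the donor gives up its donated instance (receiving
#'   the receiver's removed one in return); the default `FALSE` copies the
#'   donated instance so donor subsets are untouched.
#' @return A `wclb_config` list.
#' @export
wclb_config <- function(p_c = 0.1, n_exc = 1L, seed = 1L, swap = FALSE) {
  stopifnot(p_c >= 0, p_c <= 1, n_exc >= 1)
  structure(list(p_c = p_c, n_exc = as.integer(n_exc), seed = as.integer(seed),
                 swap = isTRUE(swap)),
            class = "wclb_config")
}

empty_event_log <- function() {
  data.frame(scheme = character(0), round = integer(0), rep = integer(0),
             tau = integer(0), ensemble = integer(0),
             removed_id = integer(0), added_id = integer(0),
             removed_margin = numeric(0), added_margin = numeric(0),
             tentative = logical(0), successful = logical(0))
}

wclb_event <- function(t, r, j, removed_id = NA_integer_, added_id = NA_integer_,
                       removed_margin = NA_real_, added_margin = NA_real_,
                       successful = FALSE) {
  data.frame(scheme = "wclb", round = t, rep = r, tau = NA_integer_,
             ensemble = j, removed_id = removed_id, added_id = added_id,
             removed_margin = removed_margin, added_margin = added_margin,
             tentative = TRUE, successful = successful)
}

# One collaboration attempt across the ring of S partial ensembles.
# `states` is a list of per-ensemble lists: idx (1-based rows into `data`),
# w (weights aligned with idx), stumps (list of stumps trained so far).
# Returns list(states, events).
wclb_attempt <- function(states, data, t, r, swap = FALSE) {
  S <- length(states)
  # Phase 1 (selection): margins under each ensemble's partial model, then
  # receiver's weakest correct instance and donor's strongest, simultaneously.
  sel <- lapply(states, function(st) {
    sub <- dataset_subset(data, st$idx)
    m <- margin(structure(list(stumps = st$stumps), class = "gentleboost"),
                sub$x, sub$y)
    list(weak = rank_correct(m, st$idx, 1L, weakest = TRUE),
         strong = rank_correct(m, st$idx, 1L, weakest = FALSE),
         m = m)
  })
  # Phase 2 (replacement): ensemble j drops its weakest correct instance and
  # receives ensemble (j mod S) + 1's strongest correct one (a copy by
  # default; in swap mode the donor receives the removed instance in return).
  # The incoming instance inherits the outgoing instance's weight, so each
  # weight vector stays a probability distribution without renormalization.
  events <- vector("list", S)
  work <- states
  for (j in seq_len(S)) {
    donor <- if (j == S) 1L else j + 1L
    wk <- sel[[j]]$weak
    sg <- sel[[donor]]$strong
    if (length(wk) == 0L || length(sg) == 0L) {
      events[[j]] <- wclb_event(t, r, j)
      next
    }
    out_pos <- wk[1L]
    in_pos <- sg[1L]
    out_row <- work[[j]]$idx[out_pos]
    in_row <- work[[donor]]$idx[in_pos]
    # duplicate guard: sampling is without replacement within a subset; a
    # self-replacement (identical instance) is a no-op, not an exchange
    cand_j <- work[[j]]$idx
    cand_j[out_pos] <- in_row
    ok <- in_row != out_row && anyDuplicated(cand_j) == 0L
    if (ok && swap) {
      cand_d <- work[[donor]]$idx
      cand_d[in_pos] <- out_row
      ok <- anyDuplicated(cand_d) == 0L
    }
    if (ok) {
      work[[j]]$idx <- cand_j
      if (swap) work[[donor]]$idx <- cand_d
    }
    events[[j]] <- wclb_event(t, r, j,
                              removed_id = data$ids[out_row],
                              added_id = data$ids[in_row],
                              removed_margin = sel[[j]]$m[out_pos],
                              added_margin = sel[[donor]]$m[in_pos],
                              successful = ok)
  }
  list(states = work, events = do.call(rbind, events))
}

#' One round of weak-learner collaboration
#'
#' Executes the stochastic exchange step that follows boosting round `t`:
#' `n_exc` repetitions, each attempted with independent probability `p_c`.
#' An attempted repetition performs a simultaneous ring exchange — every
#' ensemble j removes its weakest-conviction correctly classified instance
#' and receives a copy of the next ensemble's strongest-conviction correct
#' instance — so one collaboration touches all S ensembles. Ensembles with no
#' correct instance, and exchanges that would duplicate an instance within a
#' subset, are skipped (logged tentative but unsuccessful). Subset sizes are
#' conserved, and the incoming instance inherits the removed instance's
#' weight, so each weight vector remains a probability distribution.
#'
#' @param states List of S per-ensemble states, each a list with `idx`
#'   (1-based rows into `data`), `w` (weights aligned with `idx`), `stumps`
#'   (stumps trained so far).
#' @param data The parent [labeled_dataset()].
#' @param t Current boosting round (for the log).
#' @param cfg A [wclb_config()].
#' @param attempt_draws Logical vector of length `n_exc`: which repetitions
#'   fire (the Bernoulli(p_c) draws, pre-drawn by the trainer for
#'   reproducibility).
#' @return List with `states` (updated) and `events` (data frame of exchange
#'   events, one row per ensemble per attempted repetition).
#' @export
wclb_round <- function(states, data, t, cfg, attempt_draws) {
  events <- list()
  for (r in seq_len(cfg$n_exc)) {
    if (!attempt_draws[r]) next
    res <- wclb_attempt(states, data, t, r, swap = cfg$swap)
    states <- res$states
    events[[length(events) + 1L]] <- res$events
  }
  list(states = states,
       events = if (length(events)) do.call(rbind, events) else empty_event_log())
}

#' Train a subbagged Gentle Boost multi-model with W-CLB
#'
#' Lock-step training of S Gentle Boost ensembles on the subsets of `plan`:
#' at every round t each ensemble fits one stump and updates its weights,
#' then [wclb_round()] runs the collaboration step. With `p_c = 0` the result
#' is bitwise identical to independent (non-collaborative) subbagged
#' training on the same plan.
#'
#' @param data A [labeled_dataset()].
#' @param plan A [stratified_subsample()] plan with S >= 2 subsets.
#' @param T Number of boosting rounds.
#' @param cfg A [wclb_config()].
#' @return List with `ensembles` (S `gentleboost` models), `subsets` (final
#'   index vectors) and `log` (exchange-event data frame with attributes
#'   `n_tentative`, `n_successful`).
#' @export
train_wclb <- function(data, plan, T, cfg) {
  S <- plan$S
  if (S < 2L) {
    warning("W-CLB needs S >= 2 ensembles; collaboration disabled")
    ens <- lapply(plan$subsets, function(idx)
      gb_train(dataset_subset(data, idx), T, training_ids = data$ids[idx]))
    log <- empty_event_log()
    attr(log, "n_tentative") <- 0L
    attr(log, "n_successful") <- 0L
    return(list(ensembles = ens, subsets = plan$subsets, log = log))
  }
  states <- lapply(plan$subsets, function(idx)
    list(idx = idx, w = init_weights(length(idx)), stumps = list()))
  # Pre-draw the whole collaboration schedule: n_exc Bernoulli(p_c) draws per
  # round, independent across repetitions and rounds.
  draws <- with_seed(cfg$seed,
                     matrix(stats::runif(T * cfg$n_exc) < cfg$p_c,
                            nrow = T, ncol = cfg$n_exc))
  events <- list()
  for (t in seq_len(T)) {
    for (j in seq_len(S)) {
      sub <- dataset_subset(data, states[[j]]$idx)
      r <- boost_round(sub, states[[j]]$w)
      states[[j]]$stumps[[t]] <- r$stump
      states[[j]]$w <- r$w
    }
    res <- wclb_round(states, data, t, cfg, draws[t, ])
    states <- res$states
    if (nrow(res$events)) events[[length(events) + 1L]] <- res$events
  }
  log <- if (length(events)) do.call(rbind, events) else empty_event_log()
  # a tentative collaboration is one fired repetition (it touches all S
  # ensembles); it is successful when every ensemble exchanged
  n_tent <- sum(draws)
  n_succ <- if (nrow(log)) {
    key <- paste(log$round, log$rep)
    sum(tapply(log$successful, key, all))
  } else 0L
  attr(log, "n_tentative") <- as.integer(n_tent)
  attr(log, "n_successful") <- as.integer(n_succ)
  ens <- lapply(states, function(st)
    structure(list(stumps = st$stumps, T = T,
                   training_ids = data$ids[st$idx], weight_trace = NULL),
              class = "gentleboost"))
  list(ensembles = ens, subsets = lapply(states, `[[`, "idx"), log = log)
}
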