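#' Serialize a multi-model to JSON
#'
#' Writes a human-auditable JSON description of the trained model: the config
#' echo, the per-ensemble stump lists (feature index, threshold and the two
#' leaf values, 1-based feature indexing) and the post-collaboration training
#' subsets. Round-trips exactly through [model_from_json()] up to double
#' precision (thresholds and leaf values are written in full precision).
#'
#' @param model A `subbag_model`.
#' @param path Output path; if `NULL`, the JSON string is returned instead.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    S = model$config$S, T = model$config$T, eta = model$config$eta,
    mode = model$config$mode, p_c = model$config$p_c,
    n_exc = model$config$n_exc, seed = model$config$seed,
    ensembles = lapply(model$ensembles, function(e) {
      list(T = e$T,
           training_ids = as.integer(e$training_ids),
           stumps = lapply(e$stumps, function(st)
             list(feature = st$feature, threshold = st$threshold,
                  left = st$left, right = st$right,
                  degenerate = st$degenerate)))
    }),
    plan = lapply(model$subsets, as.integer)
  )
  # 17 significant digits round-trip IEEE doubles exactly
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Load a multi-model from JSON
#'
#' @param path Path to a file written by [model_to_json()], or a JSON string.
#' @return A `subbag_model` whose predictions match the serialized model
#'   exactly.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ens <- lapply(obj$ensembles, function(e) {
    structure(list(
      stumps = lapply(e$stumps, function(st)
        structure(list(feature = as.integer(st$feature),
                       threshold = as.numeric(st$threshold),
                       left = as.numeric(st$left),
                       right = as.numeric(st$right),
                       degenerate = isTRUE(st$degenerate)),
                  class = "stump")),
      T = as.integer(e$T),
      training_ids = as.integer(unlist(e$training_ids)),
      weight_trace = NULL), class = "gentleboost")
  })
  structure(list(
    ensembles = ens,
    plan = NULL,
    subsets = lapply(obj$plan, function(s) as.integer(unlist(s))),
    config = list(S = as.integer(obj$S), T = as.integer(obj$T),
                  eta = as.numeric(obj$eta), mode = obj$mode,
                  p_c = as.numeric(obj$p_c), n_exc = as.integer(obj$n_exc),
                  seed = as.integer(obj$seed)),
    log = NULL, error_trace = NULL), class = "subbag_model")
}

#' Write a collaboration log to CSV
#'
#' One exchange event per row, sharing one schema for both schemes (`tau` is
#' filled for S-CLB, `round`/`rep` for W-CLB).
#'
#' @param log Event data frame from a trained model's `$log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collab_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
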