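#' Construct a labeled dataset
#'
#' The basic container used throughout the package: a numeric feature matrix
#' with binary labels coded as -1/+1 and stable per-instance identifiers.
#'
#' @param x Numeric matrix (N x d) of features; a data frame of numeric
#'   columns is accepted and converted.
#' @param y Numeric vector of length N with values in \{-1, +1\}.
#' @param ids Optional vector of unique instance identifiers; defaults to
#'   0-based row indices.
#' @return An object of class `labeled_dataset` with elements `x`, `y`, `ids`.
#' @export
labeled_dataset <- function(x, y, ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("dataset must have at least 1 row and 1 feature", call. = FALSE)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing feature value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(x))
    stop("length of `y` must equal nrow(x)", call. = FALSE)
  if (anyNA(y) || !all(y %in% c(-1, 1)))
    stop("labels must be -1 or +1 with no missing values", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(nrow(x)) - 1L
  if (length(ids) != nrow(x) || anyDuplicated(ids))
    stop("`ids` must be unique and match the number of rows", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, y = y, ids = ids), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> N = %d, d = %d, positives = %d, negatives = %d\n",
              nrow(x$x), ncol(x$x), sum(x$y > 0), sum(x$y < 0)))
  invisible(x)
}

n_instances <- function(data) nrow(data$x)
n_features <- function(data) ncol(data$x)

#' Take a subset of a labeled dataset by row index
#'
#' @param data A `labeled_dataset`.
#' @param idx Integer vector of 1-based row positions (duplicates allowed;
#'   callers that need sampling without replacement enforce it themselves).
#' @return A `labeled_dataset` holding the selected rows; ids are carried over,
#'   so duplicated positions yield duplicated ids (tolerated here on purpose).
#' @export
dataset_subset <- function(data, idx) {
  structure(list(x = data$x[idx, , drop = FALSE],
                 y = data$y[idx],
                 ids = data$ids[idx]),
            class = "labeled_dataset")
}

#' Load a labeled dataset from a CSV file
#'
#' Reads an RFC-4180 CSV with a header row, maps a binary label column onto
#' -1/+1 and validates the features. No preprocessing (scaling, imputation)
#' is applied; missing values are rejected.
#'
#' @param path Path to the CSV file.
#' @param label_column Name of the label column.
#' @param positive_label Raw value in the label column mapped to +1; the other
#'   value is mapped to -1.
#' @return A [labeled_dataset()] with ids equal to 0-based row indices and row
#'   order preserved.
#' @export
load_csv <- function(path, label_column, positive_label) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (!label_column %in% names(df))
    stop(sprintf("label column '%s' not found (columns: %s)",
                 label_column, paste(names(df), collapse = ", ")), call. = FALSE)
  lab_raw <- df[[label_column]]
  if (anyNA(lab_raw)) {
    stop(sprintf("missing label at row %d", which(is.na(lab_raw))[1L]), call. = FALSE)
  }
  vals <- unique(lab_raw)
  if (length(vals) != 2L)
    stop(sprintf("label column not binary: '%s' has %d distinct values",
                 label_column, length(vals)), call. = FALSE)
  if (!as.character(positive_label) %in% as.character(vals))
    stop(sprintf("positive label '%s' not present in column '%s'",
                 positive_label, label_column), call. = FALSE)
  feat <- df[setdiff(names(df), label_column)]
  if (ncol(feat) == 0L) stop("no feature columns besides the label", call. = FALSE)
  for (nm in names(feat)) {
    if (!is.numeric(feat[[nm]])) {
      suppressWarnings(conv <- as.numeric(feat[[nm]]))
      if (anyNA(conv))
        stop(sprintf("non-numeric feature cell in column '%s' (row %d)",
                     nm, which(is.na(conv))[1L]), call. = FALSE)
      feat[[nm]] <- conv
    }
    if (anyNA(feat[[nm]]))
      stop(sprintf("missing value in column '%s' (row %d)",
                   nm, which(is.na(feat[[nm]]))[1L]), call. = FALSE)
  }
  y <- ifelse(as.character(lab_raw) == as.character(positive_label), 1, -1)
  labeled_dataset(as.matrix(feat), y, ids = seq_len(nrow(df)) - 1L)
}

#' Write a labeled dataset to CSV
#'
#' Inverse of [load_csv()]: features plus one label column holding -1/+1.
#'
#' @param data A `labeled_dataset`.
#' @param path Output path.
#' @param label_column Name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path, label_column = "label") {
  df <- as.data.frame(data$x)
  df[[label_column]] <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Largest-remainder apportionment of `total` slots across classes with
# fractional quotas `quota` (sums to ~total). Guarantees sum == total.
largest_remainder <- function(quota, total) {
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1L
  } else if (short < 0) {
    drop <- order(quota - base, decreasing = FALSE)[seq_len(-short)]
    base[drop] <- base[drop] - 1L
  }
  as.integer(base)
}

#' Stratified subsampling plan without replacement
#'
#' Draws S independent subsets of size `round(eta * N)` from a dataset,
#' stratified so each subset's class proportions match the parent's up to
#' integer rounding (largest-remainder reconciliation). Sampling is without
#' replacement within a subset; different subsets may overlap. Each subset is
#' drawn from its own seed stream (`seed + j`), so changing `S` or `eta` does
#' not perturb earlier subsets.
#'
#' @param data A `labeled_dataset`.
#' @param S Number of subsets (>= 1).
#' @param eta Subset size as a fraction of N, in (0, 1].
#' @param seed Integer master seed.
#' @return An object of class `subsample_plan`: list with `subsets` (list of S
#'   integer vectors of 1-based row positions), `eta`, `S`, `seed`.
#' @export
stratified_subsample <- function(data, S, eta, seed) {
  stopifnot(S >= 1, eta > 0, eta <= 1)
  N <- n_instances(data)
  p <- round(eta * N)
  if (p < 2L) stop("subset size round(eta * N) must be at least 2", call. = FALSE)
  cls <- sort(unique(data$y))
  counts <- vapply(cls, function(c) sum(data$y == c), integer(1))
  per_class <- largest_remainder(eta * counts, p)
  if (any(per_class < 1L))
    stop("eta too small: a class would have no instances in the subsets",
         call. = FALSE)
  class_idx <- lapply(cls, function(c) which(data$y == c))
  subsets <- lapply(seq_len(S), function(j) {
    with_seed(seed + j, {
      picked <- unlist(lapply(seq_along(cls), function(ci) {
        perm <- sample(class_idx[[ci]])
        perm[seq_len(per_class[ci])]
      }))
      sort(picked)
    })
  })
  structure(list(subsets = subsets, eta = eta, S = S, seed = seed),
            class = "subsample_plan")
}

#' Uniform train/test split
#'
#' Samples the test set uniformly at random (not stratified). The fraction is
#' restricted to the 20--40% range used for holdout evaluation.
#'
#' @param data A `labeled_dataset`.
#' @param test_fraction Fraction of instances held out, in \[0.2, 0.4\].
#' @param seed Integer seed.
#' @return List with `train` and `test`, both `labeled_dataset`s with disjoint
#'   ids whose union is the parent's.
#' @export
train_test_split <- function(data, test_fraction, seed) {
  if (test_fraction < 0.2 || test_fraction > 0.4)
    stop("test_fraction must lie in [0.2, 0.4]", call. = FALSE)
  N <- n_instances(data)
  n_test <- round(test_fraction * N)
  if (n_test < 1L || n_test >= N)
    stop("split would leave an empty set", call. = FALSE)
  test_idx <- with_seed(seed, sort(sample.int(N, n_test)))
  train_idx <- setdiff(seq_len(N), test_idx)
  train <- dataset_subset(data, train_idx)
  test <- dataset_subset(data, test_idx)
  if (length(unique(train$y)) < 2L || length(unique(test$y)) < 2L)
    stop("degenerate split: a set is missing one class; choose another seed or fraction",
         call. = FALSE)
  list(train = train, test = test)
}
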