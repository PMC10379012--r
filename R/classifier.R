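# Final supervised stage: local features and graph embeddings are joined
# into one table and a gradient-boosted tree ensemble is fitted on the
# training rows only. The graph (and hence the embeddings) may have been
# built transductively over all rows; the label information used in
# training never leaves the train split.

#' Assemble the combined feature table
#'
#' Columnwise concatenation of the local feature matrix and the embedding
#' matrix (local block first). Either part may be `NULL` for ablation runs;
#' at least one must be present.
#'
#' @param local Numeric matrix of local features (or `NULL`).
#' @param embedded `embedding_matrix` (or `NULL`).
#' @return Numeric matrix with unique column names, class `feature_table`.
#' @export
assemble_features <- function(local = NULL, embedded = NULL) {
  parts <- Filter(Negate(is.null), list(local, embedded))
  if (length(parts) == 0L) stop("at least one feature block is required")
  if (length(parts) == 2L && nrow(parts[[1]]) != nrow(parts[[2]])) {
    stop("row counts differ: ", nrow(parts[[1]]), " vs ", nrow(parts[[2]]))
  }
  tbl <- do.call(cbind, lapply(parts, unclass))
  if (anyDuplicated(colnames(tbl))) stop("duplicated feature names")
  if (any(!is.finite(tbl))) stop("non-finite feature values")
  class(tbl) <- c("feature_table", class(tbl))
  tbl
}

#' Train the gradient-boosted tree ensemble
#'
#' Fits a boosted-tree binary classifier (xgboost backend, logistic
#' objective) on the requested training rows. With `balance = "auto"`,
#' rows are weighted inversely to their class frequency so the minority
#' class is not swamped in imbalanced runs. Single-threaded and seeded, so
#' repeated fits are identical.
#'
#' @param table `feature_table` over all rows.
#' @param labels Binary label vector aligned with `table` rows.
#' @param train_indices Rows used for fitting.
#' @param iterations Boosting rounds, default 500.
#' @param depth Maximum tree depth, default 6.
#' @param learning_rate Shrinkage, default 0.05.
#' @param balance `"auto"` (inverse-frequency class weights) or `"none"`.
#' @param seed RNG seed.
#' @return A `trained_ensemble`: the fitted booster plus the training
#'   config and a snapshot of the feature names.
#' @export
train_ensemble <- function(table, labels, train_indices,
                           iterations = 500L, depth = 6L,
                           learning_rate = 0.05,
                           balance = c("auto", "none"), seed = 1L) {
  balance <- match.arg(balance)
  y <- labels[train_indices]
  if (length(unique(y)) < 2L) stop("training rows contain a single class")
  Xtr <- unclass(table)[train_indices, , drop = FALSE]
  w <- rep(1, length(y))
  if (balance == "auto") {
    freq <- base::table(y) / length(y)
    w <- as.numeric(1 / (2 * freq[as.character(y)]))
  }
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(Xtr, label = y, weight = w)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = depth,
                  eta = learning_rate, nthread = 1, seed = seed,
                  tree_method = "hist"),
    data = dtrain, nrounds = iterations, verbose = 0)
  structure(
    list(booster = booster,
         config = list(iterations = iterations, depth = depth,
                       learning_rate = learning_rate, balance = balance,
                       seed = seed),
         feature_names = colnames(table)),
    class = "trained_ensemble"
  )
}

#' Score rows with a trained ensemble
#'
#' @param model A `trained_ensemble`.
#' @param table `feature_table` whose column names must equal the model's
#'   snapshot.
#' @param rows Row indices to score (default all).
#' @param threshold Decision threshold on the class-1 probability; a score
#'   `>= threshold` is called 1. Default 0.5.
#' @return A list of class `prediction_result`: `scores` (probabilities in
#'   \[0, 1\]), `labels` (0/1 integer), `threshold`, `rows`.
#' @export
predict_ensemble <- function(model, table, rows = seq_len(nrow(table)),
                             threshold = 0.5) {
  stopifnot(inherits(model, "trained_ensemble"),
            threshold > 0, threshold < 1)
  if (!identical(colnames(table), model$feature_names)) {
    stop("feature names do not match the model's training snapshot")
  }
  X <- unclass(table)[rows, , drop = FALSE]
  scores <- stats::predict(model$booster, xgboost::xgb.DMatrix(X))
  structure(
    list(scores = as.numeric(scores),
         labels = as.integer(scores >= threshold),
         threshold = threshold, rows = rows),
    class = "prediction_result"
  )
}
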