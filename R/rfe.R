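# Random-forest recursive feature elimination. Importance is the Gini
# (impurity-decrease) variable importance summed over all split nodes and
# trees, normalised to sum 1. One feature — the lowest-VIM one — is removed
# per round until a single feature remains; every subset size along the way
# is scored by repeated k-fold cross-validation accuracy (CVS), and the
# argmax size (ties toward fewer features) defines the selected subset.

#' Random-forest configuration for importance and CVS scoring
#' @param n_trees trees per forest; default 100.
#' @param seed integer seed.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 100L, seed = 1L) {
  if (n_trees < 1) stop("`n_trees` must be >= 1")
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "forest_config")
}

#' Gini impurity of a class-proportion vector
#'
#' `1 - sum(p_c^2)`: 0 for a pure node, maximal for the uniform mix.
#' @param class_proportions non-negative proportions summing to 1.
#' @return the Gini index.
#' @export
gini_index <- function(class_proportions) {
  p <- class_proportions
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`class_proportions` must be non-negative and sum to 1")
  }
  1 - sum(p^2)
}

.check_table <- function(table) {
  feats <- setdiff(names(table), "label")
  if (length(feats) < 2L) stop("need at least 2 features")
  if (length(unique(table$label)) < 2L) stop("both classes must be present")
  feats
}

.fit_forest <- function(table, feats, fc, importance = "impurity") {
  df <- table[, c(feats, "label"), drop = FALSE]
  df$label <- factor(df$label, levels = c(0L, 1L))
  ranger::ranger(label ~ ., data = df, num.trees = fc$n_trees,
                 importance = importance, seed = fc$seed,
                 num.threads = 1L, respect.unordered.factors = TRUE)
}

#' Gini variable importance of every feature
#'
#' Fits a random forest and reports each feature's summed sample-weighted
#' impurity decrease across all split nodes and trees (raw), together with
#' the importances normalised to sum 1. A feature never chosen for a split
#' (e.g. a constant) gets importance 0.
#'
#' @param table a `feature_table` with >= 2 features and both classes.
#' @param fc a [forest_config()].
#' @return a `vim_profile` list with `raw`, `normalized`, `forest_config`.
#' @export
compute_vim <- function(table, fc = forest_config()) {
  feats <- .check_table(table)
  fit <- .fit_forest(table, feats, fc)
  raw <- fit$variable.importance[feats]
  raw[is.na(raw)] <- 0
  total <- sum(raw)
  normalized <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  structure(list(raw = raw, normalized = normalized, forest_config = fc),
            class = "vim_profile")
}

#' Recursive elimination order of the features
#'
#' Repeatedly fit a forest on the surviving features, compute the
#' normalised VIM, and remove the single lowest-VIM feature (first-listed
#' wins ties) until one remains.
#'
#' @inheritParams compute_vim
#' @return character vector from first-removed to last-surviving feature.
#' @export
rfe_rank <- function(table, fc = forest_config()) {
  feats <- .check_table(table)
  order_out <- character(0)
  surviving <- feats
  round_i <- 0L
  while (length(surviving) > 1L) {
    round_i <- round_i + 1L
    fc_round <- forest_config(fc$n_trees, derive_seed(fc$seed, 7000L + round_i))
    vim <- compute_vim(select_feature_columns(table, surviving), fc_round)
    worst <- surviving[which.min(vim$normalized[surviving])]
    order_out <- c(order_out, worst)
    surviving <- setdiff(surviving, worst)
  }
  c(order_out, surviving)
}

.stratified_fold_ids <- function(labels, k, seed) {
  set.seed(seed)
  ids <- integer(length(labels))
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    ids[rows[sample.int(length(rows))]] <- rep_len(seq_len(k), length(rows))
  }
  ids
}

#' Cross-validation score of every nested feature subset
#'
#' For each subset size `s` (the `s` last-eliminated features), computes
#' the mean classification accuracy of a random forest over
#' `k_folds x n_repeats` stratified cross-validation fits.
#'
#' @param table a `feature_table`.
#' @param elimination_order output of [rfe_rank()].
#' @param k_folds folds per repetition; default 5.
#' @param n_repeats repetitions with re-randomised folds and forest seeds;
#'   default 20.
#' @param fc a [forest_config()].
#' @return named numeric vector: CVS per subset size `"1"`..`"n"`.
#' @export
score_subsets <- function(table, elimination_order, k_folds = 5L,
                          n_repeats = 20L, fc = forest_config()) {
  if (k_folds < 2L) stop("`k_folds` must be >= 2")
  if (nrow(table) < 2L * k_folds) stop("too few rows for the requested folds")
  p <- length(elimination_order)
  labels <- table$label
  cvs <- numeric(p)
  for (s in seq_len(p)) {
    feats <- elimination_order[(p - s + 1L):p]
    accs <- c()
    for (rep_i in seq_len(n_repeats)) {
      fold <- .stratified_fold_ids(labels, k_folds,
                                   derive_seed(fc$seed, 11L, rep_i))
      for (kk in seq_len(k_folds)) {
        tr <- table[fold != kk, c(feats, "label"), drop = FALSE]
        te <- table[fold == kk, c(feats, "label"), drop = FALSE]
        fc_fit <- forest_config(fc$n_trees,
                                derive_seed(fc$seed, 13L, rep_i, kk, s))
        fit <- .fit_forest(tr, feats, fc_fit)
        pred <- predict(fit, data = te, num.threads = 1L)$predictions
        accs <- c(accs, mean(pred == factor(te$label, levels = c(0L, 1L))))
      }
    }
    cvs[s] <- mean(accs)
  }
  names(cvs) <- as.character(seq_len(p))
  cvs
}

#' Pick the optimal feature subset from the CVS curve
#'
#' Argmax of CVS over subset sizes; ties break toward the smallest size
#' (fewest features). The size-`s` subset consists of the `s`
#' last-eliminated features.
#'
#' @param cvs_by_size named CVS vector from [score_subsets()].
#' @param elimination_order output of [rfe_rank()].
#' @return character vector of selected feature names (in elimination
#'   order, least expendable last).
#' @export
select_features <- function(cvs_by_size, elimination_order) {
  sizes <- as.integer(names(cvs_by_size))
  ord <- order(cvs_by_size, -sizes, decreasing = TRUE)
  best <- sizes[ord[1L]]
  p <- length(elimination_order)
  elimination_order[(p - best + 1L):p]
}

#' Run the full recursive-feature-elimination procedure
#'
#' Elimination ranking, CVS scoring of every subset size, and optimal
#' subset selection, on the training rows only.
#'
#' @inheritParams score_subsets
#' @return an `rfe_result` with `elimination_order`, `cvs_by_size`,
#'   `selected_features`, `k_folds`, `n_repeats`.
#' @export
run_rfe <- function(table, k_folds = 5L, n_repeats = 20L,
                    fc = forest_config()) {
  elim <- rfe_rank(table, fc)
  cvs <- score_subsets(table, elim, k_folds, n_repeats, fc)
  sel <- select_features(cvs, elim)
  structure(list(elimination_order = elim, cvs_by_size = cvs,
                 selected_features = sel, k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats), forest_config = fc),
            class = "rfe_result")
}

#' @exportS3Method base::print
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %d features; selected %d (CVS %.4f)\n",
              length(x$elimination_order), length(x$selected_features),
              max(x$cvs_by_size)))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise an RFE result to JSON
#' @param x an `rfe_result`.
#' @param path optional file; if `NULL`, the JSON string is returned.
#' @export
rfe_to_json <- function(x, path = NULL) {
  obj <- list(elimination_order = x$elimination_order,
              cvs_by_size = as.list(x$cvs_by_size),
              selected_features = x$selected_features,
              k_folds = x$k_folds, n_repeats = x$n_repeats)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Plot the CVS curve against subset size
#' @param x an `rfe_result`.
#' @param path optional PNG path; plots to the active device when `NULL`.
#' @export
plot_cvs_curve <- function(x, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  sizes <- as.integer(names(x$cvs_by_size))
  plot(sizes, x$cvs_by_size, type = "b", pch = 19,
       xlab = "number of selected features",
       ylab = "cross-validation score",
       main = "CVS by feature-subset size")
  graphics::abline(v = length(x$selected_features), lty = 2)
  invisible(x)
}
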