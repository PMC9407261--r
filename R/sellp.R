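# Two-level stacking ensemble for link classification. Level one holds
# three base learners — regularised logistic regression (LR), a classical
# gradient-boosted tree machine (GBDT) and extreme gradient boosting
# (XGBoost) — each fitted once per cross-validation fold on the rows
# OUTSIDE that fold. Their out-of-fold positive-class probabilities form
# the meta table that trains the level-two XGBoost fuse model, so no base
# prediction used for meta training was made by a model that saw that row.
# At test time each learner's five fold-models predict and are averaged
# before the fuse model combines the three averages.
#
# Both boosted learners run on the same engine; GBDT uses the classical
# unregularised gradient-boosting configuration (no L1/L2 shrinkage of
# leaf weights), XGBoost keeps the engine's second-order regularisation.

BASE_LEARNERS <- c("lr", "gbdt", "xgb")

#' Default hyperparameter grids for the stack's learners
#'
#' LR is searched over ridge regularisation strengths; the two boosted
#' learners over rounds x depth x learning rate. Any grid can be replaced
#' (or collapsed to a single point) through [stack_config()].
#' @return named list of per-learner grids.
#' @export
default_grids <- function() {
  tree_grid <- expand.grid(nrounds = c(50L, 100L, 200L),
                           max_depth = c(2L, 3L, 5L),
                           eta = c(0.05, 0.1, 0.3))
  list(lr = data.frame(lambda = c(0.01, 0.1, 1, 10)),
       gbdt = tree_grid, xgb = tree_grid,
       meta = data.frame(nrounds = 100L, max_depth = 3L, eta = 0.1))
}

.fixed_params <- function() {
  list(lr = list(lambda = 0.1),
       gbdt = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
       xgb = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
       meta = list(nrounds = 100L, max_depth = 3L, eta = 0.1))
}

#' Configuration of the stacking ensemble
#'
#' @param n_folds out-of-fold partitions for level one; default 5
#'   (3 base learners x 5 folds = 15 base models).
#' @param fold_assignment `"stratified"` (default; preserves the class
#'   ratio per fold, avoiding single-class partitions on small balanced
#'   data) or `"random"`.
#' @param grids per-learner hyperparameter grids as in [default_grids()].
#' @param tune if `TRUE`, each fold-model grid-searches its grid by
#'   internal cross-validation on its own training partition; if `FALSE`,
#'   fixed mid-grid parameters are used (fast path for small studies).
#' @param inner_folds folds of the internal tuning CV; default 3.
#' @param threshold classification threshold on the fused probability.
#' @param seed integer seed governing folds, tuning and learner fits.
#' @return a `stack_config` list.
#' @export
stack_config <- function(n_folds = 5L,
                         fold_assignment = c("stratified", "random"),
                         grids = default_grids(), tune = TRUE,
                         inner_folds = 3L, threshold = 0.5, seed = 1L) {
  fold_assignment <- match.arg(fold_assignment)
  if (n_folds < 2L) stop("`n_folds` must be >= 2")
  structure(list(n_folds = as.integer(n_folds),
                 fold_assignment = fold_assignment, grids = grids,
                 tune = isTRUE(tune), inner_folds = as.integer(inner_folds),
                 threshold = threshold, seed = as.integer(seed)),
            class = "stack_config")
}

#' Assign rows to cross-validation folds
#'
#' Near-equal fold sizes (remainder spread over the first folds);
#' stratified assignment deals each class out separately so the class
#' ratio is preserved per fold.
#'
#' @param n_rows number of rows.
#' @param labels 0/1 labels (used by stratified assignment).
#' @param cfg a [stack_config()].
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(n_rows, labels, cfg = stack_config()) {
  if (n_rows < cfg$n_folds) stop("fewer rows than folds")
  set.seed(derive_seed(cfg$seed, 501L))
  if (cfg$fold_assignment == "stratified") {
    .stratified_fold_ids(labels, cfg$n_folds, derive_seed(cfg$seed, 502L))
  } else {
    ids <- rep_len(seq_len(cfg$n_folds), n_rows)
    ids[sample.int(n_rows)]
  }
}

.as_matrix_x <- function(table) {
  feats <- setdiff(names(table), "label")
  as.matrix(table[, feats, drop = FALSE])
}

.xgb_fit <- function(X, y, params, seed, regularised) {
  extra <- if (regularised) list() else list(lambda = 0, alpha = 0)
  set.seed(seed)
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1L, subsample = 1, colsample_bytree = 1),
               extra),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
    nrounds = params$nrounds, verbose = 0)
}

.fit_learner <- function(learner, X, y, params, seed) {
  model <- switch(learner,
    lr = {
      Xg <- if (ncol(X) < 2L) cbind(X, `.dummy0` = 0) else X
      glmnet::glmnet(Xg, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = params$lambda)
    },
    gbdt = .xgb_fit(X, y, params, seed, regularised = FALSE),
    xgb = ,
    meta = .xgb_fit(X, y, params, seed, regularised = TRUE)
  )
  structure(list(learner = learner, model = model, params = params,
                 feature_names = colnames(X)),
            class = "base_model")
}

.predict_learner <- function(bm, X) {
  if (bm$learner == "lr") {
    Xg <- if (ncol(X) < 2L) cbind(X, `.dummy0` = 0) else X
    as.numeric(predict(bm$model, newx = Xg, type = "response",
                       s = bm$params$lambda))
  } else {
    as.numeric(predict(bm$model, newdata = X))
  }
}

.grid_rows <- function(grid) lapply(seq_len(nrow(grid)), function(r) as.list(grid[r, , drop = FALSE]))

# grid search by internal stratified CV accuracy on (X, y); first row wins ties
.tune_learner <- function(learner, X, y, cfg, seed) {
  grid <- cfg$grids[[learner]]
  if (is.null(grid) || nrow(grid) == 1L) {
    if (is.null(grid)) return(.fixed_params()[[learner]])
    return(.grid_rows(grid)[[1L]])
  }
  combos <- .grid_rows(grid)
  fold <- .stratified_fold_ids(y, cfg$inner_folds, derive_seed(seed, 601L))
  acc <- vapply(seq_along(combos), function(ci) {
    accs <- vapply(seq_len(cfg$inner_folds), function(kk) {
      tr <- fold != kk
      bm <- .fit_learner(learner, X[tr, , drop = FALSE], y[tr], combos[[ci]],
                         derive_seed(seed, 602L, ci, kk))
      p <- .predict_learner(bm, X[!tr, , drop = FALSE])
      mean((p >= 0.5) == (y[!tr] == 1))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  combos[[which.max(acc)]]
}

.resolve_params <- function(learner, X, y, cfg, seed) {
  if (cfg$tune) .tune_learner(learner, X, y, cfg, seed)
  else if (!is.null(cfg$grids[[learner]]) && nrow(cfg$grids[[learner]]) == 1L) {
    .grid_rows(cfg$grids[[learner]])[[1L]]
  } else .fixed_params()[[learner]]
}

#' Fit the level-one base models out-of-fold
#'
#' For each base learner and fold, fits the learner on the rows outside
#' the fold (hyperparameters resolved by grid search with internal CV on
#' that same partition) and predicts positive-class probabilities on the
#' held-out fold. The collected out-of-fold predictions form the meta
#' table that will train the fuse model.
#'
#' @param table a `feature_table` (training rows).
#' @param cfg a [stack_config()].
#' @param fold_map optional precomputed fold assignment (for audits).
#' @return list with `fold_models` (per learner, per fold), `meta_table`
#'   (columns `lr`, `gbdt`, `xgb`, `label`), `fold_map`.
#' @export
fit_base_oof <- function(table, cfg = stack_config(), fold_map = NULL) {
  X <- .as_matrix_x(table)
  y <- as.integer(table$label)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(fold_map)) fold_map <- make_folds(nrow(X), y, cfg)
  for (kk in seq_len(cfg$n_folds)) {
    if (length(unique(y[fold_map != kk])) < 2L) {
      stop("a training partition contains a single class; use stratified folds")
    }
  }
  fold_models <- lapply(BASE_LEARNERS, function(l) vector("list", cfg$n_folds))
  names(fold_models) <- BASE_LEARNERS
  meta <- matrix(NA_real_, nrow(X), length(BASE_LEARNERS),
                 dimnames = list(NULL, BASE_LEARNERS))
  for (j in seq_along(BASE_LEARNERS)) {
    learner <- BASE_LEARNERS[j]
    for (kk in seq_len(cfg$n_folds)) {
      tr <- fold_map != kk
      seed_jk <- derive_seed(cfg$seed, 700L + j, kk)
      params <- .resolve_params(learner, X[tr, , drop = FALSE], y[tr], cfg, seed_jk)
      bm <- .fit_learner(learner, X[tr, , drop = FALSE], y[tr], params, seed_jk)
      fold_models[[learner]][[kk]] <- bm
      meta[!tr, j] <- .predict_learner(bm, X[!tr, , drop = FALSE])
    }
  }
  meta_table <- as.data.frame(meta)
  meta_table$label <- y
  list(fold_models = fold_models, meta_table = meta_table, fold_map = fold_map)
}

#' Fit the level-two fuse model on the out-of-fold meta table
#'
#' @param meta_table data frame with the three base-learner probability
#'   columns and `label`.
#' @param cfg a [stack_config()].
#' @return the fitted meta `base_model` (an XGBoost classifier).
#' @export
fit_meta <- function(meta_table, cfg = stack_config()) {
  X <- as.matrix(meta_table[, BASE_LEARNERS, drop = FALSE])
  y <- as.integer(meta_table$label)
  if (length(unique(y)) < 2L && all(apply(X, 2, function(c) var(c) == 0))) {
    stop("degenerate meta table: single class and constant meta-features")
  }
  seed <- derive_seed(cfg$seed, 801L)
  params <- .resolve_params("meta", X, y, cfg, seed)
  .fit_learner("meta", X, y, params, seed)
}

#' Fit the full stacking ensemble
#'
#' Out-of-fold base fitting followed by fuse-model training; the returned
#' model carries its fold bookkeeping and out-of-fold meta table as
#' provenance.
#'
#' @inheritParams fit_base_oof
#' @return a `stacked_model`.
#' @export
fit_sellp <- function(table, cfg = stack_config(), fold_map = NULL) {
  base <- fit_base_oof(table, cfg, fold_map)
  meta_model <- fit_meta(base$meta_table, cfg)
  structure(list(fold_models = base$fold_models, meta_model = meta_model,
                 fold_map = base$fold_map,
                 feature_names = setdiff(names(table), "label"),
                 training_meta_table = base$meta_table, config = cfg),
            class = "stacked_model")
}

#' @exportS3Method base::print
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> %d base learners x %d folds + fuse model; features: %s\n",
              length(x$fold_models), x$config$n_folds,
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Predict link probabilities with a stacked model
#'
#' Each base learner's fold-models predict every row; the per-learner
#' predictions are averaged over folds, and the three averages are fused
#' by the meta model.
#'
#' @param object a `stacked_model`.
#' @param table a `feature_table` whose feature columns match
#'   `object$feature_names`.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0,1]`.
#' @export
predict.stacked_model <- function(object, table, ...) {
  feats <- setdiff(names(table), "label")
  if (!identical(sort(feats), sort(object$feature_names))) {
    stop(sprintf("feature mismatch: model has [%s], table has [%s]",
                 paste(object$feature_names, collapse = ", "),
                 paste(feats, collapse = ", ")))
  }
  X <- as.matrix(table[, object$feature_names, drop = FALSE])
  meta_X <- vapply(BASE_LEARNERS, function(l) {
    preds <- vapply(object$fold_models[[l]],
                    function(bm) .predict_learner(bm, X), numeric(nrow(X)))
    if (nrow(X) == 1L) mean(preds) else rowMeans(matrix(preds, nrow = nrow(X)))
  }, numeric(nrow(X)))
  meta_X <- matrix(meta_X, nrow = nrow(X), dimnames = list(NULL, BASE_LEARNERS))
  .predict_learner(object$meta_model, meta_X)
}

#' Threshold probabilities into 0/1 labels
#' @param probabilities numeric vector in `[0,1]`.
#' @param threshold label 1 iff probability >= threshold; default 0.5.
#' @return integer vector of 0/1 labels.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  as.integer(probabilities >= threshold)
}

#' Fit a single base learner on the whole training table
#'
#' Ablation path: one learner, tuned the same way as a fold-model but on
#' the full training data.
#'
#' @param table a `feature_table`.
#' @param learner one of `"lr"`, `"gbdt"`, `"xgb"`.
#' @param cfg a [stack_config()].
#' @return a `single_model`.
#' @export
fit_single_learner <- function(table, learner = BASE_LEARNERS,
                               cfg = stack_config()) {
  learner <- match.arg(learner)
  X <- .as_matrix_x(table)
  y <- as.integer(table$label)
  seed <- derive_seed(cfg$seed, 901L, match(learner, BASE_LEARNERS))
  params <- .resolve_params(learner, X, y, cfg, seed)
  bm <- .fit_learner(learner, X, y, params, seed)
  structure(list(base = bm, feature_names = colnames(X)),
            class = "single_model")
}

#' @export
predict.single_model <- function(object, table, ...) {
  X <- as.matrix(table[, object$feature_names, drop = FALSE])
  .predict_learner(object$base, X)
}

#' Save / load a stacked model bundle
#'
#' Writes the fitted model as an RDS file next to a JSON manifest
#' (configuration, seed, feature names, fold sizes).
#'
#' @param model a `stacked_model`.
#' @param dir output directory (created if needed).
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  manifest <- list(
    feature_names = model$feature_names,
    n_folds = model$config$n_folds,
    fold_sizes = as.list(table(model$fold_map)),
    seed = model$config$seed,
    base_learners = BASE_LEARNERS,
    meta_learner = "xgb")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
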