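# End-to-end protocol: per run, split the network into a balanced labeled
# dataset, compute the twelve similarity matrices on the training graph,
# extract features, select features by RF-RFE on the training rows, train
# the stacking ensemble on the selected features, and evaluate on the test
# rows. Ablations (stack without RFE, each base learner with and without
# RFE) and similarity-only baselines are evaluated on the same split, and
# everything is aggregated over runs.

#' Configuration of a full experiment
#'
#' @param network a [linknet()], a [synthetic_spec()], or an edge-list path.
#' @param split a [split_config()] (train fraction, number of runs).
#' @param params an [index_params()].
#' @param rfe_k_folds,rfe_n_repeats,rfe_n_trees RF-RFE settings (CVS folds,
#'   CVS repetitions, forest size).
#' @param stack a [stack_config()] (its seed is re-derived per run).
#' @param baselines similarity indices evaluated as threshold-free
#'   baselines on the same splits; default `c("CN", "MFI", "SRW")`.
#' @param ablations also evaluate the no-RFE stack and each base learner
#'   with and without RFE; default `TRUE`.
#' @param threshold classification threshold on fused probabilities.
#' @param master_seed integer; run `r` derives its seed as
#'   `master_seed + r`.
#' @param freeze_selection reuse run 1's selected features for all runs
#'   instead of re-selecting per run; default `FALSE`.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(network, split = split_config(),
                              params = index_params(),
                              rfe_k_folds = 5L, rfe_n_repeats = 20L,
                              rfe_n_trees = 100L,
                              stack = stack_config(),
                              baselines = c("CN", "MFI", "SRW"),
                              ablations = TRUE, threshold = 0.5,
                              master_seed = 0L, freeze_selection = FALSE) {
  if (length(baselines) && !all(baselines %in% index_names())) {
    stop("unknown baseline index; see index_names()")
  }
  structure(list(network = network, split = split, params = params,
                 rfe_k_folds = as.integer(rfe_k_folds),
                 rfe_n_repeats = as.integer(rfe_n_repeats),
                 rfe_n_trees = as.integer(rfe_n_trees), stack = stack,
                 baselines = baselines, ablations = isTRUE(ablations),
                 threshold = threshold, master_seed = as.integer(master_seed),
                 freeze_selection = isTRUE(freeze_selection)),
            class = "experiment_config")
}

.resolve_network <- function(network) {
  if (inherits(network, "linknet")) return(network)
  if (inherits(network, "synthetic_spec")) return(generate_synthetic(network))
  if (is.character(network)) return(read_edge_list(network))
  stop("`network` must be a linknet, a synthetic_spec, or an edge-list path")
}

.stack_with_seed <- function(stack, seed) {
  stack$seed <- as.integer(seed)
  stack
}

.eval_probs <- function(labels, probs, threshold) {
  link_metrics(labels, classify(probs, threshold), probs)
}

#' Run the full multi-run link-prediction experiment
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-run progress.
#' @return an `experiment_report`: `per_run` metrics per method,
#'   `aggregates` (a [aggregate_runs()] result per method), `rfe` (one
#'   `rfe_result` per run), `selected_features` per run, and provenance.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  net <- .resolve_network(cfg$network)
  n_runs <- cfg$split$n_runs
  per_run <- list()
  rfe_runs <- list()
  selected_runs <- list()
  for (r in seq_len(n_runs)) {
    if (verbose) message(sprintf("run %d/%d", r, n_runs))
    seed_r <- cfg$master_seed + r
    sc <- split_config(cfg$split$train_fraction, cfg$split$balance_negatives,
                       seed = seed_r, n_runs = 1L)
    ds <- build_balanced_dataset(net, sc)
    sims <- compute_all_indices(ds$training_graph, cfg$params)
    ft_train <- extract_features(ds$train, sims, ds$training_graph)
    ft_test <- extract_features(ds$test, sims, ds$training_graph)
    test_labels <- ds$test$label
    ft_test_unlabeled <- ft_test
    ft_test_unlabeled$label <- NULL
    ft_test_unlabeled <- structure(
      cbind(ft_test_unlabeled, label = NA_integer_),
      pairs = attr(ft_test, "pairs"),
      feature_names = attr(ft_test, "feature_names"),
      class = class(ft_test))

    if (cfg$freeze_selection && r > 1L) {
      rfe_res <- rfe_runs[[1L]]
    } else {
      rfe_res <- run_rfe(ft_train, cfg$rfe_k_folds, cfg$rfe_n_repeats,
                         forest_config(cfg$rfe_n_trees, seed_r))
    }
    rfe_runs[[r]] <- rfe_res
    sel <- rfe_res$selected_features
    selected_runs[[r]] <- sel

    run_metrics <- list()
    stack_r <- .stack_with_seed(cfg$stack, seed_r)

    tr_sel <- select_feature_columns(ft_train, sel)
    te_sel <- select_feature_columns(ft_test_unlabeled, sel)
    model_sel <- fit_sellp(tr_sel, stack_r)
    run_metrics$sellp_rfe <- .eval_probs(
      test_labels, predict(model_sel, te_sel), cfg$threshold)

    if (cfg$ablations) {
      model_full <- fit_sellp(ft_train, stack_r)
      run_metrics$sellp_full <- .eval_probs(
        test_labels, predict(model_full, ft_test_unlabeled), cfg$threshold)
      for (l in BASE_LEARNERS) {
        m_full <- fit_single_learner(ft_train, l, stack_r)
        run_metrics[[paste0(l, "_full")]] <- .eval_probs(
          test_labels, predict(m_full, ft_test_unlabeled), cfg$threshold)
        m_sel <- fit_single_learner(tr_sel, l, stack_r)
        run_metrics[[paste0(l, "_rfe")]] <- .eval_probs(
          test_labels, predict(m_sel, te_sel), cfg$threshold)
      }
    }
    for (nm in cfg$baselines) {
      run_metrics[[paste0("sim_", nm)]] <- similarity_baseline(sims[[nm]], ds$test)
    }
    per_run[[r]] <- run_metrics
  }
  methods <- names(per_run[[1L]])
  aggregates <- lapply(methods, function(mn) {
    aggregate_runs(lapply(per_run, `[[`, mn))
  })
  names(aggregates) <- methods
  structure(list(per_run = per_run, aggregates = aggregates,
                 rfe = rfe_runs, selected_features = selected_runs,
                 provenance = list(master_seed = cfg$master_seed,
                                   n_runs = n_runs,
                                   train_fraction = cfg$split$train_fraction,
                                   n_nodes = net$n, n_edges = net$m,
                                   methods = methods,
                                   package_version = as.character(
                                     utils::packageVersion("linkstack")))),
            class = "experiment_report")
}

#' @exportS3Method base::print
print.experiment_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<experiment_report> %d runs on %d nodes / %d edges (train fraction %.2f)\n",
              p$n_runs, p$n_nodes, p$n_edges, p$train_fraction))
  cat(sprintf("%-12s %-9s %-9s %-9s %-9s %-9s\n",
              "method", "AUC", "accuracy", "precision", "recall", "F1"))
  for (mn in names(x$aggregates)) {
    m <- x$aggregates[[mn]]$mean
    cat(sprintf("%-12s %-9.4f %-9.4f %-9.4f %-9.4f %-9.4f\n",
                mn, m[["auc"]], m[["accuracy"]], m[["precision"]],
                m[["recall"]], m[["f1"]]))
  }
  invisible(x)
}

#' Run only the feature-selection stage of the protocol
#'
#' Builds run 1's balanced dataset and training-graph features, then runs
#' RF-RFE on the training rows.
#'
#' @inheritParams run_experiment
#' @return an `rfe_result`.
#' @export
run_rfe_only <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  net <- .resolve_network(cfg$network)
  seed_r <- cfg$master_seed + 1L
  sc <- split_config(cfg$split$train_fraction, cfg$split$balance_negatives,
                     seed = seed_r, n_runs = 1L)
  ds <- build_balanced_dataset(net, sc)
  sims <- compute_all_indices(ds$training_graph, cfg$params)
  ft_train <- extract_features(ds$train, sims, ds$training_graph)
  run_rfe(ft_train, cfg$rfe_k_folds, cfg$rfe_n_repeats,
          forest_config(cfg$rfe_n_trees, seed_r))
}

#' Serialise an experiment report to JSON
#' @param report an `experiment_report`.
#' @param path optional file; if `NULL`, returns the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    provenance = report$provenance,
    aggregates = lapply(report$aggregates, function(a) {
      list(mean = as.list(a$mean), sd = as.list(a$sd))
    }),
    selected_features = report$selected_features,
    per_run = lapply(report$per_run, function(rm) {
      lapply(rm, function(m) list(accuracy = m$accuracy,
                                  precision = m$precision,
                                  recall = m$recall, f1 = m$f1,
                                  auc = m$auc))
    }))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Bar chart of a metric across methods
#' @param report an `experiment_report`.
#' @param metric one of `"auc"`, `"accuracy"`, `"precision"`, `"recall"`,
#'   `"f1"`.
#' @param path optional PNG path.
#' @export
plot_metric_bars <- function(report, metric = "auc", path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 840, height = 480)
    on.exit(grDevices::dev.off())
  }
  means <- vapply(report$aggregates, function(a) a$mean[[metric]], numeric(1))
  graphics::barplot(means, las = 2, ylab = metric, ylim = c(0, 1),
                    main = sprintf("Mean %s over %d runs", metric,
                                   report$provenance$n_runs))
  invisible(report)
}
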