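# Evaluation: confusion-matrix metrics, the rank-form AUC with midranks
# for ties, similarity-only baselines, matching-score diagnostics,
# multi-run aggregation, and the two-stage F-test / t-test comparison.

#' Confusion counts of a binary prediction
#' @param labels_true,labels_pred equal-length 0/1 vectors.
#' @return a `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length")
  }
  if (!all(labels_true %in% c(0, 1)) || !all(labels_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  structure(list(
    TP = sum(labels_true == 1 & labels_pred == 1),
    FP = sum(labels_true == 0 & labels_pred == 1),
    FN = sum(labels_true == 1 & labels_pred == 0),
    TN = sum(labels_true == 0 & labels_pred == 0)),
    class = "confusion_counts")
}

#' Rank-form AUC
#'
#' `AUC = (S0 - n0(n0+1)/2) / (n0 n1)` where `S0` sums the positives'
#' ranks in the ascending-score list, `n0` and `n1` are the positive and
#' negative counts. Tied scores get midranks, making the statistic equal
#' to the concordance probability with ties counted 1/2.
#'
#' @param scores numeric scores (higher = more link-like).
#' @param labels_true 0/1 labels.
#' @return AUC in `[0,1]`.
#' @export
auc_rank <- function(scores, labels_true) {
  n0 <- sum(labels_true == 1)
  n1 <- sum(labels_true == 0)
  if (n0 == 0 || n1 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  s0 <- sum(r[labels_true == 1])
  (s0 - n0 * (n0 + 1) / 2) / (n0 * n1)
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s has zero denominator; reporting 0", what))
    return(0)
  }
  num / den
}

#' Full metrics report for one evaluation
#'
#' Accuracy, precision, recall and F1 from the confusion counts (a zero
#' denominator yields 0 with a warning) plus the rank-form AUC from the
#' scores.
#'
#' @param labels_true 0/1 labels.
#' @param labels_pred 0/1 predictions; if `NULL`, derived from `scores`
#'   at `threshold`.
#' @param scores numeric scores aligned with `labels_true`.
#' @param threshold classification threshold when `labels_pred` is `NULL`.
#' @return a `metrics_report` with `accuracy`, `precision`, `recall`,
#'   `f1`, `auc`, `counts`, `n0`, `n1`.
#' @export
link_metrics <- function(labels_true, labels_pred = NULL, scores,
                         threshold = 0.5) {
  if (is.null(labels_pred)) labels_pred <- classify(scores, threshold)
  cts <- confusion(labels_true, labels_pred)
  total <- cts$TP + cts$FP + cts$FN + cts$TN
  precision <- .safe_ratio(cts$TP, cts$TP + cts$FP, "precision")
  recall <- .safe_ratio(cts$TP, cts$TP + cts$FN, "recall")
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(
    accuracy = (cts$TP + cts$TN) / total,
    precision = precision, recall = recall, f1 = f1,
    auc = auc_rank(scores, labels_true),
    counts = cts, n0 = sum(labels_true == 1), n1 = sum(labels_true == 0)),
    class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> acc %.4f  prec %.4f  rec %.4f  F1 %.4f  AUC %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Evaluate a single similarity index as a link predictor
#'
#' Scores the test pairs by matrix lookup (the matrix must have been
#' computed on the training graph). AUC is threshold-free; the
#' classification metrics threshold at the median score of the evaluated
#' pool (balanced data then yields balanced predictions).
#'
#' @param sim a similarity matrix.
#' @param test a labeled pair data frame (columns `i`, `j`, `label`).
#' @return a `metrics_report`.
#' @export
similarity_baseline <- function(sim, test) {
  scores <- sim[cbind(test$i, test$j)]
  thr <- median(scores)
  link_metrics(test$label, classify(scores, thr), scores)
}

.rank_pool <- function(sim, pool) {
  scores <- sim[cbind(pool[, 1L], pool[, 2L])]
  # descending score; deterministic tie-break by pair order (i, then j)
  order(-scores, pool[, 1L], pool[, 2L])
}

#' Matching score of a similarity index
#'
#' Ranks the candidate pool by score (descending; ties broken by the
#' fixed pair ordering) and reports the fraction of the observed edges
#' recovered in the top `|observed|` candidates.
#'
#' @param sim a similarity matrix.
#' @param observed_edges two-column matrix of the edges to recover.
#' @param candidate_pool two-column matrix of candidate pairs; must
#'   contain `observed_edges`.
#' @return the matching score in `[0,1]`.
#' @export
matching_score <- function(sim, observed_edges, candidate_pool) {
  observed_edges <- matrix(as.integer(as.matrix(observed_edges)), ncol = 2L)
  candidate_pool <- matrix(as.integer(as.matrix(candidate_pool)), ncol = 2L)
  obs_key <- .pair_key(observed_edges[, 1L], observed_edges[, 2L])
  pool_key <- .pair_key(candidate_pool[, 1L], candidate_pool[, 2L])
  if (!all(obs_key %in% pool_key)) {
    stop("`observed_edges` must be a subset of `candidate_pool`")
  }
  top <- head(.rank_pool(sim, candidate_pool), length(obs_key))
  mean(obs_key %in% pool_key[top])
}

#' Difference of matching scores between two indices
#' @param sim_a,sim_b similarity matrices.
#' @inheritParams matching_score
#' @return `sigma(sim_a) - sigma(sim_b)`.
#' @export
delta_sigma <- function(sim_a, sim_b, observed_edges, candidate_pool) {
  matching_score(sim_a, observed_edges, candidate_pool) -
    matching_score(sim_b, observed_edges, candidate_pool)
}

#' Aggregate per-run metrics reports
#' @param reports list of `metrics_report`s (one per run).
#' @return a `run_aggregate` with the per-run reports and per-metric mean
#'   and standard deviation.
#' @export
aggregate_runs <- function(reports) {
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  values <- sapply(metric_names, function(mn) {
    vapply(reports, function(r) r[[mn]], numeric(1))
  })
  values <- matrix(values, nrow = length(reports),
                   dimnames = list(NULL, metric_names))
  structure(list(runs = reports,
                 mean = colMeans(values),
                 sd = apply(values, 2L, sd),
                 values = values),
            class = "run_aggregate")
}

#' @exportS3Method base::print
print.run_aggregate <- function(x, ...) {
  cat(sprintf("<run_aggregate> %d runs\n", nrow(x$values)))
  for (mn in colnames(x$values)) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", mn, x$mean[[mn]], x$sd[[mn]]))
  }
  invisible(x)
}

#' Two-stage statistical comparison of per-run metric samples
#'
#' First an F-test of variance equality; if its p-value is at least
#' `alpha`, a two-sample equal-variance t-test of the means follows,
#' otherwise the unequal-variance (Welch) variant. The 95% confidence
#' interval of the mean difference comes from the chosen t-test.
#'
#' @param sample_a,sample_b per-run metric values (length >= 2).
#' @param alpha significance level for the variance test; default 0.05.
#' @return a `comparison_result` with `f_test_p`, `t_test_p`,
#'   `t_test_variant`, `ci95_mean_difference`, `mean_difference`.
#' @export
compare_methods <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("both samples must have at least 2 values")
  }
  va <- var(sample_a); vb <- var(sample_b)
  diff_mean <- mean(sample_a) - mean(sample_b)
  if (va == 0 && vb == 0) {
    if (diff_mean == 0) {
      return(structure(list(f_test_p = 1, t_test_p = 1,
                            t_test_variant = "equal_variance",
                            ci95_mean_difference = c(0, 0),
                            mean_difference = 0),
                       class = "comparison_result"))
    }
    return(structure(list(f_test_p = 1, t_test_p = 0,
                          t_test_variant = "equal_variance",
                          ci95_mean_difference = rep(diff_mean, 2L),
                          mean_difference = diff_mean),
                     class = "comparison_result"))
  }
  f_p <- stats::var.test(sample_a, sample_b)$p.value
  variant <- if (f_p < alpha) "welch" else "equal_variance"
  tt <- stats::t.test(sample_a, sample_b,
                      var.equal = (variant == "equal_variance"),
                      conf.level = 0.95)
  structure(list(f_test_p = f_p, t_test_p = tt$p.value,
                 t_test_variant = variant,
                 ci95_mean_difference = as.numeric(tt$conf.int),
                 mean_difference = diff_mean),
            class = "comparison_result")
}

#' @exportS3Method base::print
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> F-test p %.3g; %s t-test p %.3g; 95%% CI [%.4f, %.4f]\n",
              x$f_test_p, gsub("_", "-", x$t_test_variant), x$t_test_p,
              x$ci95_mean_difference[1], x$ci95_mean_difference[2]))
  invisible(x)
}

#' Serialise a metrics report or run aggregate to JSON
#' @param x a `metrics_report` or `run_aggregate`.
#' @param path optional file; if `NULL`, returns the JSON string.
#' @export
metrics_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "run_aggregate")) {
    list(mean = as.list(x$mean), sd = as.list(x$sd),
         runs = lapply(x$runs, function(r) {
           list(accuracy = r$accuracy, precision = r$precision,
                recall = r$recall, f1 = r$f1, auc = r$auc)
         }))
  } else {
    list(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         f1 = x$f1, auc = x$auc,
         counts = unclass(x$counts), n0 = x$n0, n1 = x$n1)
  }
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
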