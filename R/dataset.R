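# Balanced link-prediction datasets: positives are the network's edges,
# negatives a uniform sample of non-edges of the same size; both are split
# train/test by the same fraction so class balance holds within each role.
# All similarity features are computed on the training graph (the network
# with the test positives removed) so that global indices cannot walk
# across the very links being predicted.

#' Configuration of the edge split and run replication
#'
#' @param train_fraction fraction of the balanced dataset used for
#'   training, in (0,1); default 0.9 (0.8 probes robustness to sparser
#'   observation).
#' @param balance_negatives sample exactly one negative per positive
#'   (default); the protocol assumes balanced classes.
#' @param seed integer seed; run `r` of a replicated experiment uses
#'   `seed + r`.
#' @param n_runs number of independent runs to aggregate; default 10.
#' @return a `split_config` list.
#' @export
split_config <- function(train_fraction = 0.9, balance_negatives = TRUE,
                         seed = 1L, n_runs = 10L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0,1)")
  }
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  structure(list(train_fraction = train_fraction,
                 balance_negatives = isTRUE(balance_negatives),
                 seed = as.integer(seed), n_runs = as.integer(n_runs)),
            class = "split_config")
}

# deterministic seed derivation; keeps values well inside 32-bit range
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in offs) s <- (s * 48271 + as.double(o)) %% 2147483647
  as.integer(s)
}

#' Randomly split the edges of a network into train and test sets
#'
#' @param net a [linknet()] network with at least 10 edges.
#' @param cfg a [split_config()].
#' @return list with two-column matrices `train_edges` and `test_edges`
#'   forming a disjoint partition of the edge set, with
#'   `nrow(train_edges) == round(train_fraction * M)`.
#' @export
split_edges <- function(net, cfg = split_config()) {
  stopifnot(inherits(net, "linknet"))
  if (net$m < 10L) stop("need at least 10 edges to split")
  n_train <- round(cfg$train_fraction * net$m)
  set.seed(derive_seed(cfg$seed, 101L))
  idx <- sample.int(net$m, n_train)
  list(train_edges = net$edges[idx, , drop = FALSE],
       test_edges = net$edges[-idx, , drop = FALSE])
}

.pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Sample non-edges uniformly without replacement
#'
#' Draws unordered node pairs that are neither self-pairs, edges of `net`,
#' nor members of `exclude`.
#'
#' @param net a [linknet()] network.
#' @param n_samples number of pairs to draw.
#' @param exclude optional two-column matrix of pairs to exclude.
#' @param seed integer seed.
#' @return two-column matrix of node-index pairs (`i < j`).
#' @export
sample_nonedges <- function(net, n_samples, exclude = NULL, seed = 1L) {
  stopifnot(inherits(net, "linknet"))
  n <- net$n
  total <- n * (n - 1) / 2
  excl_key <- character(0)
  if (!is.null(exclude) && length(exclude)) {
    exclude <- matrix(as.integer(as.matrix(exclude)), ncol = 2L)
    excl_key <- unique(.pair_key(exclude[, 1L], exclude[, 2L]))
  }
  edge_key <- .pair_key(net$edges[, 1L], net$edges[, 2L])
  pool_size <- total - length(unique(c(edge_key, excl_key)))
  if (n_samples > pool_size) {
    stop(sprintf("requested %d non-edges but only %.0f are available",
                 n_samples, pool_size))
  }
  if (n_samples == 0L) return(matrix(integer(0), ncol = 2L))
  set.seed(seed)
  forbidden <- unique(c(edge_key, excl_key))
  if (total <= 2e6) {
    # enumerate the complement exactly
    all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    key <- .pair_key(all_pairs[, 1L], all_pairs[, 2L])
    pool <- all_pairs[!(key %in% forbidden), , drop = FALSE]
    pick <- sample.int(nrow(pool), n_samples)
    out <- pool[pick, , drop = FALSE]
  } else {
    # rejection sampling for large vertex sets
    got <- character(0)
    out <- matrix(integer(0), ncol = 2L)
    while (nrow(out) < n_samples) {
      need <- (n_samples - nrow(out)) * 2L + 16L
      a <- sample.int(n, need, replace = TRUE)
      b <- sample.int(n, need, replace = TRUE)
      ok <- a != b
      lo <- pmin(a[ok], b[ok]); hi <- pmax(a[ok], b[ok])
      key <- .pair_key(lo, hi)
      new <- !(key %in% forbidden) & !(key %in% got) & !duplicated(key)
      got <- c(got, key[new])
      out <- rbind(out, cbind(lo[new], hi[new]))
    }
    out <- out[seq_len(n_samples), , drop = FALSE]
  }
  colnames(out) <- c("i", "j")
  out
}

new_labeled_pairs <- function(i, j, label, role) {
  structure(data.frame(i = as.integer(pmin(i, j)), j = as.integer(pmax(i, j)),
                       label = as.integer(label), role = role,
                       stringsAsFactors = FALSE),
            class = c("labeled_pairs", "data.frame"))
}

#' Build a balanced labeled link-prediction dataset
#'
#' Positives are all edges of the network; negatives are an equal-size
#' uniform sample of non-edges. Both classes are split by
#' `cfg$train_fraction` into train and test roles, so the classes stay
#' balanced within each role. The returned `training_graph` is the network
#' with the test positives removed — the graph on which all similarity
#' features must be computed (train rows included), preventing the target
#' links from leaking into global indices.
#'
#' @param net a [linknet()] network.
#' @param cfg a [split_config()].
#' @return list with `train` and `test` (labeled pair data frames with
#'   columns `i`, `j`, `label`, `role`) and `training_graph`.
#' @export
build_balanced_dataset <- function(net, cfg = split_config()) {
  sp <- split_edges(net, cfg)
  n_neg <- net$m  # 1:1 negative sampling; `balance_negatives` is the contract
  neg <- sample_nonedges(net, n_neg, seed = derive_seed(cfg$seed, 202L))
  n_train_neg <- round(cfg$train_fraction * nrow(neg))
  set.seed(derive_seed(cfg$seed, 303L))
  neg_train_idx <- sample.int(nrow(neg), n_train_neg)
  train <- new_labeled_pairs(
    c(sp$train_edges[, 1L], neg[neg_train_idx, 1L]),
    c(sp$train_edges[, 2L], neg[neg_train_idx, 2L]),
    c(rep(1L, nrow(sp$train_edges)), rep(0L, n_train_neg)),
    "train")
  neg_test <- neg[-neg_train_idx, , drop = FALSE]
  test <- new_labeled_pairs(
    c(sp$test_edges[, 1L], neg_test[, 1L]),
    c(sp$test_edges[, 2L], neg_test[, 2L]),
    c(rep(1L, nrow(sp$test_edges)), rep(0L, nrow(neg_test))),
    "test")
  list(train = train, test = test,
       training_graph = drop_edges(net, sp$test_edges))
}

#' Assemble a feature table from similarity matrices
#'
#' Looks up each pair's score in every supplied similarity matrix (all
#' computed on the same training graph) and carries the label through.
#' When the feature graph `net` is supplied, any pair that is itself an
#' edge of that graph gets its features re-evaluated on the graph minus
#' that single edge (leave-one-out), so no row's features encode the very
#' link it is labeled with; without `net` the extraction is a pure lookup.
#'
#' @param pairs a labeled pair data frame (columns `i`, `j`, `label`).
#' @param sim_matrices named list of similarity matrices in canonical
#'   order (see [compute_all_indices()]) or a recorded sub-selection.
#' @param net optional [linknet()] feature graph enabling the
#'   leave-one-out correction; requires the full 12-index `sim_matrices`.
#' @return a `feature_table` data frame: one column per index plus `label`;
#'   the pair roster is kept in the `"pairs"` attribute.
#' @export
extract_features <- function(pairs, sim_matrices, net = NULL) {
  stopifnot(is.data.frame(pairs))
  ns <- unique(vapply(sim_matrices, nrow, integer(1)))
  if (length(ns) > 1L) stop("similarity matrices disagree on network size")
  if (nrow(pairs) > 0L && max(pairs$i, pairs$j) > ns) {
    stop("pair indices exceed the similarity matrices' network size")
  }
  feats <- lapply(sim_matrices, function(S) {
    if (nrow(pairs) == 0L) numeric(0) else S[cbind(pairs$i, pairs$j)]
  })
  tbl <- as.data.frame(feats)
  names(tbl) <- names(sim_matrices)
  if (!is.null(net) && nrow(pairs) > 0L) {
    stopifnot(inherits(net, "linknet"))
    if (!identical(names(sim_matrices), index_names())) {
      stop("the leave-one-out correction needs all 12 canonical indices")
    }
    if (net$n != ns) stop("`net` size does not match the similarity matrices")
    own <- which(has_edge(net, pairs$i, pairs$j))
    if (length(own)) {
      params <- attr(sim_matrices[[1L]], "params_used")
      if (is.null(params)) params <- index_params()
      corr <- .loo_features(net, sim_matrices,
                            cbind(pairs$i[own], pairs$j[own]), params)
      tbl[own, ] <- as.data.frame(corr)
    }
  }
  tbl$label <- if (nrow(pairs)) as.integer(pairs$label) else integer(0)
  if (anyNA(tbl)) stop("feature table contains missing values")
  structure(tbl,
            pairs = pairs,
            feature_names = names(sim_matrices),
            class = c("feature_table", "data.frame"))
}

#' Restrict a feature table to a feature subset
#' @param table a `feature_table`.
#' @param features character vector of feature names to keep.
#' @return a `feature_table` with the requested columns plus `label`.
#' @export
select_feature_columns <- function(table, features) {
  missing <- setdiff(features, setdiff(names(table), "label"))
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  out <- table[, c(features, "label"), drop = FALSE]
  structure(out, pairs = attr(table, "pairs"), feature_names = features,
            class = c("feature_table", "data.frame"))
}

#' Write / read a feature table as CSV
#'
#' The CSV holds the feature columns plus `label`; the pair roster is
#' stored as leading `node_i`/`node_j` columns.
#' @param table a `feature_table`.
#' @param path file path.
#' @return `path` (write) or a `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  pairs <- attr(table, "pairs")
  df <- cbind(node_i = pairs$i, node_j = pairs$j, as.data.frame(table))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path)
  feat <- setdiff(names(df), c("node_i", "node_j", "label"))
  pairs <- new_labeled_pairs(df$node_i, df$node_j, df$label, role = NA_character_)
  tbl <- df[, c(feat, "label"), drop = FALSE]
  structure(tbl, pairs = pairs, feature_names = feat,
            class = c("feature_table", "data.frame"))
}

#' Write a labeled pair roster as TSV with node labels
#' @param pairs a labeled pair data frame.
#' @param net the [linknet()] the indices refer to.
#' @param path file path.
#' @export
write_pair_roster <- function(pairs, net, path) {
  df <- data.frame(node_label_i = net$node_ids[pairs$i],
                   node_label_j = net$node_ids[pairs$j],
                   label = pairs$label, role = pairs$role)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
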