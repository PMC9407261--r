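#' @importFrom stats predict var median sd
#' @importFrom utils head read.table write.table
#' @importFrom graphics abline barplot
#' @importFrom grDevices png dev.off
NULL

# Internal representation: nodes are 1-based contiguous indices; `node_ids`
# carries the user-facing labels. Edges are stored once with i < j.

new_linknet <- function(edges, node_ids, partition = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  colnames(edges) <- c("i", "j")
  net <- structure(
    list(
      node_ids = as.character(node_ids),
      edges = edges,
      n = length(node_ids),
      m = nrow(edges),
      partition = partition
    ),
    class = "linknet"
  )
  attr(net, "views_cache") <- new.env(parent = emptyenv())
  net
}

#' Construct an undirected simple network
#'
#' Builds the canonical network object used throughout the package: an
#' undirected, unweighted simple graph. Self-loops are dropped and
#' duplicate/reciprocal edges collapsed to a single representative with
#' `i < j`. Isolated nodes are legal and retained (they can appear as
#' negative-sample endpoints).
#'
#' @param edges two-column matrix (or data.frame) of node indices, 1-based.
#' @param n_nodes total node count (allows isolated nodes beyond the edge
#'   endpoints); defaults to `max(edges)`.
#' @param node_ids optional character labels, length `n_nodes`.
#' @param partition optional integer block assignment (recorded by the
#'   stochastic-block generator for downstream evaluation).
#' @return a `linknet` object with fields `node_ids`, `edges`, `n`, `m`.
#' @export
linknet <- function(edges, n_nodes = NULL, node_ids = NULL, partition = NULL) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L && any(edges < 1L)) stop("node indices must be >= 1")
  if (is.null(n_nodes)) n_nodes <- if (nrow(edges)) max(edges) else 0L
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) > 0L && max(edges) > n_nodes) {
    stop("edge endpoint exceeds `n_nodes`")
  }
  if (is.null(node_ids)) node_ids <- as.character(seq_len(n_nodes))
  if (length(node_ids) != n_nodes) stop("`node_ids` length must equal `n_nodes`")
  if (anyDuplicated(node_ids)) stop("`node_ids` must be unique")
  # drop self-loops, canonicalise orientation, dedupe
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(lo, hi)
  uniq <- !duplicated(key)
  edges <- cbind(lo[uniq], hi[uniq])
  if (nrow(edges) > 0L) edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  if (nrow(edges) > 0L && n_nodes < 2L) stop("a network with edges needs >= 2 nodes")
  new_linknet(edges, node_ids, partition = partition)
}

#' @exportS3Method base::print
print.linknet <- function(x, ...) {
  cat(sprintf("<linknet> %d nodes, %d edges\n", x$n, x$m))
  if (!is.null(x$partition)) {
    cat(sprintf("  planted partition: %d blocks\n", length(unique(x$partition))))
  }
  invisible(x)
}

#' Node degrees
#' @param net a [linknet()] network.
#' @return integer vector of degrees, one per node.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "linknet"))
  tabulate(c(net$edges[, 1L], net$edges[, 2L]), nbins = net$n)
}

#' Neighbour sets
#' @param net a [linknet()] network.
#' @return list of integer vectors; element `i` holds the neighbours of node `i`.
#' @export
neighbor_sets <- function(net) {
  stopifnot(inherits(net, "linknet"))
  nb <- vector("list", net$n)
  for (i in seq_len(net$n)) nb[[i]] <- integer(0)
  if (net$m > 0L) {
    all_i <- c(net$edges[, 1L], net$edges[, 2L])
    all_j <- c(net$edges[, 2L], net$edges[, 1L])
    sp <- split(all_j, all_i)
    for (nm in names(sp)) nb[[as.integer(nm)]] <- sort(sp[[nm]])
  }
  nb
}

#' Test whether a node pair is an edge
#' @param net a [linknet()] network.
#' @param i,j node indices.
#' @return logical.
#' @export
has_edge <- function(net, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  ekey <- paste(net$edges[, 1L], net$edges[, 2L])
  key %in% ekey
}

#' Read an undirected network from an edge-list file
#'
#' One whitespace-delimited node pair per line; lines starting with `#` are
#' comments. Node labels are opaque strings mapped to contiguous indices in
#' first-appearance order. Self-loops are dropped and duplicate or
#' reciprocal lines collapsed, with a warning reporting how many lines were
#' coerced. A `# nodes:` comment header (as written by [write_edge_list()])
#' fixes the node roster, so isolated nodes survive a round trip. Extra
#' tokens on a line (e.g. weights) are ignored with a warning.
#'
#' @param path path to the edge-list text file.
#' @return a [linknet()] network.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read edge list: '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  roster <- character(0)
  hdr <- grep("^#\\s*nodes:", lines)
  if (length(hdr)) {
    roster <- strsplit(sub("^#\\s*nodes:\\s*", "", lines[hdr[1L]]), "\\s+")[[1L]]
    roster <- roster[nzchar(roster)]
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  labels <- roster
  pairs_i <- character(0); pairs_j <- character(0)
  n_extra <- 0L
  for (ln in body_idx) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(toks) < 2L) {
      stop(sprintf("parse error in '%s' at line %d: expected at least 2 tokens", path, ln))
    }
    if (length(toks) > 2L) n_extra <- n_extra + 1L
    pairs_i <- c(pairs_i, toks[1L])
    pairs_j <- c(pairs_j, toks[2L])
  }
  if (n_extra > 0L) {
    warning(sprintf("%d line(s) had extra tokens (e.g. weights); ignored", n_extra))
  }
  labels <- unique(c(labels, as.vector(rbind(pairs_i, pairs_j))))
  idx_i <- match(pairs_i, labels)
  idx_j <- match(pairs_j, labels)
  n_self <- sum(idx_i == idx_j)
  if (n_self > 0L) warning(sprintf("%d self-loop line(s) dropped", n_self))
  lo <- pmin(idx_i, idx_j); hi <- pmax(idx_i, idx_j)
  keep <- lo != hi
  key <- paste(lo, hi)
  n_dup <- sum(keep & duplicated(key))
  if (n_dup > 0L) warning(sprintf("%d duplicate/reciprocal line(s) collapsed", n_dup))
  linknet(cbind(idx_i, idx_j), n_nodes = length(labels), node_ids = labels)
}

#' Write a network as an edge-list file
#'
#' Emits a `# nodes:` header preserving the full node roster (so isolated
#' nodes round-trip), then one `label_i label_j` line per stored edge
#' (`i < j`). `read_edge_list(write_edge_list(net, p))` reproduces `net`.
#'
#' @param net a [linknet()] network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "linknet"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot write edge list to '%s': %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(paste("# nodes:", paste(net$node_ids, collapse = " ")), con)
  if (net$m > 0L) {
    writeLines(paste(net$node_ids[net$edges[, 1L]], net$node_ids[net$edges[, 2L]]), con)
  }
  invisible(path)
}

#' Read a square 0/1 adjacency matrix from a text file
#'
#' Convenience reader for small demos: whitespace-delimited square matrix,
#' symmetrised, diagonal ignored.
#'
#' @param path path to the matrix text file.
#' @param node_ids optional labels.
#' @return a [linknet()] network.
#' @export
read_adjacency_matrix <- function(path, node_ids = NULL) {
  a <- as.matrix(read.table(path, header = FALSE))
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
  a <- (a + t(a)) > 0
  diag(a) <- FALSE
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  linknet(idx, n_nodes = nrow(a), node_ids = node_ids)
}

#' Derived matrix views of a network
#'
#' Returns (and caches per network object) the dense adjacency matrix `A`,
#' the degree vector `k`, the graph Laplacian `L = D - A`, its Moore-Penrose
#' pseudoinverse `L+`, and the row-stochastic transition matrix
#' `P[i,j] = A[i,j]/k(i)` (rows of isolated nodes are all zero).
#'
#' @param net a [linknet()] network.
#' @return list with elements `adjacency`, `degree`, `laplacian`,
#'   `laplacian_pinv`, `transition`.
#' @export
matrix_views <- function(net) {
  stopifnot(inherits(net, "linknet"))
  cache <- attr(net, "views_cache")
  if (!is.null(cache$views)) return(cache$views)
  n <- net$n
  A <- matrix(0, n, n)
  if (net$m > 0L) {
    A[net$edges] <- 1
    A[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  k <- rowSums(A)
  L <- diag(k, n) - A
  Lp <- MASS::ginv(L)
  Lp <- (Lp + t(Lp)) / 2  # enforce exact symmetry
  inv_k <- ifelse(k > 0, 1 / k, 0)
  P <- sweep(A, 1L, inv_k, `*`)  # row i scaled by 1/k(i)
  views <- list(adjacency = A, degree = k, laplacian = L,
                laplacian_pinv = Lp, transition = P)
  cache$views <- views
  views
}

#' Specification for a synthetic benchmark network
#'
#' @param model one of `"erdos_renyi"`, `"barabasi_albert"`,
#'   `"watts_strogatz"`, `"stochastic_block"`.
#' @param n_nodes node count (for `stochastic_block`, may be omitted when
#'   `block_sizes` is given).
#' @param seed integer seed; the same spec and seed give an identical edge set.
#' @param p edge probability (Erdos-Renyi).
#' @param m_attach edges attached per new node (Barabasi-Albert).
#' @param k_ring ring neighbourhood size and `p_rewire` rewiring probability
#'   (Watts-Strogatz).
#' @param p_rewire rewiring probability (Watts-Strogatz).
#' @param block_sizes integer vector of block sizes (stochastic block model).
#' @param p_within,p_between within-/between-block link probabilities, or
#'   `p_matrix` an explicit symmetric probability matrix.
#' @param p_matrix optional explicit block link-probability matrix.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model = c("erdos_renyi", "barabasi_albert",
                                     "watts_strogatz", "stochastic_block"),
                           n_nodes = NULL, seed = 1L, p = NULL,
                           m_attach = NULL, k_ring = NULL, p_rewire = NULL,
                           block_sizes = NULL, p_within = NULL,
                           p_between = NULL, p_matrix = NULL) {
  model <- match.arg(model)
  chk_prob <- function(x, nm) {
    if (!is.null(x) && (any(!is.finite(x)) || any(x < 0) || any(x > 1))) {
      stop(sprintf("`%s` must lie in [0,1]", nm))
    }
  }
  chk_prob(p, "p"); chk_prob(p_rewire, "p_rewire")
  chk_prob(p_within, "p_within"); chk_prob(p_between, "p_between")
  chk_prob(p_matrix, "p_matrix")
  if (model == "stochastic_block") {
    if (is.null(block_sizes)) stop("stochastic_block requires `block_sizes`")
    if (any(block_sizes < 1)) stop("block sizes must be >= 1")
    n_nodes <- sum(block_sizes)
    if (is.null(p_matrix)) {
      if (is.null(p_within) || is.null(p_between)) {
        stop("give `p_matrix` or both `p_within` and `p_between`")
      }
      b <- length(block_sizes)
      p_matrix <- matrix(p_between, b, b)
      diag(p_matrix) <- p_within
    }
  }
  if (is.null(n_nodes) || n_nodes < 1) stop("`n_nodes` must be >= 1")
  structure(list(model = model, n_nodes = as.integer(n_nodes),
                 seed = as.integer(seed), p = p, m_attach = m_attach,
                 k_ring = k_ring, p_rewire = p_rewire,
                 block_sizes = block_sizes, p_matrix = p_matrix),
            class = "synthetic_spec")
}

#' Generate a synthetic network
#'
#' Erdos-Renyi, Barabasi-Albert, Watts-Strogatz and stochastic-block-model
#' generators (via igraph), returned as a [linknet()]. Generation is
#' reproducible under the spec's seed; stochastic-block output records the
#' planted partition in `$partition`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [linknet()] network.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  g <- switch(spec$model,
    erdos_renyi = {
      if (is.null(spec$p)) stop("erdos_renyi requires `p`")
      igraph::sample_gnp(spec$n_nodes, spec$p, directed = FALSE, loops = FALSE)
    },
    barabasi_albert = {
      if (is.null(spec$m_attach)) stop("barabasi_albert requires `m_attach`")
      igraph::sample_pa(spec$n_nodes, m = spec$m_attach, directed = FALSE)
    },
    watts_strogatz = {
      if (is.null(spec$k_ring) || is.null(spec$p_rewire)) {
        stop("watts_strogatz requires `k_ring` and `p_rewire`")
      }
      igraph::sample_smallworld(1, spec$n_nodes, spec$k_ring, spec$p_rewire)
    },
    stochastic_block = {
      igraph::sample_sbm(spec$n_nodes, pref.matrix = spec$p_matrix,
                         block.sizes = spec$block_sizes)
    }
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  edges <- igraph::as_edgelist(g, names = FALSE)
  part <- if (spec$model == "stochastic_block") {
    rep(seq_along(spec$block_sizes), spec$block_sizes)
  } else NULL
  linknet(edges, n_nodes = spec$n_nodes, partition = part)
}

#' Drop a set of edges from a network
#'
#' Used to form the training graph: the node roster is preserved, only the
#' listed edges are removed.
#'
#' @param net a [linknet()] network.
#' @param edges two-column matrix of node-index pairs to remove.
#' @return a [linknet()] network on the same nodes.
#' @export
drop_edges <- function(net, edges) {
  stopifnot(inherits(net, "linknet"))
  if (is.null(edges) || length(edges) == 0L) return(net)
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  drop_key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  keep <- !(paste(net$edges[, 1L], net$edges[, 2L]) %in% drop_key)
  linknet(net$edges[keep, , drop = FALSE], n_nodes = net$n,
          node_ids = net$node_ids, partition = net$partition)
}
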