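# The twelve topological similarity indices. Local indices (CN, PA, AA,
# LHN, RA) have both a pairwise set-arithmetic form and an all-pairs matrix
# form; global and quasi-local indices (ACT, MFI, RWR, SimRank, LP, LRW,
# SRW) are computed as dense matrices from the network's matrix views.
# Diagonal entries are never consumed downstream (pairs i == j are excluded
# from all datasets); they are stored as 0, except SimRank's mandated 1.

#' Canonical similarity-index ordering
#'
#' Fixed ordering that defines feature-column identity everywhere
#' downstream (feature tables, elimination orders, selected subsets).
#' @return character vector of the 12 index names.
#' @export
index_names <- function() {
  c("CN", "PA", "AA", "LHN", "RA", "ACT", "MFI", "RWR", "SimRank",
    "LP", "LRW", "SRW")
}

#' Parameters of the similarity indices
#'
#' @param aa_log_base log base of the Adamic-Adar weight: `"natural"`
#'   (default, the canonical definition), `"log10"`, or `"log2"`. Any fixed
#'   base rescales scores by a constant and leaves rankings unchanged.
#' @param mfi_alpha positive weight of the Laplacian in the matrix forest
#'   index `(I + alpha L)^-1`; default 1 (the classical index).
#' @param rwr_restart_c continuation probability `c` of the random walk with
#'   restart, in (0,1); the walker restarts with probability `1 - c`.
#' @param simrank_decay_C SimRank decay factor in (0,1).
#' @param simrank_tol,simrank_max_iter SimRank stopping rule: iterate until
#'   the largest entry change drops below `simrank_tol` or `simrank_max_iter`
#'   sweeps.
#' @param lp_alpha weight of length-3 paths in the local-path index
#'   `A^2 + alpha A^3`; default 0.001.
#' @param walk_steps_t number of steps of the local random walk (and the
#'   superposition horizon of SRW); default 3.
#' @param linear_solve_tol numerical floor below which a commute-time
#'   denominator is treated as degenerate.
#' @return an `index_params` list.
#' @export
index_params <- function(aa_log_base = c("natural", "log10", "log2"),
                         mfi_alpha = 1.0, rwr_restart_c = 0.85,
                         simrank_decay_C = 0.8, simrank_tol = 1e-4,
                         simrank_max_iter = 100L, lp_alpha = 0.001,
                         walk_steps_t = 3L, linear_solve_tol = 1e-10) {
  aa_log_base <- match.arg(aa_log_base)
  if (mfi_alpha <= 0) stop("`mfi_alpha` must be > 0")
  if (rwr_restart_c <= 0 || rwr_restart_c >= 1) stop("`rwr_restart_c` must be in (0,1)")
  if (simrank_decay_C <= 0 || simrank_decay_C >= 1) stop("`simrank_decay_C` must be in (0,1)")
  if (simrank_tol <= 0 || linear_solve_tol <= 0) stop("tolerances must be > 0")
  if (walk_steps_t < 1) stop("`walk_steps_t` must be >= 1")
  structure(list(aa_log_base = aa_log_base, mfi_alpha = mfi_alpha,
                 rwr_restart_c = rwr_restart_c,
                 simrank_decay_C = simrank_decay_C,
                 simrank_tol = simrank_tol,
                 simrank_max_iter = as.integer(simrank_max_iter),
                 lp_alpha = lp_alpha, walk_steps_t = as.integer(walk_steps_t),
                 linear_solve_tol = linear_solve_tol),
            class = "index_params")
}

.log_fun <- function(base) {
  switch(base, natural = log, log10 = log10, log2 = log2)
}

new_similarity_matrix <- function(values, index_name, params) {
  structure(values, index_name = index_name, params_used = params,
            class = c("similarity_matrix", class(values)))
}

#' @exportS3Method base::print
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s, %d x %d\n",
              attr(x, "index_name"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write a similarity matrix as tab-separated text
#'
#' @param sim a similarity matrix as returned by the index functions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# index: %s", attr(sim, "index_name")), con)
  p <- attr(sim, "params_used")
  if (!is.null(p)) {
    writeLines(sprintf("# params: %s",
                       paste(names(p), unlist(p), sep = "=", collapse = " ")), con)
  }
  write.table(unclass(sim), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.check_pair <- function(net, i, j) {
  if (any(i == j)) stop("similarity is not defined for a node paired with itself")
  if (any(c(i, j) < 1L) || any(c(i, j) > net$n)) stop("node index out of range")
}

#' Common-neighbours index
#'
#' Number of shared neighbours of two nodes; more common neighbours make a
#' link more likely.
#' @param net a [linknet()] network.
#' @param i,j distinct node indices.
#' @return non-negative count.
#' @export
cn <- function(net, i, j) {
  .check_pair(net, i, j)
  nb <- neighbor_sets(net)
  length(intersect(nb[[i]], nb[[j]]))
}

#' Preferential-attachment index
#'
#' Product of the two node degrees.
#' @inheritParams cn
#' @export
pa <- function(net, i, j) {
  .check_pair(net, i, j)
  k <- degrees(net)
  k[i] * k[j]
}

#' Adamic-Adar index
#'
#' Sum over common neighbours of `1/log(k)`, weighting low-degree common
#' neighbours more heavily. A common neighbour of two distinct nodes always
#' has degree >= 2, so the sum is finite.
#' @inheritParams cn
#' @param params an [index_params()] list (log base).
#' @export
aa <- function(net, i, j, params = index_params()) {
  .check_pair(net, i, j)
  nb <- neighbor_sets(net)
  k <- degrees(net)
  common <- intersect(nb[[i]], nb[[j]])
  if (!length(common)) return(0)
  lg <- .log_fun(params$aa_log_base)
  sum(1 / lg(k[common]))
}

#' Leicht-Holme-Newman index
#'
#' Common-neighbour count divided by the degree product; 0 when there are
#' no common neighbours (even if a degree is 0).
#' @inheritParams cn
#' @export
lhn <- function(net, i, j) {
  .check_pair(net, i, j)
  cn_ij <- cn(net, i, j)
  if (cn_ij == 0) return(0)
  k <- degrees(net)
  cn_ij / (k[i] * k[j])
}

#' Resource-allocation index
#'
#' Sum over common neighbours of `1/k`, modelling a unit of resource spread
#' equally through shared intermediaries.
#' @inheritParams cn
#' @export
ra <- function(net, i, j) {
  .check_pair(net, i, j)
  nb <- neighbor_sets(net)
  k <- degrees(net)
  common <- intersect(nb[[i]], nb[[j]])
  if (!length(common)) return(0)
  sum(1 / k[common])
}

#' Average-commute-time index
#'
#' Inverse of the expected round-trip time of a random walk between two
#' nodes (up to the constant factor that cancels between pairs), computed
#' from the Laplacian pseudoinverse:
#' `1 / (l+_ii + l+_jj - 2 l+_ij)`. A denominator at or below
#' `linear_solve_tol` yields 0 with a warning.
#' @inheritParams aa
#' @export
act <- function(net, i, j, params = index_params()) {
  .check_pair(net, i, j)
  v <- matrix_views(net)
  if (v$degree[i] == 0 || v$degree[j] == 0) return(0)
  Lp <- v$laplacian_pinv
  denom <- Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  if (denom <= params$linear_solve_tol) {
    warning("degenerate commute-time denominator; returning 0")
    return(0)
  }
  1 / denom
}

.zero_diag <- function(m) { diag(m) <- 0; m }

.cn_matrix <- function(net) {
  A <- matrix_views(net)$adjacency
  .zero_diag(A %*% A)
}

.pa_matrix <- function(net) {
  k <- matrix_views(net)$degree
  .zero_diag(outer(k, k))
}

.aa_matrix <- function(net, params) {
  v <- matrix_views(net)
  lg <- .log_fun(params$aa_log_base)
  w <- ifelse(v$degree >= 2, 1 / lg(v$degree), 0)
  .zero_diag(v$adjacency %*% (w * v$adjacency))
}

.lhn_matrix <- function(net) {
  v <- matrix_views(net)
  cnm <- .cn_matrix(net)
  denom <- outer(v$degree, v$degree)
  out <- ifelse(cnm == 0, 0, cnm / pmax(denom, 1))
  .zero_diag(out)
}

.ra_matrix <- function(net) {
  v <- matrix_views(net)
  w <- ifelse(v$degree > 0, 1 / v$degree, 0)
  .zero_diag(v$adjacency %*% (w * v$adjacency))
}

.act_matrix <- function(net, params) {
  v <- matrix_views(net)
  Lp <- v$laplacian_pinv
  d <- diag(Lp)
  denom <- outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d) - 2 * Lp
  out <- ifelse(denom > params$linear_solve_tol, 1 / denom, 0)
  out[v$degree == 0, ] <- 0  # isolated nodes: no walk, no commute
  out[, v$degree == 0] <- 0
  .zero_diag(out)
}

#' Matrix-forest index
#'
#' Similarity matrix `(I + alpha L)^-1`, rooted in counting spanning rooted
#' forests; always well-defined since `I + alpha L` is positive definite
#' for `alpha > 0`.
#' @param net a [linknet()] network.
#' @param params an [index_params()] list.
#' @return a `similarity_matrix`.
#' @export
mfi <- function(net, params = index_params()) {
  L <- matrix_views(net)$laplacian
  S <- solve(diag(net$n) + params$mfi_alpha * L)
  S <- (S + t(S)) / 2
  new_similarity_matrix(.zero_diag(S), "MFI", params)
}

.rwr_pi <- function(net, params) {
  # column i = stationary distribution of the restarting walk from source i
  v <- matrix_views(net)
  n <- net$n
  c_ <- params$rwr_restart_c
  Pi <- (1 - c_) * solve(diag(n) - c_ * t(v$transition))
  Pi[, v$degree == 0] <- 0  # isolated source: zero vector by convention
  Pi
}

#' Random-walk-with-restart index
#'
#' For each source the walker follows the transition matrix with
#' probability `c` and restarts at the source with probability `1 - c`; the
#' stationary distribution is obtained by an exact linear solve. The score
#' is the symmetrised arrival probability `pi_i(j) + pi_j(i)`.
#' @inheritParams mfi
#' @export
rwr <- function(net, params = index_params()) {
  Pi <- .rwr_pi(net, params)
  S <- t(Pi) + Pi  # S[i,j] = Pi[j,i] + Pi[i,j] = pi_i(j) + pi_j(i)
  new_similarity_matrix(.zero_diag(S), "RWR", params)
}

#' SimRank index
#'
#' Two nodes are similar if their neighbours are similar: the fixed point
#' of `s(i,j) = C/(k_i k_j) * sum_{a in G(i), b in G(j)} s(a,b)` with base
#' case `s(v,v) = 1`, iterated from the identity until the largest entry
#' change falls below `simrank_tol` (or `simrank_max_iter` sweeps, with a
#' warning and a `converged` attribute set to `FALSE`).
#' @inheritParams mfi
#' @export
simrank <- function(net, params = index_params()) {
  v <- matrix_views(net)
  n <- net$n
  A <- v$adjacency
  k <- v$degree
  denom <- outer(k, k)
  S <- diag(n)
  converged <- FALSE
  for (iter in seq_len(params$simrank_max_iter)) {
    Snew <- ifelse(denom > 0, params$simrank_decay_C * (A %*% S %*% A) / pmax(denom, 1e-300), 0)
    diag(Snew) <- 1
    delta <- max(abs(Snew - S))
    S <- Snew
    if (delta < params$simrank_tol) { converged <- TRUE; break }
  }
  if (!converged) warning("SimRank did not converge within `simrank_max_iter`")
  out <- new_similarity_matrix((S + t(S)) / 2, "SimRank", params)
  attr(out, "converged") <- converged
  out
}

#' Local-path index
#'
#' `A^2 + alpha A^3`: counts of length-2 paths plus down-weighted counts of
#' length-3 paths (alpha = 0.001 by default).
#' @inheritParams mfi
#' @export
lp <- function(net, params = index_params()) {
  A <- matrix_views(net)$adjacency
  A2 <- A %*% A
  S <- A2 + params$lp_alpha * (A2 %*% A)
  new_similarity_matrix(.zero_diag(S), "LP", params)
}

.lrw_walk <- function(net, t_steps) {
  # returns list of matrices Pi_tau, tau = 1..t_steps, column i = pi_i(tau)
  v <- matrix_views(net)
  n <- net$n
  Pt <- t(v$transition)
  out <- vector("list", t_steps)
  Pi <- diag(n)
  for (tau in seq_len(t_steps)) {
    Pi <- Pt %*% Pi
    out[[tau]] <- Pi
  }
  out
}

.lrw_from_pi <- function(net, Pi) {
  q <- matrix_views(net)$degree / max(2 * net$m, 1)
  M1 <- q * t(Pi)  # M1[i,j] = q_i * pi_i(j)
  M1 + t(M1)
}

#' Local-random-walk index
#'
#' A walker starts at each node with initial resource `q(v) = k(v)/(2M)`
#' and is propagated `walk_steps_t` steps through the transition matrix;
#' the score is `q_i pi_i(j) + q_j pi_j(i)` at the final step.
#' @inheritParams mfi
#' @export
lrw <- function(net, params = index_params()) {
  Pis <- .lrw_walk(net, params$walk_steps_t)
  S <- .lrw_from_pi(net, Pis[[params$walk_steps_t]])
  new_similarity_matrix(.zero_diag(S), "LRW", params)
}

#' Superposed-random-walk index
#'
#' Accumulates the local-random-walk score over steps 1..`walk_steps_t`.
#' @inheritParams mfi
#' @export
srw <- function(net, params = index_params()) {
  Pis <- .lrw_walk(net, params$walk_steps_t)
  S <- Reduce(`+`, lapply(Pis, function(Pi) .lrw_from_pi(net, Pi)))
  new_similarity_matrix(.zero_diag(S), "SRW", params)
}

#' Compute all twelve similarity matrices
#'
#' Returns the similarity matrices in the canonical order given by
#' [index_names()]; this ordering defines feature-column identity in every
#' downstream table.
#' @inheritParams mfi
#' @return named list of 12 `similarity_matrix` objects.
#' @export
compute_all_indices <- function(net, params = index_params()) {
  out <- list(
    CN = new_similarity_matrix(.cn_matrix(net), "CN", params),
    PA = new_similarity_matrix(.pa_matrix(net), "PA", params),
    AA = new_similarity_matrix(.aa_matrix(net, params), "AA", params),
    LHN = new_similarity_matrix(.lhn_matrix(net), "LHN", params),
    RA = new_similarity_matrix(.ra_matrix(net), "RA", params),
    ACT = new_similarity_matrix(.act_matrix(net, params), "ACT", params),
    MFI = mfi(net, params),
    RWR = rwr(net, params),
    SimRank = simrank(net, params),
    LP = lp(net, params),
    LRW = lrw(net, params),
    SRW = srw(net, params)
  )
  out[index_names()]
}
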