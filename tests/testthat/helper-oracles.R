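# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: set arithmetic for the local indices, explicit
# eigendecompositions, power iteration, naive fixed-point loops, explicit
# per-source walk propagation, and pairwise concordance counting.

# plain numeric matrix, no class or index attributes
strip_sim <- function(S) {
  S <- unclass(S)
  attributes(S) <- list(dim = dim(S))
  S
}

oracle_adj <- function(net) {
  A <- matrix(0, net$n, net$n)
  for (r in seq_len(net$m)) {
    A[net$edges[r, 1L], net$edges[r, 2L]] <- 1
    A[net$edges[r, 2L], net$edges[r, 1L]] <- 1
  }
  A
}

oracle_nbrs <- function(A, i) which(A[i, ] > 0)

oracle_cn <- function(A, i, j) length(intersect(oracle_nbrs(A, i), oracle_nbrs(A, j)))
oracle_pa <- function(A, i, j) sum(A[i, ]) * sum(A[j, ])
oracle_aa <- function(A, i, j) {
  com <- intersect(oracle_nbrs(A, i), oracle_nbrs(A, j))
  if (!length(com)) 0 else sum(1 / log(colSums(A)[com]))
}
oracle_lhn <- function(A, i, j) {
  cnv <- oracle_cn(A, i, j)
  if (cnv == 0) 0 else cnv / (sum(A[i, ]) * sum(A[j, ]))
}
oracle_ra <- function(A, i, j) {
  com <- intersect(oracle_nbrs(A, i), oracle_nbrs(A, j))
  if (!length(com)) 0 else sum(1 / colSums(A)[com])
}

# eigendecomposition-based Moore-Penrose pseudoinverse
oracle_pinv <- function(L, tol = 1e-10) {
  e <- eigen(L, symmetric = TRUE)
  keep <- abs(e$values) > tol
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

oracle_act <- function(A, i, j) {
  if (sum(A[i, ]) == 0 || sum(A[j, ]) == 0) return(0)  # isolated convention
  L <- diag(colSums(A)) - A
  Lp <- oracle_pinv(L)
  d <- Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  if (d <= 1e-10) 0 else 1 / d
}

# eigendecomposition-based dense inverse of I + alpha L
oracle_mfi <- function(A, alpha = 1) {
  L <- diag(colSums(A)) - A
  e <- eigen(diag(nrow(A)) + alpha * L, symmetric = TRUE)
  e$vectors %*% diag(1 / e$values, nrow(A)) %*% t(e$vectors)
}

oracle_transition <- function(A) {
  k <- rowSums(A)
  P <- A / ifelse(k > 0, k, 1)
  P[k == 0, ] <- 0
  P
}

# power iteration for the restarting walk from every source
oracle_rwr <- function(A, c_ = 0.85, iters = 400L) {
  n <- nrow(A)
  P <- oracle_transition(A)
  k <- rowSums(A)
  Pt <- t(P)
  Pi <- diag(n)  # column i = pi_i
  E <- diag(n)
  for (it in seq_len(iters)) Pi <- c_ * (Pt %*% Pi) + (1 - c_) * E
  Pi[, k == 0] <- 0
  S <- t(Pi) + Pi
  diag(S) <- 0
  S
}

# naive per-pair fixed-point SimRank
oracle_simrank <- function(A, C = 0.8, tol = 1e-4, max_iter = 100L) {
  n <- nrow(A)
  k <- rowSums(A)
  s <- diag(n)
  for (it in seq_len(max_iter)) {
    s_new <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      Gi <- oracle_nbrs(A, i); Gj <- oracle_nbrs(A, j)
      if (!length(Gi) || !length(Gj)) next
      s_new[i, j] <- C * sum(s[Gi, Gj, drop = FALSE]) / (k[i] * k[j])
    }
    if (max(abs(s_new - s)) < tol) { s <- s_new; break }
    s <- s_new
  }
  s
}

# explicit repeated multiplication for the local-path index
oracle_lp <- function(A, alpha = 0.001) {
  A2 <- A %*% A
  A3 <- A %*% A %*% A
  S <- A2 + alpha * A3
  diag(S) <- 0
  S
}

# explicit per-source probability propagation
oracle_lrw_pi <- function(A, t_steps) {
  P <- oracle_transition(A)
  n <- nrow(A)
  out <- vector("list", t_steps)
  cur <- diag(n)  # column i = pi_i(0)
  Pt <- t(P)
  for (tau in seq_len(t_steps)) {
    cur <- Pt %*% cur
    out[[tau]] <- cur
  }
  out
}

oracle_lrw <- function(A, t_steps = 3L) {
  m2 <- sum(A) # = 2M
  q <- if (m2 > 0) rowSums(A) / m2 else rowSums(A) * 0
  Pi <- oracle_lrw_pi(A, t_steps)[[t_steps]]
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) S[i, j] <- q[i] * Pi[j, i] + q[j] * Pi[i, j]
  }
  S
}

oracle_srw <- function(A, t_steps = 3L) {
  m2 <- sum(A)
  q <- if (m2 > 0) rowSums(A) / m2 else rowSums(A) * 0
  Pis <- oracle_lrw_pi(A, t_steps)
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (tau in seq_len(t_steps)) {
    Pi <- Pis[[tau]]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) S[i, j] <- S[i, j] + q[i] * Pi[j, i] + q[j] * Pi[i, j]
    }
  }
  S
}

# concordance-probability AUC with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
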