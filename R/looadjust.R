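# Leave-one-out feature correction. A labeled pair that is itself an edge
# of the feature graph must not see that edge through its own features:
# walk-based and spectral indices otherwise carry a first-order
# "already connected" signal that separates training positives from
# everything else and destroys generalisation to held-out links. Each such
# pair's 12 scores are therefore evaluated on the feature graph minus that
# single edge. All corrections are exact closed forms or rank-one/rank-two
# updates except SimRank, which uses a one-step operator correction (an
# exact per-edge fixed-point recompute would cost a full SimRank iteration
# per training positive).
#
# Exact identities used, for edge e = (i,j), v = e_i - e_j:
#   CN, AA, RA  : unchanged (the edge is never its own common neighbour
#                 and removing it leaves the common neighbours' degrees
#                 untouched).
#   PA          : (k_i - 1)(k_j - 1).
#   LHN         : CN / ((k_i - 1)(k_j - 1)).
#   LP          : (A^3' )_ij = (A^3)_ij - k_i - k_j + 1; (A^2)_ij unchanged.
#   MFI         : Sherman-Morrison on (I + aL) - a vv'.
#   ACT         : with effective resistance r = v' L+ v, the commute
#                 denominator on G - e equals r/(1-r), so the score is
#                 (1-r)/r; at a bridge (r -> 1) the update is singular and
#                 the pseudoinverse is recomputed directly.
#   RWR         : Woodbury update of (I - cP')^-1 (two rows of P change).
#   LRW/SRW     : propagate the two sources under the corrected transition
#                 rows with q' = k'/(2(M-1)).

.loo_precompute <- function(net, params) {
  v <- matrix_views(net)
  n <- net$n
  A2 <- v$adjacency %*% v$adjacency
  list(views = v,
       A2 = A2,
       A3 = A2 %*% v$adjacency,
       M_mfi = solve(diag(n) + params$mfi_alpha * v$laplacian),
       F_rwr = solve(diag(n) - params$rwr_restart_c * t(v$transition)),
       Pt = t(v$transition),
       nb = neighbor_sets(net))
}

.loo_pair <- function(net, sims, pre, params, i, j) {
  v <- pre$views
  k <- v$degree
  ki2 <- k[i] - 1L; kj2 <- k[j] - 1L
  out <- numeric(12L)
  names(out) <- index_names()
  cn_ij <- sims$CN[i, j]
  out["CN"] <- cn_ij
  out["AA"] <- sims$AA[i, j]
  out["RA"] <- sims$RA[i, j]
  out["PA"] <- ki2 * kj2
  out["LHN"] <- if (cn_ij > 0) cn_ij / (ki2 * kj2) else 0
  out["LP"] <- pre$A2[i, j] +
    params$lp_alpha * (pre$A3[i, j] - k[i] - k[j] + 1)

  # MFI: Sherman-Morrison on B = I + aL, B' = B - a vv'
  a <- params$mfi_alpha
  M <- pre$M_mfi
  u <- M[, i] - M[, j]
  rv <- u[i] - u[j]
  out["MFI"] <- M[i, j] + a * u[i] * u[j] / (1 - a * rv)

  # ACT: commute denominator on G - e is r/(1-r)
  Lp <- v$laplacian_pinv
  r <- Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  if (1 - r > 1e-8) {
    denom <- r / (1 - r)
    out["ACT"] <- if (denom > params$linear_solve_tol) 1 / denom else 0
  } else {
    # bridge: removing the edge changes the Laplacian's null space
    L2 <- v$laplacian
    L2[i, i] <- L2[i, i] - 1; L2[j, j] <- L2[j, j] - 1
    L2[i, j] <- L2[i, j] + 1; L2[j, i] <- L2[j, i] + 1
    Lp2 <- MASS::ginv(L2)
    d2 <- Lp2[i, i] + Lp2[j, j] - 2 * Lp2[i, j]
    out["ACT"] <- if (d2 > params$linear_solve_tol) 1 / d2 else 0
  }

  # corrected transition rows (w = old row - new row)
  Arow_i <- v$adjacency[i, ]; Arow_i[j] <- 0
  Arow_j <- v$adjacency[j, ]; Arow_j[i] <- 0
  p_new_i <- if (ki2 > 0) Arow_i / ki2 else numeric(net$n)
  p_new_j <- if (kj2 > 0) Arow_j / kj2 else numeric(net$n)
  w1 <- v$transition[i, ] - p_new_i
  w2 <- v$transition[j, ] - p_new_j

  # RWR: Woodbury on I - cP'^T = F^-1 + c(w1 e_i' + w2 e_j')
  c_ <- params$rwr_restart_c
  Fm <- pre$F_rwr
  FW <- Fm %*% cbind(w1, w2)
  K <- diag(2) + c_ * FW[c(i, j), , drop = FALSE]
  Kinv <- solve(K)
  inv_ji <- Fm[j, i] - c_ * (FW[j, , drop = FALSE] %*% Kinv %*% c(Fm[i, i], Fm[j, i]))
  inv_ij <- Fm[i, j] - c_ * (FW[i, , drop = FALSE] %*% Kinv %*% c(Fm[i, j], Fm[j, j]))
  pi_i_j <- if (ki2 > 0) (1 - c_) * inv_ji else 0  # isolated source convention
  pi_j_i <- if (kj2 > 0) (1 - c_) * inv_ij else 0
  out["RWR"] <- pi_i_j + pi_j_i

  # SimRank: one-step operator correction from the unperturbed fixed point
  s <- sims$SimRank
  Gi <- setdiff(pre$nb[[i]], j)
  Gj <- setdiff(pre$nb[[j]], i)
  out["SimRank"] <- if (length(Gi) && length(Gj)) {
    params$simrank_decay_C * sum(s[Gi, Gj, drop = FALSE]) / (ki2 * kj2)
  } else 0

  # LRW / SRW: propagate both sources under the two corrected rows
  m2 <- net$m - 1L
  qi <- if (m2 > 0) ki2 / (2 * m2) else 0
  qj <- if (m2 > 0) kj2 / (2 * m2) else 0
  xi <- numeric(net$n); xi[i] <- 1
  xj <- numeric(net$n); xj[j] <- 1
  srw_acc <- 0; lrw_val <- 0
  for (tau in seq_len(params$walk_steps_t)) {
    xi <- as.numeric(pre$Pt %*% xi) - w1 * xi[i] - w2 * xi[j]
    xj <- as.numeric(pre$Pt %*% xj) - w1 * xj[i] - w2 * xj[j]
    lrw_val <- qi * xi[j] + qj * xj[i]
    srw_acc <- srw_acc + lrw_val
  }
  out["LRW"] <- lrw_val
  out["SRW"] <- srw_acc
  out
}

# Corrected feature rows for the pairs (subset of `pairs`) that are edges
# of `net`; returns a matrix with one row per requested pair.
.loo_features <- function(net, sims, pairs_ij, params) {
  pre <- .loo_precompute(net, params)
  t(vapply(seq_len(nrow(pairs_ij)), function(r) {
    .loo_pair(net, sims, pre, params, pairs_ij[r, 1L], pairs_ij[r, 2L])
  }, numeric(12L)))
}
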