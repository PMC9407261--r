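# Hand-derivable values first, then oracle equivalence on random graphs,
# then structural properties (symmetry, relabeling equivariance).

test_that("local indices match hand computations on small graphs", {
  p3 <- path_graph(3)
  expect_equal(cn(p3, 1, 3), 1L)
  expect_equal(pa(p3, 1, 3), 1)
  expect_equal(aa(p3, 1, 3), 1 / log(2))
  expect_equal(lhn(p3, 1, 3), 1)
  expect_equal(ra(p3, 1, 3), 0.5)

  c4 <- cycle_graph(4)
  expect_equal(cn(c4, 1, 3), 2L)
  expect_equal(aa(c4, 1, 3), 2 / log(2))
  expect_equal(lhn(c4, 1, 3), 0.5)
  expect_equal(ra(c4, 1, 3), 1)

  st <- star_graph(4)
  expect_equal(pa(st, 1, 2), 4)

  iso <- linknet(rbind(c(1L, 2L)), n_nodes = 4L)
  expect_equal(cn(iso, 3, 4), 0L)
  expect_equal(pa(iso, 3, 4), 0)
  expect_equal(aa(iso, 1, 3), 0)

  expect_error(cn(p3, 2, 2), "itself")
})

test_that("closed-form global index values hold on the single-edge graph", {
  net <- k2()
  expect_equal(act(net, 1, 2), 1.0, tolerance = 1e-9)
  expect_equal(mfi(net, index_params(mfi_alpha = 1))[1, 2], 1 / 3,
               tolerance = 1e-9)
  expect_equal(rwr(net, index_params(rwr_restart_c = 0.85))[1, 2],
               2 * 0.85 / 1.85, tolerance = 1e-9)
  expect_equal(simrank(net)[1, 2], 0, tolerance = 1e-9)
  expect_equal(lrw(net, index_params(walk_steps_t = 1))[1, 2], 1,
               tolerance = 1e-9)
})

test_that("SimRank fixes the diagonal at 1 and solves small cases exactly", {
  p3 <- path_graph(3)
  s <- simrank(p3, index_params(simrank_decay_C = 0.8))
  expect_equal(diag(s), rep(1, 3))
  # both ends share the single neighbour 2 whose self-similarity is 1
  expect_equal(s[1, 3], 0.8, tolerance = 1e-9)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("quasi-local indices reduce as expected in limit cases", {
  p4 <- path_graph(4)
  expect_equal(lp(p4)[1, 4], 0.001, tolerance = 1e-12)
  # alpha = 0 leaves pure path-2 counts, i.e. CN off-diagonal
  net <- rand_er(12, 0.3, 5)
  lp0 <- lp(net, index_params(lp_alpha = 0))
  cnm <- compute_all_indices(net)$CN
  expect_equal(unclass(lp0), unclass(cnm), ignore_attr = TRUE)
  # t = 1: SRW == LRW
  pr1 <- index_params(walk_steps_t = 1)
  expect_equal(unclass(srw(net, pr1)), unclass(lrw(net, pr1)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # telescoping: SRW(3) - SRW(2) == LRW(3)
  d <- srw(net, index_params(walk_steps_t = 3)) -
    srw(net, index_params(walk_steps_t = 2))
  expect_equal(unclass(d), unclass(lrw(net, index_params(walk_steps_t = 3))),
               ignore_attr = TRUE, tolerance = 1e-12)
  # c -> 0: restart dominates, off-diagonal RWR mass vanishes
  r0 <- rwr(net, index_params(rwr_restart_c = 1e-9))
  expect_lt(max(abs(r0)), 1e-6)
})

test_that("RWR solutions are probability vectors and match power iteration", {
  for (seed in 1:3) {
    net <- generate_synthetic(synthetic_spec("barabasi_albert", 15,
                                             seed = seed, m_attach = 2))
    pr <- index_params()
    Pi <- linkstack:::.rwr_pi(net, pr)
    expect_true(all(Pi >= -1e-12))
    expect_equal(colSums(Pi), rep(1, net$n), tolerance = 1e-8)
    S <- rwr(net, pr)
    expect_equal(unclass(S), oracle_rwr(oracle_adj(net)), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("ACT agrees with a Monte-Carlo commute-time estimate on the triangle", {
  net <- triangle()
  score <- act(net, 1, 2)
  scores_all <- sapply(list(c(1, 2), c(1, 3), c(2, 3)),
                       function(p) act(net, p[1], p[2]))
  expect_equal(max(scores_all) - min(scores_all), 0, tolerance = 1e-10)
  # simulate round trips 1 -> 2 -> 1
  set.seed(99)
  nb <- neighbor_sets(net)
  one_commute <- function() {
    steps <- 0L; cur <- 1L; target <- 2L; phase <- 1L
    repeat {
      cur <- nb[[cur]][sample.int(length(nb[[cur]]), 1L)]
      steps <- steps + 1L
      if (phase == 1L && cur == target) phase <- 2L
      else if (phase == 2L && cur == 1L) return(steps)
    }
  }
  sims <- replicate(20000, one_commute())
  # commute time = 2M * denominator = 2M / score
  expected <- 2 * net$m / score
  expect_lt(abs(mean(sims) - expected), 3 * sd(sims) / sqrt(length(sims)))
})

test_that("all twelve indices match independent brute-force oracles on random graphs", {
  pr <- index_params()
  for (seed in 1:6) {
    n <- 5L + (seed * 4L) %% 26L
    net <- rand_er(n, 0.3, seed + 100L)
    A <- oracle_adj(net)
    sims <- compute_all_indices(net, pr)
    idx_pairs <- which(upper.tri(A), arr.ind = TRUE)
    take <- idx_pairs[seq_len(min(40L, nrow(idx_pairs))), , drop = FALSE]
    for (r in seq_len(nrow(take))) {
      i <- take[r, 1L]; j <- take[r, 2L]
      expect_identical(sims$CN[i, j], as.numeric(oracle_cn(A, i, j)))
      expect_identical(sims$PA[i, j], oracle_pa(A, i, j))
      expect_equal(sims$AA[i, j], oracle_aa(A, i, j), tolerance = 1e-12)
      expect_equal(sims$LHN[i, j], oracle_lhn(A, i, j), tolerance = 1e-12)
      expect_equal(sims$RA[i, j], oracle_ra(A, i, j), tolerance = 1e-12)
      expect_equal(sims$ACT[i, j], oracle_act(A, i, j), tolerance = 1e-8)
    }
    Mo <- oracle_mfi(A, pr$mfi_alpha); diag(Mo) <- 0
    expect_equal(unclass(sims$MFI), Mo, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unclass(sims$LP), oracle_lp(A, pr$lp_alpha),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unclass(sims$LRW), oracle_lrw(A, pr$walk_steps_t),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unclass(sims$SRW), oracle_srw(A, pr$walk_steps_t),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unclass(sims$RWR), oracle_rwr(A, pr$rwr_restart_c),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # SimRank's naive oracle is O(n^4) per sweep; check smaller graphs
  for (seed in 1:3) {
    net <- rand_er(8, 0.35, seed + 30L)
    A <- oracle_adj(net)
    s <- simrank(net, pr)
    so <- oracle_simrank(A, pr$simrank_decay_C, pr$simrank_tol,
                         pr$simrank_max_iter)
    expect_equal(unclass(s), (so + t(so)) / 2, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("pairwise and matrix implementations of local indices agree exactly", {
  pr <- index_params()
  for (seed in 1:4) {
    net <- rand_er(12, 0.3, seed + 50L)
    sims <- compute_all_indices(net, pr)
    pairs <- which(upper.tri(diag(net$n)), arr.ind = TRUE)
    for (r in sample.int(nrow(pairs), 20L)) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      expect_identical(sims$CN[i, j], as.numeric(cn(net, i, j)))
      expect_identical(sims$PA[i, j], as.numeric(pa(net, i, j)))
      expect_equal(sims$AA[i, j], aa(net, i, j, pr), tolerance = 1e-12)
      expect_equal(sims$LHN[i, j], lhn(net, i, j), tolerance = 1e-12)
      expect_equal(sims$RA[i, j], ra(net, i, j), tolerance = 1e-12)
      expect_equal(sims$ACT[i, j], act(net, i, j, pr), tolerance = 1e-10)
    }
  }
})

test_that("all indices are symmetric and equivariant under node relabeling", {
  pr <- index_params()
  for (seed in 1:3) {
    net <- rand_er(15, 0.25, seed + 70L)
    sims <- compute_all_indices(net, pr)
    expect_identical(names(sims), index_names())
    for (S in sims) {
      expect_lt(max(abs(S - t(S))), 1e-10)
      expect_true(all(is.finite(S)))
    }
    for (nm in c("CN", "PA", "AA", "LHN", "RA", "LP")) {
      expect_true(all(sims[[nm]] >= 0))
    }
    expect_true(all(sims$SimRank >= 0 & sims$SimRank <= 1))
    # permute the nodes and compare
    set.seed(seed)
    perm <- sample.int(net$n)
    pedges <- cbind(perm[net$edges[, 1L]], perm[net$edges[, 2L]])
    pnet <- linknet(pedges, n_nodes = net$n)
    psims <- compute_all_indices(pnet, pr)
    for (nm in index_names()) {
      expect_equal(unclass(psims[[nm]])[perm, perm][1:net$n, 1:net$n],
                   unclass(sims[[nm]]), tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("pairs involving isolated nodes score zero everywhere", {
  net <- linknet(rbind(c(1L, 2L), c(2L, 3L)), n_nodes = 5L)
  sims <- compute_all_indices(net)
  for (nm in index_names()) {
    expect_equal(sims[[nm]][4, 5], 0)
    expect_equal(sims[[nm]][1, 4], 0)
  }
})

test_that("index parameter validation rejects out-of-range values", {
  expect_error(index_params(rwr_restart_c = 1), "\\(0,1\\)")
  expect_error(index_params(mfi_alpha = 0), "> 0")
  expect_error(index_params(walk_steps_t = 0), ">= 1")
  expect_error(index_params(simrank_decay_C = 0), "\\(0,1\\)")
})
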