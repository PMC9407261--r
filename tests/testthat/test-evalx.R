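test_that("confusion counts are exact", {
  cts <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cts)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0L)
  all_pos <- confusion(rep(c(1, 0), 5), rep(1, 10))
  expect_equal(unclass(all_pos)[c("TP", "FP", "FN", "TN")],
               list(TP = 5L, FP = 5L, FN = 0L, TN = 0L))
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("rank-form AUC equals brute-force concordance with midrank ties", {
  # hand example: positive scores (.8,.4), negative (.6,.2)
  expect_equal(auc_rank(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_rank(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  set.seed(42)
  for (case in 1:200) {
    n <- sample(6:30, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc_rank(c(1, 2), c(1, 1)), "both classes")
})

test_that("metric reports follow the confusion-count formulas", {
  labels <- c(rep(1, 10), rep(0, 10))
  preds <- c(rep(1, 8), 0, 0, rep(0, 8), 1, 1)
  scores <- ifelse(preds == 1, 0.9, 0.1)
  m <- link_metrics(labels, preds, scores)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  # degenerate: nothing predicted positive -> precision 0 with warning, F1 0
  expect_warning(m0 <- link_metrics(labels, rep(0, 20), scores), "denominator")
  expect_equal(m0$precision, 0)
  expect_equal(m0$f1, 0)
})

test_that("similarity baselines rank constant matrices at chance", {
  net <- rand_er(20, 0.3, 2)
  test <- data.frame(i = c(1L, 2L, 3L, 4L), j = c(5L, 6L, 7L, 8L),
                     label = c(1L, 1L, 0L, 0L))
  const <- matrix(1, 20, 20)
  m <- similarity_baseline(const, test)
  expect_equal(m$auc, 0.5)
  # a planted SBM scores within-block pairs above cross-block pairs
  sbm <- small_sbm(6)
  ds <- build_balanced_dataset(sbm, split_config(seed = 6))
  sims <- compute_all_indices(ds$training_graph)
  mb <- similarity_baseline(sims$CN, ds$test)
  expect_gt(mb$auc, 0.5)
  expect_identical(similarity_baseline(sims$CN, ds$test)$auc, mb$auc)
})

test_that("matching scores count recovered top-ranked edges", {
  n <- 10L
  pool <- which(upper.tri(diag(n)), arr.ind = TRUE)
  observed <- pool[1:4, ]
  sim_perfect <- matrix(0, n, n)
  sim_perfect[observed] <- 1
  sim_perfect <- sim_perfect + t(sim_perfect)
  expect_equal(matching_score(sim_perfect, observed, pool), 1)
  # 3 of the top-4 observed
  sim_3of4 <- sim_perfect
  sim_3of4[observed[4, 1], observed[4, 2]] <- 0
  sim_3of4[observed[4, 2], observed[4, 1]] <- 0
  other <- pool[10, ]
  sim_3of4[other[1], other[2]] <- sim_3of4[other[2], other[1]] <- 2
  expect_equal(matching_score(sim_3of4, observed, pool), 0.75)
  expect_error(matching_score(sim_perfect, rbind(c(1L, 1L) + 20L), pool),
               "subset")
  # random scores: expected sigma ~ |E|/|pool|
  set.seed(3)
  sigmas <- replicate(1000, {
    r <- matrix(0, n, n)
    vals <- runif(nrow(pool))
    r[pool] <- vals; r <- r + t(r)
    matching_score(r, observed, pool)
  })
  expect_lt(abs(mean(sigmas) - 4 / nrow(pool)), 3 * sd(sigmas) / sqrt(1000))
  # invariance under strictly monotone transforms
  set.seed(4)
  r <- matrix(0, n, n); r[pool] <- runif(nrow(pool)); r <- r + t(r)
  expect_equal(matching_score(r, observed, pool),
               matching_score(exp(3 * r), observed, pool))
})

test_that("delta sigma is the antisymmetric difference of matching scores", {
  n <- 10L
  pool <- which(upper.tri(diag(n)), arr.ind = TRUE)
  observed <- pool[1:4, ]
  set.seed(5)
  a <- matrix(0, n, n); a[pool] <- runif(nrow(pool)); a <- a + t(a)
  b <- matrix(0, n, n); b[pool] <- runif(nrow(pool)); b <- b + t(b)
  expect_equal(delta_sigma(a, a, observed, pool), 0)
  expect_equal(delta_sigma(a, b, observed, pool),
               -delta_sigma(b, a, observed, pool))
  expect_equal(delta_sigma(a, b, observed, pool),
               matching_score(a, observed, pool) -
                 matching_score(b, observed, pool))
})

test_that("run aggregation reports means and dispersions inside the run range", {
  mk <- function(acc) {
    link_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0),
                 scores = c(0.9, 0.8, 0.2, 0.1))
  }
  r1 <- mk(); r2 <- mk()
  agg_same <- aggregate_runs(list(r1, r2))
  expect_equal(unname(agg_same$sd["auc"]), 0)
  r2$accuracy <- 0.9; r1$accuracy <- 1.0
  agg <- aggregate_runs(list(r1, r2))
  expect_equal(unname(agg$mean["accuracy"]), 0.95)
  expect_true(all(agg$mean >= apply(agg$values, 2, min) - 1e-12 &
                    agg$mean <= apply(agg$values, 2, max) + 1e-12))
})

test_that("the two-stage comparison follows the F-test then t-test recipe", {
  same <- c(0.9, 0.91, 0.89, 0.9)
  res <- compare_methods(same, same)
  expect_equal(res$t_test_p, 1, tolerance = 1e-9)
  expect_true(res$ci95_mean_difference[1] <= 0 &&
                res$ci95_mean_difference[2] >= 0)

  a <- c(0, 0, 0, 0); b <- c(1, 1, 1, 1) + c(1e-9, -1e-9, 1e-9, -1e-9)
  res2 <- compare_methods(a, b)
  expect_lt(res2$t_test_p, 1e-6)
  expect_true(all(res2$ci95_mean_difference < 0))

  # degenerate zero-variance identical samples
  res3 <- compare_methods(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res3$t_test_p, 1)
  expect_equal(res3$ci95_mean_difference, c(0, 0))

  # the variant switches to Welch exactly when the F-test rejects
  set.seed(6)
  x <- rnorm(20, sd = 1); y <- rnorm(20, sd = 6)
  res4 <- compare_methods(x, y)
  expect_lt(res4$f_test_p, 0.05)
  expect_equal(res4$t_test_variant, "welch")
  res5 <- compare_methods(rnorm(20), rnorm(20))
  expect_equal(res5$t_test_variant,
               if (res5$f_test_p < 0.05) "welch" else "equal_variance")

  # F-test p matches a variance-ratio permutation oracle within MC error
  set.seed(7)
  x <- rnorm(12, sd = 1); y <- rnorm(12, sd = 2)
  fp <- compare_methods(x, y)$f_test_p
  pooled <- c(x, y)
  stat <- function(xx, yy) max(var(xx) / var(yy), var(yy) / var(xx))
  obs <- stat(x, y)
  perm <- replicate(10000, {
    idx <- sample(24, 12)
    stat(pooled[idx], pooled[-idx])
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(fp - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.02)
})

test_that("metrics serialise to JSON with all fields", {
  m <- link_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  js <- jsonlite::fromJSON(metrics_to_json(m))
  expect_equal(js$auc, 1)
  expect_equal(js$counts$TP, 2)
  agg <- aggregate_runs(list(m, m))
  js2 <- jsonlite::fromJSON(metrics_to_json(agg))
  expect_equal(js2$mean$accuracy, 1)
})
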