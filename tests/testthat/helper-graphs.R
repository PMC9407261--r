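# Small fixture graphs, built in code. Node indices are 1-based.

k2 <- function() linknet(rbind(c(1L, 2L)))

path_graph <- function(n) {
  linknet(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

cycle_graph <- function(n) {
  linknet(rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), c(n, 1L)))
}

star_graph <- function(n_leaves) {
  linknet(cbind(rep(1L, n_leaves), seq_len(n_leaves) + 1L))
}

triangle <- function() cycle_graph(3L)

rand_er <- function(n, p, seed) {
  generate_synthetic(synthetic_spec("erdos_renyi", n, seed = seed, p = p))
}

small_sbm <- function(seed, block = 50L, p_in = 0.3, p_out = 0.02) {
  generate_synthetic(synthetic_spec("stochastic_block", seed = seed,
                                    block_sizes = c(block, block),
                                    p_within = p_in, p_between = p_out))
}

# a feature table with a planted label-copy feature among noise columns
planted_table <- function(n_rows = 300L, n_noise = 11L, seed = 1L,
                          signal_name = "signal") {
  set.seed(seed)
  label <- rep(c(0L, 1L), length.out = n_rows)
  df <- as.data.frame(matrix(rnorm(n_rows * n_noise), n_rows,
                             dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  df[[signal_name]] <- as.numeric(label)
  df$label <- label
  df <- df[, c(signal_name, paste0("noise", seq_len(n_noise)), "label")]
  structure(df, feature_names = setdiff(names(df), "label"),
            class = c("feature_table", "data.frame"))
}

noise_table <- function(n_rows = 200L, n_feats = 12L, seed = 1L) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n_rows * n_feats), n_rows,
                             dimnames = list(NULL, paste0("f", seq_len(n_feats)))))
  df$label <- rep(c(0L, 1L), length.out = n_rows)
  structure(df, feature_names = setdiff(names(df), "label"),
            class = c("feature_table", "data.frame"))
}
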