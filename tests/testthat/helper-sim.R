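# Shared builders for small synthetic instances used across test files.

# Minimal cohort config: one planted up-pathway + background genes.
small_pathway_config <- function(seed = 1, n_per_group = 40, effect = 1.5,
                                 n_genes = 40, n_null_sets = 10) {
  simulation_config(
    n_genes = n_genes, n_tfs = 5, n_per_group = n_per_group,
    de_fraction = 0, noise_sd = 1,
    pathways = list(list(name = "pw_up", genes = 1:6, direction = "up",
                         effect = effect)),
    n_null_sets = n_null_sets, seed = seed)
}

# Tiny expression matrix with two groups for DE unit tests.
toy_two_group <- function(n_genes = 10, n_per_group = 5, delta = NULL,
                          seed = 1, sd = 1) {
  set.seed(seed)
  groups <- rep(c("TNBC", "non-TNBC", "normal"), each = n_per_group)
  ids <- sprintf("S%02d", seq_along(groups))
  vals <- matrix(rnorm(n_genes * length(ids), mean = 5, sd = sd),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes), ids))
  if (!is.null(delta)) {
    vals[seq_along(delta), groups == "TNBC"] <-
      vals[seq_along(delta), groups == "TNBC"] + delta
  }
  list(expr = expression_matrix(vals, "toy"),
       samples = sample_table(ids, groups, "toy"))
}

# Independent pooled two-sample t oracle (no shrinkage).
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# Exact hypergeometric upper tail by direct combinatorial sum.
ora_oracle <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Exact two-sided rank-sum null by full enumeration of member subsets.
ranksum_oracle <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  m <- length(x)
  W_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(all_v), m)
  W_null <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean_W <- m * length(y) / 2
  mean(abs(W_null - mean_W) >= abs(W_obs - mean_W) - 1e-9)
}

fixture_path <- function(file) system.file("extdata", file, package = "glycoreg")
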