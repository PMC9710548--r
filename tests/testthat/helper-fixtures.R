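# Small in-code fixtures shared across test files.

make_counts <- function(values, modality = "RNA",
                        feature_ids = sprintf("G%d", seq_len(nrow(values))),
                        cell_ids = sprintf("c%d", seq_len(ncol(values)))) {
  count_matrix(values, feature_ids = feature_ids, cell_ids = cell_ids,
               modality = modality)
}

# Independent O(n^2) oracle for the one-dimensional two-cluster problem:
# evaluate the within-cluster sum of squares of every sorted split point
# by direct summation and return the minimizing high-cluster size.
brute_force_two_means <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf
  best_k <- NA_integer_
  for (k in 1:(n - 1)) {
    if (v[k] == v[k + 1]) next
    left <- v[1:k]
    right <- v[(k + 1):n]
    ss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (ss < best - 1e-12) {
      best <- ss
      best_k <- k
    }
  }
  list(wss = best, n_high = n - best_k)
}

# Exhaustive rank-sum null: two-sided p-value for a two-group comparison
# by enumerating every assignment of the pooled ranks to group 1.
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  null_sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(null_sums)
  mean(abs(null_sums - mu) >= abs(obs - mu) - 1e-9)
}

# Tiny deterministic z-scored matrix for scoring tests.
random_norm_matrix <- function(n_genes, n_cells, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
              dimnames = list(sprintf("G%d", seq_len(n_genes)),
                              sprintf("c%d", seq_len(n_cells))))
  normalized_matrix(v, normalization = "lognorm")
}
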