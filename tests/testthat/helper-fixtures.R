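# Small parameter sets and independent oracles shared across test files.

tiny_params <- function(seed = 1L, n_cells = 200L, fold_change = 8,
                        proportions = c(0.1, 0.2, 0.2, 0.2, 0.3), ...) {
  simulation_params(n_cells = n_cells, proportions = proportions,
                    n_genes = 1000L, n_markers_per_type = 20L,
                    fold_change = fold_change, seed = seed, ...)
}

# Two well-separated Gaussian blobs in 2-D; returns embedding + membership.
two_blobs <- function(n_per = 10L, sep = 10, seed = 42L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(2 * n_per), ncol = 2),
             matrix(stats::rnorm(2 * n_per, mean = sep), ncol = 2))
  list(x = x, membership = rep(1:2, each = n_per))
}

# From-scratch plurality scorer: loops over cells directly, no contingency
# matrix, no code shared with evaluate_clustering().
brute_score <- function(truth, pred) {
  types <- sort(unique(truth))
  clus <- sort(unique(pred))
  map <- vapply(clus, function(cl) {
    cnt <- vapply(types, function(k) sum(truth == k & pred == cl), numeric(1))
    types[which.max(cnt)]
  }, numeric(1))
  f1s <- vapply(types, function(k) {
    inc <- pred %in% clus[map == k]
    tp <- sum(inc & truth == k)
    fp <- sum(inc & truth != k)
    fn <- sum(!inc & truth == k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  sizes <- vapply(types, function(k) sum(truth == k), numeric(1))
  list(per_type = f1s, macro = mean(f1s), rare = f1s[which.min(sizes)])
}

# Group-vs-rest mean-expression ratio on library-size-normalized counts for
# an arbitrary gene set, used by the null-injection test.
group_rest_ratio <- function(dataset, genes, type, min_rest_mean = 0.1) {
  counts <- as.matrix(dataset$counts)
  norm <- t(t(counts) / pmax(colSums(counts), 1)) * 1e4
  ing <- dataset$true_labels == type
  grp <- rowMeans(norm[genes, ing, drop = FALSE])
  rest <- rowMeans(norm[genes, !ing, drop = FALSE])
  keep <- rest >= min_rest_mean
  grp[keep] / rest[keep]
}

# TRUE when two partitions are identical up to relabeling of cluster ids.
same_partition <- function(a, b) {
  ct <- table(a, b)
  all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
}
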