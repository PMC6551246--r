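#' Shared preprocessing: normalize, select, embed
#'
#' The standard scRNA-seq reduction applied before every clustering backend,
#' so that comparisons isolate the clustering step itself: per-cell
#' total-count normalization to `scale_factor`, `log1p` transform, selection
#' of the `n_hvg` most highly variable genes, per-gene standardization
#' (clipped at +/- 10 standard deviations), and principal-component
#' projection.
#'
#' Variable genes are ranked by their variance relative to a smooth
#' mean-variance trend (a loess fit of per-gene variance against per-gene
#' mean of the log-normalized values), not by raw variance: raw variance is
#' dominated by the sampling-noise profile of highly expressed genes,
#' whereas the trend ratio surfaces genes that vary more than expected at
#' their expression level — which is where between-type signal lives. When
#' too few genes are available to fit a stable trend the ranking falls back
#' to raw variance.
#'
#' @param counts genes x cells count matrix (dense or sparse), or a
#'   `labeled_counts` object.
#' @param n_hvg number of highly variable genes to keep (default 1000).
#' @param n_pcs number of principal components (default 50; capped at
#'   `n_cells - 1` and at the number of retained genes).
#' @param scale_factor per-cell normalization target.
#' @return `n_cells x d` embedding matrix with cell ids as row names.
#' @examples
#' p <- simulation_params(n_cells = 60, proportions = c(0.5, 0.5),
#'                        n_genes = 300, n_markers_per_type = 20,
#'                        fold_change = 8, seed = 1)
#' emb <- preprocess(generate_dataset(p), n_hvg = 100, n_pcs = 10)
#' dim(emb)
#' @export
preprocess <- function(counts, n_hvg = 1000L, n_pcs = 50L,
                       scale_factor = 1e4) {
  if (inherits(counts, "labeled_counts")) counts <- counts$counts
  if (ncol(counts) < 2L) stop("need at least 2 cells")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[which(totals == 0)[1]]
    if (is.null(bad)) bad <- as.character(which(totals == 0)[1])
    stop(sprintf("all-zero cell: %s", bad))
  }
  norm <- log1p(t(t(as.matrix(counts)) / totals) * scale_factor)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  ok <- v > 0
  score <- v
  if (sum(ok) >= 50L) {
    fit <- stats::loess(v[ok] ~ mu[ok], span = 0.3, degree = 2)
    score <- rep(-Inf, length(v))
    score[ok] <- v[ok] / pmax(stats::predict(fit), 1e-8)
  }
  keep <- order(score, decreasing = TRUE)[seq_len(min(n_hvg, nrow(norm)))]
  x <- t(norm[keep, , drop = FALSE])          # cells x genes
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0      # constant genes carry no signal
  attr(x, "scaled:center") <- NULL            # leftover attrs confuse prcomp
  attr(x, "scaled:scale") <- NULL
  x[x > 10] <- 10
  x[x < -10] <- -10
  d <- min(n_pcs, ncol(x), nrow(x) - 1L)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = d)
  emb <- pc$x
  # fix the SVD sign ambiguity: largest-magnitude loading positive
  for (j in seq_len(ncol(emb))) {
    piv <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[piv, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- colnames(counts)
  emb
}

#' Construct a cluster assignment object
#'
#' @param labels integer cluster id per cell.
#' @param backend_name short backend identifier.
#' @param settings named list of the settings used (k, seed, ...).
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, backend_name, settings = list()) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty assignment")
  structure(list(labels = labels, backend_name = backend_name,
                 settings = settings),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment [%s]: %d cells, %d clusters\n",
              x$backend_name, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' K-means clustering backend
#'
#' Lloyd-style k-means on the embedding with multiple random restarts (best
#' within-cluster sum of squares kept). Deterministic given the seed. `k` is
#' set to the number of simulated cell types in reproduction runs.
#'
#' @param embedding cells x d numeric matrix from [preprocess()].
#' @param k number of clusters, `1 <= k <= n_cells`.
#' @param seed integer RNG seed.
#' @param nstart number of random restarts (default 10).
#' @return A `cluster_assignment`.
#' @export
cluster_kmeans <- function(embedding, k, seed = 1L, nstart = 10L) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(embedding)) stop("k cannot exceed the number of cells")
  labels <- if (k == nrow(embedding)) seq_len(k)  # every cell its own cluster
  else with_seed(seed, stats::kmeans(embedding, centers = k,
                                     nstart = nstart,
                                     iter.max = 100L))$cluster
  cluster_assignment(labels, "kmeans",
                     list(k = k, seed = seed, nstart = nstart))
}

# k-nearest-neighbor index matrix (self excluded), ties broken by cell index
knn_index <- function(embedding, k) {
  d <- as.matrix(stats::dist(embedding))
  n <- nrow(d)
  t(vapply(seq_len(n), function(i) order(d[i, ])[2:(k + 1L)], integer(k)))
}

# Jaccard-weighted shared-nearest-neighbor graph from a kNN index.
# Neighbor sets include the cell itself; edges below `prune` are dropped.
snn_graph <- function(nn, prune = 1 / 15) {
  n <- nrow(nn)
  k1 <- ncol(nn) + 1L                         # set size incl. self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k1),
                              j = c(seq_len(n), as.vector(nn)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- shared@x / (2 * k1 - shared@x)     # |A∩B| / |A∪B|
  jac@x[jac@x < prune] <- 0
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shared-nearest-neighbor Louvain backend
#'
#' Builds a k-nearest-neighbor graph on the embedding (`k = k_param`),
#' re-weights edges by the Jaccard overlap of the two cells' neighbor sets
#' (pruning weights below 1/15), and partitions the resulting
#' shared-nearest-neighbor graph by Louvain modularity optimization — the
#' graph-clustering recipe popularized by Seurat. Louvain does not take a
#' cluster count directly, so when the partition size differs from
#' `m_target` a bounded bisection on the resolution parameter steers it
#' toward `m_target`; the search is best-effort and the realized count is
#' recorded in `settings$n_clusters`.
#'
#' Reproduction runs follow the benchmarked configuration and set `k_param`
#' to the number of simulated cell types — an unusually small neighborhood
#' (Seurat's own default is 20); `k_param` is exposed so users can depart
#' from it.
#'
#' @param embedding cells x d numeric matrix.
#' @param k_param neighbors per cell for the kNN graph.
#' @param m_target desired number of clusters.
#' @param seed integer RNG seed (Louvain's greedy pass visits nodes in random
#'   order).
#' @param prune minimum retained Jaccard weight.
#' @param max_steps resolution bisection budget.
#' @return A `cluster_assignment`; `settings` records the resolution found.
#' @export
cluster_snn_louvain <- function(embedding, k_param = 5L, m_target = 5L,
                                seed = 1L, prune = 1 / 15, max_steps = 20L) {
  k_param <- as.integer(k_param)
  m_target <- as.integer(m_target)
  if (k_param < 1) stop("k_param must be >= 1")
  if (m_target < 1) stop("m_target must be >= 1")
  if (k_param >= nrow(embedding)) stop("k_param must be below the number of cells")
  g <- snn_graph(knn_index(embedding, k_param), prune)

  run <- function(res) {
    memb <- with_seed(seed, igraph::membership(
      igraph::cluster_louvain(g, resolution = res)))
    as.integer(memb)
  }
  lo <- 0.05; hi <- 8
  res <- 1
  best <- NULL
  for (step in seq_len(max_steps)) {
    lab <- run(res)
    nc <- length(unique(lab))
    if (is.null(best) || abs(nc - m_target) < abs(best$nc - m_target))
      best <- list(lab = lab, nc = nc, res = res)
    if (nc == m_target) break
    if (nc < m_target) lo <- res else hi <- res
    res <- (lo + hi) / 2
  }
  cluster_assignment(best$lab, "snn_louvain",
                     list(k_param = k_param, m_target = m_target,
                          resolution = best$res, n_clusters = best$nc,
                          prune = prune, seed = seed))
}

#' Multi-kernel spectral clustering backend
#'
#' A multiple-kernel similarity-learning analogue in the spirit of SIMLR:
#' Gaussian kernels over the cell-cell Euclidean distances are computed at
#' several global bandwidths (multiples of the median pairwise distance) and
#' several locally scaled bandwidths (mean distance to each cell's nearest
#' neighbors, at a bank of neighborhood fractions), averaged into a single
#' similarity matrix, sparsified to each cell's strongest `k_sparse`
#' similarities (symmetrized by union), and partitioned by normalized
#' spectral clustering into exactly `m_target` groups. The sparsification
#' step matters for rare populations: a small tight group keeps its
#' within-group similarities while its weak links to large clusters are
#' dropped, so it survives as its own connected structure in the similarity
#' graph. Kernel weights are uniform rather than learned; the eigenvector
#' sign is fixed by making the largest-magnitude entry positive, and the
#' final k-means step uses the given seed, so the procedure is
#' deterministic.
#'
#' @param embedding cells x d numeric matrix.
#' @param m_target number of clusters (>= 2).
#' @param seed integer RNG seed for the final k-means step.
#' @param bandwidth_mults multipliers of the median pairwise distance for
#'   the global kernels.
#' @param local_fracs fractions of cells defining the local-scaling
#'   neighborhood sizes.
#' @param k_sparse number of strongest similarities kept per cell (capped at
#'   `n - 1`).
#' @return A `cluster_assignment`.
#' @export
cluster_mk_spectral <- function(embedding, m_target = 5L, seed = 1L,
                                bandwidth_mults = c(0.5, 1, 2),
                                local_fracs = c(0.01, 0.02, 0.05),
                                k_sparse = 10L) {
  m_target <- as.integer(m_target)
  if (m_target < 2) stop("m_target must be >= 2")
  n <- nrow(embedding)
  if (m_target > n) stop("m_target cannot exceed the number of cells")
  d <- as.matrix(stats::dist(embedding))
  med <- stats::median(d[upper.tri(d)])
  if (!is.finite(med) || med == 0) stop("zero distance matrix")
  d2 <- d^2
  kern <- matrix(0, n, n)
  for (s in bandwidth_mults * med) kern <- kern + exp(-d2 / (2 * s^2))
  # locally scaled kernels (Zelnik-Manor/Perona style)
  for (f in local_fracs) {
    kloc <- max(2L, ceiling(f * n))
    sig <- apply(d, 1, function(r) mean(sort(r)[2:(kloc + 1L)]))
    sig[sig == 0] <- med
    kern <- kern + exp(-d2 / outer(sig, sig))
  }
  kern <- kern / (length(bandwidth_mults) + length(local_fracs))
  kern <- (kern + t(kern)) / 2
  ks <- min(k_sparse, n - 1L)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    keep[i, order(kern[i, ], decreasing = TRUE)[seq_len(ks + 1L)]] <- TRUE
  kern <- kern * (keep | t(keep))

  deg <- rowSums(kern)
  lap <- kern / sqrt(outer(deg, deg))
  ev <- eigen(lap, symmetric = TRUE)
  v <- ev$vectors[, seq_len(m_target), drop = FALSE]
  for (j in seq_len(ncol(v))) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  rn <- sqrt(rowSums(v^2))
  v <- v / pmax(rn, 1e-12)
  # Lloyd iterations: spectral coordinates hold many near-duplicate rows,
  # which trip Hartigan-Wong's quick-transfer stage. Random restarts alone
  # can still miss a small distant point cloud, so one farthest-first
  # initialization (greedy max-min, deterministic) competes with them and
  # the lowest within-cluster sum of squares wins.
  ff <- farthest_first_centers(v, m_target)
  fit_ff <- suppressWarnings(stats::kmeans(v, centers = ff, iter.max = 300L,
                                           algorithm = "Lloyd"))
  fit_rs <- with_seed(seed, suppressWarnings(
    stats::kmeans(v, centers = m_target, nstart = 10L,
                  iter.max = 300L, algorithm = "Lloyd")))
  fit <- if (fit_ff$tot.withinss <= fit_rs$tot.withinss) fit_ff else fit_rs
  cluster_assignment(fit$cluster, "mk_spectral",
                     list(m_target = m_target, seed = seed,
                          bandwidth_mults = bandwidth_mults,
                          local_fracs = local_fracs, k_sparse = ks))
}

# Greedy max-min (farthest-first) center selection: start from the point
# farthest from the grand centroid, then repeatedly add the point farthest
# from every chosen center. Deterministic; ties broken by row index.
farthest_first_centers <- function(x, k) {
  ctr <- colMeans(x)
  chosen <- which.max(rowSums(sweep(x, 2, ctr)^2))
  mind <- rowSums(sweep(x, 2, x[chosen, ])^2)
  while (length(chosen) < k) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, rowSums(sweep(x, 2, x[nxt, ])^2))
  }
  x[chosen, , drop = FALSE]
}

# ---- backend registry -------------------------------------------------------

.backends <- new.env(parent = emptyenv())

#' Register a clustering backend
#'
#' A backend is any function `(embedding, m_target, seed, ...)` returning a
#' [cluster_assignment()]. Registering under an existing name replaces the
#' previous backend, which is how the bundled analogues can be swapped for
#' external implementations (e.g. actual Seurat or SIMLR wrappers).
#'
#' @param name backend identifier used in grid specs and on the command line.
#' @param fun the backend function.
#' @export
register_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .backends)
  invisible(name)
}

#' Resolve a registered backend
#'
#' @param name backend identifier.
#' @return The backend function; unknown names are an error.
#' @export
get_backend <- function(name) {
  if (!exists(name, envir = .backends, inherits = FALSE))
    stop(sprintf("unknown backend '%s'; registered: %s", name,
                 paste(list_backends(), collapse = ", ")))
  get(name, envir = .backends, inherits = FALSE)
}

#' List registered backend names
#' @return Character vector of registered names, sorted.
#' @export
list_backends <- function() sort(ls(.backends))

register_default_backends <- function() {
  register_backend("kmeans", function(embedding, m_target, seed, ...)
    cluster_kmeans(embedding, k = m_target, seed = seed, ...))
  register_backend("snn_louvain", function(embedding, m_target, seed, ...)
    cluster_snn_louvain(embedding, k_param = m_target, m_target = m_target,
                        seed = seed, ...))
  register_backend("mk_spectral", function(embedding, m_target, seed, ...)
    cluster_mk_spectral(embedding, m_target = m_target, seed = seed, ...))
}

.onLoad <- function(libname, pkgname) register_default_backends()
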