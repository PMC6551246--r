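#' Deterministically apportion cells to types
#'
#' Largest-remainder apportionment of `n_cells` across the type proportions:
#' each type first receives `floor(n_cells * p)` cells, then the leftover
#' seats go to the types with the largest fractional remainders, ties broken
#' in favour of the lower type index. No randomness is involved, so group
#' sizes are exactly reproducible design targets rather than a multinomial
#' draw.
#'
#' @param proportions strictly positive fractions summing to 1 (length >= 2).
#' @param n_cells total number of cells to distribute.
#' @return Integer vector of per-type cell counts summing to `n_cells`.
#' @examples
#' allocate_cells(c(0.1, 0.2, 0.2, 0.2, 0.3), 1000)
#' @export
allocate_cells <- function(proportions, n_cells) {
  proportions <- as.numeric(proportions)
  m <- length(proportions)
  if (m < 2L) stop("at least two cell types are required")
  if (any(proportions <= 0)) stop("proportions must all be > 0")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  n_cells <- as.integer(n_cells)
  if (n_cells < m) stop("n_cells too small for rarest proportion")
  quota <- proportions * n_cells
  counts <- floor(quota)
  left <- n_cells - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    # order() is stable: ties go to the lower type index
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  counts <- as.integer(counts)
  if (any(counts == 0L)) stop("n_cells too small for rarest proportion")
  counts
}

#' Draw baseline mean expression per gene
#'
#' Step one of the simulator: i.i.d. gamma draws give each gene a strictly
#' positive baseline mean, reproducing the skewed mean-expression profile of
#' real scRNA-seq data (many weakly expressed genes, few strong ones).
#'
#' @param n_genes number of genes.
#' @param mean_shape,mean_rate gamma shape and rate; the distribution mean is
#'   `mean_shape / mean_rate`.
#' @return Numeric vector of length `n_genes`, all entries > 0.
#' @export
simulate_gene_means <- function(n_genes, mean_shape = 0.6, mean_rate = 0.3) {
  stopifnot(mean_shape > 0, mean_rate > 0, n_genes >= 1)
  stats::rgamma(n_genes, shape = mean_shape, rate = mean_rate)
}

#' Sample marker fold-change factors
#'
#' One multiplicative factor per (marker gene, cell type) pair, drawn from a
#' gamma distribution with shape `fold_change` and rate 1, so the expected
#' factor equals the target fold change. With `truncate_below_one = TRUE`
#' draws below 1 are rejected and redrawn (bounded retries), guaranteeing
#' every marker is upregulated in its own type; this raises the realized
#' mean factor above `fold_change`, most noticeably at `fold_change = 2`.
#'
#' @param n number of factors to draw.
#' @param fold_change target fold change, `>= 1`.
#' @param truncate_below_one reject draws `< 1`?
#' @param max_tries retry budget per rejected draw.
#' @return Numeric vector of positive factors (all `>= 1` when truncated).
#' @export
sample_fold_change <- function(n, fold_change, truncate_below_one = TRUE,
                               max_tries = 1000L) {
  stopifnot(fold_change >= 1, n >= 0)
  x <- stats::rgamma(n, shape = fold_change, rate = 1)
  if (truncate_below_one) {
    tries <- 0L
    while (any(bad <- x < 1)) {
      tries <- tries + 1L
      if (tries > max_tries) stop("fold-change truncation retry limit exceeded")
      x[bad] <- stats::rgamma(sum(bad), shape = fold_change, rate = 1)
    }
  }
  x
}

#' Build the per-type mean-expression matrix
#'
#' Starts from one shared baseline mean per gene and, for each cell type,
#' multiplies the means of that type's marker genes by freshly drawn
#' fold-change factors. Because the other types keep the baseline for those
#' genes, the baseline is exactly the marker's mean in all cells outside the
#' type, so the factor is the group-vs-rest fold change by construction.
#'
#' @param base_means positive baseline means, length `n_genes`.
#' @param marker_map list mapping type index -> integer vector of marker gene
#'   indices; sets must be pairwise disjoint.
#' @param fold_change target fold change passed to [sample_fold_change()].
#' @param truncate_below_one see [sample_fold_change()].
#' @return `n_genes x m` matrix of per-type means.
#' @export
inject_marker_means <- function(base_means, marker_map, fold_change,
                                truncate_below_one = TRUE) {
  stopifnot(all(base_means > 0))
  m <- length(marker_map)
  all_idx <- unlist(marker_map, use.names = FALSE)
  if (length(all_idx) > 0) {
    if (any(all_idx < 1 | all_idx > length(base_means)))
      stop("marker index out of range")
    if (anyDuplicated(all_idx)) stop("marker sets must be pairwise disjoint")
  }
  means <- matrix(base_means, nrow = length(base_means), ncol = m)
  for (k in seq_len(m)) {
    idx <- marker_map[[k]]
    fac <- sample_fold_change(length(idx), fold_change, truncate_below_one)
    means[idx, k] <- means[idx, k] * fac
  }
  means
}

#' Draw expected library sizes per cell
#'
#' Log-normal expected total counts per cell; the median is
#' `exp(libsize_location)`. Each cell's expected gene counts are later scaled
#' so that they sum to its library size.
#'
#' @param n_cells number of cells.
#' @param libsize_location,libsize_scale log-normal location and scale.
#' @return Numeric vector of strictly positive expected totals.
#' @export
simulate_library_sizes <- function(n_cells, libsize_location = log(20000),
                                   libsize_scale = 0.2) {
  stopifnot(libsize_scale > 0, n_cells >= 1)
  stats::rlnorm(n_cells, meanlog = libsize_location, sdlog = libsize_scale)
}

#' Sample the count matrix from per-type means
#'
#' For cell `j` of type `k`, gene `i` gets a Poisson rate
#' `lambda_ij = mean_k(i) * L_j / sum_i mean_k(i)`, so the expected column
#' sum is exactly the library size `L_j`. With `bcv_dispersion > 0` the rate
#' is first multiplied by a unit-mean gamma variate with variance
#' `bcv_dispersion` (biological noise, giving gamma-Poisson overdispersion);
#' optional logistic dropout then zeroes entries with probability decreasing
#' in the log rate (technical noise).
#'
#' @param type_means `n_genes x m` matrix of per-type means.
#' @param library_sizes expected total counts per cell, length `n_cells`.
#' @param type_of_cell integer type index per cell, values in `1..m`.
#' @param bcv_dispersion squared biological coefficient of variation (>= 0).
#' @param dropout_midpoint,dropout_shape logistic dropout parameters, both
#'   `NULL` to disable: the dropout probability for an entry with rate
#'   `lambda` is `plogis(dropout_shape * (dropout_midpoint - log(lambda)))`.
#' @return Sparse integer count matrix (`dgCMatrix`), genes x cells.
#' @export
simulate_counts <- function(type_means, library_sizes, type_of_cell,
                            bcv_dispersion = 0,
                            dropout_midpoint = NULL, dropout_shape = NULL) {
  stopifnot(is.matrix(type_means), bcv_dispersion >= 0,
            length(library_sizes) == length(type_of_cell),
            all(type_of_cell >= 1), all(type_of_cell <= ncol(type_means)))
  n_genes <- nrow(type_means)
  n_cells <- length(type_of_cell)
  totals <- colSums(type_means)
  counts <- matrix(0L, nrow = n_genes, ncol = n_cells)
  for (k in seq_len(ncol(type_means))) {
    cols <- which(type_of_cell == k)
    if (length(cols) == 0L) next
    lam <- outer(type_means[, k] / totals[k], library_sizes[cols])
    if (bcv_dispersion > 0) {
      shp <- 1 / bcv_dispersion
      lam <- lam * stats::rgamma(length(lam), shape = shp, rate = shp)
    }
    if (any(!is.finite(lam))) stop("non-finite Poisson rate")
    x <- stats::rpois(length(lam), lam)
    if (!is.null(dropout_midpoint)) {
      pdrop <- stats::plogis(dropout_shape * (dropout_midpoint - log(pmax(lam, 1e-300))))
      x[stats::runif(length(x)) < pdrop] <- 0L
    }
    counts[, cols] <- x
  }
  Matrix::Matrix(counts, sparse = TRUE)
}

#' Generate a labeled simulated scRNA-seq dataset
#'
#' Runs the full simulation pipeline: deterministic cell allocation, gamma
#' baseline gene means, random disjoint marker selection, fold-change
#' injection, log-normal library sizes, and gamma-Poisson count sampling.
#' The output is fully determined by `params` (including its seed): repeated
#' calls return bit-identical matrices. Each pipeline stage consumes its own
#' named RNG substream derived from the master seed, so changing one stage's
#' parameters never perturbs another stage's draws.
#'
#' @param params a [simulation_params()] object.
#' @return An object of class `labeled_counts` with fields `counts` (sparse
#'   genes x cells integer matrix), `gene_ids`, `cell_ids`, `true_labels`
#'   (type index per cell), `marker_map` (type -> marker gene indices), and
#'   `params`.
#' @examples
#' p <- simulation_params(n_cells = 60, proportions = c(0.5, 0.5),
#'                        n_genes = 200, n_markers_per_type = 10,
#'                        fold_change = 4, seed = 7)
#' d <- generate_dataset(p)
#' dim(d$counts)
#' table(d$true_labels)
#' @export
generate_dataset <- function(params) {
  validate_params(params)
  m <- length(params$proportions)
  sizes <- allocate_cells(params$proportions, params$n_cells)
  type_of_cell <- rep(seq_len(m), sizes)

  base_means <- with_seed(substream_seed(params$seed, "means"),
                          simulate_gene_means(params$n_genes,
                                              params$mean_shape,
                                              params$mean_rate))

  marker_idx <- with_seed(substream_seed(params$seed, "markers"),
                          sample.int(params$n_genes,
                                     m * params$n_markers_per_type))
  marker_map <- split(marker_idx,
                      rep(seq_len(m), each = params$n_markers_per_type))
  names(marker_map) <- as.character(seq_len(m))

  type_means <- with_seed(substream_seed(params$seed, "foldchange"),
                          inject_marker_means(base_means, marker_map,
                                              params$fold_change,
                                              params$truncate_fc_below_one))

  lib_sizes <- with_seed(substream_seed(params$seed, "libsize"),
                         simulate_library_sizes(params$n_cells,
                                                params$libsize_location,
                                                params$libsize_scale))

  counts <- with_seed(substream_seed(params$seed, "counts"),
                      simulate_counts(type_means, lib_sizes, type_of_cell,
                                      params$bcv_dispersion,
                                      params$dropout_midpoint,
                                      params$dropout_shape))

  gene_ids <- sprintf("gene%0*d", nchar(params$n_genes), seq_len(params$n_genes))
  cell_ids <- sprintf("cell%0*d", nchar(params$n_cells), seq_len(params$n_cells))
  dimnames(counts) <- list(gene_ids, cell_ids)

  labeled_counts(counts, gene_ids, cell_ids, type_of_cell, marker_map, params)
}

#' Construct a labeled count matrix object
#'
#' Container for a genes x cells count matrix plus ground-truth cell-type
#' labels and marker annotation. Usually produced by [generate_dataset()] or
#' [read_bundle()] rather than called directly.
#'
#' @param counts non-negative integer matrix (dense or sparse), genes x cells.
#' @param gene_ids,cell_ids unique identifier vectors matching the dims.
#' @param true_labels integer type index per cell (values `1..m`).
#' @param marker_map list of disjoint marker gene index vectors per type
#'   (may be empty for external data).
#' @param params the `simulation_params` that produced the data, or `NULL`.
#' @return An object of class `labeled_counts`.
#' @export
labeled_counts <- function(counts, gene_ids, cell_ids, true_labels,
                           marker_map = list(), params = NULL) {
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids))
    stop("counts dimensions do not match id vectors")
  if (length(true_labels) != length(cell_ids))
    stop("true_labels length does not match number of cells")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  true_labels <- as.integer(true_labels)
  m <- max(true_labels)
  if (!all(seq_len(m) %in% true_labels))
    stop("every cell-type index in 1..m must appear in true_labels")
  if (min(counts) < 0) stop("counts must be non-negative")
  idx <- unlist(marker_map, use.names = FALSE)
  if (length(idx) && (anyDuplicated(idx) || any(idx < 1 | idx > nrow(counts))))
    stop("marker_map must hold disjoint, in-range gene indices")
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 true_labels = true_labels, marker_map = marker_map,
                 params = params),
            class = "labeled_counts")
}

#' @export
print.labeled_counts <- function(x, ...) {
  cat(sprintf("labeled_counts: %d genes x %d cells, %d types\n",
              nrow(x$counts), ncol(x$counts), max(x$true_labels)))
  cat(sprintf("  type sizes: %s\n",
              paste(tabulate(x$true_labels), collapse = ", ")))
  cat(sprintf("  markers: %s\n",
              if (length(x$marker_map))
                paste(lengths(x$marker_map), collapse = ", ") else "none"))
  invisible(x)
}

#' Estimate realized marker fold changes
#'
#' Measures, on library-size-normalized counts, the mean expression of each
#' marker gene within its own type divided by its mean in all other cells,
#' and averages those ratios per type. Markers whose rest-of-cells mean falls
#' below `min_rest_mean` (in normalized counts) are excluded: for very weakly
#' expressed genes the ratio estimator is dominated by sampling noise in its
#' denominator and would bias the average upward.
#'
#' @param dataset a `labeled_counts` object with a non-empty `marker_map`.
#' @param scale_factor per-cell normalization target (counts per cell).
#' @param min_rest_mean minimum normalized rest-mean for a marker to enter
#'   the average.
#' @return List with `per_type` (mean ratio per type), `overall` (mean over
#'   all retained markers) and `n_used` (markers retained).
#' @export
realized_fold_change <- function(dataset, scale_factor = 1e4,
                                 min_rest_mean = 0.1) {
  stopifnot(inherits(dataset, "labeled_counts"), length(dataset$marker_map) > 0)
  counts <- dataset$counts
  norm <- t(t(as.matrix(counts)) / pmax(Matrix::colSums(counts), 1)) * scale_factor
  labels <- dataset$true_labels
  per_type <- numeric(length(dataset$marker_map))
  ratios_all <- numeric(0)
  for (k in seq_along(dataset$marker_map)) {
    idx <- dataset$marker_map[[k]]
    ing <- labels == k
    grp <- rowMeans(norm[idx, ing, drop = FALSE])
    rest <- rowMeans(norm[idx, !ing, drop = FALSE])
    keep <- rest >= min_rest_mean
    r <- grp[keep] / rest[keep]
    per_type[k] <- mean(r)
    ratios_all <- c(ratios_all, r)
  }
  list(per_type = per_type, overall = mean(ratios_all),
       n_used = length(ratios_all))
}
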