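#' Parameterize one simulated scRNA-seq dataset
#'
#' Bundles every knob of the labeled-count simulator into a validated object.
#' The defaults describe a typical droplet-style experiment: gene baseline
#' means drawn from a gamma distribution, log-normal library sizes centred on
#' 20,000 total counts, mild gamma-Poisson overdispersion, and no dropout.
#'
#' @param n_cells total number of cells to simulate.
#' @param proportions numeric vector of per-type fractions; length is the
#'   number of cell types `m`. Must be strictly positive and sum to 1.
#' @param n_genes total number of genes (default 10,000).
#' @param n_markers_per_type number of marker genes upregulated in each type
#'   (default 50). `m * n_markers_per_type` may not exceed `n_genes`.
#' @param fold_change target marker fold change `fC >= 1`. Per-marker factors
#'   are drawn from a gamma distribution with shape `fC` and rate 1, whose
#'   mean is `fC`.
#' @param mean_shape,mean_rate gamma parameters of the baseline gene means.
#' @param libsize_location,libsize_scale log-normal parameters of the
#'   expected total counts per cell; the median library size is
#'   `exp(libsize_location)`.
#' @param bcv_dispersion squared biological coefficient of variation of the
#'   cell-level expression noise; 0 gives pure Poisson counts.
#' @param dropout_midpoint,dropout_shape logistic dropout parameters
#'   (probability of zeroing an entry decreases with log expected count);
#'   both `NULL` (the default) disables dropout.
#' @param truncate_fc_below_one if `TRUE` (default), fold-change factors
#'   below 1 are resampled so every marker is genuinely upregulated.
#' @param seed non-negative integer master seed for the dataset.
#' @return An object of class `simulation_params`.
#' @examples
#' p <- simulation_params(n_cells = 1000,
#'                        proportions = c(0.1, 0.2, 0.2, 0.2, 0.3),
#'                        fold_change = 2, seed = 1)
#' p$n_genes
#' @seealso [generate_dataset()]
#' @export
simulation_params <- function(n_cells,
                              proportions,
                              n_genes = 10000L,
                              n_markers_per_type = 50L,
                              fold_change = 2,
                              mean_shape = 0.6,
                              mean_rate = 0.3,
                              libsize_location = log(20000),
                              libsize_scale = 0.2,
                              bcv_dispersion = 0.1,
                              dropout_midpoint = NULL,
                              dropout_shape = NULL,
                              truncate_fc_below_one = TRUE,
                              seed = 1L) {
  p <- list(n_cells = as.integer(n_cells),
            proportions = as.numeric(proportions),
            n_genes = as.integer(n_genes),
            n_markers_per_type = as.integer(n_markers_per_type),
            fold_change = as.numeric(fold_change),
            mean_shape = as.numeric(mean_shape),
            mean_rate = as.numeric(mean_rate),
            libsize_location = as.numeric(libsize_location),
            libsize_scale = as.numeric(libsize_scale),
            bcv_dispersion = as.numeric(bcv_dispersion),
            dropout_midpoint = if (is.null(dropout_midpoint)) NULL else as.numeric(dropout_midpoint),
            dropout_shape = if (is.null(dropout_shape)) NULL else as.numeric(dropout_shape),
            truncate_fc_below_one = isTRUE(truncate_fc_below_one),
            seed = as.integer(seed))
  class(p) <- "simulation_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "simulation_params"))
  if (p$n_cells < 1L) stop("n_cells must be a positive integer")
  if (p$n_genes < 1L) stop("n_genes must be a positive integer")
  m <- length(p$proportions)
  if (m < 2L) stop("at least two cell types are required (length(proportions) >= 2)")
  if (any(p$proportions <= 0)) stop("proportions must all be > 0")
  if (abs(sum(p$proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (p$n_markers_per_type < 1L) stop("n_markers_per_type must be positive")
  if (p$n_markers_per_type * m > p$n_genes)
    stop("n_markers_per_type * number of types exceeds n_genes")
  if (p$fold_change < 1) stop("fold_change must be >= 1")
  for (f in c("mean_shape", "mean_rate", "libsize_scale")) {
    if (p[[f]] <= 0) stop(sprintf("%s must be > 0", f))
  }
  if (p$bcv_dispersion < 0) stop("bcv_dispersion must be >= 0")
  if (xor(is.null(p$dropout_midpoint), is.null(p$dropout_shape)))
    stop("dropout_midpoint and dropout_shape must be supplied together")
  if (p$seed < 0L) stop("seed must be non-negative")
  invisible(p)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf("simulation_params: %d cells, %d genes, %d types\n",
              x$n_cells, x$n_genes, length(x$proportions)))
  cat(sprintf("  proportions: %s\n", paste(x$proportions, collapse = ", ")))
  cat(sprintf("  markers/type: %d at fold change %g (%struncated)\n",
              x$n_markers_per_type, x$fold_change,
              if (x$truncate_fc_below_one) "" else "un"))
  cat(sprintf("  bcv_dispersion: %g, dropout: %s, seed: %d\n",
              x$bcv_dispersion,
              if (is.null(x$dropout_midpoint)) "off" else "on", x$seed))
  invisible(x)
}
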