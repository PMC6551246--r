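#' Specify a factorial simulation-benchmark grid
#'
#' A grid crosses cell-type proportion sets, total cell numbers and marker
#' fold changes; every grid cell is simulated `replicates` times and each
#' dataset is analyzed by every backend. The defaults reproduce the bundled
#' benchmark design: three 5-type mixtures whose rarest type has proportion
#' 0.1, 0.05 or 0.02; 1000, 2000 or 3000 cells; fold changes 2, 4 and 8;
#' 10,000 genes and 50 markers per type — a 3 x 3 x 3 factorial of 27
#' distinct datasets per replicate.
#'
#' @param proportion_sets list of proportion vectors.
#' @param n_cells_levels integer vector of total cell numbers.
#' @param fold_changes numeric vector of marker fold changes.
#' @param n_genes,n_markers_per_type passed to [simulation_params()].
#' @param backends character vector of registered backend names.
#' @param replicates simulated replicates per grid cell (default 5).
#' @param master_seed master seed; all per-dataset and per-backend seeds are
#'   derived from it.
#' @param sim_overrides named list of further [simulation_params()] arguments
#'   (e.g. `bcv_dispersion`, `truncate_fc_below_one`).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(proportion_sets = list(c(0.1, 0.2, 0.2, 0.2, 0.3),
                                             c(0.05, 0.2, 0.2, 0.2, 0.35),
                                             c(0.02, 0.2, 0.2, 0.2, 0.38)),
                      n_cells_levels = c(1000L, 2000L, 3000L),
                      fold_changes = c(2, 4, 8),
                      n_genes = 10000L,
                      n_markers_per_type = 50L,
                      backends = c("kmeans", "snn_louvain", "mk_spectral"),
                      replicates = 5L,
                      master_seed = 1L,
                      sim_overrides = list()) {
  if (length(proportion_sets) == 0L || length(n_cells_levels) == 0L ||
      length(fold_changes) == 0L)
    stop("grid levels must be non-empty")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(proportion_sets = proportion_sets,
                 n_cells_levels = as.integer(n_cells_levels),
                 fold_changes = as.numeric(fold_changes),
                 n_genes = as.integer(n_genes),
                 n_markers_per_type = as.integer(n_markers_per_type),
                 backends = backends,
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed),
                 sim_overrides = sim_overrides),
            class = "grid_spec")
}

#' Enumerate the simulation parameter sets of a grid
#'
#' Expands the factorial design in a fixed order — proportion sets outermost,
#' then cell numbers, then fold changes, then replicates — and derives a
#' reproducible seed for every dataset from the master seed and the cell
#' coordinates, so re-running a grid regenerates identical data.
#'
#' @param gs a [grid_spec()].
#' @return List of entries, each holding `params` (a `simulation_params`)
#'   and `meta` (rarity, n_cells, fold_change, replicate, proportion-set
#'   index).
#' @export
enumerate_grid <- function(gs) {
  stopifnot(inherits(gs, "grid_spec"))
  out <- list()
  for (ip in seq_along(gs$proportion_sets)) {
    props <- gs$proportion_sets[[ip]]
    for (n in gs$n_cells_levels) {
      for (fc in gs$fold_changes) {
        for (r in seq_len(gs$replicates)) {
          seed <- substream_seed(gs$master_seed, "grid", ip, n, fc, r)
          args <- c(list(n_cells = n, proportions = props,
                         n_genes = gs$n_genes,
                         n_markers_per_type = gs$n_markers_per_type,
                         fold_change = fc, seed = seed),
                    gs$sim_overrides)
          out[[length(out) + 1L]] <- list(
            params = do.call(simulation_params, args),
            meta = list(prop_set = ip, rarity = min(props), n_cells = n,
                        fold_change = fc, replicate = r))
        }
      }
    }
  }
  out
}

#' Run a simulation-clustering-evaluation grid
#'
#' For every dataset of the enumerated grid: simulate, preprocess once, then
#' run each backend (with its cluster target set to the number of simulated
#' types) and score it against the true labels. A backend failure on one
#' dataset is recorded as a row with `status = "error"` and the condition
#' message, not a run abort. When `ledger_path` is given, completed rows are
#' appended to a TSV ledger as they finish and already-ledgered rows are
#' skipped on re-run, making long grids resumable.
#'
#' @param gs a [grid_spec()]; all backends must be resolvable before any
#'   simulation starts.
#' @param ledger_path optional path of an on-disk completion ledger (TSV).
#' @param verbose print one progress line per backend run?
#' @return A `power_table` data frame with one row per (dataset, backend):
#'   backend, rarity, fold_change, n_cells, replicate, seed, rare_type_f1,
#'   macro_f1, n_clusters, status, note.
#' @export
run_grid <- function(gs, ledger_path = NULL, verbose = FALSE) {
  stopifnot(inherits(gs, "grid_spec"))
  for (b in gs$backends) get_backend(b)      # fail before simulating
  cells <- enumerate_grid(gs)

  ledger <- NULL
  if (!is.null(ledger_path) && file.exists(ledger_path))
    ledger <- utils::read.delim(ledger_path, stringsAsFactors = FALSE)

  rows <- list()
  for (cell in cells) {
    meta <- cell$meta
    done_keys <- if (is.null(ledger)) character(0) else
      paste(ledger$backend, ledger$rarity, ledger$fold_change,
            ledger$n_cells, ledger$replicate)
    todo <- gs$backends[!(paste(gs$backends, meta$rarity, meta$fold_change,
                                meta$n_cells, meta$replicate) %in% done_keys)]
    if (length(todo) == 0L) next
    dataset <- generate_dataset(cell$params)
    emb <- preprocess(dataset)
    m <- length(cell$params$proportions)
    for (b in todo) {
      bseed <- substream_seed(cell$params$seed, "backend", b)
      row <- tryCatch({
        t0 <- proc.time()[["elapsed"]]
        asn <- get_backend(b)(emb, m_target = m, seed = bseed)
        sc <- evaluate_clustering(dataset$true_labels, asn)
        if (verbose)
          message(sprintf(
            "ts=%s backend=%s rarity=%g fc=%g n=%d rep=%d seed=%d rare_f1=%.3f macro_f1=%.3f secs=%.1f",
            format(Sys.time(), "%H:%M:%S"), b, meta$rarity, meta$fold_change,
            meta$n_cells, meta$replicate, cell$params$seed, sc$rare_type_f1,
            sc$macro_f1, proc.time()[["elapsed"]] - t0))
        data.frame(backend = b, rarity = meta$rarity,
                   fold_change = meta$fold_change, n_cells = meta$n_cells,
                   replicate = meta$replicate, seed = cell$params$seed,
                   rare_type_f1 = sc$rare_type_f1, macro_f1 = sc$macro_f1,
                   n_clusters = length(unique(asn$labels)),
                   status = "ok", note = "", stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(backend = b, rarity = meta$rarity,
                   fold_change = meta$fold_change, n_cells = meta$n_cells,
                   replicate = meta$replicate, seed = cell$params$seed,
                   rare_type_f1 = NA_real_, macro_f1 = NA_real_,
                   n_clusters = NA_integer_,
                   status = "error", note = conditionMessage(e),
                   stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- row
      if (!is.null(ledger_path)) {
        utils::write.table(row, ledger_path, sep = "\t", quote = FALSE,
                           row.names = FALSE, append = file.exists(ledger_path),
                           col.names = !file.exists(ledger_path))
      }
    }
  }
  fresh <- do.call(rbind, rows)
  out <- if (is.null(ledger)) fresh else rbind(ledger, fresh)
  class(out) <- c("power_table", "data.frame")
  out
}

#' Minimum cells needed to reach an F1 threshold
#'
#' For every (backend, rarity, fold change) combination, aggregates the
#' rare-type F1 over replicates at each cell-number level and reports the
#' smallest level whose aggregate meets the threshold. Levels are scanned in
#' increasing order; "not achieved" is an explicit result (`achieved =
#' FALSE`, `min_cells = NA`), not an absence.
#'
#' @param power_table output of [run_grid()].
#' @param threshold required F1 in `(0, 1]`.
#' @param aggregator `"mean"` (default) or `"median"` over replicates.
#' @param metric column to threshold, default `"rare_type_f1"`.
#' @return Data frame with backend, rarity, fold_change, min_cells,
#'   achieved, and the aggregate F1 at the returned level.
#' @export
min_cells_for_threshold <- function(power_table, threshold,
                                    aggregator = c("mean", "median"),
                                    metric = "rare_type_f1") {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  aggregator <- match.arg(aggregator)
  agg_fun <- if (aggregator == "mean") mean else stats::median
  pt <- power_table[power_table$status == "ok", , drop = FALSE]
  keys <- unique(pt[, c("backend", "rarity", "fold_change")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sl <- merge(pt, keys[i, , drop = FALSE])
    lev <- sort(unique(sl$n_cells))
    f1 <- vapply(lev, function(n)
      agg_fun(sl[sl$n_cells == n, metric]), numeric(1))
    hit <- which(f1 >= threshold)
    data.frame(keys[i, , drop = FALSE],
               min_cells = if (length(hit)) lev[hit[1]] else NA_integer_,
               achieved = length(hit) > 0,
               f1_at_min = if (length(hit)) f1[hit[1]] else max(f1),
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  out[order(out$backend, out$rarity, out$fold_change), , drop = FALSE]
}

#' Rank backends for one experimental scenario
#'
#' Slices the power table at a (rarity, fold change, cell number) scenario,
#' aggregates the rare-type F1 per backend over replicates, and returns the
#' full ranking: descending rare-type F1, ties broken by macro F1, then by
#' backend name.
#'
#' @param power_table output of [run_grid()].
#' @param rarity,fold_change,n_cells the scenario coordinates.
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return Data frame ranked best-first, with aggregated `rare_type_f1` and
#'   `macro_f1` per backend.
#' @export
select_best_pipeline <- function(power_table, rarity, fold_change, n_cells,
                                 aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  agg_fun <- if (aggregator == "mean") mean else stats::median
  sl <- power_table[power_table$status == "ok" &
                    power_table$rarity == rarity &
                    power_table$fold_change == fold_change &
                    power_table$n_cells == n_cells, , drop = FALSE]
  if (nrow(sl) == 0L) stop("no rows for the requested scenario")
  backs <- sort(unique(sl$backend))
  out <- data.frame(
    backend = backs,
    rare_type_f1 = vapply(backs, function(b)
      agg_fun(sl$rare_type_f1[sl$backend == b]), numeric(1)),
    macro_f1 = vapply(backs, function(b)
      agg_fun(sl$macro_f1[sl$backend == b]), numeric(1)),
    n_replicates = vapply(backs, function(b)
      sum(sl$backend == b), numeric(1)),
    row.names = NULL)
  out <- out[order(-out$rare_type_f1, -out$macro_f1, out$backend), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
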