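#' Write a dataset bundle to disk
#'
#' Serializes a `labeled_counts` object as a directory of plain-text files
#' in the familiar CellRanger-style layout: `counts.mtx` (Matrix Market
#' coordinate integer, genes as rows, 1-based indices, entries sorted
#' row-major), `genes.tsv` (one gene id per line), `cells.tsv` (cell id TAB
#' true type label), `markers.tsv` (gene id TAB type index) and, when the
#' data were simulated, `params.json` recording the full
#' [simulation_params()].
#'
#' @param dataset a `labeled_counts` object.
#' @param path bundle directory (created if missing).
#' @param overwrite allow writing into an existing non-empty directory?
#' @return `path`, invisibly.
#' @export
write_bundle <- function(dataset, path, overwrite = FALSE) {
  stopifnot(inherits(dataset, "labeled_counts"))
  if (dir.exists(path) && length(list.files(path)) > 0 && !overwrite)
    stop(sprintf("directory %s exists and is non-empty (use overwrite = TRUE)", path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  tm <- methods::as(Matrix::Matrix(dataset$counts, sparse = TRUE), "TsparseMatrix")
  ord <- order(tm@i, tm@j)                    # deterministic row-major order
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x)),
             sprintf("%d %d %d", tm@i[ord] + 1L, tm@j[ord] + 1L,
                     as.integer(tm@x[ord])))
  writeLines(lines, file.path(path, "counts.mtx"))

  writeLines(dataset$gene_ids, file.path(path, "genes.tsv"))
  writeLines(paste(dataset$cell_ids, dataset$true_labels, sep = "\t"),
             file.path(path, "cells.tsv"))
  mk <- dataset$marker_map
  mk_lines <- unlist(lapply(seq_along(mk), function(k)
    paste(dataset$gene_ids[mk[[k]]], k, sep = "\t")))
  writeLines(if (is.null(mk_lines)) character(0) else mk_lines,
             file.path(path, "markers.tsv"))
  if (!is.null(dataset$params)) {
    p <- unclass(dataset$params)
    jsonlite::write_json(p[!vapply(p, is.null, logical(1))],
                         file.path(path, "params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a dataset bundle from disk
#'
#' Counterpart of [write_bundle()]. `markers.tsv` and `params.json` are
#' optional so externally produced bundles (real data with known labels) can
#' be loaded; `counts.mtx`, `genes.tsv` and `cells.tsv` are required and are
#' validated against each other, with errors naming the offending file.
#'
#' @param path bundle directory.
#' @return A `labeled_counts` object.
#' @export
read_bundle <- function(path) {
  need <- c("counts.mtx", "genes.tsv", "cells.tsv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop(sprintf("bundle member missing: %s", f))
  counts <- tryCatch(suppressWarnings(Matrix::readMM(file.path(path, "counts.mtx"))),
                     error = function(e)
                       stop(sprintf("counts.mtx: unreadable Matrix Market file (%s)",
                                    conditionMessage(e))))
  counts <- methods::as(counts, "CsparseMatrix")
  if (length(counts@x)) {
    if (any(counts@x < 0)) stop("counts.mtx: negative count entry")
    if (any(counts@x != round(counts@x))) stop("counts.mtx: non-integer count entry")
  }
  gene_ids <- readLines(file.path(path, "genes.tsv"))
  cells_raw <- readLines(file.path(path, "cells.tsv"))
  if (nrow(counts) != length(gene_ids))
    stop(sprintf("genes.tsv: %d lines but counts.mtx declares %d rows",
                 length(gene_ids), nrow(counts)))
  if (ncol(counts) != length(cells_raw))
    stop(sprintf("cells.tsv: %d lines but counts.mtx declares %d columns",
                 length(cells_raw), ncol(counts)))
  parts <- strsplit(cells_raw, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    bad <- which(lengths(parts) != 2L)[1]
    stop(sprintf("cells.tsv line %d: expected 'cell_id<TAB>label'", bad))
  }
  cell_ids <- vapply(parts, `[[`, character(1), 1L)
  labels <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(labels)) {
    bad <- which(is.na(labels))[1]
    stop(sprintf("cells.tsv line %d: unknown (non-integer) label", bad))
  }

  marker_map <- list()
  mk_path <- file.path(path, "markers.tsv")
  if (file.exists(mk_path)) {
    mk_raw <- readLines(mk_path)
    if (length(mk_raw)) {
      mp <- strsplit(mk_raw, "\t", fixed = TRUE)
      if (any(lengths(mp) != 2L))
        stop("markers.tsv: expected 'gene_id<TAB>type_index'")
      g <- match(vapply(mp, `[[`, character(1), 1L), gene_ids)
      if (anyNA(g)) stop("markers.tsv: gene id not present in genes.tsv")
      ty <- as.integer(vapply(mp, `[[`, character(1), 2L))
      marker_map <- split(g, ty)
      names(marker_map) <- as.character(sort(unique(ty)))
    }
  }

  params <- NULL
  pj <- file.path(path, "params.json")
  if (file.exists(pj)) {
    raw <- jsonlite::read_json(pj, simplifyVector = TRUE)
    params <- do.call(simulation_params, raw)
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  labeled_counts(counts, gene_ids, cell_ids, labels, marker_map, params)
}
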