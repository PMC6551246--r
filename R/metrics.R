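#' Cross-tabulate true types against predicted clusters
#'
#' @param true_labels integer cell-type index per cell.
#' @param predicted_labels predicted cluster id per cell (any integers).
#' @return `m x C` integer matrix; entry `(k, c)` counts cells of true type
#'   `k` placed in cluster `c`. Row names are the type indices, column names
#'   the sorted distinct cluster ids.
#' @export
contingency_table <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (length(true_labels) == 0L) stop("empty label vectors")
  tt <- factor(true_labels, levels = sort(unique(true_labels)))
  pp <- factor(predicted_labels, levels = sort(unique(predicted_labels)))
  ct <- table(tt, pp)
  matrix(as.integer(ct), nrow = nrow(ct),
         dimnames = list(rownames(ct), colnames(ct)))
}

#' Map each cluster to a cell type by plurality
#'
#' Each cluster is assigned to the type holding the plurality of its cells,
#' ties broken in favour of the lower type index. The mapping is many-to-one:
#' a type may receive several clusters (their cells are pooled when scoring)
#' or none (precision and recall are then 0 for that type).
#'
#' @param contingency matrix from [contingency_table()].
#' @return Integer vector of row (type) positions, one per cluster column,
#'   named by cluster.
#' @export
match_clusters_to_types <- function(contingency) {
  if (length(contingency) == 0L) stop("empty contingency table")
  map <- apply(contingency, 2, which.max)   # which.max breaks ties low
  stats::setNames(as.integer(map), colnames(contingency))
}

#' Pooled precision and recall for one cell type
#'
#' Cells in all clusters mapped to type `k` are pooled: true positives are
#' the type-`k` cells among them, false positives the remainder, false
#' negatives the type-`k` cells elsewhere. When no cluster maps to `k`, both
#' precision and recall are 0 (explicit zero-division rule, never `NaN`).
#'
#' @param contingency matrix from [contingency_table()].
#' @param mapping cluster-to-type-row mapping from
#'   [match_clusters_to_types()].
#' @param type_k row position of the type to score.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(contingency, mapping, type_k) {
  if (type_k < 1 || type_k > nrow(contingency)) stop("type index out of range")
  if (length(mapping) != ncol(contingency))
    stop("mapping must cover all clusters")
  cols <- which(mapping == type_k)
  tp <- sum(contingency[type_k, cols])
  fp <- sum(contingency[, cols]) - tp
  fn <- sum(contingency[type_k, ]) - tp
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR/(P + R)`, defined as 0 when
#' both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(1, 2/3) # 0.8
#' @export
f1_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  s <- precision + recall
  unname(ifelse(s > 0, 2 * precision * recall / s, 0))
}

#' Score a clustering against the true cell types
#'
#' Builds the type-by-cluster contingency table, maps clusters to types
#' (plurality by default, optionally an exact one-to-one matching), and
#' reports pooled precision, recall and F1 per type along with two
#' summaries: `rare_type_f1`, the F1 of the least abundant true type (ties
#' broken by lower index) — the headline quantity when the design question
#' is rare-population detection — and `macro_f1`, the unweighted mean over
#' types.
#'
#' @param true_labels integer type index per cell.
#' @param assignment a `cluster_assignment` or a plain vector of predicted
#'   cluster ids.
#' @param matching `"plurality"` (many-to-one, default) or `"one_to_one"`
#'   (exact search over injective cluster-to-type maps maximizing total
#'   overlap; limited to 8 clusters).
#' @return An object of class `type_score_table`: `per_type` data frame
#'   (type, matched clusters, true count, precision, recall, f1),
#'   `rare_type_f1`, `macro_f1`, `contingency`, `mapping`.
#' @examples
#' truth <- c(1, 1, 1, 2, 2, 2)
#' pred <- c(1, 1, 2, 2, 2, 2)
#' evaluate_clustering(truth, pred)$per_type
#' @export
evaluate_clustering <- function(true_labels, assignment,
                                matching = c("plurality", "one_to_one")) {
  matching <- match.arg(matching)
  pred <- if (inherits(assignment, "cluster_assignment")) assignment$labels
          else assignment
  ct <- contingency_table(true_labels, pred)
  mapping <- if (matching == "plurality") match_clusters_to_types(ct)
             else match_one_to_one(ct)
  m <- nrow(ct)
  pr <- t(vapply(seq_len(m), function(k) precision_recall(ct, mapping, k),
                 numeric(2)))
  f1 <- f1_score(pr[, 1], pr[, 2])
  sizes <- rowSums(ct)
  rare <- which.min(sizes)                   # ties -> lower type index
  per_type <- data.frame(
    type = as.integer(rownames(ct)),
    clusters = vapply(seq_len(m), function(k)
      paste(names(mapping)[mapping == k], collapse = ","), character(1)),
    n_true = as.integer(sizes),
    precision = pr[, 1], recall = pr[, 2], f1 = f1,
    row.names = NULL)
  structure(list(per_type = per_type,
                 rare_type_f1 = f1[rare],
                 macro_f1 = mean(f1),
                 contingency = ct,
                 mapping = mapping),
            class = "type_score_table")
}

#' @export
print.type_score_table <- function(x, ...) {
  cat("type_score_table\n")
  print(x$per_type, digits = 3)
  cat(sprintf("rare_type_f1: %.4f   macro_f1: %.4f\n",
              x$rare_type_f1, x$macro_f1))
  invisible(x)
}

# Exact one-to-one matching: enumerate injective cluster -> type maps and
# keep the one maximizing the total matched cell count. Unmatched clusters
# leave their cells unpooled (they count against recall only). Feasible for
# small cluster counts; grid runs use plurality matching.
match_one_to_one <- function(contingency) {
  if (length(contingency) == 0L) stop("empty contingency table")
  m <- nrow(contingency); cc <- ncol(contingency)
  if (cc > 8L) stop("one_to_one matching supports at most 8 clusters")
  best <- NULL; best_score <- -1
  assign_next <- function(col, map, used, score) {
    if (col > cc) {
      if (score > best_score) { best_score <<- score; best <<- map }
      return(invisible())
    }
    for (k in seq_len(m)) {
      if (!used[k]) {
        used[k] <- TRUE
        assign_next(col + 1L, c(map, k), used, score + contingency[k, col])
        used[k] <- FALSE
      }
    }
    if (cc > m) assign_next(col + 1L, c(map, 0L), used, score)  # unmatched
  }
  assign_next(1L, integer(0), logical(m), 0)
  stats::setNames(as.integer(best), colnames(contingency))
}
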