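#' Confusion matrix over the ordered gene-pair universe
#'
#' Counts predicted and gold edges over all ordered pairs `(a, b)`, `a != b`,
#' of universe genes, so `tp + fp + tn + fn = N (N - 1)`. Gold networks read
#' from undirected sources should be expanded to both orientations before
#' counting (see [read_network()] with `directed = FALSE`).
#'
#' @param predicted,gold `GeneNetwork` objects.
#' @param universe Gene universe; defaults to the union of both networks'
#'   gene sets.
#' @return A `ConfusionMatrix`: list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, gold, universe = NULL) {
  if (is.null(universe)) universe <- union(predicted$genes, gold$genes)
  universe <- unique(as.character(universe))
  for (net in list(predicted, gold)) {
    bad <- setdiff(as.vector(net$edges), universe)
    if (length(bad)) stopf("edge endpoint outside universe: %s", bad[[1L]])
  }
  N <- length(universe)
  total <- N * (N - 1)
  pk <- paste(predicted$edges[, 1L], predicted$edges[, 2L], sep = "\r")
  gk <- paste(gold$edges[, 1L], gold$edges[, 2L], sep = "\r")
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  tn <- total - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat(sprintf("ConfusionMatrix: TP=%d FP=%d TN=%d FN=%d (universe %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Single-operating-point ROC and PR areas
#'
#' The predicted network gives one (FPR, TPR) operating point; the ROC curve
#' is interpolated through (0,0), (FPR, TPR), (1,1) and integrated by
#' trapezoids, so `auroc = (tpr + 1 - fpr) / 2`. The PR curve is anchored at
#' (0, 1), passes through (recall, precision), and terminates at
#' (1, prevalence).
#'
#' @param c A [confusion_matrix()] with at least one positive and one
#'   negative.
#' @return List with `auroc`, `aupr`, `tpr`, `fpr`, `precision`, `recall`.
#' @export
auc_from_confusion <- function(c) {
  pos <- c$tp + c$fn
  neg <- c$fp + c$tn
  if (pos <= 0 || neg <= 0) {
    stopf("confusion matrix needs both positives and negatives")
  }
  tpr <- c$tp / pos
  fpr <- c$fp / neg
  precision <- if (c$tp + c$fp == 0) 1 else c$tp / (c$tp + c$fp)
  recall <- tpr
  prevalence <- pos / (pos + neg)
  auroc <- (tpr + 1 - fpr) / 2
  aupr <- recall * (1 + precision) / 2 + (1 - recall) * (precision + prevalence) / 2
  list(auroc = auroc, aupr = aupr, tpr = tpr, fpr = fpr,
       precision = precision, recall = recall)
}

# Logical adjacency matrices over the universe.
edge_matrix <- function(net, universe) {
  A <- matrix(FALSE, length(universe), length(universe),
              dimnames = list(universe, universe))
  if (nrow(net$edges)) A[net$edges] <- TRUE
  A
}

#' Evaluation with indirect-edge reclassification
#'
#' Standard confusion counts plus the modified counts in which a false
#' positive pair `(a, b)` becomes a true positive when the gold network
#' (viewed undirected) joins `a` and `b` by a path of length exactly two
#' (one intermediate gene), and -- symmetrically -- a true negative pair
#' with such a two-hop gold path becomes a false negative. Counts still sum
#' to the `N (N - 1)` pair universe.
#'
#' @inheritParams confusion_matrix
#' @return An `EvaluationReport`: list with `confusion`, `tpr`, `fpr`,
#'   `precision`, `recall`, `auroc`, `aupr`, and `modified` (list with
#'   `confusion`, `fp_to_tp`, `tn_to_fn`, `auroc`, `aupr`).
#' @export
modified_reclassify <- function(predicted, gold, universe = NULL) {
  if (is.null(universe)) universe <- union(predicted$genes, gold$genes)
  universe <- sort(unique(as.character(universe)))
  cm <- confusion_matrix(predicted, gold, universe)
  P <- edge_matrix(predicted, universe)
  G <- edge_matrix(gold, universe)
  U <- G | t(G)  # undirected view for path queries
  two_hop <- (U %*% U) > 0
  diag(two_hop) <- FALSE
  offdiag <- !diag(TRUE, length(universe))
  fp_to_tp <- sum(P & !G & two_hop)
  tn_to_fn <- sum(!P & !G & two_hop & offdiag)
  mod <- structure(list(tp = cm$tp + fp_to_tp, fp = cm$fp - fp_to_tp,
                        tn = cm$tn - tn_to_fn, fn = cm$fn + tn_to_fn),
                   class = "ConfusionMatrix")
  base <- auc_from_confusion(cm)
  # reclassification can exhaust the negatives (or positives) entirely, in
  # which case the modified operating point is undefined
  mauc <- tryCatch(auc_from_confusion(mod),
                   error = function(e) list(auroc = NA_real_, aupr = NA_real_))
  structure(c(list(confusion = cm), base,
              list(modified = c(list(confusion = mod, fp_to_tp = fp_to_tp,
                                     tn_to_fn = tn_to_fn),
                                mauc[c("auroc", "aupr")]))),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: AUROC %s, AUPR %s (modified: AUROC %s, AUPR %s)\n",
              format_4dp(x$auroc), format_4dp(x$aupr),
              format_4dp(x$modified$auroc), format_4dp(x$modified$aupr)))
  invisible(x)
}

#' Network topology statistics
#'
#' Edges are treated as undirected and deduplicated. `avg_neighbors = 2E/N`
#' over the declared gene universe, `density = avg_neighbors / (N - 1)`,
#' and the diameter is the maximum eccentricity within the largest
#' connected component.
#'
#' @param net A non-empty `GeneNetwork`.
#' @return A `TopologyStats` list: `diameter`, `density`, `avg_neighbors`,
#'   `n_nodes`, `n_edges_undirected`.
#' @export
topology_stats <- function(net) {
  if (!nrow(net$edges) || !length(net$genes)) stopf("network is empty")
  g <- igraph::graph_from_data_frame(as.data.frame(net$edges),
                                     directed = FALSE,
                                     vertices = net$genes)
  g <- igraph::simplify(g)
  E <- igraph::ecount(g)
  N <- length(net$genes)
  avg_neighbors <- 2 * E / N
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  structure(list(diameter = as.integer(igraph::diameter(sub, unconnected = FALSE)),
                 density = avg_neighbors / (N - 1),
                 avg_neighbors = avg_neighbors,
                 n_nodes = N, n_edges_undirected = E),
            class = "TopologyStats")
}

#' @export
print.TopologyStats <- function(x, ...) {
  cat(sprintf("TopologyStats: diameter %d, density %.3f, avg neighbors %.2f (N=%d, E=%d)\n",
              x$diameter, x$density, x$avg_neighbors, x$n_nodes,
              x$n_edges_undirected))
  invisible(x)
}

#' Write an evaluation report table as TSV
#'
#' One row per method, columns `Method`, `EdgeCount`, `TP`, `FP`, `TN`,
#' `FN`, `FPtoTP`, `TNtoFN`, `AUROC`, `AUPR`, `AUROCmod`, `AUPRmod`; areas
#' are printed to 4 decimals (half away from zero).
#'
#' @param reports Named list of `EvaluationReport` objects.
#' @param path Output path.
#' @export
write_evaluation_tsv <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cm <- r$confusion
    data.frame(Method = nm, EdgeCount = cm$tp + cm$fp,
               TP = cm$tp, FP = cm$fp, TN = cm$tn, FN = cm$fn,
               FPtoTP = r$modified$fp_to_tp, TNtoFN = r$modified$tn_to_fn,
               AUROC = format_4dp(r$auroc), AUPR = format_4dp(r$aupr),
               AUROCmod = format_4dp(r$modified$auroc),
               AUPRmod = format_4dp(r$modified$aupr))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
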