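# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

make_expr <- function(values, genes = NULL, conds = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(conds)) conds <- sprintf("c%02d", seq_len(ncol(values)))
  expression_matrix(values, genes, conds)
}

# --- hypergeometric upper tail by exhaustive pmf summation -------------------
hyper_tail_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- mean squared residue by the literal double sum --------------------------
msr_oracle <- function(sub) {
  rM <- rowMeans(sub)
  cM <- colMeans(sub)
  aM <- mean(sub)
  acc <- 0
  for (i in seq_len(nrow(sub))) for (j in seq_len(ncol(sub))) {
    acc <- acc + (sub[i, j] - rM[i] - cM[j] + aM)^2
  }
  acc / (nrow(sub) * ncol(sub))
}

# --- exhaustive DAG enumeration (independent acyclicity check) ---------------
enumerate_dags <- function(nodes) {
  n <- length(nodes)
  pairs <- list()
  for (u in nodes) for (v in nodes) if (u != v) pairs[[length(pairs) + 1L]] <- c(u, v)
  ne <- length(pairs)
  acyclic <- function(adj) {
    # Kahn's algorithm on an adjacency matrix
    indeg <- colSums(adj)
    left <- rep(TRUE, n)
    repeat {
      src <- which(left & indeg == 0)
      if (!length(src)) break
      for (s in src) {
        left[s] <- FALSE
        indeg <- indeg - adj[s, ]
      }
    }
    !any(left)
  }
  out <- list()
  for (mask in 0:(2^ne - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0)
    adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    for (i in sel) adj[pairs[[i]][1L], pairs[[i]][2L]] <- 1L
    if (!acyclic(adj)) next
    ps <- stats::setNames(rep(list(character(0)), n), nodes)
    for (i in sel) {
      ps[[pairs[[i]][2L]]] <- c(ps[[pairs[[i]][2L]]], pairs[[i]][1L])
    }
    out[[length(out) + 1L]] <- ps
  }
  out
}

# total BDe score of an explicit parent-set list
total_bde <- function(parent_sets, dm, cfg) {
  sum(vapply(names(parent_sets), function(v) {
    bde_family_score(v, parent_sets[[v]], dm, cfg)
  }, numeric(1L)))
}

# --- exhaustive OPSM support: best support per model size --------------------
# Strict increase in (value, column index); enumerated over every ordered
# tuple of columns via recursive extension of every permutation.
opsm_best_support_oracle <- function(V) {
  nc <- ncol(V)
  supports_row <- function(row, tuple) {
    for (i in seq_len(length(tuple) - 1L)) {
      a <- tuple[i]
      b <- tuple[i + 1L]
      if (!(row[a] < row[b] || (row[a] == row[b] && a < b))) return(FALSE)
    }
    TRUE
  }
  support <- function(tuple) {
    sum(apply(V, 1L, supports_row, tuple = tuple))
  }
  best <- integer(0)
  tuples <- lapply(seq_len(nc), function(a) a)
  for (size in 2:nc) {
    ext <- list()
    for (tp in tuples) {
      for (cn in setdiff(seq_len(nc), tp)) {
        ext[[length(ext) + 1L]] <- c(tp, cn)
      }
    }
    tuples <- ext
    best[size] <- max(vapply(tuples, support, numeric(1L)))
  }
  best  # index = model size (entry 1 unused)
}

# --- brute-force two-hop reclassification ------------------------------------
two_hop_oracle <- function(pred_edges, gold_edges, universe) {
  und <- unique(rbind(gold_edges, gold_edges[, 2:1, drop = FALSE]))
  gkey <- paste(und[, 1L], und[, 2L])
  has_gold <- function(a, b) paste(a, b) %in% gkey
  pkey <- paste(pred_edges[, 1L], pred_edges[, 2L])
  fp_to_tp <- 0L
  tn_to_fn <- 0L
  for (a in universe) for (b in universe) {
    if (a == b) next
    two <- any(vapply(setdiff(universe, c(a, b)),
                      function(c) has_gold(a, c) && has_gold(c, b),
                      logical(1L)))
    if (!two) next
    if (has_gold(a, b)) next
    if (paste(a, b) %in% pkey) fp_to_tp <- fp_to_tp + 1L else tn_to_fn <- tn_to_fn + 1L
  }
  list(fp_to_tp = fp_to_tp, tn_to_fn = tn_to_fn)
}

# --- end-to-end study pipeline used by recovery tests ------------------------
# CC + ISA + k-means (the fast algorithm set) on the default planted fixture.
run_study_pipeline <- function(seed, dir,
                               algorithms = list(
                                 cc = cc_params(n_biclusters = 10),
                                 isa = isa_params(n_seeds = 100),
                                 kmeans = kmeans_params(n_clusters = 6))) {
  st <- simulate_study(rng_seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(st$matrix, file.path(dir, "expr.tsv"))
  ann <- data.frame(gene = rep(names(st$annotations$gene_to_terms),
                               lengths(st$annotations$gene_to_terms)),
                    term = unlist(st$annotations$gene_to_terms))
  utils::write.table(ann, file.path(dir, "ann.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_network(st$gold, file.path(dir, "gold.tsv"))
  cfg <- pipeline_config(
    expression = file.path(dir, "expr.tsv"),
    annotations = file.path(dir, "ann.tsv"),
    gold = file.path(dir, "gold.tsv"),
    out_dir = file.path(dir, "out"),
    algorithms = algorithms,
    gold_directed = TRUE,  # the generator already emits both orientations
    rng_seed = seed)
  manifest <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  list(study = st, manifest = manifest, out_dir = file.path(dir, "out"))
}

read_benchmark_confusion <- function() {
  path <- system.file("extdata", "yeast_benchmark_confusion.tsv",
                      package = "bicgrn")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
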