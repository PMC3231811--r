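#' Directed acyclic graph over a gene subset
#'
#' One learned subnetwork: per-family parent lists plus the total log BDe
#' score of the structure.
#'
#' @param nodes Character vector of gene IDs.
#' @param parent_sets Named list mapping each node to its (possibly empty)
#'   character vector of parents.
#' @param score Total log BDe score (sum of family scores).
#' @return A `DAGStructure` list.
#' @export
dag_structure <- function(nodes, parent_sets = NULL, score = NA_real_) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stopf("duplicate node IDs")
  if (is.null(parent_sets)) {
    parent_sets <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  }
  if (!setequal(names(parent_sets), nodes)) {
    stopf("parent_sets must name exactly the nodes")
  }
  parent_sets <- parent_sets[nodes]
  for (v in nodes) {
    pa <- parent_sets[[v]]
    if (v %in% pa) stopf("node %s cannot be its own parent", v)
    bad <- setdiff(pa, nodes)
    if (length(bad)) stopf("parent %s of %s is not a node", bad[[1L]], v)
  }
  d <- structure(list(nodes = nodes, parent_sets = parent_sets, score = score),
                 class = "DAGStructure")
  if (!dag_is_acyclic(d)) stopf("parent sets induce a cycle")
  d
}

# Kahn topological order of a DAGStructure's nodes.
topological_order <- function(d) {
  indeg <- vapply(d$parent_sets, length, integer(1L))
  children <- stats::setNames(rep(list(character(0)), length(d$nodes)), d$nodes)
  for (v in d$nodes) for (p in d$parent_sets[[v]]) {
    children[[p]] <- c(children[[p]], v)
  }
  queue <- d$nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

dag_is_acyclic <- function(d) {
  indeg <- vapply(d$parent_sets, length, integer(1L))
  children <- stats::setNames(rep(list(character(0)), length(d$nodes)), d$nodes)
  for (v in d$nodes) for (p in d$parent_sets[[v]]) {
    children[[p]] <- c(children[[p]], v)
  }
  queue <- d$nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen == length(d$nodes)
}

#' @export
print.DAGStructure <- function(x, ...) {
  ne <- sum(vapply(x$parent_sets, length, integer(1L)))
  cat(sprintf("DAGStructure: %d nodes, %d edges, log BDe score %s\n",
              length(x$nodes), ne,
              if (is.na(x$score)) "NA" else format(x$score)))
  invisible(x)
}

#' @rdname dag_structure
#' @param d A `DAGStructure`.
#' @return `dag_edges()`: two-column character matrix of directed edges
#'   (parent, child).
#' @export
dag_edges <- function(d) {
  from <- character(0)
  to <- character(0)
  for (v in d$nodes) {
    pa <- d$parent_sets[[v]]
    from <- c(from, pa)
    to <- c(to, rep(v, length(pa)))
  }
  cbind(from = from, to = to)
}

#' BDe scoring configuration
#'
#' @param ess Equivalent sample size of the Dirichlet prior (> 0); the total
#'   pseudo-count is split uniformly over parent configurations and child
#'   states. Default 1 (neutral prior).
#' @param levels Number of discrete states per variable (>= 2).
#' @export
bde_config <- function(ess = 1, levels = 3) {
  if (ess <= 0) stopf("ess must be positive")
  if (levels < 2) stopf("levels must be >= 2")
  structure(list(ess = ess, levels = as.integer(levels)), class = "BDeConfig")
}

#' Structure-search configuration
#'
#' @param max_parents Optional cap on the number of parents per node.
#' @param candidate_size Optional sparse-candidate set size; when set, each
#'   node's parents are restricted to its `candidate_size` highest
#'   mutual-information partners.
#' @param rng_seed RNG seed (reserved; the search itself is deterministic
#'   with lexicographic tie-breaking).
#' @export
search_config <- function(max_parents = NULL, candidate_size = NULL,
                          rng_seed = 1L) {
  if (!is.null(candidate_size) && candidate_size < 1) {
    stopf("candidate_size must be >= 1 when set")
  }
  structure(list(max_parents = max_parents, candidate_size = candidate_size,
                 tie_break = "lexicographic", rng_seed = as.integer(rng_seed)),
            class = "SearchConfig")
}

#' Log BDe family score
#'
#' Log marginal likelihood of one child variable given its parents under a
#' Dirichlet prior with total pseudo-count `ess` split uniformly over the
#' `q x r` parent-configuration x child-state cells:
#' `sum_j [lgamma(a_j) - lgamma(a_j + N_j)] +
#'  sum_jk [lgamma(a_jk + N_jk) - lgamma(a_jk)]`
#' with `a_j = ess / q`, `a_jk = ess / (q r)`.
#'
#' @param child Gene ID of the child variable.
#' @param parents Character vector of parent gene IDs (possibly empty).
#' @param d A [discrete_matrix()] (genes x samples).
#' @param cfg A [bde_config()].
#' @return Log score (<= 0 for non-empty data).
#' @export
bde_family_score <- function(child, parents, d, cfg = bde_config(levels = d$levels)) {
  if (cfg$ess <= 0) stopf("ess must be positive")
  S <- d$states
  bad <- setdiff(c(child, parents), rownames(S))
  if (length(bad)) stopf("unknown gene: %s", bad[[1L]])
  r <- cfg$levels
  q <- r^length(parents)
  n_samp <- ncol(S)
  if (n_samp == 0L) return(0)
  x <- S[child, ]
  j <- if (length(parents)) {
    pa <- S[parents, , drop = FALSE]
    as.vector(1 + colSums(pa * r^(seq_along(parents) - 1L)))
  } else {
    rep(1, n_samp)
  }
  aj <- cfg$ess / q
  ajk <- cfg$ess / (q * r)
  counts <- table(j, factor(x, levels = 0:(r - 1L)))
  Nj <- rowSums(counts)
  # unobserved parent configurations contribute zero and are omitted
  sum(lgamma(aj) - lgamma(aj + Nj)) +
    sum(lgamma(ajk + counts) - lgamma(ajk))
}

# Family-score memo keyed by child + sorted parent set.
make_fscore <- function(d, cfg) {
  memo <- new.env(parent = emptyenv())
  function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = "|"), sep = "::")
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- bde_family_score(child, parents, d, cfg)
    memo[[key]] <- v
    v
  }
}

# Is there a directed path from `a` to `b` in the parent-set graph?
has_path <- function(parent_sets, children, a, b) {
  if (a == b) return(TRUE)
  stack <- a
  visited <- character(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v %in% visited) next
    visited <- c(visited, v)
    ch <- children[[v]]
    if (b %in% ch) return(TRUE)
    stack <- c(stack, ch)
  }
  FALSE
}

#' Greedy hill-climbing structure search
#'
#' Steepest-ascent search over DAGs, starting from the empty graph. At each
#' step all acyclicity-preserving single-edge additions, deletions and
#' reversals (respecting `max_parents` and candidate sets) are evaluated and
#' the highest-scoring strictly improving move is applied; ties are broken
#' lexicographically on (move type, source, target) so runs are
#' reproducible. Stops at a local optimum.
#'
#' @param d A [discrete_matrix()] (genes x samples).
#' @param bde A [bde_config()]; `levels` must match `d`.
#' @param search A [search_config()].
#' @param candidates Optional precomputed candidate map (as returned by
#'   [sparse_candidate_select()]); computed from `search$candidate_size`
#'   when that is set.
#' @return A [dag_structure()] with its total log BDe score.
#' @export
greedy_hill_climb <- function(d, bde = bde_config(levels = d$levels),
                              search = search_config(), candidates = NULL) {
  if (bde$levels != d$levels) {
    stopf("bde$levels (%d) must match the matrix levels (%d)", bde$levels, d$levels)
  }
  genes <- sort(rownames(d$states))
  n <- length(genes)
  fscore <- make_fscore(d, bde)
  parents <- stats::setNames(rep(list(character(0)), n), genes)
  fam <- vapply(genes, function(g) fscore(g, character(0)), numeric(1L))
  if (n < 2L) {
    return(dag_structure(rownames(d$states), parents[rownames(d$states)],
                         score = sum(fam)))
  }
  if (is.null(candidates) && !is.null(search$candidate_size)) {
    candidates <- sparse_candidate_select(d, search$candidate_size)
  }
  children <- stats::setNames(rep(list(character(0)), n), genes)
  eps <- 1e-9
  repeat {
    best_delta <- eps
    best_move <- NULL
    # additions u -> v, scanned in (source, target) order for the tie-break
    for (u in genes) {
      for (v in genes) {
        if (u == v) next
        pav <- parents[[v]]
        if (u %in% pav) next
        if (!is.null(search$max_parents) && length(pav) >= search$max_parents) next
        if (!is.null(candidates) && !(u %in% candidates[[v]])) next
        if (has_path(parents, children, v, u)) next  # u -> v would close a cycle
        delta <- fscore(v, c(pav, u)) - fam[[v]]
        if (delta > best_delta) {
          best_delta <- delta
          best_move <- list(type = "add", u = u, v = v)
        }
      }
    }
    # deletions u -> v
    for (u in genes) {
      for (v in sort(children[[u]])) {
        delta <- fscore(v, setdiff(parents[[v]], u)) - fam[[v]]
        if (delta > best_delta) {
          best_delta <- delta
          best_move <- list(type = "delete", u = u, v = v)
        }
      }
    }
    # reversals u -> v  becomes  v -> u
    for (u in genes) {
      for (v in sort(children[[u]])) {
        if (!is.null(search$max_parents) &&
            length(parents[[u]]) >= search$max_parents) next
        if (!is.null(candidates) && !(v %in% candidates[[u]])) next
        # after removing u -> v, any remaining path u ~> v would close a cycle
        tmp_children <- children
        tmp_children[[u]] <- setdiff(tmp_children[[u]], v)
        if (has_path(parents, tmp_children, u, v)) next
        delta <- (fscore(v, setdiff(parents[[v]], u)) - fam[[v]]) +
          (fscore(u, c(parents[[u]], v)) - fam[[u]])
        if (delta > best_delta) {
          best_delta <- delta
          best_move <- list(type = "reverse", u = u, v = v)
        }
      }
    }
    if (is.null(best_move)) break
    u <- best_move$u
    v <- best_move$v
    if (best_move$type == "add") {
      parents[[v]] <- c(parents[[v]], u)
      children[[u]] <- c(children[[u]], v)
    } else if (best_move$type == "delete") {
      parents[[v]] <- setdiff(parents[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
    } else {
      parents[[v]] <- setdiff(parents[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
      parents[[u]] <- c(parents[[u]], v)
      children[[v]] <- c(children[[v]], u)
      fam[[u]] <- fscore(u, parents[[u]])
    }
    fam[[v]] <- fscore(v, parents[[v]])
  }
  dag_structure(rownames(d$states), parents[rownames(d$states)],
                score = sum(fam))
}

# Empirical mutual information between two discrete vectors.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  if (n == 0L) return(0)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

#' Sparse-candidate parent selection
#'
#' For each node, selects the `c` other nodes with the highest empirical
#' pairwise mutual information as its only permitted parents during hill
#' climbing. Ties are broken by gene ID order.
#'
#' @param d A [discrete_matrix()].
#' @param c Candidate-set size (>= 1). Five is the size at which restricted
#'   search comes closest to unrestricted hill climbing on yeast data.
#' @return Named list mapping each gene to its candidate parents.
#' @export
sparse_candidate_select <- function(d, c = 5) {
  if (c < 1) stopf("candidate size must be >= 1")
  genes <- sort(rownames(d$states))
  n <- length(genes)
  if (c >= n) {
    warnf("candidate size %d >= node count %d; all other nodes are candidates",
          c, n)
    c <- n - 1L
  }
  mi <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- mutual_information(d$states[genes[i], ], d$states[genes[j], ])
    mi[i, j] <- v
    mi[j, i] <- v
  }
  out <- lapply(genes, function(g) {
    others <- setdiff(genes, g)
    others[order(-mi[g, others], others)][seq_len(c)]
  })
  stats::setNames(out, genes)
}

#' Learn one Bayesian-network subnetwork per bicluster
#'
#' Each bicluster's submatrix (its genes over its conditions) is
#' equal-frequency discretized and a DAG is learned by
#' [greedy_hill_climb()]. Biclusters with fewer than two conditions yield
#' an empty DAG with a warning; biclusters with fewer than `3 * levels`
#' conditions trigger a small-sample warning.
#'
#' @param m An `ExpressionMatrix` with no missing values.
#' @param s A `BiclusterSet` resolvable in `m`.
#' @param pre A [preprocess_config()] (supplies the discretization levels).
#' @param bde A [bde_config()].
#' @param search A [search_config()].
#' @return List of `DAGStructure`, one per bicluster, in bicluster order.
#' @export
learn_subnetworks <- function(m, s, pre = preprocess_config(),
                              bde = bde_config(levels = pre$discretization_levels),
                              search = search_config()) {
  lapply(seq_along(s$biclusters), function(i) {
    b <- s$biclusters[[i]]
    check_bicluster_ids(b, m)
    if (length(b$conditions) < 2L) {
      warnf("bicluster %d has < 2 conditions; empty subnetwork", i)
      return(dag_structure(b$genes, score = 0))
    }
    if (length(b$conditions) < 3L * bde$levels) {
      warnf("bicluster %d has only %d conditions for %d levels (small sample)",
            i, length(b$conditions), bde$levels)
    }
    sub <- expression_matrix(m$values[b$genes, b$conditions, drop = FALSE])
    if (anyNA(sub$values)) {
      stopf("bicluster %d submatrix has missing values; impute first", i)
    }
    dm <- discretize_quantile(sub, bde$levels)
    greedy_hill_climb(dm, bde, search)
  })
}

#' Directed gene network
#'
#' @param edges Two-column character matrix or data frame of directed edges
#'   (from, to). Duplicates are removed, the result sorted.
#' @param genes Gene universe (defaults to the union of edge endpoints).
#' @return A `GeneNetwork`: list with `edges` (two-column matrix) and
#'   `genes`.
#' @export
gene_network <- function(edges, genes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L) stopf("edges must have two columns")
  if (!length(edges)) edges <- matrix(character(0), 0L, 2L)
  mode(edges) <- "character"
  colnames(edges) <- c("from", "to")
  if (any(edges[, 1L] == edges[, 2L])) stopf("self-edges are not allowed")
  if (is.null(genes)) genes <- unique(as.vector(edges))
  genes <- unique(as.character(genes))
  bad <- setdiff(as.vector(edges), genes)
  if (length(bad)) stopf("edge endpoint outside gene universe: %s", bad[[1L]])
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(list(edges = edges, genes = sort(genes)), class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d directed edges over %d genes\n",
              nrow(x$edges), length(x$genes)))
  invisible(x)
}

#' Merge learned subnetworks into one directed network
#'
#' Takes the union of all directed edges (each parent contributes an edge
#' parent -> child), removes duplicates, and pools all nodes into the gene
#' universe.
#'
#' @param dags List of `DAGStructure` objects.
#' @return A [gene_network()].
#' @export
merge_subnetworks <- function(dags) {
  edges <- do.call(rbind, lapply(dags, dag_edges))
  genes <- unique(unlist(lapply(dags, `[[`, "nodes")))
  if (is.null(edges)) edges <- matrix(character(0), 0L, 2L)
  gene_network(edges, genes %||% character(0))
}

#' Read a network file (SIF or two-column TSV)
#'
#' SIF lines are `source relation target`; TSV lines are `source<TAB>target`
#' (a single space also accepted). With `directed = FALSE` every record
#' expands to both orientations. Self-edges are skipped with a warning.
#'
#' @param path File path.
#' @param directed Is the file a directed edge list?
#' @return A [gene_network()].
#' @export
read_network <- function(path, directed = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  from <- character(0)
  to <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || grepl("^#", ln)) next
    f <- strsplit(ln, "[\t ]+")[[1L]]
    if (length(f) == 2L) {
      a <- f[[1L]]
      b <- f[[2L]]
    } else if (length(f) == 3L) {
      a <- f[[1L]]
      b <- f[[3L]]
    } else {
      stopf("malformed network line %d: %d fields", i, length(f))
    }
    if (a == b) {
      warnf("self-edge %s-%s at line %d skipped", a, b, i)
      next
    }
    from <- c(from, a)
    to <- c(to, b)
  }
  if (!directed) {
    tmp <- from
    from <- c(from, to)
    to <- c(to, tmp)
  }
  gene_network(cbind(from, to))
}

#' Write a network as two-column TSV or SIF
#'
#' @param net A `GeneNetwork`.
#' @param path Output path.
#' @param format `"tsv"` (source<TAB>target) or `"sif"`
#'   (`source pd target`).
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  e <- net$edges
  lines <- if (format == "tsv") {
    paste(e[, 1L], e[, 2L], sep = "\t")
  } else {
    paste(e[, 1L], "pd", e[, 2L])
  }
  writeLines(lines, path)
  invisible(path)
}
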