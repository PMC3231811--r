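#' Specification of a synthetic expression matrix with planted biclusters
#'
#' @param n_genes,n_conditions Matrix dimensions.
#' @param noise_sd Standard deviation of the Gaussian background.
#' @param missing_fraction Fraction of cells masked at random, in `[0, 1]`.
#' @param blocks List of planted blocks, each
#'   `list(n_genes =, n_conditions =, pattern =, amplitude =)` with pattern
#'   one of `"constant"`, `"additive"`, `"order_preserving"`. Defaults to
#'   three 15 x 10 modules, one per pattern, amplitude 4 (i.e. 4 background
#'   standard deviations) -- a recoverable target for each implemented
#'   algorithm family.
#' @param rng_seed RNG seed.
#' @export
plant_spec <- function(n_genes = 100, n_conditions = 40, noise_sd = 1,
                       missing_fraction = 0,
                       blocks = list(
                         list(n_genes = 15, n_conditions = 10,
                              pattern = "constant", amplitude = 4),
                         list(n_genes = 15, n_conditions = 10,
                              pattern = "additive", amplitude = 4),
                         list(n_genes = 15, n_conditions = 10,
                              pattern = "order_preserving", amplitude = 4)),
                       rng_seed = 1L) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (missing_fraction < 0 || missing_fraction > 1) {
    stopf("missing_fraction must lie in [0, 1]")
  }
  for (b in blocks) {
    if (!b$pattern %in% c("constant", "additive", "order_preserving")) {
      stopf("unknown block pattern: %s", b$pattern)
    }
    if (b$n_genes > n_genes || b$n_conditions > n_conditions) {
      stopf("block (%d x %d) exceeds matrix bounds (%d x %d)",
            b$n_genes, b$n_conditions, n_genes, n_conditions)
    }
    if (!is.finite(b$amplitude)) stopf("block amplitude must be finite")
  }
  if (sum(vapply(blocks, `[[`, numeric(1L), "n_genes")) > n_genes) {
    stopf("planted blocks need more genes than the matrix has")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 noise_sd = noise_sd, missing_fraction = missing_fraction,
                 blocks = blocks, rng_seed = as.integer(rng_seed)),
            class = "PlantSpec")
}

#' Simulate an expression matrix with planted biclusters
#'
#' Gaussian background noise with non-overlapping gene blocks overlaid:
#' `constant` adds `amplitude` to every block cell; `additive` adds random
#' row and column effects drawn uniformly from `[-amplitude, amplitude]`;
#' `order_preserving` replaces block cells with values strictly increasing
#' along a hidden permutation of the block's conditions. Cells are then
#' masked missing uniformly at random.
#'
#' @param spec A [plant_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (a [bicluster_set()] of the planted blocks, `source` = pattern name).
#' @export
simulate_expression <- function(spec = plant_spec()) {
  ng <- spec$n_genes
  nc <- spec$n_conditions
  genes <- sprintf("g%03d", seq_len(ng))
  conds <- sprintf("c%02d", seq_len(nc))
  truth <- list()
  with_rng(spec$rng_seed, {
    V <- matrix(stats::rnorm(ng * nc, 0, spec$noise_sd), ng, nc,
                dimnames = list(genes, conds))
    free_genes <- sample.int(ng)  # blocks take disjoint gene slices
    offset <- 0L
    for (bi in seq_along(spec$blocks)) {
      b <- spec$blocks[[bi]]
      gi <- sort(free_genes[offset + seq_len(b$n_genes)])
      offset <- offset + b$n_genes
      ci <- sort(sample.int(nc, b$n_conditions))
      if (b$pattern == "constant") {
        V[gi, ci] <- V[gi, ci] + b$amplitude
      } else if (b$pattern == "additive") {
        re <- stats::runif(length(gi), -b$amplitude, b$amplitude)
        ce <- stats::runif(length(ci), -b$amplitude, b$amplitude)
        V[gi, ci] <- V[gi, ci] + outer(re, ce, `+`)
      } else {
        hidden <- sample(ci)  # hidden column order
        base <- stats::rnorm(length(gi), 0, spec$noise_sd)
        for (kk in seq_along(hidden)) {
          V[gi, hidden[kk]] <- base + b$amplitude * kk / length(hidden)
        }
      }
      truth[[bi]] <- bicluster(genes[gi], conds[ci], source = b$pattern)
    }
    if (spec$missing_fraction > 0) {
      mask <- stats::runif(ng * nc) < spec$missing_fraction
      # keep at least one observed value per gene so imputation is defined
      for (i in seq_len(ng)) {
        row_idx <- i + ng * (seq_len(nc) - 1L)
        if (all(mask[row_idx])) mask[row_idx[1L]] <- FALSE
      }
      V[matrix(mask, ng, nc)] <- NA_real_
    }
  })
  list(matrix = expression_matrix(V), truth = bicluster_set(truth, c(ng, nc)))
}

#' Specification of a planted discrete Bayesian network
#'
#' @param n_nodes Number of variables.
#' @param edge_probability Probability of each forward edge in a random
#'   topological order, in (0, 1) (0 allowed for the degenerate empty DAG).
#' @param levels States per variable (>= 2).
#' @param n_samples Number of ancestral samples to draw.
#' @param rng_seed RNG seed.
#' @export
planted_bn <- function(n_nodes = 3, edge_probability = 0.5, levels = 3,
                       n_samples = 500, rng_seed = 1L) {
  if (edge_probability < 0 || edge_probability >= 1) {
    stopf("edge_probability must lie in [0, 1)")
  }
  if (levels < 2) stopf("levels must be >= 2")
  if (n_samples < 1) stopf("n_samples must be >= 1")
  structure(list(n_nodes = as.integer(n_nodes),
                 edge_probability = edge_probability,
                 levels = as.integer(levels),
                 n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "PlantedBN")
}

#' Simulate a random discrete Bayesian network and samples from it
#'
#' Draws a random DAG (edges kept with `edge_probability`, oriented forward
#' along a random node order, so the graph is acyclic by construction),
#' conditional probability tables from a symmetric Dirichlet(1), and
#' `n_samples` ancestral samples.
#'
#' @param p A [planted_bn()].
#' @param structure Optional `DAGStructure` to plant instead of a random
#'   graph (its node count must equal `p$n_nodes`); CPTs and samples are
#'   still drawn at random.
#' @return List with `dag` (the truth `DAGStructure`) and `data`
#'   (a [discrete_matrix()], nodes x samples).
#' @export
simulate_bn_data <- function(p = planted_bn(), structure = NULL) {
  nodes <- if (is.null(structure)) {
    sprintf("G%02d", seq_len(p$n_nodes))
  } else {
    if (length(structure$nodes) != p$n_nodes) {
      stopf("structure has %d nodes; expected %d", length(structure$nodes),
            p$n_nodes)
    }
    structure$nodes
  }
  r <- p$levels
  with_rng(p$rng_seed, {
    if (is.null(structure)) {
      ord <- sample(nodes)
      parents <- stats::setNames(rep(list(character(0)), p$n_nodes), nodes)
      for (i in seq_along(ord)) {
        if (i == 1L) next
        prev <- ord[seq_len(i - 1L)]
        keep <- stats::runif(length(prev)) < p$edge_probability
        parents[[ord[i]]] <- prev[keep]
      }
    } else {
      parents <- structure$parent_sets
      ord <- topological_order(structure)
    }
    # CPTs: one Dirichlet(1) row per parent configuration
    cpts <- lapply(nodes, function(v) {
      q <- r^length(parents[[v]])
      g <- matrix(stats::rgamma(q * r, 1), q, r)
      g / rowSums(g)
    })
    names(cpts) <- nodes
    S <- matrix(0L, p$n_nodes, p$n_samples,
                dimnames = list(nodes, sprintf("s%04d", seq_len(p$n_samples))))
    for (s in seq_len(p$n_samples)) {
      for (v in ord) {
        pa <- parents[[v]]
        j <- if (length(pa)) {
          1 + sum(S[pa, s] * r^(seq_along(pa) - 1L))
        } else 1
        S[v, s] <- sample.int(r, 1L, prob = cpts[[v]][j, ]) - 1L
      }
    }
  })
  list(dag = dag_structure(nodes, parents),
       data = discrete_matrix(S, r))
}

#' Random DAG over given nodes
#'
#' Samples a random topological order and keeps each forward edge with
#' probability `edge_probability`, so the result is acyclic by construction.
#'
#' @param nodes Character vector of node IDs.
#' @param edge_probability Probability of each forward edge.
#' @param rng_seed RNG seed.
#' @return A [dag_structure()].
#' @export
random_dag <- function(nodes, edge_probability = 0.3, rng_seed = 1L) {
  nodes <- as.character(nodes)
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  with_rng(rng_seed, {
    ord <- sample(nodes)
    for (i in seq_along(ord)) {
      if (i == 1L) next
      prev <- ord[seq_len(i - 1L)]
      keep <- stats::runif(length(prev)) < edge_probability
      parents[[ord[i]]] <- prev[keep]
    }
  })
  dag_structure(nodes, parents)
}

#' Simulate a gold-standard network and module annotations
#'
#' The gold network is the union of the truth DAGs' edges plus random
#' distractor edges. Annotations attach `terms_per_module` synthetic terms
#' to every gene of each module (each truth DAG is one module), plus one
#' uniform background term per population gene.
#'
#' @param truth_dags List of `DAGStructure` objects (the planted modules).
#' @param extra_edges Number of random distractor edges added to the gold
#'   network.
#' @param terms_per_module Synthetic terms annotating each module.
#' @param rng_seed RNG seed.
#' @param population Gene universe for the annotation map; defaults to the
#'   union of module genes.
#' @param n_background_terms Number of background terms spread uniformly
#'   over the population.
#' @return List with `gold` (a [gene_network()], both orientations of every
#'   interaction) and `annotations` (an [annotation_map()]).
#' @export
simulate_gold_and_annotations <- function(truth_dags, extra_edges = 0,
                                          terms_per_module = 1,
                                          rng_seed = 1L,
                                          population = NULL,
                                          n_background_terms = 5) {
  merged <- merge_subnetworks(truth_dags)
  if (is.null(population)) population <- merged$genes
  population <- sort(unique(as.character(population)))
  genes_pairs <- character(0)
  with_rng(rng_seed, {
    edges <- merged$edges
    # undirected gold: include both orientations of every truth edge
    edges <- rbind(edges, edges[, 2:1, drop = FALSE])
    if (extra_edges > 0) {
      have <- c(paste(edges[, 1L], edges[, 2L], sep = "\r"))
      added <- 0L
      while (added < extra_edges) {
        ab <- sample(population, 2L)
        k1 <- paste(ab[1L], ab[2L], sep = "\r")
        if (k1 %in% have) next
        edges <- rbind(edges, c(ab[1L], ab[2L]), c(ab[2L], ab[1L]))
        have <- c(have, k1, paste(ab[2L], ab[1L], sep = "\r"))
        added <- added + 1L
      }
    }
    pairs_g <- character(0)
    pairs_t <- character(0)
    for (mi in seq_along(truth_dags)) {
      for (ti in seq_len(terms_per_module)) {
        tm <- sprintf("MOD%02d_T%d", mi, ti)
        pairs_g <- c(pairs_g, truth_dags[[mi]]$nodes)
        pairs_t <- c(pairs_t, rep(tm, length(truth_dags[[mi]]$nodes)))
      }
    }
    bg <- sprintf("BG_T%d", sample.int(n_background_terms, length(population),
                                       replace = TRUE))
    pairs_g <- c(pairs_g, population)
    pairs_t <- c(pairs_t, bg)
    genes_pairs <- data.frame(gene = pairs_g, term = pairs_t)
    gold <- gene_network(edges, population)
  })
  list(gold = gold, annotations = annotation_map(genes_pairs, population))
}

#' Simulate a complete synthetic study
#'
#' Bundles the generators into one coherent fixture: an expression matrix
#' with planted modules, one random truth DAG per module, a gold-standard
#' network (both orientations of every truth edge plus distractors), and
#' module-structured annotations over all matrix genes.
#'
#' @param spec A [plant_spec()].
#' @param module_edge_probability Edge probability of each module's truth
#'   DAG.
#' @param extra_edges Distractor interactions added to the gold network.
#' @param terms_per_module Synthetic terms annotating each module.
#' @param rng_seed RNG seed (also seeds `spec` unless that was built with
#'   an explicit seed different from its default).
#' @return List with `matrix`, `truth` (planted biclusters), `truth_dags`,
#'   `gold`, `annotations`.
#' @export
simulate_study <- function(spec = NULL, module_edge_probability = 0.3,
                           extra_edges = 50, terms_per_module = 1,
                           rng_seed = 1L) {
  if (is.null(spec)) spec <- plant_spec(rng_seed = rng_seed)
  sim <- simulate_expression(spec)
  truth_dags <- lapply(seq_along(sim$truth$biclusters), function(i) {
    random_dag(sim$truth$biclusters[[i]]$genes, module_edge_probability,
               rng_seed = rng_seed + i)
  })
  ga <- simulate_gold_and_annotations(truth_dags, extra_edges = extra_edges,
                                      terms_per_module = terms_per_module,
                                      rng_seed = rng_seed + 1000L,
                                      population = gene_ids(sim$matrix))
  list(matrix = sim$matrix, truth = sim$truth, truth_dags = truth_dags,
       gold = ga$gold, annotations = ga$annotations)
}

#' Degree-matched random baseline network
#'
#' Permutes the gene labels of a predicted network uniformly at random over
#' its universe, preserving the degree sequence and edge count exactly --
#' the null model used to judge whether a learned network carries signal.
#'
#' @param net A `GeneNetwork`.
#' @param rng_seed RNG seed.
#' @return A `GeneNetwork` with the same universe and edge count.
#' @export
permute_network_labels <- function(net, rng_seed = 1L) {
  with_rng(rng_seed, {
    relabel <- stats::setNames(sample(net$genes), net$genes)
    edges <- cbind(unname(relabel[net$edges[, 1L]]),
                   unname(relabel[net$edges[, 2L]]))
  })
  gene_network(edges, net$genes)
}
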