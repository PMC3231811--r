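#' Bicluster and bicluster-set containers
#'
#' A bicluster is a subset of genes showing a coherent expression pattern
#' over a subset of conditions. A `BiclusterSet` is the ordered output of one
#' biclustering run and is the unit of comparison between algorithms.
#'
#' @param genes,conditions Non-empty character vectors of identifiers.
#' @param source Name of the producing algorithm.
#' @param score Optional algorithm-specific score (e.g. mean squared residue).
#' @return A `Bicluster` list.
#' @export
bicluster <- function(genes, conditions, source = "manual", score = NA_real_) {
  genes <- as.character(genes)
  conditions <- as.character(conditions)
  if (!length(genes)) stopf("bicluster gene set may not be empty")
  if (!length(conditions)) stopf("bicluster condition set may not be empty")
  if (anyDuplicated(genes) || anyDuplicated(conditions)) {
    stopf("bicluster members must be unique")
  }
  structure(list(genes = genes, conditions = conditions,
                 source = source, score = score),
            class = "Bicluster")
}

#' @rdname bicluster
#' @param biclusters List of `Bicluster` objects (possibly empty).
#' @param matrix_shape Integer vector `c(n_genes, n_conditions)` of the
#'   source matrix.
#' @export
bicluster_set <- function(biclusters, matrix_shape) {
  matrix_shape <- as.integer(matrix_shape)
  if (length(matrix_shape) != 2L || any(matrix_shape < 1L)) {
    stopf("matrix_shape must be two positive integers")
  }
  if (!all(vapply(biclusters, inherits, logical(1L), "Bicluster"))) {
    stopf("all elements must be Bicluster objects")
  }
  structure(list(biclusters = biclusters, matrix_shape = matrix_shape),
            class = "BiclusterSet")
}

#' @export
length.BiclusterSet <- function(x) length(x$biclusters)

#' @export
print.BiclusterSet <- function(x, ...) {
  src <- unique(vapply(x$biclusters, `[[`, character(1L), "source"))
  cat(sprintf("BiclusterSet: %d biclusters (%s) from a %d x %d matrix\n",
              length(x$biclusters),
              if (length(src)) paste(src, collapse = ", ") else "empty",
              x$matrix_shape[1L], x$matrix_shape[2L]))
  invisible(x)
}

check_bicluster_ids <- function(b, m) {
  bad <- setdiff(b$genes, gene_ids(m))
  if (length(bad)) stopf("unknown gene ID in bicluster: %s", bad[[1L]])
  bad <- setdiff(b$conditions, condition_ids(m))
  if (length(bad)) stopf("unknown condition ID in bicluster: %s", bad[[1L]])
  invisible(TRUE)
}

#' Mean squared residue of a bicluster
#'
#' Cheng-Church coherence score: the mean over the submatrix of
#' `(x_ij - rowmean_i - colmean_j + mean)^2`. Zero for constant and purely
#' additive (row effect + column effect) submatrices.
#'
#' @param m An `ExpressionMatrix`.
#' @param b A [bicluster()] indexable in `m`.
#' @return Non-negative scalar.
#' @export
mean_squared_residue <- function(m, b) {
  check_bicluster_ids(b, m)
  sub <- m$values[b$genes, b$conditions, drop = FALSE]
  if (anyNA(sub)) stopf("missing values inside bicluster submatrix")
  msr_of(sub)
}

msr_of <- function(sub) {
  res <- sub - outer(rowMeans(sub), colMeans(sub), `+`) + mean(sub)
  mean(res^2)
}

# Per-row / per-column mean squared residues of a submatrix.
msr_parts <- function(sub) {
  res <- sub - outer(rowMeans(sub), colMeans(sub), `+`) + mean(sub)
  res2 <- res^2
  list(msr = mean(res2), row = rowMeans(res2), col = colMeans(res2))
}

#' Cheng-Church parameters
#'
#' Defaults follow the settings commonly used for yeast stress/cell-cycle
#' compendia: `delta = 0.5` (maximum accepted score), `alpha = 1.2` (scaling
#' factor for multiple node deletion) and 100 biclusters.
#'
#' @param delta Maximum accepted mean squared residue (>= 0).
#' @param alpha Multiple-deletion scaling factor (>= 1).
#' @param n_biclusters Number of biclusters to extract.
#' @param rng_seed Seed for the random masking of extracted biclusters.
#' @export
cc_params <- function(delta = 0.5, alpha = 1.2, n_biclusters = 100,
                      rng_seed = 1L) {
  if (delta < 0) stopf("delta must be >= 0")
  if (alpha < 1) stopf("alpha must be >= 1")
  if (n_biclusters < 0) stopf("n_biclusters must be >= 0")
  structure(list(delta = delta, alpha = alpha,
                 n_biclusters = as.integer(n_biclusters),
                 rng_seed = as.integer(rng_seed)),
            class = "CCParams")
}

cc_find_one <- function(V, delta, alpha) {
  I <- seq_len(nrow(V))
  J <- seq_len(ncol(V))
  # multiple node deletion
  repeat {
    p <- msr_parts(V[I, J, drop = FALSE])
    if (p$msr <= delta) break
    changed <- FALSE
    drop_r <- which(p$row > alpha * p$msr)
    if (length(drop_r) && length(I) - length(drop_r) >= 2L) {
      I <- I[-drop_r]
      changed <- TRUE
      p <- msr_parts(V[I, J, drop = FALSE])
      if (p$msr <= delta) break
    }
    drop_c <- which(p$col > alpha * p$msr)
    if (length(drop_c) && length(J) - length(drop_c) >= 2L) {
      J <- J[-drop_c]
      changed <- TRUE
    }
    if (!changed) break
  }
  # single node deletion
  repeat {
    p <- msr_parts(V[I, J, drop = FALSE])
    if (p$msr <= delta) break
    if (length(I) <= 1L && length(J) <= 1L) break
    ri <- if (length(I) > 1L) max(p$row) else -Inf
    cj <- if (length(J) > 1L) max(p$col) else -Inf
    if (ri >= cj) I <- I[-which.max(p$row)] else J <- J[-which.max(p$col)]
  }
  # node addition: add rows/columns whose residue does not exceed the MSR;
  # a batch is kept only if the overall MSR does not increase, so the
  # delta bound reached by deletion is preserved
  repeat {
    changed <- FALSE
    p <- msr_parts(V[I, J, drop = FALSE])
    outJ <- setdiff(seq_len(ncol(V)), J)
    if (length(outJ)) {
      sub <- V[I, J, drop = FALSE]
      rm_ <- rowMeans(sub)
      cand <- V[I, outJ, drop = FALSE]
      cm_ <- colMeans(cand)
      am <- mean(sub)
      res2 <- (cand - outer(rm_, cm_, `+`) + am)^2
      add <- outJ[colMeans(res2) <= p$msr]
      if (length(add)) {
        Jnew <- sort(c(J, add))
        if (msr_of(V[I, Jnew, drop = FALSE]) <= p$msr + 1e-12) {
          J <- Jnew
          changed <- TRUE
          p <- msr_parts(V[I, J, drop = FALSE])
        }
      }
    }
    outI <- setdiff(seq_len(nrow(V)), I)
    if (length(outI)) {
      sub <- V[I, J, drop = FALSE]
      cm_ <- colMeans(sub)
      cand <- V[outI, J, drop = FALSE]
      rm_ <- rowMeans(cand)
      am <- mean(sub)
      res2 <- (cand - outer(rm_, cm_, `+`) + am)^2
      add <- outI[rowMeans(res2) <= p$msr]
      if (length(add)) {
        Inew <- sort(c(I, add))
        if (msr_of(V[Inew, J, drop = FALSE]) <= p$msr + 1e-12) {
          I <- Inew
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  list(rows = I, cols = J, msr = msr_of(V[I, J, drop = FALSE]))
}

#' Cheng-Church biclustering
#'
#' Greedy node-deletion/addition search for low mean-squared-residue
#' submatrices. After each bicluster is reported its cells are masked with
#' independent uniform random values over the matrix's observed range, so
#' subsequent iterations discover different biclusters.
#'
#' @param m An `ExpressionMatrix` with no missing values.
#' @param params A [cc_params()].
#' @return A [bicluster_set()]; every bicluster has
#'   `mean_squared_residue <= delta`.
#' @export
cc_bicluster <- function(m, params = cc_params()) {
  V <- m$values
  if (anyNA(V)) stopf("missing values present; run knn_impute() first")
  if (nrow(V) < 2L || ncol(V) < 2L) stopf("matrix must be at least 2 x 2")
  out <- vector("list", params$n_biclusters)
  with_rng(params$rng_seed, {
    lo <- min(V)
    hi <- max(V)
    W <- V
    for (b in seq_len(params$n_biclusters)) {
      f <- cc_find_one(W, params$delta, params$alpha)
      out[[b]] <- bicluster(rownames(V)[f$rows], colnames(V)[f$cols],
                            source = "CC", score = f$msr)
      W[f$rows, f$cols] <- stats::runif(length(f$rows) * length(f$cols), lo, hi)
    }
  })
  bicluster_set(out, dim(V))
}

#' ISA parameters
#'
#' Defaults follow the usual yeast settings: gene and condition thresholds
#' of 2.0 and 500 random seeds.
#'
#' @param t_g,t_c Gene / condition z-score thresholds (> 0).
#' @param n_seeds Number of random gene seeds.
#' @param rng_seed RNG seed.
#' @param max_iter Iteration cap per seed.
#' @param dedup_jaccard Gene-set Jaccard threshold above which converged
#'   modules are considered duplicates (first kept).
#' @param seed_size Genes per random seed.
#' @export
isa_params <- function(t_g = 2, t_c = 2, n_seeds = 500, rng_seed = 1L,
                       max_iter = 100, dedup_jaccard = 0.9, seed_size = 5) {
  if (t_g <= 0 || t_c <= 0) stopf("thresholds t_g and t_c must be positive")
  if (n_seeds < 1) stopf("n_seeds must be >= 1")
  if (dedup_jaccard <= 0 || dedup_jaccard > 1) {
    stopf("dedup_jaccard must lie in (0, 1]")
  }
  structure(list(t_g = t_g, t_c = t_c, n_seeds = as.integer(n_seeds),
                 rng_seed = as.integer(rng_seed),
                 max_iter = as.integer(max_iter),
                 dedup_jaccard = dedup_jaccard,
                 seed_size = as.integer(seed_size)),
            class = "ISAParams")
}

# One ISA signature iteration: gene set -> (condition set, gene set).
# `orientation` (+1 up-modules, -1 down-modules) keeps the threshold sign
# consistent: conditions where the gene set is coherently shifted in the
# module's direction, then genes coherently shifted over those conditions.
# Magnitude-only thresholding would let the anticorrelated tail contaminate
# the module.
isa_step <- function(G, Er, Ec, t_g, t_c, orientation = 1) {
  zc <- orientation * colMeans(Er[G, , drop = FALSE]) * sqrt(length(G))
  C <- which(zc >= t_c)
  if (!length(C)) return(list(G = integer(0), C = integer(0)))
  zg <- orientation * rowMeans(Ec[, C, drop = FALSE]) * sqrt(length(C))
  list(G = which(zg >= t_g), C = C)
}

standardize_rows <- function(V) {
  s <- t(scale(t(V)))
  s[!is.finite(s)] <- 0
  s
}

standardize_cols <- function(V) {
  s <- scale(V)
  s[!is.finite(s)] <- 0
  s
}

#' Iterative Signature Algorithm biclustering
#'
#' From each random gene seed, alternates condition scoring (mean of
#' row-standardized values over the current genes, kept when the z-score
#' crosses `t_c`) and gene scoring (mean of column-standardized values over
#' the kept conditions, kept when the z-score crosses `t_g`) until the gene
#' set is a fixed point. Thresholds are applied sign-consistently: each seed
#' is iterated once seeking up-regulated modules and once seeking
#' down-regulated modules (the module's direction is recorded in `score`,
#' +1/-1). Converged non-empty modules are deduplicated by gene-set Jaccard
#' similarity.
#'
#' @param m An `ExpressionMatrix` with no missing values.
#' @param params An [isa_params()].
#' @return A [bicluster_set()] of converged transcription modules.
#' @export
isa_bicluster <- function(m, params = isa_params()) {
  V <- m$values
  if (anyNA(V)) stopf("missing values present; run knn_impute() first")
  Er <- standardize_rows(V)
  Ec <- standardize_cols(V)
  ng <- nrow(V)
  modules <- list()
  with_rng(params$rng_seed, {
    for (s in seq_len(params$n_seeds)) {
      seed_genes <- sort(sample.int(ng, min(params$seed_size, ng)))
      for (orientation in c(1, -1)) {  # up- and down-regulated modules
        G <- seed_genes
        converged <- FALSE
        C <- integer(0)
        for (it in seq_len(params$max_iter)) {
          st <- isa_step(G, Er, Ec, params$t_g, params$t_c, orientation)
          if (!length(st$G)) {
            G <- integer(0)
            break
          }
          if (identical(st$G, G)) {
            converged <- TRUE
            C <- st$C
            break
          }
          G <- st$G
        }
        if (converged && length(G) && length(C)) {
          modules[[length(modules) + 1L]] <-
            list(G = G, C = C, orientation = orientation)
        }
      }
    }
  })
  # deduplicate: keep the first of any pair with gene Jaccard >= threshold
  kept <- list()
  for (mod in modules) {
    dup <- any(vapply(kept, function(kk) {
      length(intersect(kk$G, mod$G)) / length(union(kk$G, mod$G)) >=
        params$dedup_jaccard
    }, logical(1L)))
    if (!dup) kept[[length(kept) + 1L]] <- mod
  }
  bcs <- lapply(kept, function(mod) {
    bicluster(rownames(V)[mod$G], colnames(V)[mod$C], source = "ISA",
              score = mod$orientation)  # score records module direction
  })
  bicluster_set(bcs, dim(V))
}

#' OPSM parameters
#'
#' @param l_models Number of best partial models carried per size.
#' @param min_columns Minimum number of matrix columns required (>= 2).
#' @export
opsm_params <- function(l_models = 100, min_columns = 2) {
  if (l_models < 1) stopf("l_models must be >= 1")
  if (min_columns < 2) stopf("min_columns must be >= 2")
  structure(list(l_models = as.integer(l_models),
                 min_columns = as.integer(min_columns)),
            class = "OPSMParams")
}

# Rows supporting a column sequence: strictly increasing ranks, where
# within-row ties are broken by column index (ties.method = "first").
opsm_support <- function(R, seq_cols) {
  ok <- rep(TRUE, nrow(R))
  for (i in seq_len(length(seq_cols) - 1L)) {
    ok <- ok & (R[, seq_cols[i]] < R[, seq_cols[i + 1L]])
  }
  which(ok)
}

#' Order-preserving submatrix biclustering
#'
#' Grows partial column orderings from all ordered pairs, keeping the
#' `l_models` best partial models per size (score = number of rows whose
#' values strictly increase along the ordering, within-row ties broken by
#' column index; model ties broken lexicographically). Each kept model is
#' grown by inserting an unused column at every position. One bicluster is
#' recorded per model size with at least two supporting rows, reported
#' largest-support first.
#'
#' @param m An `ExpressionMatrix` with no missing values.
#' @param params An [opsm_params()].
#' @return A [bicluster_set()]; each bicluster's conditions are stored in
#'   the model's column order.
#' @export
opsm_bicluster <- function(m, params = opsm_params()) {
  V <- m$values
  if (anyNA(V)) stopf("missing values present; run knn_impute() first")
  nc <- ncol(V)
  if (nc < params$min_columns) {
    stopf("matrix has %d columns; OPSM needs at least %d", nc,
          params$min_columns)
  }
  R <- matrix(0L, nrow(V), nc, dimnames = dimnames(V))
  for (i in seq_len(nrow(V))) R[i, ] <- rank(V[i, ], ties.method = "first")

  seq_key <- function(s) paste(sprintf("%06d", s), collapse = ",")

  # rank by support (desc), ties lexicographic on the column sequence
  take_top <- function(models, l) {
    key <- vapply(models, function(m) seq_key(m$seq), character(1L))
    dup <- duplicated(key)
    models <- models[!dup]
    key <- key[!dup]
    sup <- vapply(models, function(m) length(m$rows), integer(1L))
    models[order(-sup, key)][seq_len(min(l, length(models)))]
  }

  models <- list()
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    if (a == b) next
    rows <- which(R[, a] < R[, b])
    if (length(rows) >= 2L) {
      models[[length(models) + 1L]] <- list(seq = c(a, b), rows = rows)
    }
  }
  best_per_size <- list()
  while (length(models)) {
    models <- take_top(models, params$l_models)
    size <- length(models[[1L]]$seq)
    best_per_size[[as.character(size)]] <- models[[1L]]
    if (size == nc) break
    # grow each kept model by inserting an unused column at any position;
    # supporting rows shrink incrementally (only the two new comparisons
    # need checking)
    ext <- list()
    for (mdl in models) {
      s <- mdl$seq
      for (cnew in setdiff(seq_len(nc), s)) {
        for (pos in 0:length(s)) {
          rows <- mdl$rows
          if (pos > 0L) rows <- rows[R[rows, s[pos]] < R[rows, cnew]]
          if (pos < length(s)) rows <- rows[R[rows, cnew] < R[rows, s[pos + 1L]]]
          if (length(rows) >= 2L) {
            ext[[length(ext) + 1L]] <- list(
              seq = append(s, cnew, after = pos), rows = rows)
          }
        }
      }
    }
    models <- ext
  }
  bcs <- lapply(best_per_size, function(bm) {
    bicluster(rownames(V)[sort(bm$rows)], colnames(V)[bm$seq], source = "OPSM",
              score = length(bm$rows))
  })
  if (length(bcs)) {
    sup <- vapply(bcs, function(b) b$score, numeric(1L))
    sz <- vapply(bcs, function(b) length(b$conditions), numeric(1L))
    bcs <- bcs[order(-sup, sz)]
  }
  bicluster_set(unname(bcs), dim(V))
}

#' k-means parameters
#'
#' Defaults match common yeast practice: 100 clusters, 100 Lloyd iterations,
#' 10 random replicates, Euclidean distance.
#'
#' @param n_clusters Number of clusters (<= gene count).
#' @param n_iter Lloyd iterations per replicate.
#' @param n_replicates Random initializations; best within-cluster sum of
#'   squares kept.
#' @param distance Distance metric; only `"euclidean"` is supported.
#' @param rng_seed RNG seed.
#' @export
kmeans_params <- function(n_clusters = 100, n_iter = 100, n_replicates = 10,
                          distance = "euclidean", rng_seed = 1L) {
  distance <- match.arg(distance, "euclidean")
  if (n_clusters < 1) stopf("n_clusters must be >= 1")
  structure(list(n_clusters = as.integer(n_clusters),
                 n_iter = as.integer(n_iter),
                 n_replicates = as.integer(n_replicates),
                 distance = distance, rng_seed = as.integer(rng_seed)),
            class = "KMeansParams")
}

#' k-means gene clusters as biclusters
#'
#' Lloyd's algorithm on gene rows (Euclidean distance) with seeded random
#' restarts; each non-empty cluster becomes a bicluster spanning all
#' conditions.
#'
#' @param m An `ExpressionMatrix` with no missing values.
#' @param params A [kmeans_params()].
#' @return A [bicluster_set()] whose gene sets partition the genes.
#' @export
kmeans_as_biclusters <- function(m, params = kmeans_params()) {
  V <- m$values
  if (anyNA(V)) stopf("missing values present; run knn_impute() first")
  if (params$n_clusters > nrow(V)) {
    stopf("n_clusters (%d) exceeds gene count (%d)", params$n_clusters, nrow(V))
  }
  best <- NULL
  with_rng(params$rng_seed, {
    for (rep in seq_len(params$n_replicates)) {
      # replicates that fail (e.g. an empty cluster under Lloyd) are skipped;
      # quality is judged by the within-cluster sum of squares across replicates
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(V, centers = params$n_clusters,
                        iter.max = params$n_iter, nstart = 1L,
                        algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
  })
  if (is.null(best)) stopf("k-means failed in all %d replicates", params$n_replicates)
  bcs <- list()
  for (cl in sort(unique(best$cluster))) {
    g <- rownames(V)[best$cluster == cl]
    bcs[[length(bcs) + 1L]] <- bicluster(g, colnames(V), source = "kmeans")
  }
  bicluster_set(bcs, dim(V))
}

#' Read / write biclusters in plain-text interchange format
#'
#' Format: a header line `#source=<name>`, then for each bicluster two
#' lines (space-separated gene IDs, space-separated condition IDs) followed
#' by a blank line.
#'
#' @param path File path.
#' @param m The `ExpressionMatrix` against which identifiers are resolved.
#' @return A [bicluster_set()].
#' @export
import_external_biclusters <- function(path, m) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  src <- "external"
  if (length(lines) && grepl("^#source=", lines[[1L]])) {
    src <- sub("^#source=", "", lines[[1L]])
    lines <- lines[-1L]
  }
  lines <- sub("\\s+$", "", lines)
  bcs <- list()
  i <- 1L
  idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(lines[[i]])) {
      i <- i + 1L
      next
    }
    if (i + 1L > length(lines)) stopf("truncated bicluster record at line %d", i)
    idx <- idx + 1L
    g <- strsplit(lines[[i]], " +")[[1L]]
    cn <- strsplit(lines[[i + 1L]], " +")[[1L]]
    bad <- setdiff(g, gene_ids(m))
    if (length(bad)) {
      stopf("bicluster %d names unknown gene: %s", idx, bad[[1L]])
    }
    bad <- setdiff(cn, condition_ids(m))
    if (length(bad)) {
      stopf("bicluster %d names unknown condition: %s", idx, bad[[1L]])
    }
    bcs[[idx]] <- bicluster(g, cn, source = src)
    i <- i + 2L
  }
  bicluster_set(bcs, dim(m$values))
}

#' @rdname import_external_biclusters
#' @param s A `BiclusterSet` to write.
#' @param source Source name recorded in the header; defaults to the first
#'   bicluster's source.
#' @export
write_biclusters <- function(s, path, source = NULL) {
  if (is.null(source)) {
    source <- if (length(s$biclusters)) s$biclusters[[1L]]$source else "external"
  }
  out <- c(paste0("#source=", source))
  for (b in s$biclusters) {
    out <- c(out, paste(b$genes, collapse = " "),
             paste(b$conditions, collapse = " "), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Summary statistics of a bicluster set
#'
#' @param s A `BiclusterSet`.
#' @return List with `n_biclusters`, `min_dims`/`max_dims` (genes x
#'   conditions of the smallest/largest bicluster by cell count), and
#'   `gene_coverage` / `condition_coverage` (percent of matrix genes /
#'   conditions in the union of biclusters).
#' @export
bicluster_stats <- function(s) {
  if (!length(s$biclusters)) {
    return(list(n_biclusters = 0L, min_dims = NULL, max_dims = NULL,
                gene_coverage = 0, condition_coverage = 0))
  }
  dims <- vapply(s$biclusters,
                 function(b) c(length(b$genes), length(b$conditions)),
                 integer(2L))
  area <- dims[1L, ] * dims[2L, ]
  g_union <- unique(unlist(lapply(s$biclusters, `[[`, "genes")))
  c_union <- unique(unlist(lapply(s$biclusters, `[[`, "conditions")))
  list(n_biclusters = length(s$biclusters),
       min_dims = dims[, which.min(area)],
       max_dims = dims[, which.max(area)],
       gene_coverage = 100 * length(g_union) / s$matrix_shape[1L],
       condition_coverage = 100 * length(c_union) / s$matrix_shape[2L])
}
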