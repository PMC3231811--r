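#' Expression matrix with explicit missing values
#'
#' Container for a real-valued genes x conditions expression matrix
#' (log-ratio scale). Missing measurements are stored as `NA` in `values`;
#' the missing mask is available via [missing_mask()].
#'
#' @param values Numeric matrix, genes in rows, conditions in columns.
#'   `NA` entries mark missing measurements; all other entries must be finite.
#' @param gene_ids,condition_ids Character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return An object of class `ExpressionMatrix`: a list with element
#'   `values` (named numeric matrix).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              condition_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(gene_ids) || is.null(condition_ids)) {
    stopf("gene and condition identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  condition_ids <- as.character(condition_ids)
  if (length(gene_ids) != nrow(values) || length(condition_ids) != ncol(values)) {
    stopf("identifier lengths do not match matrix dimensions")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stopf("duplicate gene ID: %s", dup[[1L]])
  dup <- condition_ids[duplicated(condition_ids)]
  if (length(dup)) stopf("duplicate condition ID: %s", dup[[1L]])
  if (any(is.infinite(values))) stopf("non-finite expression values present")
  dimnames(values) <- list(gene_ids, condition_ids)
  structure(list(values = values), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d conditions (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m An `ExpressionMatrix`.
#' @export
missing_mask <- function(m) is.na(m$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
condition_ids <- function(m) colnames(m$values)

#' Preprocessing configuration
#'
#' @param knn_k Neighbours used by [knn_impute()] (>= 1).
#' @param variance_threshold Minimum observed-value variance a gene must show
#'   to survive [filter_genes()]; 0 disables the variance filter.
#' @param max_missing_fraction Maximum tolerated fraction of missing values
#'   per gene, in `[0, 1]`.
#' @param discretization_levels Number of equal-frequency bins used by
#'   [discretize_quantile()] (>= 2).
#' @return A `PreprocessConfig` list.
#' @export
preprocess_config <- function(knn_k = 10, variance_threshold = 0,
                              max_missing_fraction = 1,
                              discretization_levels = 3) {
  if (knn_k < 1) stopf("knn_k must be >= 1")
  if (variance_threshold < 0) stopf("variance_threshold must be >= 0")
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stopf("max_missing_fraction must lie in [0, 1]")
  }
  if (discretization_levels < 2) stopf("discretization_levels must be >= 2")
  structure(list(knn_k = as.integer(knn_k),
                 variance_threshold = variance_threshold,
                 max_missing_fraction = max_missing_fraction,
                 discretization_levels = as.integer(discretization_levels)),
            class = "PreprocessConfig")
}

MISSING_TOKENS <- c("", "na", "nan")

#' Read an expression matrix from TSV
#'
#' Expects a header row `GENE<TAB>cond1<TAB>...` followed by one row per gene.
#' Empty cells, `NA` and `NaN` (case-insensitive) mark missing values.
#'
#' @param path Path to a tab-delimited file.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 1L]
  if (length(lines) < 1L) stopf("empty expression file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  conds <- header[-1L]
  if (!length(conds)) stopf("header row has no condition IDs")
  n_col <- length(header)
  genes <- character(length(fields) - 1L)
  vals <- matrix(NA_real_, length(fields) - 1L, length(conds))
  for (i in seq_along(fields)[-1L]) {
    f <- fields[[i]]
    if (length(f) != n_col) {
      stopf("ragged row at line %d: expected %d fields, found %d",
            i, n_col, length(f))
    }
    genes[i - 1L] <- f[[1L]]
    cells <- trimws(f[-1L])
    miss <- tolower(cells) %in% MISSING_TOKENS
    num <- suppressWarnings(as.numeric(cells))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      stopf("cannot parse value '%s' at line %d", cells[bad][[1L]], i)
    }
    num[miss] <- NA_real_
    vals[i - 1L, ] <- num
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) stopf("duplicate gene ID: %s", dup[[1L]])
  expression_matrix(vals, genes, conds)
}

#' Write an expression matrix as TSV
#'
#' Emits the dialect read by [read_expression_tsv()] (`GENE` header corner,
#' missing values written as `NA`). Output is byte-stable for a given matrix.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  V <- m$values
  txt <- matrix(vapply(V, function(x) {
    if (is.na(x)) "NA" else format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1L)), nrow(V), ncol(V))
  rows <- c(paste(c("GENE", colnames(V)), collapse = "\t"),
            paste(rownames(V), apply(txt, 1L, paste, collapse = "\t"),
                  sep = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Gene-wise KNN imputation: for a gene with a missing measurement, the k
#' nearest gene rows (Euclidean distance over mutually observed conditions,
#' scaled by the number of shared conditions) that carry an observed value in
#' the target condition are averaged, unweighted.
#'
#' @param m An `ExpressionMatrix`.
#' @param k Number of neighbours (>= 1); if fewer neighbours are eligible,
#'   all of them are used and a warning is emitted.
#' @return An `ExpressionMatrix` with no missing values. Observed entries are
#'   never altered.
#' @export
knn_impute <- function(m, k = 10) {
  if (k < 1) stopf("k must be >= 1")
  V <- m$values
  obs <- !is.na(V)
  empty <- rowSums(obs) == 0L
  if (any(empty)) {
    stopf("gene with no observed values: %s", rownames(V)[which(empty)[1L]])
  }
  if (all(obs)) return(m)
  out <- V
  for (i in which(rowSums(!obs) > 0L)) {
    xi <- V[i, ]
    sq <- (V - matrix(xi, nrow(V), ncol(V), byrow = TRUE))^2
    nshared <- rowSums(!is.na(sq))
    d <- sqrt(rowSums(sq, na.rm = TRUE) / nshared)
    d[i] <- Inf
    d[nshared == 0L] <- Inf
    for (j in which(!obs[i, ])) {
      elig <- which(obs[, j] & is.finite(d))
      if (!length(elig)) {
        stopf("cannot impute %s at %s: no eligible neighbour",
              rownames(V)[i], colnames(V)[j])
      }
      if (length(elig) < k) {
        warnf("only %d eligible neighbours (< k = %d) for %s at %s",
              length(elig), k, rownames(V)[i], colnames(V)[j])
      }
      nb <- elig[order(d[elig], elig)][seq_len(min(k, length(elig)))]
      out[i, j] <- mean(V[nb, j])
    }
  }
  expression_matrix(out)
}

#' Remove genes with no significant expression changes
#'
#' Keeps genes whose observed-value variance is at least
#' `cfg$variance_threshold` and whose missing fraction is at most
#' `cfg$max_missing_fraction`. Gene order and conditions are preserved.
#'
#' @param m An `ExpressionMatrix`.
#' @param cfg A [preprocess_config()].
#' @return Filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(m, cfg = preprocess_config()) {
  V <- m$values
  v <- apply(V, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  mf <- rowMeans(is.na(V))
  keep <- v >= cfg$variance_threshold & mf <= cfg$max_missing_fraction
  if (!any(keep)) {
    stopf("all genes removed by filtering; reduce variance_threshold (%g) or raise max_missing_fraction (%g)",
          cfg$variance_threshold, cfg$max_missing_fraction)
  }
  expression_matrix(V[keep, , drop = FALSE])
}

#' Discrete (binned) expression matrix
#'
#' @param states Integer matrix of states in `0 ... levels - 1`, genes in
#'   rows, samples/conditions in columns, with dimnames.
#' @param levels Number of states (>= 2).
#' @return A `DiscreteMatrix` list.
#' @export
discrete_matrix <- function(states, levels) {
  if (!is.matrix(states)) stopf("`states` must be a matrix")
  if (levels < 2) stopf("levels must be >= 2")
  if (anyNA(states)) stopf("discrete states may not be missing")
  storage.mode(states) <- "integer"
  if (any(states < 0L) || any(states >= levels)) {
    stopf("states must lie in 0 ... levels - 1")
  }
  if ((nrow(states) > 0L && is.null(rownames(states))) ||
      (ncol(states) > 0L && is.null(colnames(states)))) {
    stopf("states matrix requires gene and condition dimnames")
  }
  structure(list(states = states, levels = as.integer(levels)),
            class = "DiscreteMatrix")
}

#' @export
print.DiscreteMatrix <- function(x, ...) {
  cat(sprintf("DiscreteMatrix: %d genes x %d samples, %d levels\n",
              nrow(x$states), ncol(x$states), x$levels))
  invisible(x)
}

#' Per-gene equal-frequency discretization
#'
#' Assigns each gene's values to `levels` equal-frequency bins by rank.
#' Equal values always share the lower bin, so a constant gene maps to all
#' zeros and the binning is invariant to strictly monotone transforms.
#'
#' @param m An `ExpressionMatrix` with no missing values (impute first).
#' @param levels Number of bins (>= 2).
#' @return A [discrete_matrix()].
#' @export
discretize_quantile <- function(m, levels = 3) {
  V <- m$values
  if (anyNA(V)) stopf("matrix contains missing values; run knn_impute() first")
  if (levels < 2) stopf("levels must be >= 2")
  n <- ncol(V)
  states <- matrix(0L, nrow(V), n, dimnames = dimnames(V))
  for (i in seq_len(nrow(V))) {
    r <- rank(V[i, ], ties.method = "min")
    states[i, ] <- pmin(floor((r - 1L) * levels / n), levels - 1L)
  }
  discrete_matrix(states, levels)
}
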