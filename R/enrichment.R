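#' Gene-to-term annotation map
#'
#' @param pairs Two-column data frame or matrix of (gene, term) pairs.
#' @param population Character vector: the background gene set. Pairs whose
#'   gene is outside the population are dropped.
#' @return An `AnnotationMap`: list with `gene_to_terms`, `term_to_genes`
#'   and `population`.
#' @export
annotation_map <- function(pairs, population) {
  population <- unique(as.character(population))
  g <- as.character(pairs[[1L]])
  t <- as.character(pairs[[2L]])
  keep <- g %in% population
  dropped <- sum(!keep)
  if (dropped) {
    message(sprintf("annotation_map: %d pair(s) outside the population ignored",
                    dropped))
  }
  g <- g[keep]
  t <- t[keep]
  key <- !duplicated(paste0(g, "\r", t))
  g <- g[key]
  t <- t[key]
  structure(list(
    gene_to_terms = split(t, factor(g, levels = unique(g))),
    term_to_genes = split(g, factor(t, levels = unique(t))),
    population = population), class = "AnnotationMap")
}

#' @export
print.AnnotationMap <- function(x, ...) {
  cat(sprintf("AnnotationMap: %d annotated genes, %d terms, population %d\n",
              length(x$gene_to_terms), length(x$term_to_genes),
              length(x$population)))
  invisible(x)
}

#' Read gene annotations (two-column TSV or GAF 2.x)
#'
#' TSV: two tab-separated columns (gene ID, term ID); `#` comments allowed.
#' GAF: detected by `!` header lines or >= 15 tab-separated fields; columns
#' 2 (gene) and 5 (term) are used and rows whose qualifier contains `NOT`
#' are skipped.
#'
#' @param path File path.
#' @param population Background gene set the map is restricted to.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, population) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  is_gaf <- any(grepl("^!", lines)) ||
    (length(lines) && length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]) >= 15L)
  genes <- character(0)
  terms <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || grepl("^[!#]", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (is_gaf) {
      if (length(f) < 15L) stopf("malformed GAF line %d: %d fields", i, length(f))
      if (grepl("NOT", f[[4L]])) next
      genes <- c(genes, f[[2L]])
      terms <- c(terms, f[[5L]])
    } else {
      if (length(f) != 2L) stopf("malformed annotation line %d: expected 2 fields, found %d",
                                 i, length(f))
      genes <- c(genes, f[[1L]])
      terms <- c(terms, f[[2L]])
    }
  }
  annotation_map(data.frame(gene = genes, term = terms), population)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a population of `N` genes of which `K` carry the annotation.
#'
#' @param k Annotated genes observed in the draw.
#' @param n Number of genes drawn.
#' @param K Annotated genes in the population.
#' @param N Population size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (k < 0 || k > n || n > N || k > K || K > N) {
    stopf("invalid hypergeometric arguments: k=%d n=%d K=%d N=%d", k, n, K, N)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric term enrichment of a bicluster
#'
#' Tests every term annotating at least one bicluster gene for
#' over-representation against the annotation map's population. Only
#' bicluster genes inside the population are counted.
#'
#' @param b A [bicluster()].
#' @param a An [annotation_map()].
#' @param alpha Significance level used to flag significant terms.
#' @param correction Multiple-testing correction over the tested terms:
#'   `"none"` (default; the comparison methodology sweeps raw significance
#'   levels) or `"bonferroni"`.
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`, `p_value`,
#'   `significant`, sorted by ascending p-value (ties by term ID).
#' @export
enrich_bicluster <- function(b, a, alpha = 0.05,
                             correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      significant = logical(0))
  genes <- intersect(b$genes, a$population)
  if (!length(genes)) {
    warnf("bicluster shares no genes with the annotation population")
    return(empty)
  }
  N <- length(a$population)
  n <- length(genes)
  terms <- sort(unique(unlist(a$gene_to_terms[intersect(genes, names(a$gene_to_terms))],
                              use.names = FALSE)))
  if (!length(terms)) return(empty)
  res <- lapply(terms, function(tm) {
    tg <- a$term_to_genes[[tm]]
    k <- length(intersect(genes, tg))
    K <- length(tg)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p_value = hypergeom_pvalue(k, n, K, N))
  })
  res <- do.call(rbind, res)
  if (correction == "bonferroni") {
    res$p_value <- stats::p.adjust(res$p_value, method = "bonferroni")
  }
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

bicluster_is_enriched <- function(b, a, alpha, filtered = FALSE) {
  genes <- intersect(b$genes, a$population)
  if (!length(genes)) return(FALSE)
  if (filtered) {
    annotated <- sum(b$genes %in% names(a$gene_to_terms))
    if (annotated < length(b$genes) / 2) return(FALSE)
  }
  e <- suppressWarnings(enrich_bicluster(b, a, alpha))
  any(e$p_value < alpha)
}

#' Percentage of enriched biclusters per algorithm and significance level
#'
#' The core biclustering-comparison metric: for each algorithm and each
#' level `alpha`, the percentage of its biclusters containing at least one
#' term with `p < alpha`. With `filtered = TRUE` the numerator additionally
#' requires at least half of the bicluster's genes to carry at least one
#' annotation, penalising algorithms whose enriched biclusters contain few
#' annotated genes.
#'
#' @param sets Named list mapping algorithm name to `BiclusterSet`.
#' @param a An [annotation_map()].
#' @param levels Numeric vector of significance levels in (0, 1).
#' @param filtered Apply the annotated-fraction filtration?
#' @return A `ComparisonReport`: data frame with columns `algorithm`,
#'   `alpha`, `percent`, `filtered`.
#' @export
percent_enriched <- function(sets, a, levels = c(0.01, 0.05), filtered = FALSE) {
  if (!length(levels) || any(levels <= 0 | levels >= 1)) {
    stopf("significance levels must lie in (0, 1)")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stopf("`sets` must be a named list of BiclusterSet objects")
  }
  rows <- list()
  for (alg in names(sets)) {
    s <- sets[[alg]]
    nb <- length(s$biclusters)
    if (!nb) warnf("algorithm %s produced no biclusters; reporting 0%%", alg)
    for (al in levels) {
      pct <- if (!nb) 0 else {
        100 * sum(vapply(s$biclusters, bicluster_is_enriched, logical(1L),
                         a = a, alpha = al, filtered = filtered)) / nb
      }
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, alpha = al, percent = pct, filtered = filtered)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ComparisonReport", class(out))
  out
}

#' Pattern-recovery table
#'
#' For each algorithm and each target term: the maximum, over the
#' algorithm's biclusters, of the number of bicluster genes annotated to
#' the term. Maxima below 2 are floored to 0, so isolated single-gene hits
#' are not reported as recovered patterns.
#'
#' @param sets Named list mapping algorithm name to `BiclusterSet`.
#' @param a An [annotation_map()].
#' @param target_terms Character vector of term IDs present in `a`.
#' @return Integer matrix, terms x algorithms.
#' @export
pattern_recovery <- function(sets, a, target_terms) {
  unknown <- setdiff(target_terms, names(a$term_to_genes))
  if (length(unknown)) stopf("unknown term: %s", unknown[[1L]])
  out <- matrix(0L, length(target_terms), length(sets),
                dimnames = list(target_terms, names(sets)))
  for (alg in names(sets)) {
    for (tm in target_terms) {
      tg <- a$term_to_genes[[tm]]
      counts <- vapply(sets[[alg]]$biclusters,
                       function(b) length(intersect(b$genes, tg)), integer(1L))
      mx <- if (length(counts)) max(counts) else 0L
      out[tm, alg] <- if (mx < 2L) 0L else mx
    }
  }
  out
}

#' Write a comparison report as TSV
#'
#' @param report A `ComparisonReport` from [percent_enriched()].
#' @param path Output path.
#' @export
write_comparison_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
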