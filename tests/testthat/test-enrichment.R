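test_that("annotation readers handle TSV, GAF and restriction to population", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "g1\tT1", "g2\tT1", "g2\tT2", "gX\tT9"), f)
  expect_message(a <- read_annotations(f, c("g1", "g2", "g3")), "ignored")
  expect_setequal(a$term_to_genes$T1, c("g1", "g2"))
  expect_identical(a$gene_to_terms$g2, c("T1", "T2"))
  expect_false("T9" %in% names(a$term_to_genes))

  writeLines(character(0), f)
  expect_length(read_annotations(f, "g1")$term_to_genes, 0)

  writeLines(c("g1\tT1\textra"), f)
  expect_error(read_annotations(f, "g1"), "line 1")

  # minimal GAF 2.x: 17 columns, qualifier in col 4, gene col 2, term col 5
  gaf_row <- function(gene, term, qual = "") {
    paste(c("SGD", gene, gene, qual, term, "PMID:1", "IDA", "", "P", "", "",
            "gene", "taxon:4932", "20200101", "SGD", "", ""), collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.1", gaf_row("g1", "GO:1"),
               gaf_row("g2", "GO:1", "NOT"), gaf_row("g2", "GO:2")), f)
  a <- read_annotations(f, c("g1", "g2"))
  expect_identical(a$term_to_genes[["GO:1"]], "g1")  # NOT row skipped
  expect_identical(a$term_to_genes[["GO:2"]], "g2")
})

test_that("hypergeometric upper tail matches exhaustive pmf summation", {
  expect_equal(hypergeom_pvalue(3, 4, 5, 20), 155 / 4845, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(0, 4, 5, 20), 1)
  expect_equal(hypergeom_pvalue(5, 20, 5, 20), 1)  # n = N draws everything

  for (N in c(5, 12, 25, 41, 60)) {
    for (K in unique(c(1, floor(N / 3), N - 1))) {
      for (n in unique(c(1, floor(N / 2), N))) {
        ks <- 0:min(n, K)
        p <- vapply(ks, hypergeom_pvalue, numeric(1L), n = n, K = K, N = N)
        o <- vapply(ks, hyper_tail_oracle, numeric(1L), n = n, K = K, N = N)
        expect_equal(p, o, tolerance = 1e-12)
        # monotone non-increasing in k
        expect_true(all(diff(p) <= 1e-15))
      }
    }
  }
  expect_error(hypergeom_pvalue(5, 4, 5, 20), "invalid")
})

test_that("bicluster enrichment counts population-restricted genes", {
  pairs <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5", "g1"),
                      term = c("TA", "TA", "TA", "TB", "TB", "TB"))
  a <- annotation_map(pairs, sprintf("g%d", 1:20))
  b <- bicluster(c("g1", "g2", "g3", "g9"), "c1")
  res <- enrich_bicluster(b, a, 0.05)
  expect_identical(res$term[1], "TA")
  ra <- res[res$term == "TA", ]
  expect_equal(ra$p_value, hyper_tail_oracle(3, 4, 3, 20), tolerance = 1e-12)
  # the term equal to its bicluster attains the minimum possible p for (n,K,N)
  expect_equal(ra$p_value, min(vapply(0:3, hyper_tail_oracle, numeric(1L),
                                      n = 4, K = 3, N = 20)))

  # ties broken by term ID; identical counts give identical p-values
  pairs2 <- data.frame(gene = c("g1", "g2", "g1", "g2"),
                       term = c("T2", "T2", "T1", "T1"))
  a2 <- annotation_map(pairs2, sprintf("g%d", 1:10))
  res2 <- enrich_bicluster(bicluster(c("g1", "g2"), "c1"), a2, 0.05)
  expect_identical(res2$term, c("T1", "T2"))
  expect_equal(res2$p_value[1], res2$p_value[2])

  expect_warning(out <- enrich_bicluster(bicluster("zz", "c1"), a, 0.05),
                 "population")
  expect_identical(nrow(out), 0L)

  # p-values are invariant to the bicluster's condition content
  b2 <- bicluster(c("g3", "g1", "g2", "g9"), c("c5", "c9"))
  expect_equal(enrich_bicluster(b2, a, 0.05)$p_value, res$p_value)

  # optional Bonferroni correction scales by the number of tested terms
  resb <- enrich_bicluster(b, a, 0.05, correction = "bonferroni")
  expect_equal(resb$p_value, pmin(1, res$p_value * nrow(res)))
})

test_that("percent enriched counts biclusters per level with filtration", {
  pop <- sprintf("g%d", 1:40)
  pairs <- data.frame(gene = sprintf("g%d", 1:6),
                      term = rep(c("TA", "TB"), each = 3))
  a <- annotation_map(pairs, pop)
  enriched1 <- bicluster(c("g1", "g2", "g3"), "c1")        # all annotated, tiny p
  enriched2 <- bicluster(c("g4", "g5", "g6"), "c1")
  dull <- bicluster(sprintf("g%d", 11:20), "c1")           # no annotations
  half <- bicluster(c("g1", sprintf("g%d", 21:29)), "c1")  # 1 annotated of 10

  s4 <- bicluster_set(list(enriched1, enriched2, dull, half), c(40, 5))
  rep <- suppressWarnings(percent_enriched(list(alg = s4), a, levels = 0.05))
  # g1 alone in `half` gives p = K/N-ish; check by direct counting
  flags <- vapply(list(enriched1, enriched2, dull, half), function(b) {
    e <- suppressWarnings(enrich_bicluster(b, a, 0.05))
    any(e$p_value < 0.05)
  }, logical(1L))
  expect_equal(rep$percent, 100 * sum(flags) / 4)

  s2 <- bicluster_set(list(enriched1, dull), c(40, 5))
  rep2 <- suppressWarnings(percent_enriched(list(alg = s2), a, levels = 0.05))
  expect_equal(rep2$percent, 50)

  all2 <- bicluster_set(list(enriched1, enriched2), c(40, 5))
  expect_equal(suppressWarnings(
    percent_enriched(list(alg = all2), a, 0.05))$percent, 100)

  # filtration drops biclusters with under half their genes annotated
  repf <- suppressWarnings(percent_enriched(list(alg = s4), a, 0.05,
                                            filtered = TRUE))
  expect_lte(repf$percent, rep$percent)
  s_half <- bicluster_set(list(half), c(40, 5))
  expect_equal(suppressWarnings(
    percent_enriched(list(alg = s_half), a, 0.05, filtered = TRUE))$percent, 0)

  # monotone non-decreasing in alpha
  levels <- c(0.001, 0.01, 0.05, 0.2)
  repl <- suppressWarnings(percent_enriched(list(alg = s4), a, levels))
  expect_true(all(diff(repl$percent[order(repl$alpha)]) >= 0))

  empty <- bicluster_set(list(), c(40, 5))
  expect_warning(rep0 <- percent_enriched(list(alg = empty), a, 0.05),
                 "no biclusters")
  expect_equal(rep0$percent, 0)
})

test_that("pattern recovery reports per-term maxima with the <2 floor", {
  pop <- sprintf("g%d", 1:30)
  pairs <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                      term = c("TA", "TA", "TA", "TB", "TC"))
  a <- annotation_map(pairs, pop)
  s <- bicluster_set(list(bicluster(c("g1", "g2", "g3", "g9"), "c1"),
                          bicluster(c("g4", "g5"), "c1")), c(30, 4))
  tab <- pattern_recovery(list(alg = s), a, c("TA", "TB", "TC"))
  expect_identical(tab["TA", "alg"], 3L)
  expect_identical(tab["TB", "alg"], 0L)  # single-gene hit floored
  expect_identical(tab["TC", "alg"], 0L)
  expect_error(pattern_recovery(list(alg = s), a, "TZ"), "TZ")
})
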