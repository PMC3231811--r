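test_that("mean squared residue matches the closed form and the literal sum", {
  m <- make_expr(rbind(c(1, 2), c(3, 5)))
  b <- bicluster(gene_ids(m), condition_ids(m))
  expect_equal(mean_squared_residue(m, b), 0.0625)

  # constant and purely additive submatrices have zero residue
  expect_equal(mean_squared_residue(make_expr(matrix(3, 4, 5)),
                                    bicluster(sprintf("g%02d", 1:4),
                                              sprintf("c%02d", 1:5))), 0)
  r <- c(1, 4, -2)
  cc <- c(0, 2, 5, 1)
  madd <- make_expr(outer(r, cc, `+`))
  expect_equal(mean_squared_residue(madd, bicluster(gene_ids(madd),
                                                    condition_ids(madd))), 0)

  # random submatrices against the literal double-sum oracle
  set.seed(11)
  for (rep in 1:5) {
    V <- matrix(rnorm(42), 6, 7)
    m <- make_expr(V)
    g <- sample(gene_ids(m), 4)
    cn <- sample(condition_ids(m), 5)
    expect_equal(mean_squared_residue(m, bicluster(g, cn)),
                 msr_oracle(V[match(g, gene_ids(m)), match(cn, condition_ids(m))]),
                 tolerance = 1e-12)
  }

  m2 <- make_expr(rbind(c(1, NA), c(2, 3)))
  expect_error(mean_squared_residue(m2, bicluster(c("g01", "g02"), c("c01", "c02"))),
               "missing")
})

test_that("Cheng-Church honours delta, spans perfect matrices, and is seeded", {
  # a purely additive matrix is one perfect bicluster: first result spans it
  madd <- make_expr(outer(c(1, 4, -2, 0), c(0, 2, 5, 1, 3), `+`))
  s <- cc_bicluster(madd, cc_params(delta = 0.5, n_biclusters = 1, rng_seed = 3))
  expect_setequal(s$biclusters[[1]]$genes, gene_ids(madd))
  expect_setequal(s$biclusters[[1]]$conditions, condition_ids(madd))

  expect_length(cc_bicluster(madd, cc_params(n_biclusters = 0))$biclusters, 0)
  expect_error(cc_bicluster(make_expr(matrix(1:2, 1, 2)), cc_params()),
               "2 x 2")

  set.seed(5)
  m <- make_expr(matrix(rnorm(40 * 20), 40, 20))
  p <- cc_params(delta = 0.5, alpha = 1.2, n_biclusters = 8, rng_seed = 9)
  s1 <- cc_bicluster(m, p)
  # contract: every bicluster satisfies the delta bound on the working matrix
  # it was discovered in (recorded as its score); the first bicluster is found
  # before any masking, so its bound also holds on the original matrix
  for (b in s1$biclusters) {
    expect_lte(b$score, 0.5 + 1e-12)
    expect_true(all(b$genes %in% gene_ids(m)))
    expect_true(all(b$conditions %in% condition_ids(m)))
  }
  expect_lte(mean_squared_residue(m, s1$biclusters[[1]]), 0.5 + 1e-12)
  # bit-reproducible under the seed
  s2 <- cc_bicluster(m, p)
  expect_identical(s1, s2)
})

test_that("ISA recovers a planted module exactly and returns fixed points", {
  sp <- plant_spec(100, 40, 1,
                   blocks = list(list(n_genes = 15, n_conditions = 10,
                                      pattern = "constant", amplitude = 4)),
                   rng_seed = 2)
  sim <- simulate_expression(sp)
  truth <- sim$truth$biclusters[[1]]
  s <- isa_bicluster(sim$matrix, isa_params(2, 2, n_seeds = 100, rng_seed = 2))
  expect_true(any(vapply(s$biclusters,
                         function(b) setequal(b$genes, truth$genes),
                         logical(1L))))

  # every returned module is a fixed point of one signature iteration
  V <- sim$matrix$values
  Er <- bicgrn:::standardize_rows(V)
  Ec <- bicgrn:::standardize_cols(V)
  for (b in s$biclusters[seq_len(min(5, length(s$biclusters)))]) {
    G <- match(b$genes, rownames(V))
    st <- bicgrn:::isa_step(sort(G), Er, Ec, 2, 2, orientation = b$score)
    expect_setequal(rownames(V)[st$G], b$genes)
    expect_setequal(colnames(V)[st$C], b$conditions)
  }

  # no two retained modules exceed the dedup threshold
  if (length(s$biclusters) > 1) {
    gs <- lapply(s$biclusters, `[[`, "genes")
    for (i in seq_along(gs)[-1]) {
      for (j in seq_len(i - 1)) {
        expect_lt(jaccard(gs[[i]], gs[[j]]), 0.9)
      }
    }
  }

  # determinism and degenerate cases
  expect_identical(isa_bicluster(sim$matrix, isa_params(2, 2, 20, rng_seed = 4)),
                   isa_bicluster(sim$matrix, isa_params(2, 2, 20, rng_seed = 4)))
  zero <- make_expr(matrix(0, 10, 8))
  expect_length(isa_bicluster(zero, isa_params(2, 2, 10))$biclusters, 0)
  expect_error(isa_bicluster(zero, isa_params(t_g = 0)), "positive")
})

test_that("OPSM returns strictly increasing models and matches exhaustive search", {
  # 3 increasing rows + 1 decreasing row: identity order over all 4 columns
  V <- rbind(1:4, c(1, 3, 5, 7), c(2, 4, 6, 8), c(9, 6, 4, 2))
  m <- make_expr(V)
  s <- opsm_bicluster(m, opsm_params(100))
  four <- Filter(function(b) length(b$conditions) == 4, s$biclusters)
  expect_length(four, 1)
  expect_identical(four[[1]]$conditions, condition_ids(m))
  expect_setequal(four[[1]]$genes, gene_ids(m)[1:3])

  # identical increasing rows support the full matrix
  mfull <- make_expr(matrix(rep(1:5, each = 3), 3, 5))
  sf <- opsm_bicluster(mfull, opsm_params(10))
  top <- Filter(function(b) length(b$conditions) == 5, sf$biclusters)
  expect_setequal(top[[1]]$genes, gene_ids(mfull))

  expect_error(opsm_bicluster(make_expr(matrix(1:3, 3, 1)), opsm_params()),
               "at least 2")

  set.seed(23)
  for (rep in 1:4) {
    nr <- sample(3:5, 1)
    nc <- sample(4:5, 1)
    V <- matrix(sample(100, nr * nc), nr, nc)
    m <- make_expr(V)
    s <- opsm_bicluster(m, opsm_params(200))  # beam wide enough to be complete
    oracle <- opsm_best_support_oracle(V)
    for (b in s$biclusters) {
      ci <- match(b$conditions, condition_ids(m))
      # each included row strictly increases along the model's column order
      for (g in b$genes) {
        row <- V[match(g, gene_ids(m)), ]
        expect_true(all(diff(rank(row, ties.method = "first")[ci]) > 0))
      }
      # top model support per size equals the exhaustive maximum
      expect_identical(length(b$genes), as.integer(oracle[length(ci)]))
    }
  }
})

test_that("k-means biclusters partition the genes and span all conditions", {
  V <- rbind(matrix(0, 4, 6), matrix(10, 3, 6)) + matrix(rnorm(42, 0, 0.01), 7, 6)
  m <- make_expr(V)
  s <- suppressWarnings(kmeans_as_biclusters(m, kmeans_params(2, 50, 5, rng_seed = 3)))
  expect_length(s$biclusters, 2)
  sets <- lapply(s$biclusters, `[[`, "genes")
  expect_setequal(unlist(sets), gene_ids(m))
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  grp <- Filter(function(b) "g01" %in% b$genes, s$biclusters)[[1]]
  expect_setequal(grp$genes, gene_ids(m)[1:4])
  for (b in s$biclusters) expect_identical(b$conditions, condition_ids(m))

  one <- suppressWarnings(kmeans_as_biclusters(m, kmeans_params(1, 10, 2)))
  expect_setequal(one$biclusters[[1]]$genes, gene_ids(m))

  expect_error(kmeans_as_biclusters(m, kmeans_params(50)), "exceeds")
  p <- kmeans_params(2, 50, 5, rng_seed = 11)
  expect_identical(suppressWarnings(kmeans_as_biclusters(m, p)),
                   suppressWarnings(kmeans_as_biclusters(m, p)))
})

test_that("bicluster text format round-trips and validates identifiers", {
  m <- make_expr(matrix(rnorm(20), 4, 5))
  s <- bicluster_set(list(bicluster(c("g01", "g03"), c("c02", "c05"), "ext"),
                          bicluster("g02", c("c01", "c03", "c04"), "ext")),
                     dim(m$values))
  f <- withr::local_tempfile()
  write_biclusters(s, f, source = "ext")
  s2 <- import_external_biclusters(f, m)
  expect_identical(s2, s)

  writeLines("#source=none", f)
  expect_length(import_external_biclusters(f, m)$biclusters, 0)

  writeLines(c("#source=x", "g01 gZZ", "c01", ""), f)
  expect_error(import_external_biclusters(f, m), "gZZ")
})

test_that("bicluster statistics report counts, sizes and coverages", {
  m <- make_expr(matrix(0, 4, 10))
  s <- bicluster_set(list(bicluster(c("g01", "g02"), c("c01", "c02")),
                          bicluster(c("g02", "g03"), sprintf("c%02d", 1:10))),
                     c(4, 10))
  st <- bicluster_stats(s)
  expect_identical(st$n_biclusters, 2L)
  expect_equal(st$gene_coverage, 75)  # union {g01,g02,g03} of 4
  expect_equal(st$condition_coverage, 100)
  expect_equal(unname(st$min_dims), c(2, 2))
  expect_equal(unname(st$max_dims), c(2, 10))

  empty <- bicluster_stats(bicluster_set(list(), c(4, 10)))
  expect_identical(empty$n_biclusters, 0L)
  expect_equal(empty$gene_coverage, 0)

  full <- bicluster_stats(bicluster_set(
    list(bicluster(sprintf("g%02d", 1:4), sprintf("c%02d", 1:10))), c(4, 10)))
  expect_equal(full$gene_coverage, 100)
  expect_equal(full$condition_coverage, 100)
})
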