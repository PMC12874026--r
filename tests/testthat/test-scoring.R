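test_that("rank and sum scorers match literal brute-force recomputation", {
  for (seed in 1:20) {
    x <- random_em(10, 8, seed = seed)
    set.seed(seed + 100)
    set_genes <- toupper(sample(x$gene_ids, sample(3:5, 1)))
    gs <- gene_set("S", set_genes)

    got <- score_ssgsea(x, gs, alpha = 0.25, min_genes = 1)$scores[, 1]
    want <- vapply(seq_len(8), function(j) {
      oracle_ssgsea_one(x$values[, j], x$gene_ids, gs$genes, 0.25)
    }, numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-9)

    got0 <- score_ssgsea(x, gs, alpha = 0, min_genes = 1)$scores[, 1]
    want0 <- vapply(seq_len(8), function(j) {
      oracle_ssgsea_one(x$values[, j], x$gene_ids, gs$genes, 0)
    }, numeric(1))
    expect_equal(unname(got0), want0, tolerance = 1e-9)

    got <- score_aucell(x, gs, top_frac = 0.5)$scores[, 1]
    want <- vapply(seq_len(8), function(j) {
      oracle_aucell_one(x$values[, j], x$gene_ids, gs$genes, 0.5)
    }, numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-9)

    got <- score_scse(x, gs)$scores[, 1]
    want <- vapply(seq_len(8), function(j) {
      oracle_scse_one(x$values[, j], x$gene_ids, gs$genes)
    }, numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-9)

    xz <- x
    xz$values[xz$values < 0.4] <- 0   # introduce dropout for jasmine
    got <- score_jasmine(xz, gs, min_genes = 1)$scores[, 1]
    want <- oracle_jasmine(xz$values, xz$gene_ids, gs$genes)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("ssGSEA reproduces the hand-computed 4-gene running sum", {
  # ranking g1 > g2 > g3 > g4, set {g1,g2}, alpha 0:
  # P_in steps .5,1,1,1; P_out steps 0,0,.5,1; ES = .5 + 1 + .5 + 0 = 2
  x <- make_em(matrix(c(4, 3, 2, 1), 4, 1))
  gs <- gene_set("S", c("G1", "G2"))
  expect_equal(unname(score_ssgsea(x, gs, alpha = 0, min_genes = 1)$scores[, 1]), 2)
  expect_error(score_ssgsea(x, gene_set("ALL", paste0("G", 1:4)), min_genes = 1),
               "covers every gene")
})

test_that("AUCell matches hand-enumerated recovery curves and extremes", {
  # 10 genes, set at descending ranks 3 and 7, top half: hits 0,0,1,1,1 -> 3;
  # max area min(r,2): 1+2+2+2+2 = 9
  v <- 10:1
  x <- make_em(matrix(v, 10, 1))
  gs <- gene_set("S", c("G3", "G7"))
  expect_equal(unname(score_aucell(x, gs, top_frac = 0.5)$scores[, 1]), 3 / 9)

  # all set genes on top -> maximal score 1
  gs_top <- gene_set("TOP", c("G1", "G2"))
  expect_equal(unname(score_aucell(x, gs_top, top_frac = 0.5)$scores[, 1]), 1)

  # no set gene within the top fraction -> 0
  gs_bot <- gene_set("BOT", c("G9", "G10"))
  expect_equal(unname(score_aucell(x, gs_bot, top_frac = 0.2)$scores[, 1]), 0)
})

test_that("SCSE is a percentage of total expression and scale-invariant", {
  x <- make_em(matrix(c(2, 3, 10, 5, 1, 2, 3, 4), 4, 2))
  gs <- gene_set("S", c("G1", "G2"))
  expect_equal(unname(score_scse(x, gs)$scores[, 1]), c(25, 30))

  all_gs <- gene_set("ALL", paste0("G", 1:4))
  expect_equal(unname(score_scse(x, all_gs)$scores[, 1]), c(100, 100))

  x2 <- x
  x2$values[, 2] <- x2$values[, 2] * 7   # per-sample rescale
  expect_equal(score_scse(x2, gs)$scores[, 1], score_scse(x, gs)$scores[, 1])
})

test_that("JASMINE matches the hand-computed 6-gene pipeline", {
  vals <- cbind(s1 = c(5, 3, 0, 1, 0, 2),
                s2 = c(0, 1, 2, 3, 4, 0),
                s3 = c(6, 5, 4, 3, 2, 1))
  x <- make_em(vals, genes = paste0("g", 1:6))
  gs <- gene_set("S", c("G1", "G2"))
  got <- unname(score_jasmine(x, gs, min_genes = 1)$scores[, 1])
  expect_equal(got, c(0.96875, 0, 0.5138888888888888), tolerance = 1e-12)

  # identical samples score identically
  x2 <- make_em(cbind(vals[, 1], vals[, 1], vals[, 3]))
  s2 <- score_jasmine(x2, gs, min_genes = 1)$scores[, 1]
  expect_equal(s2[[1]], s2[[2]])
})

test_that("a sample expressing all and only the set genes maximizes the JASMINE enrichment component", {
  vals <- cbind(s1 = c(3, 2, 0, 0, 0, 0),   # only set genes expressed
                s2 = c(1, 2, 3, 4, 0, 0),
                s3 = c(0, 1, 2, 3, 4, 5))
  gs <- gene_set("S", c("G1", "G2"))
  ors <- apply(vals, 2, function(v) {
    inset <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
    a <- sum(inset & v > 0); b <- sum(inset & v == 0)
    cc <- sum(!inset & v > 0); d <- sum(!inset & v == 0)
    ((a + 0.5) / (b + 0.5)) / ((cc + 0.5) / (d + 0.5))
  })
  expect_equal(which.max(ors), 1L, ignore_attr = TRUE)
  x <- make_em(vals, genes = paste0("g", 1:6))
  sc <- score_jasmine(x, gs, min_genes = 1)$scores[, 1]
  expect_gt(sc[[1]], sc[[2]])
})

test_that("scorers are invariant under gene and sample permutations", {
  x <- random_em(12, 9, seed = 5)
  x$values[x$values < 0.3] <- 0
  gs <- gene_set("S", toupper(x$gene_ids[c(2, 5, 8, 11)]))
  set.seed(6)
  gp <- sample(nrow(x$values))
  sp <- sample(ncol(x$values))
  xp <- make_em(x$values[gp, sp], genes = x$gene_ids[gp],
                samples = x$sample_ids[sp])
  for (fn in list(function(z) score_ssgsea(z, gs, min_genes = 1),
                  function(z) score_aucell(z, gs),
                  function(z) score_scse(z, gs),
                  function(z) score_jasmine(z, gs, min_genes = 1),
                  function(z) score_nnpca(z, gs, n_components = 1,
                                          min_genes = 1, seed = 1))) {
    a <- fn(x)$scores[, 1]
    b <- fn(xp)$scores[, 1]
    expect_equal(a[x$sample_ids], b[x$sample_ids], tolerance = 1e-9)
  }
})

test_that("rank-based scorers are invariant under strictly monotone transforms; SCSE under rescaling", {
  x <- random_em(15, 7, seed = 9)
  x$values[x$values < 0.3] <- 0
  gs <- gene_set("S", toupper(x$gene_ids[1:4]))
  transforms <- list(function(v) v^2, function(v) 3 * v)
  for (tf in transforms) {
    xt <- make_em(tf(x$values), genes = x$gene_ids, samples = x$sample_ids)
    expect_equal(score_aucell(x, gs)$scores, score_aucell(xt, gs)$scores)
    expect_equal(score_jasmine(x, gs, min_genes = 1)$scores,
                 score_jasmine(xt, gs, min_genes = 1)$scores)
  }
  # ssGSEA's rank weights are monotone-dependent only through ranks
  xt <- make_em(x$values^2, genes = x$gene_ids, samples = x$sample_ids)
  expect_equal(score_ssgsea(x, gs, min_genes = 1)$scores,
               score_ssgsea(xt, gs, min_genes = 1)$scores)
  xs <- x
  xs$values <- sweep(xs$values, 2, c(1, 7, 0.2, 3, 1, 5, 2), "*")
  expect_equal(score_scse(x, gs)$scores, score_scse(xs, gs)$scores)
})

test_that("the score dispatcher wires methods, axes and errors", {
  x <- random_em(20, 10, seed = 2)
  coll <- gene_set_collection(list(gene_set("A", toupper(x$gene_ids[1:5])),
                                   gene_set("B", toupper(x$gene_ids[6:10]))))
  r <- score(x, coll, method = "scse")
  expect_equal(r$axis_names, c("A", "B"))
  expect_equal(dim(r$scores), c(10L, 2L))

  pair <- list(E = gene_set("Epi", toupper(x$gene_ids[1:6])),
               M = gene_set("Mes", toupper(x$gene_ids[7:14])))
  rn <- score(x, pair, method = "nnpca", n_components = 2, min_genes = 5,
              seed = 1)
  expect_equal(rn$axis_names, c("E", "M1", "M2"))
  expect_true(all(names(rn$loadings) == c("E", "M1", "M2")))

  expect_error(score(x, pair, method = "tsne"),
               "unknown scoring method 'tsne'.*nnpca, ssgsea, aucell, scse, jasmine")

  r1 <- score(x, pair, method = "ssgsea", min_genes = 1)
  r2 <- score(x, pair, method = "ssgsea", min_genes = 1)
  expect_identical(r1$scores, r2$scores)
})

test_that("scoring requires log-normalized input and enough matching genes", {
  raw <- make_em(matrix(1:20, 5, 4), normalized = "raw")
  gs <- gene_set("S", c("G1", "G2"))
  expect_error(score_scse(raw, gs), "log-normalized")

  x <- random_em(10, 5, seed = 3)
  small <- gene_set("SMALL", c("G1", "G2"))
  expect_error(score_nnpca(x, small, min_genes = 5),
               "matches only 2 genes.*min_genes = 5")
})
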